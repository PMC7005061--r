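# Ordination of relative vertical wood-density profiles: the trees x
# compartments matrix, scaled PCA, axis orientation, supplementary-variable
# correlations, and the per-tree gradient statistic.

#' Build the trees x compartments relative-WD matrix
#'
#' Pivots the measured compartment table into a trees x 6 matrix of WD_c
#' values and normalizes each row so that tree-level differences in overall
#' WD drop out and only the vertical shape remains: mode
#' \code{"row_mean_ratio"} divides each row by its mean (row means of the
#' output are 1), mode \code{"row_center"} subtracts the row mean (row
#' means are 0). A missing stem base (Ste_b) is imputed as the mean of the
#' tree's stump and stem WD before normalization and flagged; trees with
#' fewer than 5 of the 6 compartments are excluded with a warning.
#'
#' @param compartments measured compartment table with \code{tree_id},
#'   \code{compartment} and \code{WD_c}.
#' @param mode normalization mode, \code{"row_mean_ratio"} (default) or
#'   \code{"row_center"}.
#' @return object of class \code{profile_matrix}: list with \code{matrix}
#'   (trees x 6, rownames = tree ids), \code{mode}, \code{imputed_steb}
#'   (tree ids whose Ste_b was imputed) and \code{excluded} (tree ids
#'   dropped).
#' @export
build_profile_matrix <- function(compartments,
                                 mode = c("row_mean_ratio", "row_center")) {
  mode <- match.arg(mode)
  stop_if_not(all(c("tree_id", "compartment", "WD_c") %in%
                    names(compartments)),
              "compartments must have tree_id, compartment, WD_c")
  wide <- stats::reshape(
    compartments[, c("tree_id", "compartment", "WD_c")],
    idvar = "tree_id", timevar = "compartment", direction = "wide")
  names(wide) <- sub("^WD_c\\.", "", names(wide))
  missing_cols <- setdiff(COMPARTMENTS, names(wide))
  for (mc in missing_cols) wide[[mc]] <- NA_real_
  m <- as.matrix(wide[, COMPARTMENTS])
  rownames(m) <- wide$tree_id

  n_present <- rowSums(!is.na(m))
  excluded <- rownames(m)[n_present < 5L]
  if (length(excluded)) {
    warning(length(excluded), " tree(s) with < 5 compartments excluded: ",
            paste(utils::head(excluded, 5L), collapse = ", "),
            if (length(excluded) > 5L) ", ..." else "", call. = FALSE)
    m <- m[n_present >= 5L, , drop = FALSE]
  }

  # stem base is physically intermediate between stump and stem
  imputed <- character(0L)
  na_steb <- is.na(m[, "Ste_b"])
  if (any(na_steb)) {
    m[na_steb, "Ste_b"] <- (m[na_steb, "Stu"] + m[na_steb, "Ste"]) / 2
    imputed <- rownames(m)[na_steb]
  }
  stop_if_not(!anyNA(m), "unexpected missing compartments after imputation")

  rm_ <- rowMeans(m)
  m <- if (mode == "row_mean_ratio") m / rm_ else m - rm_
  structure(list(matrix = m, mode = mode,
                 imputed_steb = imputed, excluded = excluded),
            class = "profile_matrix")
}

#' Scaled PCA of vertical WD profiles
#'
#' Column-standardized (correlation-matrix) principal component analysis of
#' the relative-WD matrix. Axes are oriented deterministically: the small
#' branch (SB) loading on axis 1 is positive — so trees with relatively
#' dense bases and decreasing profiles score negative on axis 1 — and the
#' stem (Ste) loading on axis 2 is positive; remaining axes have their
#' largest-magnitude loading positive.
#'
#' @param x a \code{profile_matrix} (from [build_profile_matrix()]) or a
#'   plain numeric matrix (trees x compartments).
#' @param n_axes number of axes to retain (default: all columns).
#' @return object of class \code{profile_pca}: list with \code{scores}
#'   (trees x n_axes), \code{loadings} (columns x n_axes),
#'   \code{eigenvalues} (all of them; they sum to the number of columns),
#'   \code{center}, \code{scale}, plus the \code{mode} and imputation flags
#'   when built from a \code{profile_matrix}.
#' @export
run_pca <- function(x, n_axes = NULL) {
  pm <- NULL
  if (inherits(x, "profile_matrix")) {
    pm <- x
    x <- x$matrix
  }
  stop_if_not(is.matrix(x) && is.numeric(x), "x must be a numeric matrix")
  n_axes <- n_axes %||% ncol(x)
  stop_if_not(nrow(x) >= n_axes + 1L,
              "need at least n_axes + 1 rows for the PCA")
  stop_if_not(!anyNA(x), "matrix contains missing values")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s) cannot be standardized: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }

  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  load <- pc$rotation[, seq_len(n_axes), drop = FALSE]
  scores <- pc$x[, seq_len(n_axes), drop = FALSE]

  # deterministic axis orientation
  flip <- rep(1, n_axes)
  if (n_axes >= 1L && "SB" %in% rownames(load) && load["SB", 1L] < 0)
    flip[1L] <- -1
  if (n_axes >= 2L && "Ste" %in% rownames(load) && load["Ste", 2L] < 0)
    flip[2L] <- -1
  if (n_axes >= 3L) {
    for (k in 3:n_axes) {
      if (load[which.max(abs(load[, k])), k] < 0) flip[k] <- -1
    }
  }
  load <- sweep(load, 2L, flip, `*`)
  scores <- sweep(scores, 2L, flip, `*`)
  colnames(load) <- colnames(scores) <- paste0("PC", seq_len(n_axes))

  structure(list(scores = scores, loadings = load, eigenvalues = eig,
                 center = pc$center, scale = pc$scale,
                 mode = pm$mode, imputed_steb = pm$imputed_steb,
                 excluded = pm$excluded),
            class = "profile_pca")
}

#' Correlations of supplementary variables with the PCA axes
#'
#' Pearson correlation (with two-sided p-value) of each wood or structure
#' variable against the first two axis scores, with the usual significance
#' codes (*** p <= 0.001, ** p <= 0.01, * p <= 0.05, ns).
#'
#' @param ordination a \code{profile_pca} from [run_pca()].
#' @param trees tree table carrying the supplementary variables; matched to
#'   the ordination rows by \code{tree_id}.
#' @param variables variables to correlate (default: the standard eight
#'   wood and structure parameters, those present in \code{trees}).
#' @return data.frame with one row per variable: \code{r_axis1},
#'   \code{p_axis1}, \code{sig_axis1}, and the same for axis 2. Constant
#'   variables get NA correlations.
#' @export
supplementary_correlations <- function(ordination, trees,
                                       variables = c("WD_Stu", "WD_GWD",
                                                     "VWWD", "DBH", "H",
                                                     "Ht", "Cr", "Sm")) {
  stop_if_not(inherits(ordination, "profile_pca"),
              "ordination must come from run_pca()")
  stop_if_not(ncol(ordination$scores) >= 2L,
              "need at least two retained axes")
  variables <- intersect(variables, names(trees))
  ids <- rownames(ordination$scores)
  idx <- match(ids, trees$tree_id)
  stop_if_not(!anyNA(idx), "ordination trees missing from the tree table")
  tr <- trees[idx, , drop = FALSE]

  one_axis <- function(v, axis_scores) {
    if (stats::sd(v, na.rm = TRUE) == 0 || all(is.na(v))) {
      return(c(r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(v, axis_scores)
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  rows <- lapply(variables, function(nm) {
    a1 <- one_axis(tr[[nm]], ordination$scores[, 1L])
    a2 <- one_axis(tr[[nm]], ordination$scores[, 2L])
    data.frame(variable = nm,
               r_axis1 = a1[["r"]], p_axis1 = a1[["p"]],
               sig_axis1 = signif_code(a1[["p"]]),
               r_axis2 = a2[["r"]], p_axis2 = a2[["p"]],
               sig_axis2 = signif_code(a2[["p"]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Small-branch vs stump WD difference, in percent of the stump WD
#'
#' 100 * (WD_SB - WD_Stu) / WD_Stu: negative for trees whose wood gets
#' lighter from the base towards the branch tips.
#'
#' @param WD_SB small-branch WD, g cm-3.
#' @param WD_Stu stump WD, g cm-3.
#' @return percent difference. Vectorized.
#' @export
gradient_percent <- function(WD_SB, WD_Stu) {
  stop_if_not(all(WD_Stu > 0), "stump WD must be positive")
  100 * (WD_SB - WD_Stu) / WD_Stu
}
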