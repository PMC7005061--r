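# Guild-level and taxonomic structure of the vertical profiles: one-way
# ANOVA with Tukey HSD, species x site variance partitioning, and
# Blomberg's K phylogenetic signal with a tip-randomization test.

#' One-way analysis of variance
#'
#' Classical between/within decomposition of a numeric response across
#' groups, fitted with \code{stats::aov}.
#'
#' @param values numeric response.
#' @param groups grouping factor (>= 2 groups, each with >= 2 values).
#' @return list with \code{F}, \code{df_between}, \code{df_within},
#'   \code{p}, \code{ss_between}, \code{ss_within}, \code{ss_total} and the
#'   underlying \code{aov} fit.
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  stop_if_not(length(values) == length(groups),
              "values and groups differ in length")
  stop_if_not(nlevels(groups) >= 2L, "need at least 2 groups")
  counts <- table(groups)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    stop("group(s) with fewer than 2 values: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  list(F = tab[1L, "F value"],
       df_between = tab[1L, "Df"],
       df_within = tab[2L, "Df"],
       p = tab[1L, "Pr(>F)"],
       ss_between = tab[1L, "Sum Sq"],
       ss_within = tab[2L, "Sum Sq"],
       ss_total = sum(tab[, "Sum Sq"]),
       fit = fit)
}

# Piepho-style insert-and-absorb compact letter display: groups not
# significantly different must share a letter.
letter_display <- function(levels, sig_pairs) {
  sets <- list(levels)
  if (nrow(sig_pairs)) {
    for (i in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs$g1[i]; b <- sig_pairs$g2[i]
      hit <- vapply(sets, function(s) a %in% s && b %in% s, logical(1L))
      if (!any(hit)) next
      new_sets <- list()
      for (j in seq_along(sets)) {
        if (hit[j]) {
          new_sets <- c(new_sets, list(setdiff(sets[[j]], a)),
                        list(setdiff(sets[[j]], b)))
        } else {
          new_sets <- c(new_sets, sets[j])
        }
      }
      # absorb: drop sets that are subsets of another
      keep <- rep(TRUE, length(new_sets))
      for (j in seq_along(new_sets)) {
        for (k in seq_along(new_sets)) {
          if (j != k && keep[k] &&
              all(new_sets[[j]] %in% new_sets[[k]]) &&
              (length(new_sets[[j]]) < length(new_sets[[k]]) || j > k)) {
            keep[j] <- FALSE
            break
          }
        }
      }
      sets <- new_sets[keep]
    }
  }
  sets <- sets[order(vapply(sets, function(s) min(match(s, levels)),
                            numeric(1L)))]
  out <- stats::setNames(rep("", length(levels)), levels)
  for (j in seq_along(sets)) {
    out[sets[[j]]] <- paste0(out[sets[[j]]], letters[j])
  }
  out
}

#' Tukey honest significant difference test
#'
#' Studentized-range pairwise comparisons after a one-way ANOVA
#' (\code{stats::TukeyHSD}), plus a compact letter display for annotating
#' group plots: groups sharing a letter are not significantly different at
#' \code{alpha}.
#'
#' @inheritParams oneway_anova
#' @param alpha family-wise significance level in (0, 1).
#' @return list with \code{pairs} (data.frame: comparison, diff, lwr, upr,
#'   p_adj) and \code{letters} (named character vector per group).
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  stop_if_not(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  aov_res <- oneway_anova(values, groups)
  tk <- stats::TukeyHSD(aov_res$fit, conf.level = 1 - alpha)$groups
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- data.frame(g1 = vapply(cmp, `[`, "", 1L),
                      g2 = vapply(cmp, `[`, "", 2L),
                      diff = tk[, "diff"],
                      lwr = tk[, "lwr"],
                      upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      row.names = NULL,
                      stringsAsFactors = FALSE)
  lev <- levels(factor(groups))
  sig <- pairs[pairs$p_adj < alpha, c("g1", "g2"), drop = FALSE]
  list(pairs = pairs, letters = letter_display(lev, sig), alpha = alpha)
}

#' Species x site variance partitioning of a trait
#'
#' Sequential (type-I) two-way ANOVA with interaction,
#' \code{trait ~ species * site}, restricted to species occurring in at
#' least \code{min_sites} distinct sites. The variance fraction of each
#' term is its sum of squares over the total.
#'
#' @param values numeric trait (e.g. axis-1 scores), one per tree.
#' @param species,site factors, one per tree.
#' @param min_sites minimum number of distinct sites a species must occupy
#'   to be retained (default 3).
#' @return list with \code{table} (term, df, ss, F, p, fraction),
#'   \code{n_retained}, \code{n_species}, \code{n_sites} and the \code{aov}
#'   fit. If the interaction is inestimable it is dropped with a warning.
#' @export
variance_partition <- function(values, species, site, min_sites = 3L) {
  species <- factor(species)
  site <- factor(site)
  stop_if_not(length(values) == length(species) &&
                length(values) == length(site),
              "values, species and site must have equal length")
  # a species cannot occupy more sites than exist in the data
  eff_min <- min(min_sites, nlevels(site))
  n_sites_sp <- tapply(site, species, function(s) length(unique(s)))
  keep_sp <- names(n_sites_sp)[!is.na(n_sites_sp) & n_sites_sp >= eff_min]
  keep <- species %in% keep_sp
  stop_if_not(length(unique(species[keep])) >= 2L,
              "fewer than 2 species remain after the ",
              eff_min, "-site filter")
  v <- values[keep]
  sp <- droplevels(species[keep])
  st <- droplevels(site[keep])

  if (nlevels(st) < 2L) {
    warning("only one site present; site and interaction variance are 0",
            call. = FALSE)
    fit <- stats::aov(v ~ sp)
    tab <- summary(fit)[[1L]]
    ss_total <- sum(tab[, "Sum Sq"])
    out <- data.frame(
      term = c("species", "site", "residuals"),
      df = c(tab[1L, "Df"], 0L, tab[2L, "Df"]),
      ss = c(tab[1L, "Sum Sq"], 0, tab[2L, "Sum Sq"]),
      F = c(tab[1L, "F value"], NA, NA),
      p = c(tab[1L, "Pr(>F)"], NA, NA),
      fraction = c(tab[1L, "Sum Sq"], 0, tab[2L, "Sum Sq"]) / ss_total,
      stringsAsFactors = FALSE)
    return(list(table = out, n_retained = sum(keep),
                n_species = nlevels(sp), n_sites = 1L, fit = fit))
  } else {
    fit <- stats::aov(v ~ sp * st)
    tab <- summary(fit)[[1L]]
    terms <- trimws(rownames(tab))
    if (!("sp:st" %in% terms) || anyNA(tab[, "Sum Sq"])) {
      warning("interaction inestimable with the available species x site ",
              "cells; dropped", call. = FALSE)
      fit <- stats::aov(v ~ sp + st)
      tab <- summary(fit)[[1L]]
      terms <- trimws(rownames(tab))
    }
  }
  ss_total <- sum(tab[, "Sum Sq"])
  pretty <- c(sp = "species", st = "site", `sp:st` = "species:site",
              Residuals = "residuals")
  out <- data.frame(term = unname(pretty[terms]),
                    df = tab[, "Df"],
                    ss = tab[, "Sum Sq"],
                    F = tab[, "F value"],
                    p = tab[, "Pr(>F)"],
                    fraction = tab[, "Sum Sq"] / ss_total,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  list(table = out, n_retained = sum(keep),
       n_species = nlevels(sp), n_sites = nlevels(st), fit = fit)
}

# Shared machinery for Blomberg's K: phylogenetic covariance pieces that do
# not depend on the trait values, so randomizations are cheap.
k_precompute <- function(phy, tip_order) {
  C <- ape::vcv(phy)
  C <- C[tip_order, tip_order]
  Cinv <- solve(C)
  n <- nrow(C)
  list(Cinv = Cinv,
       sum_cinv = sum(Cinv),
       col_cinv = colSums(Cinv),
       expected = (sum(diag(C)) - n / sum(Cinv)) / (n - 1),
       n = n)
}

k_statistic <- function(trait, pre) {
  ahat <- sum(pre$col_cinv * trait) / pre$sum_cinv
  d <- trait - ahat
  mse0 <- sum(d^2) / (pre$n - 1)
  mse <- drop(crossprod(d, pre$Cinv %*% d)) / (pre$n - 1)
  (mse0 / mse) / pre$expected
}

#' Blomberg's K phylogenetic signal statistic
#'
#' K compares the trait variance among tips (around the phylogenetically
#' corrected GLS mean) with the variance expected under Brownian motion on
#' the tree: the observed MSE0/MSE ratio divided by its Brownian-motion
#' expectation, computed from the phylogenetic variance-covariance matrix
#' of shared branch lengths. K near 1 indicates Brownian-motion-like trait
#' evolution; K near 0, no phylogenetic signal. K is invariant to
#' rescaling all branch lengths by a constant.
#'
#' @param trait named numeric vector, one value per tip; names must match
#'   the tree's tip labels exactly.
#' @param phy an \code{ape} \code{phylo} tree with branch lengths.
#' @return the K statistic (>= 0).
#' @export
blomberg_k <- function(trait, phy) {
  stop_if_not(inherits(phy, "phylo"), "phy must be an ape phylo tree")
  stop_if_not(!is.null(phy$edge.length), "phylogeny has no branch lengths")
  stop_if_not(!is.null(names(trait)), "trait must be named by tip label")
  bad <- c(setdiff(names(trait), phy$tip.label),
           setdiff(phy$tip.label, names(trait)))
  if (length(bad)) {
    stop("trait/tip label mismatch: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  stop_if_not(stats::sd(trait) > 0, "trait has zero variance")
  pre <- k_precompute(phy, phy$tip.label)
  k_statistic(trait[phy$tip.label], pre)
}

#' Tip-randomization p-value for Blomberg's K
#'
#' Shuffles the trait values across the tips \code{n_rand} times and ranks
#' the observed K among the randomized ones:
#' p = (1 + #\{randomized K at least as extreme\}) / (n_rand + 1). The
#' default lower tail treats a K smaller than random as the signal of
#' interest (taxonomic overdispersion); \code{"upper"} tests for
#' conservatism, \code{"two.sided"} doubles the smaller tail.
#'
#' @inheritParams blomberg_k
#' @param n_rand number of tip randomizations (>= 99; default 999).
#' @param seed integer seed for the shuffles.
#' @param tail \code{"lower"}, \code{"upper"} or \code{"two.sided"}.
#' @return list of class \code{phylo_signal}: \code{K}, \code{p},
#'   \code{n_randomizations}, \code{tail}, \code{K_rand}.
#' @export
blomberg_k_pvalue <- function(trait, phy, n_rand = 999L, seed = 1L,
                              tail = c("lower", "upper", "two.sided")) {
  tail <- match.arg(tail)
  stop_if_not(n_rand >= 99L, "use at least 99 randomizations")
  k_obs <- blomberg_k(trait, phy)
  pre <- k_precompute(phy, phy$tip.label)
  y <- unname(trait[phy$tip.label])
  k_rand <- withr::with_seed(seed, {
    vapply(seq_len(n_rand),
           function(i) k_statistic(sample(y), pre),
           numeric(1L))
  })
  p_lo <- (1 + sum(k_rand <= k_obs)) / (n_rand + 1)
  p_hi <- (1 + sum(k_rand >= k_obs)) / (n_rand + 1)
  p <- switch(tail,
              lower = p_lo,
              upper = p_hi,
              two.sided = min(1, 2 * min(p_lo, p_hi)))
  structure(list(K = k_obs, p = p, n_randomizations = n_rand,
                 tail = tail, K_rand = k_rand),
            class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4f, p = %.4g (%s tail, %d randomizations)\n",
              x$K, x$p, x$tail, x$n_randomizations))
  invisible(x)
}
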