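# The volume-weighted wood density estimator and volume-to-biomass
# conversion under alternative WD sources.

#' Compartment contribution to the volume-weighted wood density
#'
#' VWWD_c = WD_c * V_c / V_obs: the compartment's WD weighted by its share
#' of the tree volume. Summing VWWD_c over compartments gives the tree
#' VWWD, the unbiased whole-tree converter of volume to dry biomass.
#'
#' @param WD_c compartment wood density, g cm-3.
#' @param V_c compartment fresh volume, cm3.
#' @param V_obs total tree fresh volume, cm3.
#' @return VWWD_c, g cm-3. Vectorized.
#' @export
compartment_vwwd <- function(WD_c, V_c, V_obs) {
  stop_if_not(all(V_c > 0) && all(V_obs > 0),
              "volumes must be positive")
  stop_if_not(all(V_c <= V_obs * (1 + 1e-12)),
              "compartment volume V_c exceeds tree volume V_obs")
  WD_c * V_c / V_obs
}

#' Tree-level volume-weighted wood density
#'
#' VWWD = sum_c WD_c V_c / sum_c V_c. Multiplying the tree volume V_obs by
#' VWWD returns the reference biomass AGB_obs exactly when compartment dry
#' masses are built from volumes, which is what makes VWWD the unbiased WD
#' choice for volume-to-mass conversion.
#'
#' @param compartments data.frame with columns \code{WD_c} and \code{V_c}
#'   (one row per compartment of a single tree).
#' @return VWWD, g cm-3; always within the range of the compartment WDs.
#' @export
tree_vwwd <- function(compartments) {
  stop_if_not(is.data.frame(compartments) && nrow(compartments) >= 1L,
              "need at least one compartment")
  stop_if_not(all(c("WD_c", "V_c") %in% names(compartments)),
              "compartments must have WD_c and V_c columns")
  v <- compartments$V_c
  stop_if_not(sum(v) > 0, "total compartment volume must be positive")
  sum(compartments$WD_c * v) / sum(v)
}

#' Convert a tree volume to an AGB estimate with a chosen WD
#'
#' AGB_est = V_obs * wd, tagged with the WD source used (species database
#' average, stump WD, exact VWWD, or a model-predicted VWWD).
#'
#' @param V_obs tree volume, cm3.
#' @param wd wood density used for the conversion, g cm-3.
#' @param source label of the WD source, one of \code{"WD_GWD"},
#'   \code{"WD_Stu"}, \code{"VWWD"}, \code{"VWWD_model"}.
#' @param tree_id optional tree id(s) carried through.
#' @return data.frame with \code{tree_id}, \code{wd_source}, \code{AGB_est}
#'   (g). Vectorized over trees.
#' @export
convert_volume_to_agb <- function(V_obs, wd,
                                  source = c("WD_GWD", "WD_Stu", "VWWD",
                                             "VWWD_model"),
                                  tree_id = NULL) {
  source <- match.arg(source)
  stop_if_not(all(V_obs > 0), "tree volume must be positive")
  stop_if_not(all(wd > 0), "wood density must be positive")
  data.frame(tree_id = tree_id %||% seq_along(V_obs),
             wd_source = source,
             AGB_est = V_obs * wd,
             stringsAsFactors = FALSE)
}

#' Look up species database-average WD for trees
#'
#' Exact \code{species_id} match against the species table; missing species
#' are an error unless a fallback constant is supplied.
#'
#' @param trees data.frame with a \code{species_id} column.
#' @param species data.frame with \code{species_id} and \code{WD_GWD}.
#' @param fallback optional WD (g cm-3) used for species absent from the
#'   table; default errors.
#' @return numeric vector of WD_GWD, one per tree.
#' @export
lookup_wd_gwd <- function(trees, species, fallback = NULL) {
  i <- match(trees$species_id, species$species_id)
  wd <- species$WD_GWD[i]
  if (anyNA(wd)) {
    missing_sp <- unique(trees$species_id[is.na(wd)])
    if (is.null(fallback)) {
      stop("species without database WD: ",
           paste(missing_sp, collapse = ", "), call. = FALSE)
    }
    wd[is.na(wd)] <- fallback
  }
  wd
}
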