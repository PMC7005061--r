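# Laboratory and field calculations: from raw wedge-sample and log
# measurements to compartment wood properties, volumes and dry biomass, and
# tree-level totals. All internal units are g, cm, cm3, g cm-3.

#' Wood properties of a wedge sample
#'
#' Computes, per sample, the basic wood density WD = m_d / v_f (g cm-3), the
#' moisture content MC = (m_d - m_f) / m_f (dimensionless, negative since
#' dry mass is below fresh mass) and the fresh biomass-to-volume ratio
#' BV = v_f / m_f (cm3 g-1). Vectorized over samples.
#'
#' @param m_f fresh mass, g.
#' @param v_f fresh volume, cm3.
#' @param m_d oven-dry mass, g.
#' @param strict if \code{TRUE}, a dry mass exceeding its fresh mass is an
#'   error; otherwise a warning.
#' @return data.frame with columns \code{WD}, \code{MC}, \code{BV}.
#' @export
sample_properties <- function(m_f, v_f, m_d, strict = FALSE) {
  stop_if_not(all(m_f > 0) && all(v_f > 0),
              "fresh mass and fresh volume must be positive")
  stop_if_not(all(m_d > 0), "dry mass must be positive")
  if (any(m_d > m_f)) {
    msg <- "dry mass exceeds fresh mass for some sample(s)"
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  data.frame(WD = m_d / v_f,
             MC = (m_d - m_f) / m_f,
             BV = v_f / m_f)
}

#' Truncated-cone (frustum) volume
#'
#' Volume of a log approximated as a truncated cone:
#' V = pi * h / 3 * (r1^2 + r1 r2 + r2^2).
#'
#' @param r1,r2 end radii, cm (either may be 0, giving a full cone).
#' @param h log length, cm.
#' @return volume, cm3. Vectorized.
#' @export
truncated_cone_volume <- function(r1, r2, h) {
  stop_if_not(all(h > 0), "log length h must be positive")
  stop_if_not(all(r1 >= 0) && all(r2 >= 0), "radii must be >= 0")
  pi * h / 3 * (r1^2 + r1 * r2 + r2^2)
}

#' Summarize one tree compartment from its samples and logs
#'
#' Averages the wedge samples (unweighted) into compartment-level WD_c, MC_c
#' and BV_c, then converts each field log: a weighed log's fresh mass gives
#' dry mass \code{fresh_mass * (1 + MC_c)} and fresh volume
#' \code{fresh_mass * BV_c}; a coned log's frustum volume gives dry mass
#' \code{volume * WD_c}; a log of kind \code{"volume"} supplies a
#' precomputed fresh volume directly (e.g. a stump cross-section area times
#' height) and is converted like a coned log. Compartment volume V_c and
#' dry biomass AGB_c are the sums over logs.
#'
#' @param samples data.frame of the compartment's wedge samples with
#'   columns \code{tree_id}, \code{compartment}, \code{m_f}, \code{v_f},
#'   \code{m_d}.
#' @param logs data.frame of the compartment's logs with columns
#'   \code{tree_id}, \code{compartment}, \code{kind} (\code{"weighed"},
#'   \code{"coned"} or \code{"volume"}) and, as required by kind,
#'   \code{fresh_mass} (g), \code{r1}, \code{r2}, \code{h} (cm) or
#'   \code{volume} (cm3). May have zero rows (V_c = AGB_c = 0).
#' @param strict passed to [sample_properties()].
#' @return one-row data.frame: \code{tree_id}, \code{compartment},
#'   \code{WD_c}, \code{MC_c}, \code{BV_c}, \code{V_c}, \code{AGB_c},
#'   \code{n_samples}.
#' @export
summarize_compartment <- function(samples, logs = NULL, strict = FALSE) {
  stop_if_not(is.data.frame(samples) && nrow(samples) >= 1L,
              "at least one wedge sample is required per compartment")
  ids <- unique(samples$tree_id)
  comps <- unique(samples$compartment)
  stop_if_not(length(ids) == 1L && length(comps) == 1L,
              "samples mix several trees or compartments")
  if (!is.null(logs) && nrow(logs)) {
    stop_if_not(all(logs$tree_id == ids) && all(logs$compartment == comps),
                "logs do not belong to the samples' tree/compartment")
  }

  props <- sample_properties(samples$m_f, samples$v_f, samples$m_d,
                             strict = strict)
  wd_c <- mean(props$WD)
  mc_c <- mean(props$MC)
  bv_c <- mean(props$BV)
  stop_if_not(mc_c > -1 && mc_c <= 0,
              "compartment moisture content out of (-1, 0]")

  v_c <- 0
  agb_c <- 0
  if (!is.null(logs) && nrow(logs)) {
    for (i in seq_len(nrow(logs))) {
      kind <- logs$kind[i]
      if (kind == "weighed") {
        stop_if_not(is.finite(logs$fresh_mass[i]) && logs$fresh_mass[i] > 0,
                    "weighed log without a positive fresh mass")
        v <- logs$fresh_mass[i] * bv_c
        m <- logs$fresh_mass[i] * (1 + mc_c)
      } else if (kind == "coned") {
        v <- truncated_cone_volume(logs$r1[i], logs$r2[i], logs$h[i])
        m <- v * wd_c
      } else if (kind == "volume") {
        stop_if_not(is.finite(logs$volume[i]) && logs$volume[i] > 0,
                    "volume log without a positive volume")
        v <- logs$volume[i]
        m <- v * wd_c
      } else {
        stop("unknown log kind: ", kind, call. = FALSE)
      }
      v_c <- v_c + v
      agb_c <- agb_c + m
    }
  }
  data.frame(tree_id = ids, compartment = comps,
             WD_c = wd_c, MC_c = mc_c, BV_c = bv_c,
             V_c = v_c, AGB_c = agb_c,
             n_samples = nrow(samples),
             stringsAsFactors = FALSE)
}

#' Tree-level totals from compartment summaries
#'
#' Sums compartment volumes and dry biomass into V_obs and AGB_obs, takes
#' the stump WD as WD_Stu, computes the tree VWWD (see [tree_vwwd()]) and
#' the stem morphology index Sm = Ht / H.
#'
#' @param compartments data.frame of one tree's compartment summaries (from
#'   [summarize_compartment()]).
#' @param structure one-row data.frame or list with \code{tree_id},
#'   \code{species_id}, \code{site}, \code{DBH} (cm), \code{H}, \code{Ht},
#'   \code{Cr} (m).
#' @return one-row data.frame: ids, structure, \code{Sm}, \code{V_obs}
#'   (cm3), \code{AGB_obs} (g), \code{WD_Stu} and \code{VWWD} (g cm-3).
#' @export
tree_totals <- function(compartments, structure) {
  stop_if_not(is.data.frame(compartments) && nrow(compartments) >= 1L,
              "at least one compartment summary is required")
  stop_if_not(length(unique(compartments$tree_id)) == 1L,
              "compartments mix several trees")
  if (!("Stu" %in% compartments$compartment)) {
    stop("missing stump (Stu) compartment for tree ",
         compartments$tree_id[1L], call. = FALSE)
  }
  stop_if_not(structure$Ht <= structure$H,
              "trunk height Ht exceeds total height H")
  stop_if_not(structure$H > 0, "total height H must be positive")

  v_obs <- sum(compartments$V_c)
  agb_obs <- sum(compartments$AGB_c)
  wd_stu <- compartments$WD_c[compartments$compartment == "Stu"][1L]
  vwwd <- tree_vwwd(compartments)
  data.frame(tree_id = compartments$tree_id[1L],
             species_id = structure$species_id %||% NA_character_,
             site = structure$site %||% NA_character_,
             DBH = structure$DBH, H = structure$H,
             Ht = structure$Ht, Cr = structure$Cr %||% NA_real_,
             Sm = structure$Ht / structure$H,
             V_obs = v_obs, AGB_obs = agb_obs,
             WD_Stu = wd_stu, VWWD = vwwd,
             stringsAsFactors = FALSE)
}

#' Process a whole campaign of samples, logs and tree structures
#'
#' Runs [summarize_compartment()] for every tree x compartment present in
#' the sample table and [tree_totals()] for every tree, returning the
#' measured compartment table and the enriched tree table.
#'
#' @param samples all wedge samples (see [summarize_compartment()]).
#' @param logs all field logs.
#' @param trees tree structure table with one row per tree (\code{tree_id},
#'   \code{species_id}, \code{site}, \code{DBH}, \code{H}, \code{Ht},
#'   \code{Cr}).
#' @param strict passed to [sample_properties()].
#' @return list with \code{compartments} (measured summaries) and
#'   \code{trees} (totals incl. WD_Stu and VWWD).
#' @export
process_field_data <- function(samples, logs, trees, strict = FALSE) {
  stop_if_not(all(trees$tree_id %in% samples$tree_id),
              "some trees have no wedge samples")
  key_s <- interaction(samples$tree_id, samples$compartment, drop = TRUE)
  key_l <- interaction(logs$tree_id, logs$compartment, drop = TRUE)
  comp_list <- lapply(levels(key_s), function(k) {
    s <- samples[key_s == k, , drop = FALSE]
    l <- logs[key_l == k, , drop = FALSE]
    summarize_compartment(s, l, strict = strict)
  })
  comp <- do.call(rbind, comp_list)

  tree_list <- lapply(seq_len(nrow(trees)), function(i) {
    tc <- comp[comp$tree_id == trees$tree_id[i], , drop = FALSE]
    tree_totals(tc, trees[i, , drop = FALSE])
  })
  list(compartments = comp, trees = do.call(rbind, tree_list))
}
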