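# End-to-end orchestration: simulate -> process -> convert -> pca ->
# fit/correct -> crossval -> group/physig -> report, under one seed.

#' Run the full analysis pipeline
#'
#' Executes every stage of the analysis on a simulated campaign: data
#' generation, laboratory/field processing, volume-to-biomass conversion
#' under the alternative WD sources, profile ordination, the m1-m6
#' correction-model table, leave-one-site-out cross-validation (skipped
#' with a logged reason when there is a single site), guild ANOVA with
#' Tukey HSD, species x site variance partitioning, and Blomberg's K on
#' species-mean axis-1 scores. All tables are written as CSV, the headline
#' statistics as \code{report.json}, and a run manifest (config snapshot,
#' seed, file digests, timings, warnings) as \code{manifest.json}.
#'
#' @param config a [sim_config()], a list of its arguments, or the path to
#'   a YAML file holding them.
#' @param out_dir output directory.
#' @param seed optional integer overriding the config seed; every stage
#'   derives its RNG substream from it.
#' @param n_rand tip randomizations for the phylogenetic-signal test.
#' @return invisibly, a list with the \code{report}, the \code{manifest}
#'   and the in-memory stage results.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = NULL,
                         n_rand = 999L) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- as_sim_config(config)
  if (!is.null(seed)) {
    args <- unclass(cfg)
    args$seed <- as.integer(seed)
    cfg <- do.call(sim_config, args)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  notes <- character(0L)
  note <- function(...) notes <<- c(notes, paste0(...))
  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), ts, units = "secs"))
    res
  }

  # -- simulate -------------------------------------------------------------
  dat <- stage("simulate", simulate_dataset(cfg))
  write_dataset(dat, out_dir)

  # -- process --------------------------------------------------------------
  proc <- stage("process", process_field_data(dat$samples, dat$logs,
                                              dat$trees))
  trees <- proc$trees
  trees$WD_GWD <- lookup_wd_gwd(trees, dat$species)
  trees$guild <- dat$species$guild[match(trees$species_id,
                                         dat$species$species_id)]
  utils::write.csv(proc$compartments,
                   file.path(out_dir, "compartments_measured.csv"),
                   row.names = FALSE)

  # -- convert: AGB under the alternative WD sources ------------------------
  conv <- stage("convert", {
    list(WD_GWD = bias_report(trees$V_obs * trees$WD_GWD, trees$AGB_obs),
         WD_Stu = bias_report(trees$V_obs * trees$WD_Stu, trees$AGB_obs),
         VWWD = bias_report(trees$V_obs * trees$VWWD, trees$AGB_obs))
  })

  # -- pca ------------------------------------------------------------------
  pca <- stage("pca", {
    pm <- build_profile_matrix(proc$compartments)
    run_pca(pm)
  })
  if (length(pca$imputed_steb)) {
    note("imputed Ste_b for ", length(pca$imputed_steb), " tree(s)")
  }
  if (length(pca$excluded)) {
    note("excluded ", length(pca$excluded),
         " tree(s) with < 5 compartments from the ordination")
  }
  score_df <- data.frame(tree_id = rownames(pca$scores), pca$scores,
                         stringsAsFactors = FALSE)
  utils::write.csv(score_df, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(compartment = rownames(pca$loadings),
                              pca$loadings),
                   file.path(out_dir, "loadings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(axis = seq_along(pca$eigenvalues),
                              eigenvalue = pca$eigenvalues),
                   file.path(out_dir, "eigenvalues.csv"), row.names = FALSE)
  suppl <- supplementary_correlations(pca, trees)
  utils::write.csv(suppl, file.path(out_dir, "supplementary.csv"),
                   row.names = FALSE)

  trees$PC1 <- pca$scores[match(trees$tree_id, rownames(pca$scores)), 1L]
  utils::write.csv(trees, file.path(out_dir, "trees_measured.csv"),
                   row.names = FALSE)

  # -- fit: the model family ------------------------------------------------
  fits <- stage("fit", lapply(stats::setNames(nm = names(VWWD_MODEL_TERMS)),
                              fit_vwwd_model, data = trees))
  model_table <- do.call(rbind, lapply(fits, function(f) {
    data.frame(model = f$model_id, n = f$n,
               r_squared = f$r_squared, adj_r_squared = f$adj_r_squared,
               model_rse = f$model_rse, aic = f$aic,
               B = f$bias$B, CV = f$bias$CV,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(model_table, file.path(out_dir, "models.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(fits, function(f) {
      list(coefficients = f$coefficients, r_squared = f$r_squared,
           adj_r_squared = f$adj_r_squared, model_rse = f$model_rse,
           aic = f$aic, B = f$bias$B, CV = f$bias$CV)
    }),
    file.path(out_dir, "models.json"), auto_unbox = TRUE, digits = NA)

  # -- crossval -------------------------------------------------------------
  cv <- NULL
  if (length(unique(trees$site)) >= 2L) {
    cv <- stage("crossval", loso_crossval(trees, "m1"))
    utils::write.csv(cv$per_site, file.path(out_dir, "crossval.csv"),
                     row.names = FALSE)
  } else {
    note("crossval skipped: only one site in the data")
  }

  # -- group: guild ANOVA + Tukey, variance partition -----------------------
  grp <- stage("group", {
    ok <- !is.na(trees$PC1)
    an <- oneway_anova(trees$PC1[ok], trees$guild[ok])
    tk <- tukey_hsd(trees$PC1[ok], trees$guild[ok])
    vp <- tryCatch(
      variance_partition(trees$PC1[ok], trees$species_id[ok],
                         trees$site[ok]),
      error = function(e) {
        note("variance partition skipped: ", conditionMessage(e))
        NULL
      })
    list(anova = an, tukey = tk, varpart = vp)
  })
  utils::write.csv(grp$tukey$pairs, file.path(out_dir, "tukey.csv"),
                   row.names = FALSE)

  # -- physig: Blomberg's K on species-mean axis-1 scores -------------------
  physig <- NULL
  if (!is.null(dat$phylogeny)) {
    physig <- stage("physig", {
      sp_mean <- tapply(trees$PC1, trees$species_id, mean, na.rm = TRUE)
      sp_mean <- sp_mean[!is.na(sp_mean)]
      phy <- ape::keep.tip(dat$phylogeny,
                           intersect(dat$phylogeny$tip.label,
                                     names(sp_mean)))
      blomberg_k_pvalue(sp_mean[phy$tip.label], phy, n_rand = n_rand,
                        seed = derive_seed(cfg$seed, "physig"))
    })
    jsonlite::write_json(list(K = physig$K, p = physig$p,
                              n_randomizations = physig$n_randomizations,
                              tail = physig$tail),
                         file.path(out_dir, "physignal.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    note("phylogenetic signal skipped: fewer than 2 species")
  }

  # -- report ---------------------------------------------------------------
  grad <- gradient_from_compartments(proc$compartments)
  report <- list(
    n_trees = nrow(trees),
    n_species = nrow(dat$species),
    n_sites = length(unique(trees$site)),
    fraction_decreasing = mean(grad < 0),
    mean_gradient_percent = mean(grad),
    bias_by_source = lapply(conv, function(b) {
      list(B = b$B, sd_b = b$sd_b, CV = b$CV)
    }),
    b_i_by_source = lapply(conv, function(b) b$b_i),
    pca = list(eigenvalues = pca$eigenvalues,
               r_pc1_wd_stu = suppl$r_axis1[suppl$variable == "WD_Stu"]),
    models = model_table,
    crossval = if (!is.null(cv)) cv$per_site else NULL,
    guild_anova = list(F = grp$anova$F, p = grp$anova$p,
                       df_between = grp$anova$df_between,
                       df_within = grp$anova$df_within),
    tukey_letters = as.list(grp$tukey$letters),
    variance_partition = if (!is.null(grp$varpart)) {
      list(table = grp$varpart$table, n_retained = grp$varpart$n_retained)
    } else NULL,
    phylo_signal = if (!is.null(physig)) {
      list(K = physig$K, p = physig$p)
    } else NULL,
    notes = notes)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  files <- list.files(out_dir, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("woodgrad")),
    seed = cfg$seed,
    config = unclass(cfg),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))),
    timings_sec = timings,
    total_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    warnings = notes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(report = report, manifest = manifest,
                 data = dat, processed = proc, trees = trees,
                 conversions = conv, pca = pca, supplementary = suppl,
                 fits = fits, crossval = cv, grouping = grp,
                 phylo_signal = physig))
}

# Per-tree small-branch vs stump gradient (%) from a compartment table.
gradient_from_compartments <- function(compartments) {
  sb <- compartments[compartments$compartment == "SB", ]
  stu <- compartments[compartments$compartment == "Stu", ]
  wd_col <- if ("WD_c" %in% names(compartments)) "WD_c" else "wd_true"
  i <- match(stu$tree_id, sb$tree_id)
  gradient_percent(sb[[wd_col]][i], stu[[wd_col]])
}
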