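# Synthetic destructive-sampling campaign generator.
#
# The generator emulates the statistical structure of a multi-site tropical
# destructive dataset: a species pool spanning the full tropical WD range,
# trees whose vertical WD profiles are coupled to their basal WD (dense-wood
# trees get lighter upward, light-wood trees denser), compartment volumes
# from a simple taper/crown allometry, and raw field measurements (wedge
# samples, weighed and coned logs) consistent with the underlying truth.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults are
#' the reference study conditions: 51 species, 822 trees, 6 sites, and a
#' gradient-to-basal-WD coupling calibrated so that roughly 83% of trees
#' have a lower small-branch than stump WD with a population mean
#' small-branch-vs-stump difference near -13%.
#'
#' @param n_species number of species in the pool.
#' @param n_trees number of trees.
#' @param n_sites number of sampling sites.
#' @param gradient_slope dimensionless coupling between the vertical WD
#'   slope and basal WD: the expected total stump-to-small-branch WD change
#'   is \code{gradient_slope * (wd_pivot - WD_basal)}, so trees denser than
#'   \code{wd_pivot} decrease upward and lighter trees increase.
#' @param wd_pivot basal WD (g cm-3) at which the expected vertical profile
#'   is flat.
#' @param quad_term optional quadratic term (in relative rank, centered) of
#'   the vertical profile; 0 gives a linear profile.
#' @param slope_sd between-tree SD (g cm-3) of the total vertical WD change.
#' @param basal_sd within-species SD (g cm-3) of tree basal WD around the
#'   species mean.
#' @param noise_sd_wd per-compartment SD (g cm-3) of true WD around the
#'   tree's smooth profile.
#' @param noise_sd_mass relative (lognormal) measurement noise on sample and
#'   log masses/volumes.
#' @param site_sd SD of the additive site intercept on basal WD (g cm-3);
#'   0 mirrors a non-significant site effect.
#' @param drop_stem_base_prob probability that a tree has no separate stem
#'   base compartment (its wood then counted with the stem).
#' @param vol_fractions named mean volume fractions for the six
#'   compartments; must sum to 1.
#' @param dirichlet_conc concentration of the Dirichlet spread of the
#'   per-tree volume fractions around \code{vol_fractions}.
#' @param seed integer seed; all generator functions derive their RNG
#'   substreams from it.
#'
#' @return an object of class \code{sim_config} (a named list).
#' @export
sim_config <- function(n_species = 51L,
                       n_trees = 822L,
                       n_sites = 6L,
                       gradient_slope = 0.41,
                       wd_pivot = 0.38,
                       quad_term = 0,
                       slope_sd = 0.04,
                       basal_sd = 0.04,
                       noise_sd_wd = 0.02,
                       noise_sd_mass = 0.02,
                       site_sd = 0,
                       drop_stem_base_prob = 0.15,
                       vol_fractions = c(Stu = 0.05, Ste_b = 0.05,
                                         Ste = 0.55, LB = 0.20,
                                         MB = 0.10, SB = 0.05),
                       dirichlet_conc = 60,
                       seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              n_trees = as.integer(n_trees),
              n_sites = as.integer(n_sites),
              gradient_slope = gradient_slope,
              wd_pivot = wd_pivot,
              quad_term = quad_term,
              slope_sd = slope_sd,
              basal_sd = basal_sd,
              noise_sd_wd = noise_sd_wd,
              noise_sd_mass = noise_sd_mass,
              site_sd = site_sd,
              drop_stem_base_prob = drop_stem_base_prob,
              vol_fractions = vol_fractions,
              dirichlet_conc = dirichlet_conc,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stop_if_not(cfg$n_species >= 1L && cfg$n_trees >= 1L && cfg$n_sites >= 1L,
              "counts (n_species, n_trees, n_sites) must all be >= 1")
  stop_if_not(cfg$noise_sd_wd >= 0 && cfg$noise_sd_mass >= 0 &&
                cfg$slope_sd >= 0 && cfg$basal_sd >= 0 && cfg$site_sd >= 0,
              "noise standard deviations must be >= 0")
  stop_if_not(cfg$drop_stem_base_prob >= 0 && cfg$drop_stem_base_prob <= 1,
              "drop_stem_base_prob must be a probability in [0, 1]")
  stop_if_not(length(cfg$vol_fractions) == 6L &&
                all(COMPARTMENTS %in% names(cfg$vol_fractions)) &&
                abs(sum(cfg$vol_fractions) - 1) < 1e-8 &&
                all(cfg$vol_fractions > 0),
              "vol_fractions must be 6 positive fractions summing to 1, ",
              "named after the compartments")
  invisible(cfg)
}

as_sim_config <- function(config) {
  if (inherits(config, "sim_config")) return(config)
  stop_if_not(is.list(config), "config must be a sim_config or a list")
  do.call(sim_config, config)
}

#' Generate a synthetic species pool
#'
#' Species mean wood densities are drawn uniformly over the tropical range
#' 0.22-1.02 g cm-3 and each species is assigned a regeneration guild with
#' probabilities that shift from pioneer (P) at low WD through non-pioneer
#' light-demanding (NPLD) to shade-tolerant (ST) at high WD. Species are
#' grouped into families (up to 16) for taxonomic analyses.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns \code{species_id}, \code{family},
#'   \code{WD_GWD} (species database-average WD, g cm-3) and \code{guild}.
#' @export
generate_species_pool <- function(config) {
  cfg <- as_sim_config(config)
  withr::with_seed(derive_seed(cfg$seed, "species"), {
    n <- cfg$n_species
    wd <- stats::runif(n, 0.22, 1.02)
    z <- (wd - 0.22) / 0.80
    w <- cbind(P = (1 - z)^2, NPLD = 2 * z * (1 - z), ST = z^2)
    guild <- apply(w, 1L, function(p) sample(GUILDS, 1L, prob = p))
    n_fam <- max(1L, min(16L, n))
    family <- paste0("F", sample.int(n_fam, n, replace = TRUE))
    data.frame(species_id = sprintf("sp%02d", seq_len(n)),
               family = family,
               WD_GWD = wd,
               guild = factor(guild, levels = GUILDS),
               stringsAsFactors = FALSE)
  })
}

# True vertical WD profile of one tree: linear (plus optional quadratic) in
# relative compartment rank, with the total change coupled to basal WD.
profile_wd <- function(basal, total_change, quad, noise_sd) {
  r <- (seq_along(COMPARTMENTS) - 1) / (length(COMPARTMENTS) - 1)
  wd <- basal + total_change * r + quad * (r - 0.5)^2
  wd <- wd + stats::rnorm(length(r), 0, noise_sd)
  pmax(wd, 0.05)
}

#' Generate synthetic trees with true vertical WD profiles
#'
#' Each tree draws a basal WD around its species mean, a vertical WD profile
#' whose direction depends on the basal WD (see [sim_config()]), structure
#' variables (DBH, heights, crown radius) from simple allometries, and
#' per-compartment fresh volumes from a Dirichlet split of a total volume
#' allometry. Species are confined to a subset of the sites (most species
#' occur at only one or two) so that site-restricted analyses are
#' meaningful.
#'
#' @param pool species pool from [generate_species_pool()].
#' @param config a [sim_config()].
#' @return list with elements \code{trees} (one row per tree: ids, site,
#'   structure, true basal WD) and \code{compartments} (one row per tree x
#'   compartment: true WD g cm-3, true fresh volume cm3, rank). Trees whose
#'   stem base was merged into the stem have no \code{Ste_b} row.
#' @export
generate_trees <- function(pool, config) {
  cfg <- as_sim_config(config)
  stop_if_not(is.data.frame(pool) && nrow(pool) >= 1L,
              "species pool must be a nonempty data.frame")
  withr::with_seed(derive_seed(cfg$seed, "trees"), {
    n <- cfg$n_trees
    nsp <- nrow(pool)
    sites <- sprintf("site%d", seq_len(cfg$n_sites))
    site_eff <- stats::rnorm(cfg$n_sites, 0, cfg$site_sd)
    names(site_eff) <- sites

    # uneven species abundances; every species gets at least one tree
    w <- stats::rgamma(nsp, shape = 2, rate = 1) + 0.05
    idx <- if (n <= nsp) sample.int(nsp, n) else
      c(seq_len(nsp), sample.int(nsp, n - nsp, replace = TRUE, prob = w))
    idx <- sample(idx)

    # each species occupies 1..n_sites sites, small counts most common
    k_prob <- 0.5^seq_len(cfg$n_sites)
    sp_sites <- lapply(seq_len(nsp), function(i) {
      k <- sample.int(cfg$n_sites, 1L, prob = k_prob)
      sample(sites, k)
    })

    tree_id <- sprintf("t%04d", seq_len(n))
    species_id <- pool$species_id[idx]
    site <- vapply(idx, function(i) {
      s <- sp_sites[[i]]
      if (length(s) == 1L) s else sample(s, 1L)
    }, character(1L))

    dbh <- pmin(pmax(stats::rlnorm(n, log(45), 0.45), 10), 180)
    h <- 40 * dbh / (dbh + 30) * exp(stats::rnorm(n, 0, 0.08))
    sm <- stats::rbeta(n, 8, 6)
    ht <- sm * h
    cr <- 0.12 * dbh * exp(stats::rnorm(n, 0, 0.2))

    basal <- pool$WD_GWD[idx] + stats::rnorm(n, 0, cfg$basal_sd) +
      site_eff[site]
    basal <- pmax(basal, 0.10)
    total_change <- cfg$gradient_slope * (cfg$wd_pivot - basal) +
      stats::rnorm(n, 0, cfg$slope_sd)
    has_steb <- stats::runif(n) >= cfg$drop_stem_base_prob

    # total fresh volume, cm3: ~0.7 of the DBH cylinder
    v_total <- 0.7 * pi / 4 * dbh^2 * (h * 100)

    comp_rows <- vector("list", n)
    alpha <- cfg$dirichlet_conc * cfg$vol_fractions[COMPARTMENTS]
    for (i in seq_len(n)) {
      wd_c <- profile_wd(basal[i], total_change[i], cfg$quad_term,
                         cfg$noise_sd_wd)
      frac <- rdirichlet1(alpha)
      names(frac) <- names(wd_c) <- COMPARTMENTS
      keep <- COMPARTMENTS
      if (!has_steb[i]) {
        # stem base wood is counted with the stem
        frac["Ste"] <- frac["Ste"] + frac["Ste_b"]
        keep <- setdiff(COMPARTMENTS, "Ste_b")
      }
      comp_rows[[i]] <- data.frame(
        tree_id = tree_id[i],
        compartment = keep,
        rank = match(keep, COMPARTMENTS) - 1L,
        wd_true = unname(wd_c[keep]),
        volume_true = unname(v_total[i] * frac[keep]),
        stringsAsFactors = FALSE)
    }

    trees <- data.frame(tree_id = tree_id,
                        species_id = species_id,
                        site = site,
                        DBH = dbh, H = h, Ht = ht, Cr = cr,
                        wd_basal_true = basal,
                        has_steb = has_steb,
                        stringsAsFactors = FALSE)
    list(trees = trees, compartments = do.call(rbind, comp_rows))
  })
}

# True compartment moisture content for one tree, reproducible from the
# config seed and the tree id so samples and logs agree.
compartment_mc <- function(tree_id, compartments, config) {
  cfg <- as_sim_config(config)
  withr::with_seed(derive_seed(cfg$seed, "mc", tree_id), {
    mc <- stats::runif(length(compartments), -0.6, -0.2)
    names(mc) <- compartments
    mc
  })
}

#' Generate wedge samples for one tree
#'
#' Two opposite pith-to-bark wedge samples are drawn per present
#' compartment. Each sample's fresh mass, fresh volume and dry mass are
#' consistent with the compartment's true WD and a drawn moisture content,
#' perturbed by relative lognormal measurement noise
#' (\code{noise_sd_mass}). With zero noise the sample's dry mass over fresh
#' volume equals the true WD exactly.
#'
#' @param tree one tree's rows of the \code{compartments} table from
#'   [generate_trees()] (a data.frame with \code{tree_id},
#'   \code{compartment}, \code{wd_true}).
#' @param config a [sim_config()].
#' @return data.frame of samples: \code{tree_id}, \code{compartment},
#'   \code{sample_no}, \code{m_f}, \code{v_f}, \code{m_d} (g / cm3 / g).
#' @export
generate_samples <- function(tree, config) {
  cfg <- as_sim_config(config)
  stop_if_not(is.data.frame(tree) && nrow(tree) >= 1L &&
                length(unique(tree$tree_id)) == 1L,
              "tree must be the compartment rows of a single tree")
  id <- tree$tree_id[1L]
  mc <- compartment_mc(id, tree$compartment, cfg)
  withr::with_seed(derive_seed(cfg$seed, "samples", id), {
    out <- lapply(seq_len(nrow(tree)), function(i) {
      comp <- tree$compartment[i]
      v_f <- stats::runif(2L, 30, 80)
      m_d <- tree$wd_true[i] * v_f *
        exp(stats::rnorm(2L, 0, cfg$noise_sd_mass))
      m_f <- m_d / (1 + mc[[comp]]) *
        exp(stats::rnorm(2L, 0, cfg$noise_sd_mass))
      m_f <- pmax(m_f, m_d)  # dry mass can never exceed fresh mass
      data.frame(tree_id = id, compartment = comp, sample_no = 1:2,
                 m_f = m_f, v_f = v_f, m_d = m_d,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Generate field log measurements for one tree
#'
#' Stump, stem base and stem are recorded as pairs of coned logs (truncated
#' cones whose end radii and length reproduce the compartment's true fresh
#' volume); branch compartments are weighed in the field, their fresh mass
#' derived from the true volume, WD and moisture content. Noise on weighed
#' masses is relative lognormal (\code{noise_sd_mass}).
#'
#' @inheritParams generate_samples
#' @return data.frame of logs: \code{tree_id}, \code{compartment},
#'   \code{kind} ("weighed" or "coned"), \code{fresh_mass} (g),
#'   \code{r1}, \code{r2}, \code{h} (cm).
#' @export
generate_logs <- function(tree, config) {
  cfg <- as_sim_config(config)
  stop_if_not(is.data.frame(tree) && nrow(tree) >= 1L &&
                length(unique(tree$tree_id)) == 1L,
              "tree must be the compartment rows of a single tree")
  id <- tree$tree_id[1L]
  mc <- compartment_mc(id, tree$compartment, cfg)
  withr::with_seed(derive_seed(cfg$seed, "logs", id), {
    out <- lapply(seq_len(nrow(tree)), function(i) {
      comp <- tree$compartment[i]
      v <- tree$volume_true[i]
      if (comp %in% c("Stu", "Ste_b", "Ste")) {
        # two consecutive coned logs reproducing the compartment volume
        n_log <- 2L
        v_log <- rep(v / n_log, n_log)
        q <- 0.85  # taper ratio r2/r1
        h <- stats::runif(n_log, 100, 200)
        r1 <- sqrt(3 * v_log / (pi * h * (1 + q + q^2)))
        data.frame(tree_id = id, compartment = comp, kind = "coned",
                   fresh_mass = NA_real_, r1 = r1, r2 = q * r1, h = h,
                   stringsAsFactors = FALSE)
      } else {
        fresh_density <- tree$wd_true[i] / (1 + mc[[comp]])
        m <- v * fresh_density * exp(stats::rnorm(1L, 0, cfg$noise_sd_mass))
        data.frame(tree_id = id, compartment = comp, kind = "weighed",
                   fresh_mass = m, r1 = NA_real_, r2 = NA_real_,
                   h = NA_real_, stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, out)
  })
}

#' Generate a random ultrametric phylogeny over the species pool
#'
#' A stand-in species-level tree (coalescent, hence ultrametric, branch
#' lengths scaled to unit depth) for phylogenetic-signal analyses.
#'
#' @param pool species pool from [generate_species_pool()].
#' @param config a [sim_config()].
#' @return an \code{ape} \code{phylo} object with the species ids as tips.
#' @export
generate_phylogeny <- function(pool, config) {
  cfg <- as_sim_config(config)
  stop_if_not(is.data.frame(pool) && nrow(pool) >= 2L,
              "need at least 2 species to build a phylogeny")
  withr::with_seed(derive_seed(cfg$seed, "phylo"), {
    phy <- ape::rcoal(nrow(pool), tip.label = pool$species_id)
    depth <- max(ape::node.depth.edgelength(phy))
    phy$edge.length <- phy$edge.length / depth
    phy
  })
}

#' Simulate a full destructive-sampling dataset
#'
#' Convenience wrapper running the whole generator: species pool, trees and
#' true compartments, wedge samples and logs for every tree, and (when the
#' pool has at least two species) a phylogeny.
#'
#' @param config a [sim_config()] or a list of its arguments.
#' @return list with \code{species}, \code{trees}, \code{compartments},
#'   \code{samples}, \code{logs}, \code{phylogeny} and the \code{config}.
#' @export
simulate_dataset <- function(config = sim_config()) {
  cfg <- as_sim_config(config)
  species <- generate_species_pool(cfg)
  gen <- generate_trees(species, cfg)
  by_tree <- split(gen$compartments, gen$compartments$tree_id)
  samples <- do.call(rbind, lapply(by_tree, generate_samples, config = cfg))
  logs <- do.call(rbind, lapply(by_tree, generate_logs, config = cfg))
  rownames(samples) <- rownames(logs) <- NULL
  phy <- if (nrow(species) >= 2L) generate_phylogeny(species, cfg) else NULL
  list(species = species, trees = gen$trees,
       compartments = gen$compartments,
       samples = samples, logs = logs,
       phylogeny = phy, config = cfg)
}

#' Write a simulated dataset as delimited text tables
#'
#' Writes \code{species.csv}, \code{trees.csv}, \code{compartments.csv},
#' \code{samples.csv}, \code{logs.csv} and \code{phylogeny.nwk} into a
#' directory.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(species = file.path(dir, "species.csv"),
             trees = file.path(dir, "trees.csv"),
             compartments = file.path(dir, "compartments.csv"),
             samples = file.path(dir, "samples.csv"),
             logs = file.path(dir, "logs.csv"))
  for (nm in names(paths)) {
    utils::write.csv(dataset[[nm]], paths[[nm]], row.names = FALSE)
  }
  if (!is.null(dataset$phylogeny)) {
    nwk <- file.path(dir, "phylogeny.nwk")
    ape::write.tree(dataset$phylogeny, nwk)
    paths <- c(paths, phylogeny = nwk)
  }
  invisible(paths)
}
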