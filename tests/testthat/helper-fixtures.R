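# Shared fixture builders for the test suite.

# A small, fast simulation config; override any field.
quick_cfg <- function(...) {
  args <- list(n_species = 12L, n_trees = 60L, n_sites = 3L, seed = 42L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# A config with every stochastic component silenced: profiles are exactly
# the deterministic gradient and measurements are exact.
noiseless_cfg <- function(...) {
  quick_cfg(slope_sd = 0, basal_sd = 0, noise_sd_wd = 0,
            noise_sd_mass = 0, site_sd = 0, drop_stem_base_prob = 0, ...)
}

# Hand-built compartment summary table for one tree (volume-built: AGB
# exactly V * WD per compartment).
volume_built_compartments <- function(tree_id = "t1",
                                      wd = c(0.8, 0.7, 0.6, 0.5, 0.45, 0.4),
                                      v = c(500, 500, 5500, 2000, 1000, 500)) {
  data.frame(tree_id = tree_id,
             compartment = c("Stu", "Ste_b", "Ste", "LB", "MB", "SB"),
             WD_c = wd, MC_c = -0.4, BV_c = 1.2,
             V_c = v, AGB_c = v * wd,
             stringsAsFactors = FALSE)
}

# Two wedge samples with identical properties, giving exact compartment
# means WD_c = wd, MC_c = mc, BV_c = (1 + mc) / wd.
exact_samples <- function(tree_id = "t1", compartment = "Stu",
                          wd = 0.6, mc = -0.4, v_f = 100) {
  m_d <- wd * v_f
  m_f <- m_d / (1 + mc)
  data.frame(tree_id = tree_id, compartment = compartment,
             sample_no = 1:2, m_f = m_f, v_f = v_f, m_d = m_d,
             stringsAsFactors = FALSE)
}
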