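# Profile matrix construction, scaled PCA, supplementary correlations.

make_comp_table <- function(m, tree_ids = sprintf("t%03d", seq_len(nrow(m)))) {
  comps <- c("Stu", "Ste_b", "Ste", "LB", "MB", "SB")
  data.frame(tree_id = rep(tree_ids, each = 6),
             compartment = rep(comps, nrow(m)),
             WD_c = as.vector(t(m)),
             stringsAsFactors = FALSE)
}

test_that("row normalization modes behave as documented", {
  flat <- make_comp_table(matrix(0.6, 1, 6))
  pm_ratio <- build_profile_matrix(flat, mode = "row_mean_ratio")
  expect_equal(unname(pm_ratio$matrix[1, ]), rep(1, 6))
  pm_center <- build_profile_matrix(flat, mode = "row_center")
  expect_equal(unname(pm_center$matrix[1, ]), rep(0, 6))

  prof <- matrix(seq(0.8, 0.4, length.out = 6), 1)
  a <- build_profile_matrix(make_comp_table(prof))$matrix
  b <- build_profile_matrix(make_comp_table(2 * prof))$matrix
  expect_equal(unname(a), unname(b))  # ratio mode is scale invariant

  set.seed(10)
  m <- matrix(runif(60, 0.3, 0.9), 10, 6)
  r <- build_profile_matrix(make_comp_table(m))$matrix
  expect_equal(unname(rowMeans(r)), rep(1, 10), tolerance = 1e-12)
  c_ <- build_profile_matrix(make_comp_table(m), mode = "row_center")$matrix
  expect_equal(unname(rowMeans(c_)), rep(0, 10), tolerance = 1e-12)
})

test_that("missing stem base is imputed and short trees are excluded", {
  set.seed(11)
  m <- matrix(runif(36, 0.3, 0.9), 6, 6)
  tab <- make_comp_table(m)
  tab <- tab[!(tab$tree_id == "t001" & tab$compartment == "Ste_b"), ]
  tab <- tab[!(tab$tree_id == "t002" &
                 tab$compartment %in% c("Ste_b", "LB")), ]
  expect_warning(pm <- build_profile_matrix(tab), "excluded")
  expect_equal(pm$excluded, "t002")
  expect_equal(pm$imputed_steb, "t001")
  # imputed value = mean(Stu, Ste) before normalization
  raw <- (m[1, 1] + m[1, 3]) / 2
  full <- m[1, ]; full[2] <- raw
  expect_equal(unname(pm$matrix["t001", ]), unname(full / mean(full)))
})

test_that("scaled PCA matches a brute-force eigendecomposition oracle", {
  set.seed(12)
  for (rep in 1:8) {
    x <- matrix(rnorm(120), 20, 6,
                dimnames = list(NULL, c("Stu", "Ste_b", "Ste",
                                        "LB", "MB", "SB")))
    pca <- run_pca(x)
    # independent oracle: eigendecomposition of the correlation matrix
    ev <- eigen(cor(x), symmetric = TRUE)
    expect_equal(pca$eigenvalues, ev$values, tolerance = 1e-8)
    xs <- scale(x)
    sc_oracle <- xs %*% ev$vectors
    for (k in 1:6) {
      s <- sign(sum(sc_oracle[, k] * pca$scores[, k]))
      expect_equal(unname(pca$scores[, k]), s * unname(sc_oracle[, k]),
                   tolerance = 1e-8)
    }
    # reconstruction with all axes retained
    recon <- pca$scores %*% t(pca$loadings)
    expect_lt(norm(unname(recon) - unname(xs), "F"), 1e-8)
    expect_equal(sum(pca$eigenvalues), 6, tolerance = 1e-10)
  }
})

test_that("uncorrelated columns give near-unit eigenvalues", {
  set.seed(13)
  x <- matrix(rnorm(6 * 4000), ncol = 6)
  pca <- run_pca(x)
  expect_true(all(abs(pca$eigenvalues - 1) < 0.1))
})

test_that("axis orientation is deterministic and permutation-equivariant", {
  set.seed(14)
  dat <- simulate_dataset(quick_cfg(n_trees = 80, drop_stem_base_prob = 0))
  proc <- process_field_data(dat$samples, dat$logs, dat$trees)
  pm <- build_profile_matrix(proc$compartments)
  pca <- run_pca(pm)
  expect_gt(pca$loadings["SB", 1], 0)
  expect_gt(pca$loadings["Ste", 2], 0)

  perm <- sample(nrow(pm$matrix))
  pca_p <- run_pca(pm$matrix[perm, ])
  expect_equal(unname(pca_p$scores), unname(pca$scores[perm, ]),
               tolerance = 1e-10)

  # dense-based decreasing trees score negative on axis 1
  tr <- proc$trees
  s1 <- pca$scores[match(tr$tree_id, rownames(pca$scores)), 1]
  expect_lt(cor(s1, tr$WD_Stu), 0)
})

test_that("constant columns are reported as degenerate", {
  x <- cbind(matrix(rnorm(50), 10, 5), Ste = rep(1, 10))
  colnames(x) <- c("Stu", "Ste_b", "LB", "MB", "SB", "Ste")
  expect_error(run_pca(x), "Ste")
})

test_that("individual axis-1 signs mostly agree with their species mean", {
  dat <- simulate_dataset(quick_cfg(n_trees = 300, n_species = 25,
                                    seed = 17))
  proc <- process_field_data(dat$samples, dat$logs, dat$trees)
  pca <- run_pca(build_profile_matrix(proc$compartments))
  s1 <- pca$scores[, 1]
  sp <- proc$trees$species_id[match(rownames(pca$scores),
                                    proc$trees$tree_id)]
  sp_mean <- tapply(s1, sp, mean)
  agree <- sign(s1) == sign(sp_mean[sp])
  expect_gt(mean(agree), 0.75)
})

test_that("supplementary correlations match a hand-rolled Pearson oracle", {
  set.seed(15)
  dat <- simulate_dataset(quick_cfg(n_trees = 60))
  proc <- process_field_data(dat$samples, dat$logs, dat$trees)
  tr <- proc$trees
  tr$WD_GWD <- lookup_wd_gwd(tr, dat$species)
  pca <- run_pca(build_profile_matrix(proc$compartments))
  sup <- supplementary_correlations(pca, tr)

  ids <- rownames(pca$scores)
  tr2 <- tr[match(ids, tr$tree_id), ]
  for (v in sup$variable) {
    x <- tr2[[v]]
    r_oracle <- mean((x - mean(x)) * (pca$scores[, 1] -
                                        mean(pca$scores[, 1]))) /
      (sqrt(mean((x - mean(x))^2)) *
         sqrt(mean((pca$scores[, 1] - mean(pca$scores[, 1]))^2)))
    expect_equal(sup$r_axis1[sup$variable == v], r_oracle,
                 tolerance = 1e-12)
  }

  # a variable identical to the axis scores correlates perfectly
  tr$self <- pca$scores[match(tr$tree_id, ids), 1]
  sup_self <- supplementary_correlations(pca, tr, variables = "self")
  expect_equal(sup_self$r_axis1, 1, tolerance = 1e-12)
  expect_lt(sup_self$p_axis1, 1e-12)

  # constant variables are reported as not available
  tr$const <- 1
  sup_c <- supplementary_correlations(pca, tr, variables = "const")
  expect_true(is.na(sup_c$r_axis1))
  expect_equal(sup_c$sig_axis1, "na")
})

test_that("gradient percent is plain arithmetic on stump and branch WD", {
  expect_equal(gradient_percent(0.52, 0.60), -13.3333333, tolerance = 1e-6)
  expect_equal(gradient_percent(0.6, 0.6), 0)
  expect_equal(gradient_percent(0.9, 0.6), 50)
  expect_error(gradient_percent(0.5, 0), "positive")
})
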