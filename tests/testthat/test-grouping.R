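# Guild ANOVA / Tukey HSD, variance partitioning, Blomberg's K.

test_that("one-way ANOVA matches hand-computed sums of squares", {
  # A = {1,2}, B = {3,4}: SSB = 4, SSW = 1, F = (4/1)/(1/2) = 8
  res <- oneway_anova(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_equal(res$ss_between, 4)
  expect_equal(res$ss_within, 1)
  expect_equal(res$F, 8)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 2)
  expect_equal(res$ss_total, res$ss_between + res$ss_within)

  ident <- oneway_anova(c(1, 2, 1, 2), c("A", "A", "B", "B"))
  expect_equal(ident$F, 0)

  expect_error(oneway_anova(1:3, c("A", "A", "B")), "B")
})

test_that("ANOVA F matches a regression-on-dummies oracle", {
  set.seed(30)
  for (i in 1:5) {
    g <- factor(sample(c("a", "b", "c"), 40, replace = TRUE))
    y <- rnorm(40) + as.integer(g) * 0.5
    res <- oneway_anova(y, g)
    # independent route: F test of the dummy regression
    f_oracle <- summary(lm(y ~ g))$fstatistic
    expect_equal(res$F, unname(f_oracle["value"]), tolerance = 1e-10)
    expect_equal(res$p,
                 pf(f_oracle["value"], f_oracle["numdf"], f_oracle["dendf"],
                    lower.tail = FALSE),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("Tukey HSD reduces to the pooled t-test for two groups", {
  set.seed(31)
  y <- c(rnorm(8), rnorm(9, 0.8))
  g <- rep(c("A", "B"), c(8, 9))
  tk <- tukey_hsd(y, g)
  p_t <- t.test(y ~ g, var.equal = TRUE)$p.value
  expect_equal(tk$pairs$p_adj, p_t, tolerance = 1e-10)
})

test_that("identical groups share a letter with adjusted p = 1", {
  y <- rep(c(5, 6, 7), times = 3)
  g <- rep(c("A", "B", "C"), each = 3)
  tk <- tukey_hsd(y, g)
  expect_true(all(tk$pairs$p_adj > 0.999))
  expect_equal(unname(tk$letters), rep("a", 3))

  # well-separated groups get distinct letters
  y2 <- c(rnorm(10, 0, 0.1), rnorm(10, 5, 0.1), rnorm(10, 10, 0.1))
  g2 <- rep(c("A", "B", "C"), each = 10)
  tk2 <- tukey_hsd(y2, g2)
  expect_equal(length(unique(tk2$letters)), 3)
  expect_error(tukey_hsd(y2, g2, alpha = 1.5), "alpha")
})

test_that("pairwise differences are antisymmetric under group swap", {
  set.seed(32)
  y <- rnorm(30); g <- rep(c("A", "B", "C"), each = 10)
  tk <- tukey_hsd(y, g)
  relabel <- c(A = "B", B = "A", C = "C")
  tk2 <- tukey_hsd(y, unname(relabel[g]))
  d1 <- tk$pairs$diff[tk$pairs$g1 == "B" & tk$pairs$g2 == "A"]
  d2 <- tk2$pairs$diff[tk2$pairs$g1 == "B" & tk2$pairs$g2 == "A"]
  expect_equal(d1, -d2, tolerance = 1e-12)
})

test_that("Tukey adjusted p agrees with a permutation oracle", {
  set.seed(33)
  n_per <- 6
  y <- c(rnorm(n_per, 0), rnorm(n_per, 1.2), rnorm(n_per, 0.4))
  g <- factor(rep(c("A", "B", "C"), each = n_per))
  tk <- tukey_hsd(y, g)

  # oracle: permutation distribution of the maximum studentized range
  q_stat <- function(y) {
    m <- tapply(y, g, mean)
    s2 <- sum((y - ave(y, g))^2) / (length(y) - 3)
    max(dist(m)) / sqrt(s2 / n_per)
  }
  q_pair <- function(y, a, b) {
    m <- tapply(y, g, mean)
    s2 <- sum((y - ave(y, g))^2) / (length(y) - 3)
    abs(m[[a]] - m[[b]]) / sqrt(s2 / n_per)
  }
  n_perm <- 4000
  q_null <- replicate(n_perm, q_stat(sample(y)))
  for (i in seq_len(nrow(tk$pairs))) {
    q_obs <- q_pair(y, tk$pairs$g1[i], tk$pairs$g2[i])
    p_perm <- mean(q_null >= q_obs)
    # permutation null vs studentized-range reference: agreement within
    # Monte-Carlo + distributional slack on the absolute scale
    expect_lt(abs(tk$pairs$p_adj[i] - p_perm), 0.05)
  }
})

test_that("variance partition isolates species, site and interaction", {
  # pure species means, several sites: species takes all the variance
  set.seed(34)
  sp <- rep(c("s1", "s2", "s3"), each = 12)
  site <- rep(rep(c("A", "B", "C"), each = 4), times = 3)
  mu <- c(s1 = -1, s2 = 0, s3 = 2)
  vp <- variance_partition(mu[sp], sp, site)
  tab <- vp$table
  expect_equal(tab$fraction[tab$term == "species"], 1, tolerance = 1e-9)
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-12)
  expect_equal(vp$n_retained, 36)

  # constant site: site fraction is 0
  expect_warning(
    vp1 <- variance_partition(rnorm(20), rep(c("x", "y"), 10),
                              rep("onlysite", 20)),
    "one site")
  expect_equal(vp1$table$fraction[vp1$table$term == "site"], 0)
})

test_that("balanced-design fractions match a group-mean SS oracle", {
  set.seed(35)
  sp <- rep(c("s1", "s2", "s3"), each = 20)
  site <- rep(rep(c("A", "B", "C", "D", "E"), each = 4), times = 3)
  y <- rnorm(60) + as.integer(factor(sp)) + 0.3 * as.integer(factor(site))
  vp <- variance_partition(y, sp, site)
  tab <- vp$table

  # orthogonal balanced decomposition from group means
  gm <- mean(y)
  ss_sp <- sum(tapply(y, sp, function(v) length(v) * (mean(v) - gm)^2))
  ss_site <- sum(tapply(y, site, function(v) length(v) * (mean(v) - gm)^2))
  cell <- interaction(sp, site)
  ss_cells <- sum(tapply(y, cell, function(v) length(v) * (mean(v) - gm)^2))
  ss_int <- ss_cells - ss_sp - ss_site
  ss_tot <- sum((y - gm)^2)
  expect_equal(tab$ss[tab$term == "species"], ss_sp, tolerance = 1e-8)
  expect_equal(tab$ss[tab$term == "site"], ss_site, tolerance = 1e-8)
  expect_equal(tab$ss[tab$term == "species:site"], ss_int, tolerance = 1e-8)
  expect_equal(tab$fraction, tab$ss / ss_tot, tolerance = 1e-12)
})

test_that("species found in too few sites are filtered out", {
  sp <- c(rep("wide1", 9), rep("wide2", 9), rep("rare", 2))
  site <- c(rep(c("A", "B", "C"), 3), rep(c("A", "B", "C"), 3), "A", "B")
  y <- rnorm(20)
  vp <- variance_partition(y, sp, site, min_sites = 3)
  expect_equal(vp$n_retained, 18)
  expect_equal(vp$n_species, 2)
})

test_that("Blomberg's K is scale invariant and matches picante", {
  set.seed(36)
  phy <- ape::rcoal(30)
  trait <- setNames(rnorm(30), phy$tip.label)
  k <- blomberg_k(trait, phy)
  expect_equal(k, picante::Kcalc(trait[phy$tip.label], phy),
               tolerance = 1e-8, ignore_attr = TRUE)

  phy2 <- phy
  phy2$edge.length <- phy2$edge.length * 7.3
  expect_equal(blomberg_k(trait, phy2), k, tolerance = 1e-10)
})

test_that("K is near 1 for Brownian traits, low for iid traits", {
  set.seed(37)
  phy <- ape::rcoal(40)
  k_bm <- replicate(60, {
    tr <- ape::rTraitCont(phy, sigma = 1)
    blomberg_k(tr, phy)
  })
  expect_gt(mean(k_bm), 0.75)
  expect_lt(mean(k_bm), 1.3)

  k_iid <- replicate(60, blomberg_k(setNames(rnorm(40), phy$tip.label),
                                    phy))
  expect_lt(mean(k_iid), mean(k_bm))
  expect_lt(mean(k_iid), 0.8)
})

test_that("K rejects malformed input", {
  phy <- ape::rcoal(5)
  expect_error(blomberg_k(setNames(rnorm(5), letters[1:5]), phy),
               "mismatch")
  expect_error(blomberg_k(setNames(rep(1, 5), phy$tip.label), phy),
               "variance")
  trait <- setNames(rnorm(5), phy$tip.label)
  phy_nobl <- phy; phy_nobl$edge.length <- NULL
  expect_error(blomberg_k(trait, phy_nobl), "branch lengths")
})

test_that("tip-randomization p follows the rank formula and seed", {
  set.seed(38)
  phy <- ape::rcoal(25)
  trait <- ape::rTraitCont(phy, sigma = 1)
  ps <- blomberg_k_pvalue(trait, phy, n_rand = 199, seed = 5,
                          tail = "upper")
  expect_equal(ps$p, (1 + sum(ps$K_rand >= ps$K)) / 200)
  expect_gte(ps$p, 1 / 200)
  expect_lte(ps$p, 1)

  ps2 <- blomberg_k_pvalue(trait, phy, n_rand = 199, seed = 5,
                           tail = "upper")
  expect_identical(ps$p, ps2$p)
  expect_identical(ps$K_rand, ps2$K_rand)

  lo <- blomberg_k_pvalue(trait, phy, n_rand = 199, seed = 5,
                          tail = "lower")
  expect_equal(lo$p, (1 + sum(lo$K_rand <= lo$K)) / 200)

  expect_error(blomberg_k_pvalue(trait, phy, n_rand = 10), "99")
})
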