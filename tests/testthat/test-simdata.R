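test_that("cohort generation is a pure function of config and seed", {
  s1 <- tiny_cohort(11)
  s2 <- tiny_cohort(11)
  expect_identical(s1$cohort$beta, s2$cohort$beta)
  expect_identical(s1$cohort$detection_p, s2$cohort$detection_p)
  expect_identical(s1$truth, s2$truth)
  s3 <- tiny_cohort(12)
  expect_false(identical(s1$cohort$beta, s3$cohort$beta))
})

test_that("null configuration plants nothing and groups differ only by noise", {
  sim <- tiny_cohort(21, n_probes = 2000, n_cases = 50, n_controls = 50)
  expect_length(sim$truth$true_dmp_ids, 0)
  grp <- sim$cohort$samples$fibrosis == "yes"
  d <- rowMeans(sim$cohort$beta[, grp]) - rowMeans(sim$cohort$beta[, !grp])
  expect_lt(mean(abs(d)), 0.05)        # pure sampling noise at n = 50/group
  expect_gt(mean(abs(d)), 0)
})

test_that("planted logit effects reproduce the closed-form beta-scale difference", {
  ## baseline 0.8 dropping to ~0.65 in cases; truth solved by inverse logit
  planted <- list(list(locus = "GENE0001", delta = -0.15, n_affected = 2))
  sim <- tiny_cohort(31, n_probes = 500, n_cases = 200, n_controls = 200,
                     planted = planted)
  truth <- sim$truth
  expect_length(truth$true_dmp_ids, 2)
  expect_equal(unname(truth$true_effect_betas), c(-0.15, -0.15), tolerance = 1e-12)
  grp <- sim$cohort$samples$fibrosis == "yes"
  for (id in truth$true_dmp_ids) {
    emp <- mean(sim$cohort$beta[id, grp]) - mean(sim$cohort$beta[id, !grp])
    expect_lt(abs(emp - truth$true_effect_betas[[id]]), 0.03)
  }
})

test_that("cohort layers respect their ranges and QC artifacts appear at configured rates", {
  cfg <- meth_cohort_config(n_probes = 4000, n_loci = 300, seed = 41,
                            detection_fail_rate = 0.01, low_bead_rate = 0.005)
  sim <- simulate_methylation_cohort(cfg)
  b <- sim$cohort$beta
  expect_true(all(b >= 0 & b <= 1))
  expect_true(all(sim$cohort$detection_p >= 0 & sim$cohort$detection_p <= 1))
  expect_true(all(sim$cohort$bead_count >= 0))
  n_cells <- length(b)
  expect_equal(mean(sim$cohort$detection_p > 0.01), 0.01, tolerance = 0.35)
  expect_equal(mean(sim$cohort$bead_count < 3), 0.005, tolerance = 0.35)
  ## type II compression narrows the beta distribution
  t2 <- sim$cohort$annotation$design_type == "II"
  expect_lt(stats::sd(b[t2, 1]), stats::sd(b[!t2, 1]) + 0.05)
})

test_that("undersized cohorts are refused", {
  expect_error(meth_cohort_config(n_cases = 2, n_controls = 1, seed = 1),
               "at least 4 samples")
  expect_error(meth_cohort_config(seed = NULL), "seed")
})

test_that("protein panel truth encodes conditional independence", {
  ## diagonal precision: no edges at all
  sp <- simulate_protein_panel(diag(4), 20, seed = 5)
  expect_equal(sp$truth$true_partial_correlations, diag(4),
               ignore_attr = TRUE)
  expect_equal(nrow(sp$truth$true_edge_support), 0)
  ## chain 1-2-3: omega13 = 0 means pcor(1,3) = 0 despite marginal correlation
  om <- diag(3); om[1, 2] <- om[2, 1] <- -0.5; om[2, 3] <- om[3, 2] <- -0.5
  sp <- simulate_protein_panel(om, 20, seed = 5)
  expect_equal(sp$truth$true_partial_correlations[1, 3], 0)
  expect_equal(sp$truth$true_partial_correlations[1, 2], 0.5)
})

test_that("protein panel sampling matches the closed-form marginal correlation", {
  om <- diag(3); om[1, 2] <- om[2, 1] <- -0.5; om[2, 3] <- om[3, 2] <- -0.5
  sp <- simulate_protein_panel(om, 10000, seed = 6)
  sigma <- solve(om)
  target <- stats::cov2cor(sigma)
  emp <- stats::cor(t(sp$panel))
  expect_lt(max(abs(emp - target)), 0.05)
})

test_that("non-positive-definite precision is refused with a diagnostic", {
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(simulate_protein_panel(bad, 10, seed = 1), "positive definite")
  expect_error(simulate_protein_panel(matrix(c(1, 0.5, 0, 1), 2, 2), 10, seed = 1),
               "symmetric")
})

test_that("dose grids satisfy Bliss independence by construction", {
  fa <- c(0, 0.2, 0.4); fb <- c(0, 0.3, 0.5)
  dg <- simulate_dose_grid(fa, fb, interaction = 0, noise_sd = 0,
                           n_replicates = 2, seed = 1)
  obs_fa <- 1 - dg$grid$signal[, , 1] / dg$grid$signal[1, 1, 1]
  expect_equal(obs_fa, outer(fa, fb, function(a, b) a + b - a * b),
               ignore_attr = TRUE, tolerance = 1e-12)
  ## zero-dose row reproduces the single-agent effect exactly
  expect_equal(unname(obs_fa[1, ]), fb, tolerance = 1e-12)
  expect_error(simulate_dose_grid(fa, fb, noise_sd = -1, seed = 1), "noise_sd")
  expect_error(simulate_dose_grid(c(0.1, 0.2), fb, seed = 1), "untreated control")
})

test_that("planted dose-grid interaction is recoverable from replicates", {
  inter <- matrix(0, 3, 3); inter[2, 2] <- 0.15
  dg <- simulate_dose_grid(c(0, 0.2, 0.4), c(0, 0.3, 0.5), interaction = inter,
                           noise_sd = 0.02, n_replicates = 4, seed = 2)
  expect_equal(dg$truth$true_interaction, inter)
  sm <- synergy_map(dg$grid)
  expect_lt(abs(sm$delta[2, 2] - 0.15), 3 * max(sm$se[2, 2], 0.01))
})

test_that("qPCR tables recover configured fold changes through ddct", {
  tab1 <- simulate_qpcr_table(c(GENE = 1), ct_noise_sd = 0, seed = 1)
  expect_equal(ddct_expression(tab1)$relative_expression, 1, tolerance = 1e-12)
  tab2 <- simulate_qpcr_table(c(GENE = 2), ct_noise_sd = 0, seed = 1)
  expect_equal(ddct_expression(tab2)$relative_expression, 2, tolerance = 1e-12)
  ## noisy recovery: mean over 100 seeds within 5% of the true fold change
  est <- vapply(1:100, function(s) {
    tab <- simulate_qpcr_table(c(GENE = 2), ct_noise_sd = 0.1, seed = s)
    ddct_expression(tab)$relative_expression
  }, numeric(1))
  expect_lt(abs(mean(est) - 2) / 2, 0.05)
  expect_error(simulate_qpcr_table(c(G = -1), seed = 1), "fold changes")
})
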