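test_that("Benjamini-Hochberg adjustment matches the step-up definition", {
  expect_equal(adjust_bh(0.02), 0.02)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(adjust_bh(c(0.01, NA, 0.03)), c(0.02, NA, 0.03))
  ## order invariance: permute, adjust, unpermute equals adjust
  set.seed(1)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(adjust_bh(p[perm])[order(perm)], adjust_bh(p))
  expect_true(all(adjust_bh(p) >= p))
})

test_that("group difference estimation inverts the logit link", {
  expect_equal(estimate_group_difference(c("(Intercept)" = 0.7, fibrosis = 0)), 0)
  cc <- c("(Intercept)" = 0, fibrosis = 1.2)
  expect_equal(estimate_group_difference(cc), plogis(1.2) - 0.5)
  cc2 <- c("(Intercept)" = 0.2, fibrosis = 0.8, age = 0.01)
  expect_equal(estimate_group_difference(cc2, reference = c(age = 55)),
               plogis(0.2 + 0.55 + 0.8) - plogis(0.2 + 0.55))
  expect_error(estimate_group_difference(cc2, reference = c(bmi = 1)), "unknown")
})

test_that("candidate selection applies the difference and locus rules", {
  dmp <- data.frame(
    probe_id = sprintf("cg%02d", 1:5),
    p_adjusted = c(0.01, 0.02, 0.03, 0.2, 0.01),
    estimated_difference = c(0.12, 0.04, 0.05, 0.5, 0.02),
    gene_symbols = c("A", "G", "G", "B", NA),
    stringsAsFactors = FALSE)
  sel <- select_candidates(dmp, alpha = 0.05, delta_min = 0.10,
                           min_cpgs_per_locus = 2)
  got <- sel$candidates
  ## cg01 by difference; cg02/cg03 share locus G with two significant CpGs;
  ## cg04 is not significant; cg05 is significant but small and intergenic
  expect_setequal(got$probe_id, c("cg01", "cg02", "cg03"))
  expect_equal(got$reason[got$probe_id == "cg01"], "difference")
  expect_equal(got$reason[got$probe_id == "cg02"], "locus")
  ## degenerate thresholds reduce selection to the significance cut
  all_sig <- select_candidates(dmp, alpha = 0.05, delta_min = 0,
                               min_cpgs_per_locus = 1)
  expect_setequal(all_sig$candidates$probe_id, c("cg01", "cg02", "cg03", "cg05"))
  ## nothing significant: empty set
  none <- select_candidates(transform(dmp, p_adjusted = 0.9))
  expect_equal(nrow(none$candidates), 0)
  ## multi-gene probes count toward each locus
  dmp2 <- data.frame(probe_id = c("a", "b"), p_adjusted = c(0.01, 0.01),
                     estimated_difference = c(0.01, 0.01),
                     gene_symbols = c("X;Y", "Y"), stringsAsFactors = FALSE)
  expect_setequal(select_candidates(dmp2)$candidates$probe_id, c("a", "b"))
})

test_that("amplicon means average the available CpG units", {
  panel <- data.frame(
    amplicon_id = c("amp1", "amp1", "amp1", "amp2", "amp2", "amp2", "amp3"),
    sample_id = "S1",
    methylation = c(0.2, 0.4, 0.6, 0.5, NA, 0.7, 0.9))
  out <- amplicon_mean_methylation(panel)
  expect_equal(out$mean_methylation[out$amplicon_id == "amp1"], 0.4)
  expect_equal(out$mean_methylation[out$amplicon_id == "amp2"], 0.6)
  expect_equal(out$mean_methylation[out$amplicon_id == "amp3"], 0.9)
  allna <- data.frame(amplicon_id = "a", sample_id = "S1",
                      methylation = NA_real_)
  expect_warning(res <- amplicon_mean_methylation(allna), "no available")
  expect_true(is.na(res$mean_methylation))
})

test_that("Wilcoxon rank-sum test enumerates exactly for small untied samples", {
  ## most extreme ranking of 3 vs 3: 2 of the 20 assignments are as extreme
  res <- wilcoxon_group_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$p_value, 0.1)
  ## identical pooled values: no evidence at all
  tied <- wilcoxon_group_test(rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(tied$p_value, 1)
  ## label swap leaves the p-value unchanged
  x <- c(3.2, 1.5, 4.8, 2.2, 5.1, 0.7, 3.9, 2.8)
  g <- rep(c("a", "b"), 4)
  g2 <- ifelse(g == "a", "b", "a")
  expect_equal(wilcoxon_group_test(x, g)$p_value,
               wilcoxon_group_test(x, g2)$p_value)
  expect_error(wilcoxon_group_test(1:3, rep("a", 3)), "two groups")
})

test_that("Pearson correlation and the slope F-test agree with linear theory", {
  x <- 1:10
  ## lm warns that a perfect fit makes its summary unreliable; expected here
  perfect <- suppressWarnings(correlate_with_ftest(x, 2 * x))
  expect_equal(perfect$r, 1)
  expect_equal(perfect$slope, 2)
  expect_lt(perfect$p_value, 1e-12)
  ## F equals the squared t of the slope on arbitrary data
  set.seed(5)
  y <- 0.5 * x + rnorm(10)
  res <- correlate_with_ftest(x, y)
  fit <- stats::lm(y ~ x)
  tval <- summary(fit)$coefficients["x", "t value"]
  expect_equal(res$F, tval^2)
  expect_equal(res$slope_ci, unname(stats::confint(fit)["x", ]))
  ## null p-values are roughly uniform
  set.seed(6)
  ps <- vapply(1:200, function(i) correlate_with_ftest(rnorm(20), rnorm(20))$p_value,
               numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 1e-3)
  expect_error(correlate_with_ftest(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("dmp_scan excludes degenerate probes and finds a planted effect", {
  planted <- list(list(locus = "GENE0001", delta = 0.15, n_affected = 2))
  hits <- 0
  for (s in 1:10) {
    sim <- tiny_cohort(400 + s, n_probes = 300, planted = planted)
    clean <- as_clean(sim$cohort)
    clean$beta[5, ] <- 0.42                       # constant probe
    dmp <- dmp_scan(clean)
    expect_false(dmp$converged[5])
    expect_true(is.na(dmp$p_value[5]))
    pid <- sim$truth$true_dmp_ids[1]
    hits <- hits + (dmp$p_value[dmp$probe_id == pid] < 0.05)
  }
  expect_gte(hits, 6)   # a ~0.15 difference at 12 vs 12 is found most of the time
})

test_that("dmp_scan p-values are calibrated on a null cohort", {
  sim <- tiny_cohort(500, n_probes = 1000)
  dmp <- dmp_scan(as_clean(sim$cohort))
  p <- dmp$p_value[!is.na(dmp$p_value)]
  frac <- mean(p < 0.05)
  ## 95% binomial band around 0.05 at m = 1000
  expect_lt(abs(frac - 0.05), 1.96 * sqrt(0.05 * 0.95 / length(p)) + 0.005)
  expect_true(all(dmp$p_adjusted >= dmp$p_value, na.rm = TRUE))
})
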