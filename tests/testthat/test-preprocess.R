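make_mini_cohort <- function(np = 10, ns = 6, seed = 1) {
  set.seed(seed)
  beta <- matrix(runif(np * ns), np, ns,
                 dimnames = list(sprintf("cg%03d", 1:np), sprintf("S%02d", 1:ns)))
  structure(list(
    beta = beta,
    detection_p = matrix(0.001, np, ns, dimnames = dimnames(beta)),
    bead_count = matrix(10L, np, ns, dimnames = dimnames(beta)),
    signal_meth = NULL, signal_unmeth = NULL,
    annotation = data.frame(probe_id = rownames(beta),
                            chromosome = "chr1", position = seq_len(np) * 100L,
                            strand = "+", design_type = rep(c("I", "II"), length.out = np),
                            channel = rep(c("red", "green"), length.out = np),
                            gene_symbols = NA_character_,
                            region_relation = "body", cgi_relation = "open_sea",
                            snp_associated = FALSE, stringsAsFactors = FALSE),
    samples = data.frame(sample_id = colnames(beta),
                         fibrosis = rep(c("yes", "no"), length.out = ns),
                         age = 50 + seq_len(ns), smoker_ever = "no",
                         chemotherapy = "no", stringsAsFactors = FALSE)
  ), class = "MethylationCohort")
}

test_that("bead filter marks low-bead measurements via detection p", {
  ch <- make_mini_cohort()
  expect_identical(apply_bead_filter(ch, 3)$detection_p, ch$detection_p)
  ch$bead_count[2, 3] <- 2L
  out <- apply_bead_filter(ch, 3)
  expect_equal(out$detection_p[2, 3], 1)
  expect_equal(sum(out$detection_p == 1), 1)
  expect_identical(out$beta, ch$beta)          # beta untouched at this stage
  expect_identical(apply_bead_filter(ch, 0)$detection_p, ch$detection_p)
  ch$bead_count <- NULL
  expect_error(apply_bead_filter(ch), "bead_count")
})

test_that("detection mask uses a strict inequality at the threshold", {
  ch <- make_mini_cohort()
  expect_equal(sum(is.na(mask_by_detection(ch, 0.01)$beta)), 0)
  ch$detection_p[1, 1] <- 0.02    # above: masked
  ch$detection_p[2, 2] <- 0.01    # exactly at the threshold: kept
  out <- mask_by_detection(ch, 0.01)
  expect_true(is.na(out$beta[1, 1]))
  expect_false(is.na(out$beta[2, 2]))
  expect_equal(attr(out, "n_masked"), 1)
})

test_that("missingness filter drops probes strictly above the cap", {
  ch <- make_mini_cohort(np = 6, ns = 24)
  ch$beta[1, 1:8] <- NA   # 8/24 = 0.333 > 0.3: dropped
  ch$beta[2, 1:7] <- NA   # 7/24 = 0.292: kept
  out <- drop_high_missing_probes(ch, 0.3)
  expect_false("cg001" %in% rownames(out$beta))
  expect_true("cg002" %in% rownames(out$beta))
  expect_equal(attr(out, "dropped"), "cg001")
  complete <- drop_high_missing_probes(make_mini_cohort(), 0.3)
  expect_equal(nrow(complete$beta), 10)
})

test_that("SNP-associated probes are removed from every layer", {
  ch <- make_mini_cohort()
  expect_equal(nrow(drop_snp_probes(ch)$beta), 10)
  ch$annotation$snp_associated[c(3, 7)] <- TRUE
  out <- drop_snp_probes(ch)
  expect_equal(nrow(out$beta), 8)
  expect_equal(nrow(out$annotation), 8)
  expect_equal(nrow(out$bead_count), 8)
  ch$annotation$snp_associated <- TRUE
  expect_warning(out <- drop_snp_probes(ch), "all probes")
  expect_equal(nrow(out$beta), 0)
  ch$annotation$snp_associated <- NULL
  expect_error(drop_snp_probes(ch), "snp_associated")
})

test_that("kNN imputation preserves observed values and fills from neighbours", {
  b <- make_mini_cohort(np = 30, ns = 8)$beta
  expect_identical(impute_knn(b, 10), b)    # complete matrix: unchanged
  ## a probe identical to its neighbours except one masked cell
  b2 <- matrix(rep(seq(0.1, 0.8, length.out = 8), each = 12), 12, 8,
               dimnames = list(sprintf("p%02d", 1:12), sprintf("S%d", 1:8)))
  b2[1, 4] <- NA
  out <- impute_knn(b2, 10)
  expect_equal(out[1, 4], b2[2, 4], tolerance = 1e-12)
  expect_identical(out[-1, ], b2[-1, ])
  expect_true(all(out >= 0 & out <= 1))
})

test_that("mask-and-recover: kNN beats global-mean imputation on correlated probes", {
  sim <- tiny_cohort(77, n_probes = 800, n_cases = 12, n_controls = 12)
  b <- sim$cohort$beta
  ## correlate probes in blocks by sharing a latent sample effect
  set.seed(77)
  eff <- matrix(rep(rnorm(ncol(b), 0, 0.05), each = 40), 40, ncol(b))
  for (blk in seq_len(nrow(b) %/% 40)) {
    rows <- ((blk - 1) * 40 + 1):(blk * 40)
    b[rows, ] <- pmin(pmax(b[rows, ] + eff, 0), 1)
  }
  holdout <- cbind(sample(nrow(b), 150), sample(ncol(b), 150, replace = TRUE))
  truth <- b[holdout]
  bm <- b; bm[holdout] <- NA
  imp <- impute_knn(bm, 10)
  rmse_knn <- sqrt(mean((imp[holdout] - truth)^2))
  rmse_mean <- sqrt(mean((mean(bm, na.rm = TRUE) - truth)^2))
  probe_sd <- mean(apply(b, 1, stats::sd))
  expect_lt(rmse_knn, rmse_mean)
  expect_lt(rmse_knn, probe_sd)
  expect_true(all(!is.na(imp)))
})

test_that("colour correction equalizes channels and preserves in-channel ranks", {
  cfg <- meth_cohort_config(n_probes = 3000, n_loci = 200, seed = 9,
                            dye_bias = 0.5, detection_fail_rate = 0,
                            low_bead_rate = 0, snp_rate = 0)
  sim <- simulate_methylation_cohort(cfg)
  ch <- sim$cohort
  chan <- ch$annotation$channel
  red_of <- function(x) c(x$signal_meth[chan == "red", 1],
                          x$signal_unmeth[chan == "red", 1],
                          x$signal_unmeth[chan == "both", 1])
  green_of <- function(x) c(x$signal_meth[chan == "green", 1],
                            x$signal_unmeth[chan == "green", 1],
                            x$signal_meth[chan == "both", 1])
  ks_before <- ks_distance(red_of(ch), green_of(ch))
  out <- correct_color_bias(ch)
  ks_after <- ks_distance(red_of(out), green_of(out))
  expect_lt(ks_after, 0.2 * ks_before)     # at least 80% of the distortion gone
  ## monotone within channel and sample
  red1 <- ch$signal_meth[chan == "red", 1]
  red1c <- out$signal_meth[chan == "red", 1]
  expect_identical(order(red1), order(red1c))
  ## without channel information the stage is skipped with a warning
  ch$signal_meth <- NULL
  expect_warning(same <- correct_color_bias(ch), "skipped")
  expect_identical(same$beta, ch$beta)
})

test_that("colour correction is exact on identically distributed channels", {
  ## red and green intensity multisets made exactly equal: the quantile map
  ## degenerates to the identity and betas do not move
  ch <- make_mini_cohort(np = 8, ns = 2)
  ch$annotation$channel <- rep(c("red", "green"), each = 4)
  ch$annotation$design_type <- "I"
  vals <- matrix(seq(100, 1500, length.out = 16), 8, 2)
  ch$signal_meth <- vals
  ch$signal_unmeth <- vals[8:1, ]
  dimnames(ch$signal_meth) <- dimnames(ch$signal_unmeth) <- dimnames(ch$beta)
  ch$beta <- ch$signal_meth / (ch$signal_meth + ch$signal_unmeth + 100)
  out <- correct_color_bias(ch)
  expect_lt(max(abs(out$beta - ch$beta)), 1e-6)
})

test_that("colour correction is a near fixed point on unbiased channels", {
  cfg <- meth_cohort_config(n_probes = 3000, n_loci = 200, seed = 10,
                            dye_bias = 0, emit_intensities = TRUE,
                            detection_fail_rate = 0, low_bead_rate = 0,
                            snp_rate = 0)
  sim <- simulate_methylation_cohort(cfg)
  out <- correct_color_bias(sim$cohort)
  ## channels drawn from one distribution: betas move only by the sampling
  ## difference between the two channels' empirical quantile functions
  expect_lt(stats::median(abs(out$beta - sim$cohort$beta)), 0.01)
})

test_that("BMIQ restores the type II distribution and never touches type I", {
  cfg <- meth_cohort_config(n_probes = 5000, n_loci = 300, seed = 12,
                            type2_compression = 0.7, dye_bias = 0,
                            detection_fail_rate = 0, low_bead_rate = 0,
                            snp_rate = 0)
  sim <- simulate_methylation_cohort(cfg)
  b <- sim$cohort$beta
  dt <- sim$cohort$annotation$design_type
  out <- suppressWarnings(bmiq_normalize(b, dt))
  expect_identical(out[dt == "I", ], b[dt == "I", ])
  improved <- vapply(seq_len(ncol(b)), function(s) {
    ks_distance(out[dt == "II", s], out[dt == "I", s]) <
      ks_distance(b[dt == "II", s], b[dt == "I", s])
  }, logical(1))
  expect_gte(mean(improved), 0.95)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("BMIQ handles a degenerate constant type II distribution", {
  set.seed(3)
  b <- matrix(c(rbeta(200, 2, 2), rep(0.31, 200)), ncol = 1)
  dt <- rep(c("I", "II"), each = 200)
  out <- suppressWarnings(bmiq_normalize(b, dt))
  expect_equal(length(unique(out[dt == "II", 1])), 1)  # constant in, constant out
  expect_true(all(is.finite(out)))
})

test_that("variance filter drops flat probes with a strict cut", {
  b <- rbind(constant = rep(0.4, 6),
             swing = rep(c(0.2, 0.8), 3),
             mild = c(0.50, 0.55, 0.45, 0.52, 0.48, 0.50))
  colnames(b) <- sprintf("S%d", 1:6)
  out <- filter_low_variance(b, 0.05)
  expect_identical(rownames(out), "swing")   # sd 0.33 kept; 0 and 0.035 dropped
  expect_identical(attr(out, "dropped"), c("constant", "mild"))
  expect_equal(nrow(filter_low_variance(b, 0)), 3)
})

test_that("full preprocessing is conservative, ordered and accounted for", {
  cfg <- meth_cohort_config(n_probes = 3000, n_loci = 200, seed = 13)
  sim <- simulate_methylation_cohort(cfg)
  clean <- suppressWarnings(run_preprocess(sim$cohort))
  qc <- clean$qc
  expect_equal(qc$probes_in - qc$probes_dropped_missing - qc$probes_dropped_snp -
                 qc$probes_dropped_low_sd, qc$probes_out)
  expect_true(all(!is.na(clean$beta)))
  expect_true(all(clean$beta >= 0 & clean$beta <= 1))
  expect_identical(colnames(clean$beta), sim$cohort$samples$sample_id)
  expect_identical(rownames(clean$beta), clean$annotation$probe_id)
  ## determinism of the whole pipeline
  clean2 <- suppressWarnings(run_preprocess(sim$cohort))
  expect_identical(clean$beta, clean2$beta)
})

test_that("preprocessing is an approximate fixed point on its own output", {
  cfg <- meth_cohort_config(n_probes = 3000, n_loci = 200, seed = 14)
  sim <- simulate_methylation_cohort(cfg)
  clean <- suppressWarnings(run_preprocess(sim$cohort))
  ## wrap the clean output as a raw cohort with perfect QC layers
  again <- structure(list(
    beta = clean$beta,
    detection_p = matrix(0, nrow(clean$beta), ncol(clean$beta),
                         dimnames = dimnames(clean$beta)),
    bead_count = matrix(10L, nrow(clean$beta), ncol(clean$beta),
                        dimnames = dimnames(clean$beta)),
    signal_meth = NULL, signal_unmeth = NULL,
    annotation = clean$annotation, samples = clean$samples
  ), class = "MethylationCohort")
  clean2 <- suppressWarnings(run_preprocess(again))
  ## no filter has anything left to remove
  expect_equal(clean2$qc$probes_dropped_missing, 0)
  expect_equal(clean2$qc$probes_dropped_snp, 0)
  expect_equal(clean2$qc$cells_masked, 0)
  expect_lt(clean2$qc$probes_dropped_low_sd / nrow(clean$beta), 0.025)
  ## renormalizing already-normalized values moves them very little
  shared <- intersect(rownames(clean$beta), rownames(clean2$beta))
  expect_lt(stats::median(abs(clean2$beta[shared, ] - clean$beta[shared, ])), 0.01)
})
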