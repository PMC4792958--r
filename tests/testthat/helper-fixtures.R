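# shared fixtures and independent oracles for the test suite

# small artifact-free cohort (latent betas only), optionally with planted loci
tiny_cohort <- function(seed, n_probes = 300, n_cases = 12, n_controls = 12,
                        planted = list(), ...) {
  cfg <- meth_cohort_config(
    n_cases = n_cases, n_controls = n_controls, n_probes = n_probes,
    n_loci = max(20, n_probes %/% 10), planted_loci = planted,
    dye_bias = 0, detection_fail_rate = 0, low_bead_rate = 0, snp_rate = 0,
    type2_compression = 1, seed = seed, ...)
  simulate_methylation_cohort(cfg)
}

# bypass preprocessing: wrap a cohort as a clean input for dmp_scan
as_clean <- function(cohort) {
  list(beta = cohort$beta, samples = cohort$samples,
       annotation = cohort$annotation)
}

# independent maximum-likelihood oracle for beta regression: a
# general-purpose numerical maximizer of the same log-likelihood,
# started from the naive logit least-squares initializer
oracle_betareg <- function(y, X, eps = 1e-6) {
  yc <- pmin(pmax(y, eps), 1 - eps)
  nll <- function(th) -beta_reg_loglik(th, yc, X)
  init <- c(qr.solve(X, qlogis(yc)), log(10))
  op <- stats::optim(init, nll, method = "BFGS",
                     control = list(maxit = 2000, reltol = 1e-14))
  op <- stats::optim(op$par, nll, control = list(maxit = 10000, reltol = 1e-14))
  list(par = op$par, loglik = -op$value)
}

# brute-force step-down Sidak adjustment straight from the definition
oracle_holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, 1 - (1 - p[o[i]])^(m - i + 1))
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# two-sample KS distance
ks_distance <- function(a, b)
  unname(suppressWarnings(stats::ks.test(a, b))$statistic)

# recovery metrics of a candidate selection against ground truth
recovery_metrics <- function(selected_ids, true_ids) {
  c(sensitivity = if (length(true_ids)) mean(true_ids %in% selected_ids) else NA_real_,
    fdr = if (length(selected_ids)) mean(!(selected_ids %in% true_ids)) else 0)
}

# planted-locus configuration used by the recovery experiments:
# 10 loci, 2-4 affected CpGs each, beta-scale differences 0.12-0.20
planted_loci_default <- function(seed) {
  set.seed(seed * 1000L + 7L)
  deltas <- stats::runif(10, 0.12, 0.20) * sample(c(-1, 1), 10, replace = TRUE)
  lapply(1:10, function(i)
    list(locus = sprintf("GENE%04d", i), delta = deltas[i],
         n_affected = sample(2:4, 1)))
}

# one full recovery run at the given scale
recovery_run <- function(seed, n_probes = 20000, n_loci = 1500) {
  planted <- planted_loci_default(seed)
  cfg <- meth_cohort_config(n_probes = n_probes, n_loci = n_loci,
                            planted_loci = planted, seed = seed)
  sim <- simulate_methylation_cohort(cfg)
  clean <- suppressWarnings(run_preprocess(sim$cohort))
  dmp <- dmp_scan(clean)
  cand <- select_candidates(dmp)
  c(recovery_metrics(cand$candidates$probe_id, sim$truth$true_dmp_ids),
    n_candidates = nrow(cand$candidates))
}

# block precision matrix with n_edges disjoint couplings of given pcor
edge_precision <- function(p = 22, n_edges = 5, pcor = 0.5) {
  omega <- diag(p)
  for (r in seq_len(n_edges)) {
    i <- 2 * r - 1; j <- 2 * r
    omega[i, j] <- omega[j, i] <- -pcor
  }
  rownames(omega) <- colnames(omega) <- sprintf("P%02d", seq_len(p))
  omega
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
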