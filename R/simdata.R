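#' Configuration for the synthetic 450K-style methylation cohort
#'
#' Bundles and validates every knob of [simulate_methylation_cohort()].
#' Defaults emulate a two-group fibroblast cohort profiled on a two-design
#' methylation array: beta-distributed methylation with a bimodal baseline,
#' covariate structure (age, smoking, chemotherapy), Infinium type II
#' dynamic-range compression, a two-colour dye bias, sporadic detection
#' failures and low-bead measurements.
#'
#' @param n_cases,n_controls group sizes (samples).
#' @param n_probes total number of CpG probes.
#' @param n_loci number of gene loci; probes not assigned to a locus are
#'   intergenic.
#' @param probes_per_locus integer vector `c(min, max)`; each locus gets a
#'   uniformly drawn number of member CpGs.
#' @param planted_loci list of per-locus effects. Each element is a list with
#'   `locus` (gene symbol, e.g. `"GENE0001"`), `n_affected` (CpGs carrying the
#'   effect) and either `delta` (target case-minus-control difference on the
#'   beta-value scale, solved to a logit-scale shift per probe) or `effect`
#'   (a shift applied directly on the logit-mean scale).
#' @param baseline_weights,baseline_shapes mixture from which per-probe
#'   baseline methylation means are drawn: `baseline_shapes` is a 3x2 matrix
#'   of beta shape pairs (unmethylated / methylated / intermediate
#'   components), `baseline_weights` their mixing weights.
#' @param phi beta-distribution precision; scalar or per-probe vector.
#'   Sampling variance of a probe is `mu*(1-mu)/(1+phi)`.
#' @param covariate_effects named numeric vector with logit-scale
#'   coefficients `age` (per year), `smoking`, `chemotherapy`.
#' @param age_range,smoking_rate,chemo_rate covariate distributions:
#'   age ~ Uniform(range), smoking/chemotherapy ~ Bernoulli(rate).
#' @param type2_fraction proportion of Infinium type II probes.
#' @param type2_compression scale factor in (0,1] shrinking type II betas
#'   toward 0.5 (`beta' = 0.5 + c*(beta-0.5)`), the reduced dynamic range of
#'   the type II chemistry.
#' @param dye_bias multiplicative inflation of red-channel intensities
#'   (0 = no bias). When positive (or `emit_intensities = TRUE`) per-channel
#'   signal intensities are emitted and observed betas are recomputed as
#'   `M/(M+U+100)`.
#' @param emit_intensities force emission of channel intensities.
#' @param detection_fail_rate probability a measurement fails detection
#'   (detection p-value > 0.01; its beta value is replaced by noise).
#' @param low_bead_rate probability a measurement has bead count < 3.
#' @param snp_rate fraction of probes flagged as SNP-associated.
#' @param seed integer seed (mandatory; the generator is a pure function of
#'   config and seed).
#' @return an object of class `meth_cohort_config` (a validated list).
#' @export
meth_cohort_config <- function(n_cases = 12, n_controls = 12,
                               n_probes = 20000, n_loci = 1500,
                               probes_per_locus = c(1, 6),
                               planted_loci = list(),
                               baseline_weights = c(0.35, 0.35, 0.30),
                               baseline_shapes = rbind(c(2, 10), c(10, 2), c(5, 5)),
                               phi = 50,
                               covariate_effects = c(age = 0.01, smoking = 0.15,
                                                     chemotherapy = 0.15),
                               age_range = c(40, 70),
                               smoking_rate = 0.4,
                               chemo_rate = 0.5,
                               type2_fraction = 0.7,
                               type2_compression = 0.8,
                               dye_bias = 0.1,
                               emit_intensities = NULL,
                               detection_fail_rate = 0.005,
                               low_bead_rate = 0.002,
                               snp_rate = 0.02,
                               seed = NULL) {
  if (is.null(seed)) stopf("meth_cohort_config: 'seed' is mandatory")
  for (nm in c("n_cases", "n_controls", "n_probes", "n_loci")) {
    v <- get(nm)
    if (!is_count(v) || v < 1) stopf("meth_cohort_config: '%s' must be a positive count", nm)
  }
  if (n_cases + n_controls < 4)
    stopf("meth_cohort_config: need at least 4 samples; regression downstream is unidentifiable")
  for (nm in c("detection_fail_rate", "low_bead_rate", "snp_rate",
               "smoking_rate", "chemo_rate", "type2_fraction")) {
    if (!is_prob(get(nm))) stopf("meth_cohort_config: '%s' must lie in [0,1]", nm)
  }
  if (!(type2_compression > 0 && type2_compression <= 1))
    stopf("meth_cohort_config: 'type2_compression' must lie in (0,1]")
  if (any(phi <= 0)) stopf("meth_cohort_config: 'phi' must be positive")
  if (dye_bias < 0) stopf("meth_cohort_config: 'dye_bias' must be >= 0")
  if (length(probes_per_locus) != 2L || probes_per_locus[1] > probes_per_locus[2] ||
      probes_per_locus[1] < 1)
    stopf("meth_cohort_config: 'probes_per_locus' must be c(min, max) with 1 <= min <= max")
  stopifnot(length(baseline_weights) == nrow(baseline_shapes))
  for (pl in planted_loci) {
    if (is.null(pl$locus) || is.null(pl$n_affected) ||
        (is.null(pl$delta) && is.null(pl$effect)))
      stopf("meth_cohort_config: each planted locus needs 'locus', 'n_affected' and 'delta' or 'effect'")
  }
  if (is.null(emit_intensities)) emit_intensities <- dye_bias > 0
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_probes = as.integer(n_probes), n_loci = as.integer(n_loci),
    probes_per_locus = as.integer(probes_per_locus),
    planted_loci = planted_loci,
    baseline_weights = baseline_weights / sum(baseline_weights),
    baseline_shapes = baseline_shapes,
    phi = phi, covariate_effects = covariate_effects,
    age_range = age_range, smoking_rate = smoking_rate, chemo_rate = chemo_rate,
    type2_fraction = type2_fraction, type2_compression = type2_compression,
    dye_bias = dye_bias, emit_intensities = isTRUE(emit_intensities),
    detection_fail_rate = detection_fail_rate, low_bead_rate = low_bead_rate,
    snp_rate = snp_rate, seed = as.integer(seed)
  ), class = "meth_cohort_config")
}

# draw per-probe baseline means from the configured beta mixture,
# kept away from the boundary so logit-scale effects stay finite
draw_baseline_means <- function(n, weights, shapes) {
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  m <- stats::rbeta(n, shapes[comp, 1], shapes[comp, 2])
  clamp(m, 0.02, 0.98)
}

#' Simulate a two-group methylation-array cohort with planted DMRs
#'
#' Generates a probes-by-samples cohort with the statistical structure the
#' downstream pipeline assumes: beta-distributed methylation whose logit
#' means carry group, age, smoking and chemotherapy effects; Infinium
#' type II compression applied before the dye bias; detection-p, bead-count
#' and (optionally) channel-intensity layers; and a `GroundTruth` record of
#' every planted signal.
#'
#' Planted effects are additive on the logit-mean scale for case samples
#' only; covariate contributions are centred so that at cohort-mean
#' covariates the control mean of a probe equals its drawn baseline and the
#' case-minus-control difference equals the recorded truth exactly. When a
#' planted locus specifies a beta-scale `delta`, the logit shift is solved
#' per probe as `logit(m + delta) - logit(m)`; baselines for which
#' `m + delta` would leave (0.02, 0.98) are redrawn uniformly on an interior
#' range so the target is attainable.
#'
#' @param config a [meth_cohort_config()].
#' @return a list with components `cohort` (a `MethylationCohort`: matrices
#'   `beta`, `detection_p`, `bead_count`, optional `signal_meth` /
#'   `signal_unmeth`, plus `annotation` and `samples` data frames) and
#'   `truth` (class `GroundTruth`: `true_dmp_ids`, `true_effect_betas`,
#'   `planted` table).
#' @export
simulate_methylation_cohort <- function(config) {
  stopifnot(inherits(config, "meth_cohort_config"))
  set.seed(config$seed)
  np <- config$n_probes
  ns <- config$n_cases + config$n_controls

  ## ---- annotation -------------------------------------------------------
  probe_id <- sprintf("cg%08d", seq_len(np))
  locus_sizes <- sample(seq(config$probes_per_locus[1], config$probes_per_locus[2]),
                        config$n_loci, replace = TRUE)
  gene <- rep(NA_character_, np)
  assign_n <- min(sum(locus_sizes), np)
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_loci))
  gene[seq_len(assign_n)] <- rep(gene_ids, times = locus_sizes)[seq_len(assign_n)]
  ## shuffle probe order so loci are not positionally clustered in the matrix
  perm <- sample.int(np)
  gene <- gene[perm]
  region_levels <- c("TSS200", "TSS1500", "body", "UTR", "1st exon")
  region <- ifelse(is.na(gene), "intergenic",
                   sample(region_levels, np, replace = TRUE,
                          prob = c(0.12, 0.12, 0.45, 0.21, 0.10)))
  design_type <- ifelse(stats::runif(np) < config$type2_fraction, "II", "I")
  channel <- ifelse(design_type == "II", "both",
                    ifelse(stats::runif(np) < 0.5, "red", "green"))
  annotation <- data.frame(
    probe_id = probe_id,
    chromosome = paste0("chr", sample(1:22, np, replace = TRUE)),
    position = sample.int(2e8, np, replace = TRUE),
    strand = sample(c("+", "-"), np, replace = TRUE),
    design_type = design_type,
    channel = channel,
    gene_symbols = gene,
    region_relation = region,
    cgi_relation = sample(c("island", "shore", "shelf", "open_sea"), np,
                          replace = TRUE, prob = c(0.3, 0.23, 0.1, 0.37)),
    snp_associated = stats::runif(np) < config$snp_rate,
    stringsAsFactors = FALSE
  )

  ## ---- samples ----------------------------------------------------------
  sample_id <- sprintf("S%03d", seq_len(ns))
  fibrosis <- c(rep("yes", config$n_cases), rep("no", config$n_controls))
  age <- stats::runif(ns, config$age_range[1], config$age_range[2])
  smoker <- ifelse(stats::runif(ns) < config$smoking_rate, "yes", "no")
  chemo <- ifelse(stats::runif(ns) < config$chemo_rate, "yes", "no")
  samples <- data.frame(sample_id = sample_id, fibrosis = fibrosis, age = age,
                        smoker_ever = smoker, chemotherapy = chemo,
                        stringsAsFactors = FALSE)

  ## ---- baseline means and planted effects -------------------------------
  m <- draw_baseline_means(np, config$baseline_weights, config$baseline_shapes)
  effect_logit <- numeric(np)
  planted_rows <- list()
  for (pl in config$planted_loci) {
    members <- which(!is.na(gene) & gene == pl$locus)
    if (length(members) == 0L)
      stopf("simulate_methylation_cohort: planted locus '%s' has no member probes", pl$locus)
    n_aff <- min(pl$n_affected, length(members))
    aff <- members[seq_len(n_aff)]
    if (!is.null(pl$delta)) {
      ## redraw baselines that cannot accommodate the target difference
      bad <- m[aff] + pl$delta <= 0.02 | m[aff] + pl$delta >= 0.98
      if (any(bad)) {
        lo <- max(0.05, 0.02 - min(0, pl$delta))
        hi <- min(0.95, 0.98 - max(0, pl$delta))
        m[aff[bad]] <- stats::runif(sum(bad), lo, hi)
      }
      effect_logit[aff] <- logit(m[aff] + pl$delta) - logit(m[aff])
    } else {
      effect_logit[aff] <- pl$effect
    }
    planted_rows[[length(planted_rows) + 1L]] <-
      data.frame(locus = pl$locus, probe_id = probe_id[aff],
                 effect_logit = effect_logit[aff], stringsAsFactors = FALSE)
  }

  ## ---- latent beta values -----------------------------------------------
  is_case <- as.numeric(fibrosis == "yes")
  ce <- config$covariate_effects
  cov_shift <- ce[["age"]] * (age - mean(age)) +
    ce[["smoking"]] * ((smoker == "yes") - mean(smoker == "yes")) +
    ce[["chemotherapy"]] * ((chemo == "yes") - mean(chemo == "yes"))
  eta <- outer(logit(m), rep(1, ns)) + outer(effect_logit, is_case) +
    outer(rep(1, np), cov_shift)
  mu <- invlogit(eta)
  phi <- if (length(config$phi) == 1L) rep(config$phi, np) else config$phi
  beta_lat <- matrix(stats::rbeta(np * ns, mu * phi, (1 - mu) * phi), np, ns)
  beta_lat <- clamp(beta_lat, 1e-4, 1 - 1e-4)

  ## type II dynamic-range compression precedes any channel distortion
  t2 <- design_type == "II"
  beta_obs <- beta_lat
  beta_obs[t2, ] <- 0.5 + config$type2_compression * (beta_lat[t2, ] - 0.5)

  ## ---- channel intensities and dye bias ---------------------------------
  signal_meth <- signal_unmeth <- NULL
  if (config$emit_intensities) {
    total <- matrix(stats::rlnorm(np * ns, log(5000), 0.2), np, ns)
    signal_meth <- beta_obs * total
    signal_unmeth <- (1 - beta_obs) * total
    gain <- 1 + config$dye_bias
    red_i <- channel == "red"
    signal_meth[red_i, ] <- signal_meth[red_i, ] * gain
    signal_unmeth[red_i, ] <- signal_unmeth[red_i, ] * gain
    ## type II: methylated signal read in green, unmethylated in red
    signal_unmeth[t2, ] <- signal_unmeth[t2, ] * gain
    beta_obs <- signal_meth / (signal_meth + signal_unmeth + 100)
  }

  ## ---- QC layers ---------------------------------------------------------
  detection_p <- matrix(stats::runif(np * ns, 0, 0.005), np, ns)
  fail <- matrix(stats::runif(np * ns) < config$detection_fail_rate, np, ns)
  detection_p[fail] <- stats::runif(sum(fail), 0.02, 0.8)
  beta_obs[fail] <- stats::runif(sum(fail))
  bead_count <- matrix(3L + stats::rpois(np * ns, 11), np, ns)
  low <- matrix(stats::runif(np * ns) < config$low_bead_rate, np, ns)
  bead_count[low] <- sample(0:2, sum(low), replace = TRUE)
  beta_obs[low] <- stats::runif(sum(low))

  dimnames(beta_obs) <- dimnames(detection_p) <- dimnames(bead_count) <-
    list(probe_id, sample_id)
  if (!is.null(signal_meth))
    dimnames(signal_meth) <- dimnames(signal_unmeth) <- list(probe_id, sample_id)

  cohort <- structure(list(
    beta = beta_obs, detection_p = detection_p, bead_count = bead_count,
    signal_meth = signal_meth, signal_unmeth = signal_unmeth,
    annotation = annotation, samples = samples
  ), class = "MethylationCohort")

  planted <- if (length(planted_rows)) do.call(rbind, planted_rows) else
    data.frame(locus = character(), probe_id = character(),
               effect_logit = numeric(), stringsAsFactors = FALSE)
  true_ids <- probe_id[effect_logit != 0]
  true_delta <- invlogit(logit(m) + effect_logit) - m
  names(true_delta) <- probe_id
  truth <- structure(list(
    true_dmp_ids = true_ids,
    true_effect_betas = true_delta[true_ids],
    baseline_means = stats::setNames(m, probe_id),
    planted = planted
  ), class = "GroundTruth")

  list(cohort = cohort, truth = truth)
}

#' @export
print.MethylationCohort <- function(x, ...) {
  cat(sprintf("MethylationCohort: %d probes x %d samples\n",
              nrow(x$beta), ncol(x$beta)))
  cat(sprintf("  design types: %s\n",
              paste(sprintf("%s=%d", names(table(x$annotation$design_type)),
                            table(x$annotation$design_type)), collapse = ", ")))
  cat(sprintf("  intensities: %s\n", if (is.null(x$signal_meth)) "absent" else "present"))
  cat(sprintf("  missing beta values: %d\n", sum(is.na(x$beta))))
  invisible(x)
}

#' Simulate a paired-condition protein panel from a known precision matrix
#'
#' Draws `n_samples` i.i.d. observations from the zero-mean multivariate
#' normal distribution with the given precision (inverse covariance) matrix.
#' Values play the role of log relative protein signals (irradiated versus
#' unirradiated) as consumed by the network module. The ground truth carries
#' the implied partial correlations `-omega_ij / sqrt(omega_ii * omega_jj)`.
#'
#' @param precision symmetric positive-definite precision matrix (proteins x
#'   proteins); row names, if set, become protein labels.
#' @param n_samples number of samples (columns).
#' @param seed integer seed.
#' @param measurement_noise_sd optional additive Gaussian measurement noise
#'   on the log scale (0 disables it).
#' @return list with `panel` (proteins x samples matrix) and `truth`
#'   (`GroundTruth` with `true_partial_correlations` and `true_edge_support`,
#'   the i<j index pairs with nonzero partial correlation).
#' @export
simulate_protein_panel <- function(precision, n_samples, seed,
                                   measurement_noise_sd = 0) {
  if (!isSymmetric(unname(precision), tol = 1e-8))
    stopf("simulate_protein_panel: precision matrix must be symmetric")
  p <- nrow(precision)
  ch <- tryCatch(chol(precision), error = function(e) NULL)
  if (is.null(ch))
    stopf("simulate_protein_panel: precision matrix is not positive definite (chol failed)")
  if (measurement_noise_sd < 0)
    stopf("simulate_protein_panel: measurement_noise_sd must be >= 0")
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(p * n_samples), p, n_samples)
  ## if R'R = Omega then X = R^{-1} Z has covariance Omega^{-1}
  x <- backsolve(ch, z)
  if (measurement_noise_sd > 0)
    x <- x + matrix(stats::rnorm(p * n_samples, 0, measurement_noise_sd), p, n_samples)
  labels <- rownames(precision)
  if (is.null(labels)) labels <- sprintf("P%02d", seq_len(p))
  dimnames(x) <- list(labels, sprintf("S%02d", seq_len(n_samples)))
  omega <- as.matrix(precision)
  pc <- -stats::cov2cor(omega)
  diag(pc) <- 1
  dimnames(pc) <- list(labels, labels)
  support <- which(upper.tri(pc) & abs(pc) > 1e-12, arr.ind = TRUE)
  truth <- structure(list(
    true_partial_correlations = pc,
    true_edge_support = support
  ), class = "GroundTruth")
  list(panel = x, truth = truth)
}

#' Simulate a replicated dose-combination viability grid
#'
#' Wells are generated under the Bliss independence null — expected
#' viability fraction `(1-fa)*(1-fb)` — minus an optional planted
#' interaction (positive = extra growth suppression, i.e. synergy), plus
#' Gaussian noise, clamped to \[0,1\] and scaled to signal units.
#'
#' @param effect_a,effect_b single-agent fraction-affected values per dose
#'   level, each starting with the zero-dose entry 0.
#' @param interaction scalar or `length(effect_a)` x `length(effect_b)`
#'   matrix of planted viability depressions beyond independence.
#' @param noise_sd Gaussian noise s.d. on the viability-fraction scale.
#' @param n_replicates replicate wells per dose combination.
#' @param seed integer seed.
#' @param doses_a,doses_b dose labels (default 0, 1, 2, ... level indices).
#' @param signal_scale signal units of a fully viable well.
#' @return list with `grid` (a `DoseGrid`: `doses_a`, `doses_b`, 3-d `signal`
#'   array doses_a x doses_b x replicate, `signal_scale`) and `truth`
#'   (`GroundTruth` with `true_interaction` grid).
#' @export
simulate_dose_grid <- function(effect_a, effect_b, interaction = 0,
                               noise_sd = 0, n_replicates = 4, seed,
                               doses_a = NULL, doses_b = NULL,
                               signal_scale = 1) {
  if (any(effect_a < 0 | effect_a > 1) || any(effect_b < 0 | effect_b > 1))
    stopf("simulate_dose_grid: single-agent fractions affected must lie in [0,1]")
  if (effect_a[1] != 0 || effect_b[1] != 0)
    stopf("simulate_dose_grid: first dose level of each agent must be the untreated control (effect 0)")
  if (noise_sd < 0) stopf("simulate_dose_grid: noise_sd must be >= 0")
  na <- length(effect_a); nb <- length(effect_b)
  inter <- if (length(interaction) == 1L) matrix(interaction, na, nb) else as.matrix(interaction)
  if (!all(dim(inter) == c(na, nb)))
    stopf("simulate_dose_grid: interaction grid must be %d x %d", na, nb)
  if (is.null(doses_a)) doses_a <- seq_len(na) - 1
  if (is.null(doses_b)) doses_b <- seq_len(nb) - 1
  set.seed(as.integer(seed))
  v_expect <- outer(1 - effect_a, 1 - effect_b) - inter
  signal <- array(NA_real_, c(na, nb, n_replicates),
                  dimnames = list(doses_a, doses_b, paste0("rep", seq_len(n_replicates))))
  for (r in seq_len(n_replicates)) {
    v <- v_expect
    if (noise_sd > 0) v <- v + matrix(stats::rnorm(na * nb, 0, noise_sd), na, nb)
    signal[, , r] <- clamp(v, 0, 1) * signal_scale
  }
  grid <- structure(list(doses_a = doses_a, doses_b = doses_b, signal = signal,
                         n_replicates = n_replicates, signal_scale = signal_scale),
                    class = "DoseGrid")
  truth <- structure(list(true_interaction = inter), class = "GroundTruth")
  list(grid = grid, truth = truth)
}

#' Simulate a qPCR ct table with known fold changes
#'
#' Emits treatment/control ct values for target genes plus the housekeeping
#' trio such that, without noise, the delta-delta-ct computation recovers the
#' configured fold changes exactly.
#'
#' @param true_fold_changes named positive vector: treatment/control
#'   expression ratio per target gene.
#' @param ct_noise_sd Gaussian noise s.d. added to every ct measurement.
#' @param seed integer seed.
#' @param n_samples biological samples to emit.
#' @param housekeeping housekeeping gene names (all emitted per sample and
#'   condition).
#' @return a long-format data frame (class `QPCRTable`) with columns
#'   `sample`, `gene`, `condition` ("treatment"/"control"), `ct`; the
#'   housekeeping set is stored in `attr(, "housekeeping")`.
#' @export
simulate_qpcr_table <- function(true_fold_changes, ct_noise_sd = 0, seed,
                                n_samples = 1,
                                housekeeping = c("ACTB", "GAPDH", "HPRT1")) {
  if (any(true_fold_changes <= 0)) stopf("simulate_qpcr_table: fold changes must be > 0")
  if (is.null(names(true_fold_changes)))
    names(true_fold_changes) <- sprintf("TARGET%02d", seq_along(true_fold_changes))
  if (ct_noise_sd < 0) stopf("simulate_qpcr_table: ct_noise_sd must be >= 0")
  set.seed(as.integer(seed))
  rows <- list()
  hk_base <- stats::setNames(seq(18, 24, length.out = length(housekeeping)), housekeeping)
  for (s in seq_len(n_samples)) {
    sid <- sprintf("S%02d", s)
    off <- stats::runif(1, -1, 1)  # plate/sample shift, cancels in delta-delta-ct
    for (h in housekeeping) {
      for (cond in c("treatment", "control"))
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sid, gene = h, condition = cond,
          ct = hk_base[[h]] + off + stats::rnorm(1, 0, ct_noise_sd))
    }
    for (g in names(true_fold_changes)) {
      base_ct <- 26 + off
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sid, gene = g, condition = "control",
        ct = base_ct + stats::rnorm(1, 0, ct_noise_sd))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sid, gene = g, condition = "treatment",
        ct = base_ct - log2(true_fold_changes[[g]]) + stats::rnorm(1, 0, ct_noise_sd))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "housekeeping") <- housekeeping
  class(out) <- c("QPCRTable", class(out))
  out
}
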