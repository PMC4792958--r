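#' Preprocessing parameters
#'
#' Defaults reproduce the filtering and preprocessing settings of the
#' fibrosis EWAS workflow: bead-count threshold 3, detection p-value cutoff
#' 0.01 (strict inequality), probe missingness cap 0.3, kNN imputation with
#' k = 10, and a 5% (0.05) standard-deviation floor on the beta scale.
#'
#' @param min_beads minimum bead count; measurements below it get detection
#'   p-value 1.
#' @param detection_p_max beta values with detection p strictly above this
#'   are set to missing.
#' @param max_missing_fraction probes with a missing fraction strictly above
#'   this are dropped.
#' @param knn_k neighbours used for imputation.
#' @param sd_min probes with across-sample s.d. strictly below this (beta
#'   scale) are dropped after normalization.
#' @param color_correction,bmiq stage toggles.
#' @return a `preprocess_params` list.
#' @export
preprocess_params <- function(min_beads = 3, detection_p_max = 0.01,
                              max_missing_fraction = 0.3, knn_k = 10,
                              sd_min = 0.05, color_correction = TRUE,
                              bmiq = TRUE) {
  stopifnot(min_beads >= 0, is_prob(detection_p_max),
            is_prob(max_missing_fraction), knn_k >= 1, sd_min >= 0)
  structure(list(min_beads = min_beads, detection_p_max = detection_p_max,
                 max_missing_fraction = max_missing_fraction,
                 knn_k = as.integer(knn_k), sd_min = sd_min,
                 color_correction = isTRUE(color_correction),
                 bmiq = isTRUE(bmiq)),
            class = "preprocess_params")
}

#' Bead-count filter
#'
#' Measurements supported by fewer than `min_beads` beads are marked
#' unreliable by setting their detection p-value to 1; beta values are left
#' untouched at this stage (the detection mask removes them next).
#'
#' @param cohort a `MethylationCohort`.
#' @param min_beads bead-count threshold (default 3).
#' @return the modified cohort.
#' @export
apply_bead_filter <- function(cohort, min_beads = 3) {
  if (is.null(cohort$bead_count))
    stopf("apply_bead_filter: cohort has no bead_count layer")
  low <- cohort$bead_count < min_beads
  cohort$detection_p[low] <- 1
  attr(cohort, "n_low_bead") <- sum(low)
  cohort
}

#' Detection-p mask
#'
#' Beta values whose detection p-value exceeds `detection_p_max` (strictly)
#' are set to missing.
#'
#' @param cohort a `MethylationCohort`.
#' @param detection_p_max threshold (default 0.01; a value exactly at the
#'   threshold is kept).
#' @return the modified cohort; the count of newly missing cells is attached
#'   as attribute `n_masked`.
#' @export
mask_by_detection <- function(cohort, detection_p_max = 0.01) {
  if (is.null(cohort$detection_p))
    stopf("mask_by_detection: cohort has no detection_p layer")
  bad <- cohort$detection_p > detection_p_max & !is.na(cohort$beta)
  cohort$beta[bad] <- NA_real_
  attr(cohort, "n_masked") <- sum(bad)
  cohort
}

# subset every probe-indexed layer of a cohort
subset_probes <- function(cohort, keep) {
  for (layer in c("beta", "detection_p", "bead_count", "signal_meth", "signal_unmeth"))
    if (!is.null(cohort[[layer]])) cohort[[layer]] <- cohort[[layer]][keep, , drop = FALSE]
  cohort$annotation <- cohort$annotation[keep, , drop = FALSE]
  rownames(cohort$annotation) <- NULL
  cohort
}

#' Drop probes with excessive missingness
#'
#' @param cohort a `MethylationCohort` with the detection mask already
#'   applied.
#' @param max_missing_fraction probes whose fraction of missing beta values
#'   strictly exceeds this are removed from all layers (default 0.3).
#' @return the reduced cohort; dropped probe ids in attribute `dropped`.
#' @export
drop_high_missing_probes <- function(cohort, max_missing_fraction = 0.3) {
  frac <- rowMeans(is.na(cohort$beta))
  keep <- frac <= max_missing_fraction
  dropped <- rownames(cohort$beta)[!keep]
  cohort <- subset_probes(cohort, keep)
  attr(cohort, "dropped") <- dropped
  cohort
}

#' Drop SNP-associated probes
#'
#' @param cohort a `MethylationCohort` whose annotation carries the
#'   `snp_associated` flag.
#' @return the reduced cohort; dropped probe ids in attribute `dropped`.
#' @export
drop_snp_probes <- function(cohort) {
  if (is.null(cohort$annotation$snp_associated))
    stopf("drop_snp_probes: annotation lacks the 'snp_associated' flag")
  keep <- !cohort$annotation$snp_associated
  dropped <- rownames(cohort$beta)[!keep]
  if (!any(keep)) warnf("drop_snp_probes: all probes flagged; cohort is empty")
  cohort <- subset_probes(cohort, keep)
  attr(cohort, "dropped") <- dropped
  cohort
}

#' k-nearest-neighbour imputation of missing beta values
#'
#' Probes are the items, samples the feature axis. For each probe with
#' missing entries, the k nearest probes are found by Euclidean distance on
#' co-observed samples (rescaled to the full sample count to keep distances
#' comparable across overlap sizes), and each missing entry is replaced by
#' the inverse-distance-weighted mean of the neighbours observed at that
#' sample. Observed entries are never altered; the result is complete and
#' stays in \[0,1\].
#'
#' @param beta probes x samples numeric matrix with `NA` for missing.
#' @param k neighbours (default 10).
#' @return the completed matrix.
#' @export
impute_knn <- function(beta, k = 10) {
  obs <- !is.na(beta)
  if (all(obs)) return(beta)
  np <- nrow(beta)
  if (np < k + 1) {
    warnf("impute_knn: only %d probes; using all available neighbours", np)
    k <- max(np - 1L, 1L)
  }
  if (any(rowSums(obs) == 0))
    stopf("impute_knn: probes with all values missing must be removed upstream")
  out <- .knn_impute_cpp(beta, as.integer(k))
  dimnames(out) <- dimnames(beta)
  clamp(out, 0, 1)
}

#' Two-colour smooth quantile normalization
#'
#' Equalizes the intensity distributions of the red and green channels
#' within each sample by mapping both channels onto their pooled average
#' quantile function through monotone interpolation, then recomputes beta
#' values as `M / (M + U + offset)` from the corrected intensities. Ranks
#' within a channel are preserved. Type I probes contribute both signals to
#' their assigned channel; type II probes read the methylated signal in
#' green and the unmethylated signal in red.
#'
#' @param cohort a `MethylationCohort` with `signal_meth` / `signal_unmeth`
#'   and a per-probe `channel` column ("red", "green", "both") in the
#'   annotation.
#' @param offset stabilizing offset in the beta recomputation (default 100,
#'   the platform convention).
#' @param n_quantiles knots of the quantile map.
#' @param preserve optional logical matrix marking cells whose beta values
#'   (e.g. imputed ones) must not be overwritten by the recomputation.
#' @return the cohort with corrected intensities and recomputed betas; if no
#'   channel information is available the stage is skipped with a warning.
#' @export
correct_color_bias <- function(cohort, offset = 100, n_quantiles = 512,
                               preserve = NULL) {
  if (is.null(cohort$signal_meth) || is.null(cohort$annotation$channel)) {
    warnf("correct_color_bias: no channel intensities/assignment; stage skipped")
    return(cohort)
  }
  chan <- cohort$annotation$channel
  t1_red <- chan == "red"; t1_green <- chan == "green"; t2 <- chan == "both"
  p_grid <- seq(0, 1, length.out = n_quantiles)
  for (s in seq_len(ncol(cohort$beta))) {
    red <- c(cohort$signal_meth[t1_red, s], cohort$signal_unmeth[t1_red, s],
             cohort$signal_unmeth[t2, s])
    green <- c(cohort$signal_meth[t1_green, s], cohort$signal_unmeth[t1_green, s],
               cohort$signal_meth[t2, s])
    if (length(red) < 2L || length(green) < 2L) next
    q_red <- stats::quantile(red, p_grid, names = FALSE, type = 7)
    q_green <- stats::quantile(green, p_grid, names = FALSE, type = 7)
    q_avg <- (q_red + q_green) / 2
    map_red <- function(x) stats::approx(q_red, q_avg, xout = x, rule = 2, ties = "ordered")$y
    map_green <- function(x) stats::approx(q_green, q_avg, xout = x, rule = 2, ties = "ordered")$y
    cohort$signal_meth[t1_red, s] <- map_red(cohort$signal_meth[t1_red, s])
    cohort$signal_unmeth[t1_red, s] <- map_red(cohort$signal_unmeth[t1_red, s])
    cohort$signal_unmeth[t2, s] <- map_red(cohort$signal_unmeth[t2, s])
    cohort$signal_meth[t1_green, s] <- map_green(cohort$signal_meth[t1_green, s])
    cohort$signal_unmeth[t1_green, s] <- map_green(cohort$signal_unmeth[t1_green, s])
    cohort$signal_meth[t2, s] <- map_green(cohort$signal_meth[t2, s])
  }
  new_beta <- cohort$signal_meth / (cohort$signal_meth + cohort$signal_unmeth + offset)
  keep_old <- is.na(new_beta)
  if (!is.null(preserve)) keep_old <- keep_old | preserve
  cohort$beta[!keep_old] <- new_beta[!keep_old]
  cohort
}

#' Low-variance probe filter
#'
#' Removes probes whose across-sample standard deviation of methylation
#' (beta scale) falls strictly below `sd_min`.
#'
#' @param beta complete probes x samples matrix.
#' @param sd_min threshold on the beta scale (default 0.05, i.e. 5%).
#' @return the reduced matrix; dropped probe ids in attribute `dropped`.
#' @export
filter_low_variance <- function(beta, sd_min = 0.05) {
  sds <- apply(beta, 1, stats::sd)
  keep <- sds >= sd_min
  out <- beta[keep, , drop = FALSE]
  attr(out, "dropped") <- rownames(beta)[!keep]
  out
}

#' Run the full preprocessing pipeline
#'
#' Executes, in order: bead filter, detection mask, missingness drop, SNP
#' drop, kNN imputation, two-colour correction, beta-mixture quantile
#' normalization of type II probes, and the low-variance filter. The stage
#' order follows the workflow's enumeration; the variance filter runs last,
#' on normalized values.
#'
#' @param cohort a raw `MethylationCohort`.
#' @param params a [preprocess_params()] object.
#' @return a list with `beta` (clean normalized matrix), `samples`,
#'   `annotation` (restricted to retained probes) and `qc` (per-stage
#'   removal/masking counts).
#' @export
run_preprocess <- function(cohort, params = preprocess_params()) {
  stopifnot(inherits(params, "preprocess_params"))
  qc <- list(probes_in = nrow(cohort$beta), samples = ncol(cohort$beta))

  cohort <- apply_bead_filter(cohort, params$min_beads)
  qc$cells_low_bead <- attr(cohort, "n_low_bead")
  cohort <- mask_by_detection(cohort, params$detection_p_max)
  qc$cells_masked <- attr(cohort, "n_masked")
  cohort <- drop_high_missing_probes(cohort, params$max_missing_fraction)
  qc$probes_dropped_missing <- length(attr(cohort, "dropped"))
  cohort <- drop_snp_probes(cohort)
  qc$probes_dropped_snp <- length(attr(cohort, "dropped"))

  imputed_mask <- is.na(cohort$beta)
  qc$cells_imputed <- sum(imputed_mask)
  cohort$beta <- impute_knn(cohort$beta, params$knn_k)

  if (params$color_correction)
    cohort <- correct_color_bias(cohort, preserve = imputed_mask)

  if (params$bmiq)
    cohort$beta <- bmiq_normalize(cohort$beta, cohort$annotation$design_type)

  beta <- filter_low_variance(cohort$beta, params$sd_min)
  qc$probes_dropped_low_sd <- length(attr(beta, "dropped"))
  keep <- rownames(cohort$beta) %in% rownames(beta)
  annotation <- cohort$annotation[keep, , drop = FALSE]
  rownames(annotation) <- NULL
  qc$probes_out <- nrow(beta)

  list(beta = beta, samples = cohort$samples, annotation = annotation, qc = qc)
}
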