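#' Default pipeline configuration
#'
#' All stage defaults in one place: cohort simulation, preprocessing
#' (bead/detection/missingness/SNP filters, kNN k, s.d. floor), DMP calling
#' (FDR level 0.05, difference threshold 0.10, locus rule 2 CpGs), network
#' inference (posterior threshold 0.6) and synergy flagging (alpha 0.05).
#'
#' @param seed master seed; stage seeds are derived from it.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = NULL,
    cohort = list(n_cases = 12, n_controls = 12, n_probes = 5000, n_loci = 400,
                  planted_deltas = c(0.15, 0.15, -0.15), n_affected = 2),
    preprocess = list(min_beads = 3, detection_p_max = 0.01,
                      max_missing_fraction = 0.3, knn_k = 10, sd_min = 0.05,
                      color_correction = TRUE, bmiq = TRUE),
    dmp = list(alpha = 0.05, delta_min = 0.10, min_cpgs_per_locus = 2),
    network = list(enabled = TRUE, n_proteins = 22, n_samples = 7,
                   min_posterior = 0.6),
    synergy = list(enabled = TRUE, alpha = 0.05, n_replicates = 4,
                   noise_sd = 0.02, interaction = 0.15)
  )
}

check_range <- function(value, field, lo, hi, violations) {
  if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
      value < lo || value > hi)
    violations <- c(violations, sprintf("'%s' must be a number in [%g, %g]", field, lo, hi))
  violations
}

#' Validate a raw configuration mapping
#'
#' Merges the input over [default_run_config()], rejecting unknown keys and
#' out-of-range values. All violations are reported together.
#'
#' @param raw named list (possibly nested, e.g. parsed from YAML).
#' @param seed fallback seed when the mapping does not set one.
#' @return the validated, fully populated configuration.
#' @export
validate_config <- function(raw = list(), seed = 1L) {
  defaults <- default_run_config(seed)
  violations <- character()
  config <- defaults
  for (key in names(raw)) {
    if (!key %in% names(defaults)) {
      violations <- c(violations, sprintf("unknown configuration key '%s'", key))
      next
    }
    if (is.list(defaults[[key]])) {
      for (sub in names(raw[[key]])) {
        if (!sub %in% names(defaults[[key]])) {
          violations <- c(violations, sprintf("unknown configuration key '%s.%s'", key, sub))
        } else {
          config[[key]][[sub]] <- raw[[key]][[sub]]
        }
      }
    } else {
      config[[key]] <- raw[[key]]
    }
  }
  violations <- check_range(config$dmp$alpha, "dmp.alpha", 0, 1, violations)
  violations <- check_range(config$dmp$delta_min, "dmp.delta_min", 0, 1, violations)
  violations <- check_range(config$preprocess$detection_p_max,
                            "preprocess.detection_p_max", 0, 1, violations)
  violations <- check_range(config$preprocess$max_missing_fraction,
                            "preprocess.max_missing_fraction", 0, 1, violations)
  violations <- check_range(config$network$min_posterior,
                            "network.min_posterior", 0, 1, violations)
  violations <- check_range(config$synergy$alpha, "synergy.alpha", 0, 1, violations)
  if (length(violations))
    stopf("invalid configuration:\n  - %s", paste(violations, collapse = "\n  - "))
  config
}

# block-diagonal precision with a handful of unit-strength 2x2 couplings;
# default truth for the pipeline's protein-panel stage
demo_precision <- function(p = 22, n_edges = 5, pcor = 0.5) {
  omega <- diag(p)
  pairs <- matrix(seq_len(2 * n_edges), ncol = 2, byrow = TRUE)
  for (r in seq_len(n_edges)) {
    omega[pairs[r, 1], pairs[r, 2]] <- -pcor
    omega[pairs[r, 2], pairs[r, 1]] <- -pcor
  }
  rownames(omega) <- colnames(omega) <- sprintf("P%02d", seq_len(p))
  omega
}

#' Run the end-to-end pipeline on simulated inputs
#'
#' Simulates a methylation cohort, preprocesses it, calls and filters DMPs,
#' infers the protein partial-correlation network, and scores a
#' dose-combination grid for Bliss synergy. With `out_dir` set, stage
#' outputs (`beta_clean.tsv`, `qc_report.json`, `dmp_results.tsv`,
#' `candidates.bed`, `network_edges.tsv`, `synergy_map.tsv`, `report.json`)
#' are written to disk. Rerunning with an identical configuration is
#' bit-identical.
#'
#' @param config a configuration from [validate_config()] /
#'   [default_run_config()].
#' @return a run report list (per-stage counts, parameter echo) with the
#'   stage results attached in `$results`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  t0 <- proc.time()[["elapsed"]]
  seed <- config$seed
  cc <- config$cohort
  planted <- list()
  if (length(cc$planted_deltas)) {
    planted <- lapply(seq_along(cc$planted_deltas), function(i)
      list(locus = sprintf("GENE%04d", i), delta = cc$planted_deltas[i],
           n_affected = cc$n_affected))
  }
  sim <- simulate_methylation_cohort(meth_cohort_config(
    n_cases = cc$n_cases, n_controls = cc$n_controls, n_probes = cc$n_probes,
    n_loci = cc$n_loci, planted_loci = planted, seed = seed))

  pp <- config$preprocess
  clean <- run_preprocess(sim$cohort, preprocess_params(
    min_beads = pp$min_beads, detection_p_max = pp$detection_p_max,
    max_missing_fraction = pp$max_missing_fraction, knn_k = pp$knn_k,
    sd_min = pp$sd_min, color_correction = pp$color_correction, bmiq = pp$bmiq))

  dmp <- dmp_scan(clean)
  cand <- select_candidates(dmp, config$dmp$alpha, config$dmp$delta_min,
                            config$dmp$min_cpgs_per_locus)

  network <- NULL
  if (isTRUE(config$network$enabled)) {
    panel <- simulate_protein_panel(
      demo_precision(config$network$n_proteins),
      config$network$n_samples, seed = seed + 1L)
    network <- ggm_network(panel$panel, config$network$min_posterior)
  }

  syn <- NULL
  if (isTRUE(config$synergy$enabled)) {
    sg <- config$synergy
    inter <- matrix(0, 5, 5)
    inter[4, 4] <- sg$interaction
    dg <- simulate_dose_grid(
      effect_a = c(0, 0.1, 0.2, 0.35, 0.5), effect_b = c(0, 0.1, 0.2, 0.3, 0.45),
      interaction = inter, noise_sd = sg$noise_sd,
      n_replicates = sg$n_replicates, seed = seed + 2L)
    syn <- flag_synergy(synergy_map(dg$grid), sg$alpha)
  }

  report <- list(
    package_version = as.character(utils::packageVersion("fibromark")),
    seed = seed,
    qc = clean$qc,
    n_probes_tested = sum(!is.na(dmp$p_value)),
    n_significant = sum(dmp$p_adjusted < config$dmp$alpha, na.rm = TRUE),
    n_candidates = nrow(cand$candidates),
    n_network_edges = if (is.null(network)) NA_integer_ else nrow(network$edges),
    n_flagged_synergistic = if (is.null(syn)) NA_integer_ else
      sum(syn$flag == "synergistic"),
    elapsed_seconds = round(proc.time()[["elapsed"]] - t0, 2),
    parameters = config[c("preprocess", "dmp", "network", "synergy")]
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(matrix_to_dt(clean$beta),
                       file.path(config$out_dir, "beta_clean.tsv"), sep = "\t")
    jsonlite::write_json(clean$qc, file.path(config$out_dir, "qc_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    data.table::fwrite(dmp, file.path(config$out_dir, "dmp_results.tsv"), sep = "\t")
    write_candidates_bed(cand$candidates, clean$annotation,
                         file.path(config$out_dir, "candidates.bed"))
    if (!is.null(network))
      data.table::fwrite(network$edges,
                         file.path(config$out_dir, "network_edges.tsv"), sep = "\t")
    if (!is.null(syn)) {
      long <- data.table::data.table(
        dose_a = rep(syn$doses_a, times = length(syn$doses_b)),
        dose_b = rep(syn$doses_b, each = length(syn$doses_a)),
        fa_observed = as.vector(syn$fa_observed),
        fa_expected = as.vector(syn$fa_expected),
        delta = as.vector(syn$delta), se = as.vector(syn$se),
        p_adjusted = as.vector(syn$p_adjusted), flag = as.vector(syn$flag))
      data.table::fwrite(long, file.path(config$out_dir, "synergy_map.tsv"), sep = "\t")
    }
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  report$results <- list(truth = sim$truth, clean = clean, dmp = dmp,
                         candidates = cand, network = network, synergy = syn)
  invisible(report)
}
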