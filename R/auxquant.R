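#' Relative expression by the delta-delta-ct method
#'
#' For each target gene and sample, computes
#' `ddct = (ct_target - ct_housekeeper)_treatment - (ct_target - ct_housekeeper)_control`
#' and the relative expression `2^-ddct` separately against each
#' housekeeping gene, then reports the average of the per-housekeeper
#' values (arithmetic by default).
#'
#' @param table long-format qPCR data with columns `sample`, `gene`,
#'   `condition` ("treatment"/"control"), `ct` (e.g. from
#'   [simulate_qpcr_table()]).
#' @param housekeeping housekeeping gene names; defaults to the table's
#'   `housekeeping` attribute or the ACTB/GAPDH/HPRT1 trio.
#' @param average `"arithmetic"` (default) or `"geometric"` mean across
#'   housekeepers.
#' @return data frame `sample`, `gene`, `relative_expression`,
#'   `n_housekeepers` used. Missing housekeeper cts are skipped with a
#'   warning; a target with no usable housekeeper is an error.
#' @export
ddct_expression <- function(table, housekeeping = NULL,
                            average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  if (is.null(housekeeping))
    housekeeping <- attr(table, "housekeeping")
  if (is.null(housekeeping)) housekeeping <- c("ACTB", "GAPDH", "HPRT1")
  stopifnot(all(c("sample", "gene", "condition", "ct") %in% names(table)))
  targets <- setdiff(unique(table$gene), housekeeping)
  get_ct <- function(s, g, cond) {
    v <- table$ct[table$sample == s & table$gene == g & table$condition == cond]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  rows <- list()
  for (s in unique(table$sample)) {
    for (g in targets) {
      ct_t_trt <- get_ct(s, g, "treatment")
      ct_t_ctl <- get_ct(s, g, "control")
      vals <- c()
      for (h in housekeeping) {
        ct_h_trt <- get_ct(s, h, "treatment")
        ct_h_ctl <- get_ct(s, h, "control")
        if (anyNA(c(ct_h_trt, ct_h_ctl))) {
          warnf("ddct_expression: housekeeper %s missing for sample %s; skipped", h, s)
          next
        }
        ddct <- (ct_t_trt - ct_h_trt) - (ct_t_ctl - ct_h_ctl)
        vals <- c(vals, 2^(-ddct))
      }
      if (length(vals) == 0)
        stopf("ddct_expression: no usable housekeeping gene for target %s in sample %s", g, s)
      expr <- if (average == "arithmetic") mean(vals) else exp(mean(log(vals)))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, gene = g, relative_expression = expr,
        n_housekeepers = length(vals), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ChIP signal normalized to input chromatin
#'
#' Ratio of the immunoprecipitated quantity to the non-immunoprecipitated
#' input control; multiplying by the input dilution factor expresses it as
#' percent input.
#'
#' @param ip_quantity immunoprecipitated signal(s).
#' @param input_quantity positive input signal (scalar or same length).
#' @param dilution_factor input dilution factor (default 1; e.g. 100 for a
#'   1% input yields percent-input units).
#' @return normalized signal(s).
#' @export
chip_relative_signal <- function(ip_quantity, input_quantity, dilution_factor = 1) {
  if (any(input_quantity <= 0))
    stopf("chip_relative_signal: input quantity must be positive")
  ip_quantity / input_quantity * dilution_factor
}

#' SRM light/heavy peptide ratio
#'
#' Background-reduced peak areas are computed per transition (floored at
#' zero so no transition contributes negatively), summed across transitions
#' within the light and heavy channels, and divided.
#'
#' @param light,heavy per-transition peak areas (equal length, >= 2
#'   transitions).
#' @param background_light,background_heavy per-transition background
#'   estimates (scalar or same length; default 0).
#' @return the light/heavy ratio; `NA` with a warning when the summed
#'   background-reduced heavy area is zero.
#' @export
srm_ratio <- function(light, heavy, background_light = 0, background_heavy = 0) {
  if (length(light) != length(heavy))
    stopf("srm_ratio: light and heavy need the same number of transitions")
  if (any(light < 0) || any(heavy < 0))
    stopf("srm_ratio: peak areas must be non-negative")
  num <- sum(pmax(light - background_light, 0))
  den <- sum(pmax(heavy - background_heavy, 0))
  if (den <= 0) {
    warnf("srm_ratio: summed background-reduced heavy area is zero; ratio undefined")
    return(NA_real_)
  }
  num / den
}

#' Holm-Sidak step-down multiple-testing correction
#'
#' Sorted ascending, the i-th smallest p-value is adjusted to
#' `1 - (1 - p)^(m - i + 1)`; running maxima enforce monotonicity and the
#' result is capped at 1. Missing values are ignored and propagate.
#'
#' @param p_values numeric vector in \[0,1\].
#' @return adjusted p-values, same length and order.
#' @export
holm_sidak <- function(p_values) {
  out <- rep(NA_real_, length(p_values))
  ok <- which(!is.na(p_values))
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) stopf("holm_sidak: p-values must lie in [0,1]")
  m <- length(p)
  if (m == 0) return(out)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  res <- numeric(m)
  res[o] <- adj
  out[ok] <- res
  out
}
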