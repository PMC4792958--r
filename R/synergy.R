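#' Fraction affected relative to the untreated control
#'
#' `fa = 1 - signal_treated / signal_control`, clamped to \[0,1\]. Growth
#' stimulation above the control clamps to 0 (attribute `n_clamped` counts
#' such wells).
#'
#' @param signal_treated viability signal(s) of treated wells.
#' @param signal_control positive control signal (scalar).
#' @return fraction(s) affected in \[0,1\].
#' @export
fraction_affected <- function(signal_treated, signal_control) {
  if (length(signal_control) != 1L || !is.finite(signal_control) ||
      signal_control <= 0)
    stopf("fraction_affected: control signal must be a single positive value")
  fa <- 1 - signal_treated / signal_control
  n_clamped <- sum(fa < 0 | fa > 1)
  out <- clamp(fa, 0, 1)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Bliss-independence expected combined effect
#'
#' Expected fraction affected of a combination of two independently acting
#' agents: `fa + fb - fa * fb`.
#'
#' @param fa,fb single-agent fractions affected in \[0,1\] (vectorized).
#' @return expected combined fraction affected.
#' @export
bliss_expected <- function(fa, fb) {
  if (any(fa < 0 | fa > 1 | fb < 0 | fb > 1, na.rm = TRUE))
    stopf("bliss_expected: fractions affected must lie in [0,1]")
  fa + fb - fa * fb
}

#' Observed-minus-expected Bliss synergy map
#'
#' For every dose combination, compares the replicate-averaged observed
#' fraction affected with the Bliss expectation computed from the
#' single-agent marginals (row `(a, 0)` and column `(0, b)` of the same
#' grid). Positive delta means more growth suppression than independence
#' predicts (synergy); `delta_viability = -delta` expresses the same on the
#' viability scale.
#'
#' @param grid a `DoseGrid` (see [simulate_dose_grid()]): dose axes and a
#'   doses_a x doses_b x replicate signal array with the untreated control
#'   at `(0, 0)`.
#' @return a `SynergyMap`: list with `fa_observed`, `fa_expected`, `delta`,
#'   `delta_viability`, `se` (replicate standard error of delta),
#'   `replicate_delta` array, dose axes.
#' @export
synergy_map <- function(grid) {
  stopifnot(inherits(grid, "DoseGrid") || is.list(grid))
  sig <- grid$signal
  na <- dim(sig)[1]; nb <- dim(sig)[2]; nr <- dim(sig)[3]
  if (grid$doses_a[1] != 0 || grid$doses_b[1] != 0)
    stopf("synergy_map: grid must contain the untreated control at (0, 0)")
  control <- mean(sig[1, 1, ])
  if (!is.finite(control) || control <= 0)
    stopf("synergy_map: control signal must be positive")
  fa_rep <- 1 - sig / control                # per-replicate fraction affected
  fa_rep <- clamp(fa_rep, 0, 1)
  fa_obs <- apply(fa_rep, c(1, 2), mean)
  fa_a <- fa_obs[, 1]                        # single-agent marginals
  fa_b <- fa_obs[1, ]
  if (anyNA(fa_a) || anyNA(fa_b))
    stopf("synergy_map: single-agent marginal rows/columns are incomplete")
  expected <- outer(fa_a, fa_b, bliss_expected)
  delta_rep <- sweep(fa_rep, c(1, 2), expected)
  delta <- apply(delta_rep, c(1, 2), mean)
  se <- apply(delta_rep, c(1, 2), stats::sd) / sqrt(nr)
  dn <- list(grid$doses_a, grid$doses_b)
  dimnames(fa_obs) <- dimnames(expected) <- dimnames(delta) <- dimnames(se) <- dn
  structure(list(
    fa_observed = fa_obs, fa_expected = expected, delta = delta,
    delta_viability = -delta, se = se, replicate_delta = delta_rep,
    doses_a = grid$doses_a, doses_b = grid$doses_b, n_replicates = nr
  ), class = "SynergyMap")
}

#' Significance flags for a synergy map
#'
#' Per combination, a one-sample t-test of the mean replicate delta against
#' 0, corrected across the grid by the Holm-Sidak method; combinations are
#' flagged `synergistic` (positive delta), `antagonistic` (negative) or
#' `additive`. Single-agent margins and the control have delta identically
#' zero by construction and always come out additive.
#'
#' Viability assays read one plate with one noise level, so by default the
#' replicate variance is pooled across all dose combinations
#' (`variance = "pooled"`), giving the t statistic
#' `(grid cells) * (replicates - 1)` degrees of freedom. With quadruplicate
#' wells a per-combination variance estimate has only 3 degrees of freedom
#' and the family-wise threshold becomes nearly unreachable;
#' `variance = "per_combination"` restores that conservative behaviour.
#'
#' @param map a `SynergyMap`.
#' @param alpha family-wise significance level (default 0.05).
#' @param variance `"pooled"` (default) or `"per_combination"` replicate
#'   variance estimation.
#' @return the map with added `p_value`, `p_adjusted` and `flag` matrices;
#'   with fewer than 2 replicates the flags are withheld with a warning.
#' @export
flag_synergy <- function(map, alpha = 0.05,
                         variance = c("pooled", "per_combination")) {
  stopifnot(inherits(map, "SynergyMap"))
  variance <- match.arg(variance)
  nr <- map$n_replicates
  if (nr < 2) {
    warnf("flag_synergy: need at least 2 replicates; flags withheld")
    map$flag <- NULL
    return(map)
  }
  na <- nrow(map$delta); nb <- ncol(map$delta)
  p <- matrix(NA_real_, na, nb, dimnames = dimnames(map$delta))
  ## the Bliss expectation is built from estimated marginals, whose noise
  ## propagates into delta with delta-method factor 1 + (1-fb)^2 + (1-fa)^2
  fa_a <- map$fa_observed[, 1]
  fa_b <- map$fa_observed[1, ]
  infl <- 1 + outer(rep(1, na), (1 - fa_b)^2) + outer((1 - fa_a)^2, rep(1, nb))
  v <- apply(map$replicate_delta, c(1, 2), stats::var)
  if (variance == "pooled") {
    s2 <- matrix(mean(v), na, nb)
    df_t <- na * nb * (nr - 1)
  } else {
    s2 <- v
    df_t <- nr - 1
  }
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (i == 1 || j == 1) {
      ## margins and control: delta is identically zero by construction
      p[i, j] <- 1
      next
    }
    d_mean <- map$delta[i, j]
    if (s2[i, j] == 0) {
      p[i, j] <- if (abs(d_mean) < 1e-12) 1 else 0
    } else {
      tstat <- d_mean / sqrt(s2[i, j] * infl[i, j] / nr)
      p[i, j] <- 2 * stats::pt(-abs(tstat), df = df_t)
    }
  }
  padj <- matrix(holm_sidak(as.vector(p)), na, nb, dimnames = dimnames(p))
  flag <- matrix("additive", na, nb, dimnames = dimnames(p))
  flag[padj < alpha & map$delta > 0] <- "synergistic"
  flag[padj < alpha & map$delta < 0] <- "antagonistic"
  map$p_value <- p
  map$p_adjusted <- padj
  map$flag <- flag
  map
}

#' @export
print.SynergyMap <- function(x, ...) {
  cat(sprintf("SynergyMap: %d x %d dose combinations, %d replicates\n",
              nrow(x$delta), ncol(x$delta), x$n_replicates))
  cat(sprintf("  delta range: [%.3f, %.3f]\n", min(x$delta), max(x$delta)))
  if (!is.null(x$flag))
    cat(sprintf("  flagged synergistic: %d, antagonistic: %d\n",
                sum(x$flag == "synergistic"), sum(x$flag == "antagonistic")))
  invisible(x)
}
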