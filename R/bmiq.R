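# ---- three-state beta mixture ------------------------------------------
#
# EM fit of a 3-component beta mixture (unmethylated / hemimethylated /
# methylated) to a vector of beta values. Responsibilities are initialized
# by fixed thresholds (<= 0.25 U, >= 0.75 M, else H); the M-step updates
# component shapes by weighted method of moments. Deterministic.
fit_beta_mixture3 <- function(x, tol = 1e-4, maxit = 100) {
  x <- clamp_unit_open(x, 1e-6)
  n <- length(x)
  r <- matrix(0, n, 3)
  r[x <= 0.25, 1] <- 1
  r[x > 0.25 & x < 0.75, 2] <- 1
  r[x >= 0.75, 3] <- 1
  ## empty init classes get a uniform sliver so every component survives
  r <- r + 1e-3
  r <- r / rowSums(r)

  shapes <- matrix(NA_real_, 3, 2)
  w <- rep(1 / 3, 3)
  mom <- function(resp) {
    wsum <- sum(resp)
    m <- sum(resp * x) / wsum
    v <- sum(resp * (x - m)^2) / wsum
    v <- max(v, 1e-6)
    common <- max(m * (1 - m) / v - 1, 0.1)
    clamp(c(m * common, (1 - m) * common), 0.05, 1e4)
  }
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  dens <- matrix(0, n, 3)
  repeat {
    iter <- iter + 1
    for (cmp in 1:3) shapes[cmp, ] <- mom(r[, cmp])
    w <- colSums(r) / n
    for (cmp in 1:3)
      dens[, cmp] <- w[cmp] * stats::dbeta(x, shapes[cmp, 1], shapes[cmp, 2])
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    r <- dens / tot
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    if (iter >= maxit) break
    ll_old <- ll
  }
  ord <- order(shapes[, 1] / rowSums(shapes))  # sort components by mean
  list(shapes = shapes[ord, , drop = FALSE], weights = w[ord],
       loglik = ll, converged = converged, n_iter = iter)
}

# mixture CDF of a fitted 3-state beta mixture
beta_mixture_cdf <- function(x, fit) {
  out <- 0
  for (cmp in 1:3)
    out <- out + fit$weights[cmp] * stats::pbeta(x, fit$shapes[cmp, 1], fit$shapes[cmp, 2])
  out
}

#' Beta-mixture quantile normalization of Infinium type II probes
#'
#' Removes the reduced dynamic range of the type II probe chemistry, per
#' sample. A 3-state beta mixture (unmethylated / hemimethylated /
#' methylated classes) is fitted by EM to the type I and type II beta
#' distributions separately; type II values are then passed through the
#' monotone quantile map `F_I^{-1}(F_II(x))` built from the two fitted
#' mixture distribution functions, so the type II distribution matches the
#' type I reference. Type I probes are returned bit-identical.
#'
#' If the mixture cannot be fitted for a sample (near-zero spread), the
#' empirical distribution function of the type II values stands in for
#' `F_II`, which keeps the map defined (a constant input maps to a
#' constant). Samples with fewer than 50 probes of either design are
#' skipped with a warning.
#'
#' @param beta complete probes x samples matrix in \[0,1\].
#' @param design_type per-probe design vector ("I"/"II").
#' @param tol,maxit EM convergence tolerance (relative log-likelihood) and
#'   iteration cap; non-convergence returns the best iterate with a warning.
#' @param fit_subsample mixture parameters are fitted on at most this many
#'   values per design type (deterministic thinning; the map is applied to
#'   all values). Mixture fits stabilize well below this size.
#' @return the normalized matrix, same shape, values in \[0,1\].
#' @export
bmiq_normalize <- function(beta, design_type, tol = 1e-4, maxit = 100,
                           fit_subsample = 5000) {
  stopifnot(length(design_type) == nrow(beta))
  i1 <- design_type == "I"
  i2 <- design_type == "II"
  if (!any(i1) || !any(i2)) {
    warnf("bmiq_normalize: need both design types; matrix returned unchanged")
    return(beta)
  }
  grid <- seq(1e-6, 1 - 1e-6, length.out = 4001)
  out <- beta
  for (s in seq_len(ncol(beta))) {
    y1 <- beta[i1, s]; y2 <- beta[i2, s]
    if (sum(i1) < 50 || sum(i2) < 50) {
      warnf("bmiq_normalize: sample %d has < 50 probes of one design; skipped", s)
      next
    }
    thin <- function(y) {
      if (length(y) <= fit_subsample) return(y)
      y[seq(1L, length(y), length.out = fit_subsample)]
    }
    fit1 <- fit_beta_mixture3(thin(y1), tol, maxit)
    if (!fit1$converged)
      warnf("bmiq_normalize: type I mixture EM hit iteration cap in sample %d; best iterate used", s)
    ref_cdf <- beta_mixture_cdf(grid, fit1)
    if (stats::sd(y2) > 1e-8) {
      fit2 <- fit_beta_mixture3(thin(y2), tol, maxit)
      if (!fit2$converged)
        warnf("bmiq_normalize: type II mixture EM hit iteration cap in sample %d; best iterate used", s)
      p2 <- beta_mixture_cdf(clamp_unit_open(y2, 1e-6), fit2)
    } else {
      p2 <- stats::ecdf(y2)(y2) * length(y2) / (length(y2) + 1)
    }
    ## invert the type I mixture CDF by monotone interpolation on the grid
    out[i2, s] <- stats::approx(ref_cdf, grid, xout = p2, rule = 2,
                                ties = "ordered")$y
  }
  clamp(out, 0, 1)
}
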