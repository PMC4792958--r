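#' Shrinkage estimate of the correlation matrix
#'
#' Analytic-shrinkage correlation estimator: the convex combination
#' `(1 - lambda) * R + lambda * I` of the sample correlation with the
#' identity target, with the shrinkage intensity chosen to minimize the
#' expected squared loss — `lambda* = sum(Var(r_ij)) / sum(r_ij^2)` over
#' the off-diagonal entries, clamped to \[0,1\]. The result is positive
#' definite whenever `lambda > 0`, which makes partial correlations
#' computable in the small-n, large-p regime of protein panels.
#'
#' @param data proteins x samples matrix (variables in rows).
#' @return list with `correlation` (shrunk matrix) and `lambda`.
#' @export
shrink_correlation <- function(data) {
  x <- t(as.matrix(data))         # samples x variables
  n <- nrow(x); p <- ncol(x)
  if (n < 2) stopf("shrink_correlation: need at least 2 samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stopf("shrink_correlation: zero-variance variable(s): %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
  xs <- scale(x)                  # centred, unit variance (denominator n-1)
  r <- crossprod(xs) / (n - 1)
  ## unbiased-flavour variance of each r_ij from the centred products
  ## w_kij = xs_ki * xs_kj:  Var(r_ij) = n / (n-1)^3 * sum_k (w_kij - wbar)^2
  num <- 0
  den <- 0
  for (j in seq_len(p - 1)) {
    wj <- xs[, (j + 1):p, drop = FALSE] * xs[, j]
    wbar <- colMeans(wj)
    vr <- n / (n - 1)^3 * colSums(sweep(wj, 2, wbar)^2)
    num <- num + sum(vr)
    den <- den + sum(r[j, (j + 1):p]^2)
  }
  lambda <- if (den > 0) clamp(num / den, 0, 1) else 1
  rs <- (1 - lambda) * r
  diag(rs) <- 1
  dimnames(rs) <- list(rownames(data), rownames(data))
  list(correlation = rs, lambda = lambda)
}

#' Partial correlations from a correlation matrix
#'
#' Inverts the (positive-definite) correlation matrix and standardizes:
#' `pcor_ij = -omega_ij / sqrt(omega_ii * omega_jj)`, unit diagonal.
#'
#' @param correlation positive-definite correlation matrix.
#' @return the partial-correlation matrix, same dimnames.
#' @export
partial_correlations <- function(correlation) {
  omega <- tryCatch(solve(correlation), error = function(e) NULL)
  if (is.null(omega))
    stopf("partial_correlations: correlation matrix is singular; shrink it first")
  pc <- -stats::cov2cor(omega)
  diag(pc) <- 1
  dimnames(pc) <- dimnames(correlation)
  pc
}

# null density of a sample partial correlation with kappa degrees of
# freedom: f0(r) = (1 - r^2)^((kappa-3)/2) / Beta(1/2, (kappa-1)/2)
pcor_null_density <- function(r, kappa) {
  exp((kappa - 3) / 2 * log1p(-clamp(r^2, 0, 1 - 1e-12)) -
        lbeta(0.5, (kappa - 1) / 2))
}

#' Two-sided p-values for partial correlations
#'
#' Under the null, the squared partial correlation with `kappa` degrees of
#' freedom follows Beta(1/2, (kappa-1)/2); the two-sided p-value is the
#' upper tail at `r^2`.
#'
#' @param pcor partial-correlation matrix or vector.
#' @param n_samples,n_proteins panel shape, used for the default degrees of
#'   freedom `kappa = max(n - p - 1, 2)`.
#' @param kappa degrees of freedom override (e.g. a value fitted from the
#'   data by [fit_local_fdr()], which is preferable under shrinkage).
#' @return p-values with the shape of `pcor` (diagonal set to `NA` for a
#'   matrix input).
#' @export
pcor_pvalues <- function(pcor, n_samples, n_proteins, kappa = NULL) {
  if (is.null(kappa)) kappa <- max(n_samples - n_proteins - 1, 2)
  p <- stats::pbeta(pcor^2, 0.5, (kappa - 1) / 2, lower.tail = FALSE)
  if (is.matrix(p)) diag(p) <- NA_real_
  p
}

#' Empirical-Bayes local FDR over partial correlations
#'
#' Fits, by maximum likelihood, the two-component mixture
#' `f(r) = eta0 * f0(r; kappa) + (1 - eta0) / 2` over the observed edge
#' partial correlations, where `f0` is the null density with `kappa`
#' degrees of freedom (fitted, since shrinkage inflates the effective
#' sample size) and the alternative is uniform on \[-1,1\]. The posterior
#' probability that an edge is present is `1 - local fdr`, with
#' `local fdr = eta0 * f0(r) / f(r)`.
#'
#' @param pcor_values numeric vector of off-diagonal partial correlations
#'   (at least 10; pass `pcor[upper.tri(pcor)]`).
#' @return list with `posterior` (per input value, in \[0,1\]), `local_fdr`
#'   (`= 1 - posterior`), `eta0`, `kappa`.
#' @export
fit_local_fdr <- function(pcor_values) {
  r <- pcor_values
  if (length(r) < 10)
    stopf("fit_local_fdr: need at least 10 edge values (5 or more variables)")
  if (all(abs(r) < 1e-12)) {
    z <- rep(0, length(r))
    return(list(posterior = z, local_fdr = 1 - z, eta0 = 1, kappa = Inf))
  }
  nll <- function(par) {
    eta0 <- invlogit(par[1])
    kappa <- 2 + exp(par[2])
    f <- eta0 * pcor_null_density(r, kappa) + (1 - eta0) * 0.5
    -sum(log(pmax(f, 1e-300)))
  }
  starts <- expand.grid(e = c(2, 4), k = log(c(5, 30, 200, 2000)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    op <- stats::optim(c(starts$e[i], starts$k[i]), nll, method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || op$value < best$value) best <- op
  }
  eta0 <- invlogit(best$par[1])
  kappa <- 2 + exp(best$par[2])
  f0 <- pcor_null_density(r, kappa)
  f <- eta0 * f0 + (1 - eta0) * 0.5
  lfdr <- clamp(eta0 * f0 / pmax(f, 1e-300), 0, 1)
  list(posterior = 1 - lfdr, local_fdr = lfdr, eta0 = eta0, kappa = kappa)
}

#' Select network edges by posterior probability
#'
#' Edges whose posterior probability of being present reaches
#' `min_posterior` (inclusive) form the reported network, each carrying its
#' sign (inverse correlations are the dotted edges of the usual network
#' drawing) and `|pcor|` as strength.
#'
#' @param result a `GGMResult` from [ggm_network()].
#' @param min_posterior inclusion threshold (default 0.6, equivalently
#'   local FDR at most 0.4).
#' @return data frame `protein_a`, `protein_b`, `pcor`, `p_value`,
#'   `posterior`, `sign`, `strength`, ordered by decreasing posterior.
#' @export
select_edges <- function(result, min_posterior = 0.6) {
  ut <- which(upper.tri(result$pcor), arr.ind = TRUE)
  keep <- result$posterior[ut] >= min_posterior
  idx <- ut[keep, , drop = FALSE]
  labels <- rownames(result$pcor)
  out <- data.frame(
    protein_a = labels[idx[, 1]],
    protein_b = labels[idx[, 2]],
    pcor = result$pcor[idx],
    p_value = result$p_values[idx],
    posterior = result$posterior[idx],
    sign = ifelse(result$pcor[idx] >= 0, "positive", "inverse"),
    strength = abs(result$pcor[idx]),
    stringsAsFactors = FALSE
  )
  out[order(-out$posterior), , drop = FALSE]
}

#' Gaussian graphical model over a protein panel
#'
#' Full network inference: shrinkage correlation, partial correlations,
#' per-edge two-sided p-values (annotation), empirical-Bayes posterior edge
#' probabilities with local FDR, and posterior-thresholded edge selection.
#'
#' @param panel proteins x samples matrix of relative signals. Ratio-scale
#'   inputs should be log-transformed first (`transform = "log"`).
#' @param min_posterior edge-selection threshold (default 0.6).
#' @param transform `"none"` (default; input already on log scale) or
#'   `"log"` for raw positive ratios.
#' @return object of class `GGMResult`: `pcor`, `shrinkage_lambda`,
#'   `p_values`, `posterior` (matrices), `local_fdr`, `eta0`, `kappa`,
#'   `edges` (selected edge table).
#' @export
ggm_network <- function(panel, min_posterior = 0.6,
                        transform = c("none", "log")) {
  transform <- match.arg(transform)
  x <- as.matrix(panel)
  if (anyNA(x)) stopf("ggm_network: panel must not contain missing values")
  if (ncol(x) < 3) stopf("ggm_network: need at least 3 samples")
  if (transform == "log") {
    if (any(x <= 0)) stopf("ggm_network: log transform requires positive ratios")
    x <- log(x)
  }
  sh <- shrink_correlation(x)
  pc <- partial_correlations(sh$correlation)
  ut <- upper.tri(pc)
  lf <- fit_local_fdr(pc[ut])
  pv <- pcor_pvalues(pc, ncol(x), nrow(x),
                     kappa = if (is.finite(lf$kappa)) lf$kappa else NULL)
  post <- lfdr <- matrix(NA_real_, nrow(pc), ncol(pc), dimnames = dimnames(pc))
  post[ut] <- lf$posterior; lfdr[ut] <- lf$local_fdr
  post[lower.tri(post)] <- t(post)[lower.tri(post)]
  lfdr[lower.tri(lfdr)] <- t(lfdr)[lower.tri(lfdr)]
  res <- structure(list(
    pcor = pc, shrinkage_lambda = sh$lambda, p_values = pv,
    posterior = post, local_fdr = lfdr, eta0 = lf$eta0, kappa = lf$kappa,
    n_samples = ncol(x), n_proteins = nrow(x)
  ), class = "GGMResult")
  res$edges <- select_edges(res, min_posterior)
  res
}

#' @export
print.GGMResult <- function(x, ...) {
  cat(sprintf("GGMResult: %d proteins, %d samples\n", x$n_proteins, x$n_samples))
  cat(sprintf("  shrinkage lambda: %.3f; eta0: %.3f; kappa: %.1f\n",
              x$shrinkage_lambda, x$eta0, x$kappa))
  cat(sprintf("  selected edges: %d\n", nrow(x$edges)))
  invisible(x)
}
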