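#' Beta-regression log-likelihood
#'
#' Log-likelihood of the beta regression model with logit mean link and
#' intercept-only log-link precision, at parameters `theta = c(b, log_phi)`.
#' Shared by the fitter and by independent numerical maximizers in checks.
#'
#' @param theta parameter vector: mean coefficients followed by log(phi).
#' @param y response strictly inside (0,1).
#' @param design model matrix (with intercept).
#' @return the log-likelihood value.
#' @export
beta_reg_loglik <- function(theta, y, design) {
  k <- ncol(design)
  b <- theta[seq_len(k)]
  phi <- exp(theta[k + 1])
  mu <- invlogit(drop(design %*% b))
  sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
        (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y))
}

#' Fit a beta regression by maximum likelihood
#'
#' Mean submodel `logit(mu) = design %*% b`, precision `phi` intercept-only
#' with log link, fitted by Fisher scoring with step halving; the asymptotic
#' covariance comes from the observed information at the optimum.
#'
#' @param y response values; clamped to `[eps, 1-eps]` before the
#'   likelihood.
#' @param design numeric model matrix including the intercept column; must
#'   have full column rank.
#' @param eps boundary clamp (default 1e-6).
#' @param maxit,tol scoring iteration cap and gradient tolerance.
#' @return list with `coefficients` (named: design columns plus `log_phi`),
#'   `se`, `vcov_diag`-free `phi`, `loglik`, `converged`, `iterations`.
#'   Non-convergence is flagged, not raised.
#' @export
fit_beta_regression <- function(y, design, eps = 1e-6, maxit = 100, tol = 1e-8) {
  design <- as.matrix(design)
  if (length(y) != nrow(design))
    stopf("fit_beta_regression: length(y) != nrow(design)")
  if (qr(design)$rank < ncol(design))
    stopf("fit_beta_regression: design matrix is rank deficient")
  nms <- c(colnames(design), "log_phi")
  if (is.null(colnames(design))) nms <- c(paste0("b", seq_len(ncol(design)) - 1), "log_phi")
  if (max(y) - min(y) < 1e-12) {
    ## degenerate: response constant, mean fitted exactly, precision unbounded
    b <- qr.solve(design, rep(logit(clamp_unit_open(y[1], eps)), length(y)))
    return(list(coefficients = stats::setNames(c(b, NA_real_), nms),
                se = stats::setNames(rep(NA_real_, ncol(design) + 1), nms),
                phi = NA_real_, loglik = NA_real_, converged = FALSE,
                iterations = 0L))
  }
  fit <- .beta_reg_batch(matrix(y, nrow = 1), design, eps, maxit, tol)
  list(coefficients = stats::setNames(drop(fit$coefficients), nms),
       se = stats::setNames(drop(fit$se), nms),
       phi = exp(fit$coefficients[1, ncol(design) + 1]),
       loglik = fit$loglik[1],
       converged = fit$converged[1],
       iterations = fit$iterations[1])
}
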