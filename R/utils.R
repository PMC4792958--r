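#' Logit and inverse-logit
#'
#' Link functions used throughout: methylation beta values are modelled on
#' the logit scale, effects are planted and estimated there.
#'
#' @param p probability in (0,1).
#' @param x real number.
#' @return `logit()` returns log(p/(1-p)); `invlogit()` returns 1/(1+exp(-x)).
#' @export
logit <- function(p) stats::qlogis(p)

#' @rdname logit
#' @export
invlogit <- function(x) stats::plogis(x)

# clamp into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# clamp a beta value strictly inside (0,1) for likelihood work
clamp_unit_open <- function(x, eps = 1e-6) clamp(x, eps, 1 - eps)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x) && x >= 0

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1
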