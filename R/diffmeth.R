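#' Per-CpG differential methylation scan by beta regression
#'
#' Fits, for every probe, a multivariable beta regression of the beta
#' values on fibrosis status, age, ever-smoking and chemotherapy exposure,
#' and tests the fibrosis coefficient with a two-sided Wald test.
#' Benjamini-Hochberg adjustment controls the FDR across probes. The
#' beta-scale effect estimate is the model difference between cases and
#' controls with the other covariates held at their cohort means.
#'
#' In cohorts of a few dozen samples the per-probe maximum-likelihood
#' precision estimate is noisy and biased upward, which deflates Wald
#' standard errors and inflates the z statistics. With `moderate = TRUE`
#' (default) the scan therefore borrows strength across probes,
#' limma-fashion: each probe's log-precision is first bias-corrected by
#' the residual-degrees-of-freedom factor `(n - k) / n` (k mean-model
#' parameters), then shrunk toward the cohort-wide centre by its posterior
#' mean under a normal prior whose spread is estimated from the excess
#' variance of the observed log-precisions over their sampling variance.
#' Standard errors are rescaled to the moderated precision and the Wald
#' statistic is referred to a Student t distribution with
#' `(n - k) + d0` degrees of freedom, where the prior degrees of freedom
#' `d0 = 2 / tau^2` reflect how much the probes share (a common precision
#' gives `d0 -> Inf`, i.e. a normal reference). Under null simulations at
#' n = 24 this restores approximate uniformity of the p-values, which the
#' plain normal-reference Wald test does not achieve at this sample size,
#' while retaining most of its power.
#'
#' @param clean a preprocessed cohort as returned by [run_preprocess()]
#'   (components `beta`, `samples`, `annotation`).
#' @param eps boundary clamp applied to beta values before the likelihood.
#' @param moderate apply the empirical-Bayes precision moderation described
#'   above (set `FALSE` for the plain asymptotic normal-reference Wald
#'   test).
#' @return a `data.frame` (one row per probe): `probe_id`,
#'   `fibrosis_coefficient` (logit scale), `se`, `wald_z`, `p_value`,
#'   `p_adjusted`, `estimated_difference` (beta scale, cases - controls),
#'   `converged`, `gene_symbols`, `region_relation`. Probes whose fit does
#'   not converge keep `NA` statistics; their count is in
#'   `attr(, "n_failed")`.
#' @export
dmp_scan <- function(clean, eps = 1e-6, moderate = TRUE) {
  beta <- clean$beta
  samples <- clean$samples
  if (anyNA(beta)) stopf("dmp_scan: beta matrix must be complete (run preprocessing first)")
  if (anyNA(samples[c("fibrosis", "age", "smoker_ever", "chemotherapy")]))
    stopf("dmp_scan: sample covariates must be complete")
  design <- stats::model.matrix(
    ~ fibrosis + age + smoker_ever + chemotherapy,
    data = within(samples, {
      fibrosis <- as.integer(fibrosis == "yes")
      smoker_ever <- as.integer(smoker_ever == "yes")
      chemotherapy <- as.integer(chemotherapy == "yes")
    }))
  fit <- .beta_reg_batch(beta, design, eps)
  k <- ncol(design)
  coef_fib <- fit$coefficients[, 2]
  se_fib <- fit$se[, 2]
  if (moderate) {
    n <- nrow(design)
    d_resid <- n - k
    g <- fit$coefficients[, k + 1]           # log precision per probe
    vg <- fit$se[, k + 1]^2                  # its squared standard error
    usable <- fit$converged & is.finite(g) & is.finite(vg) & vg > 0
    g_corr <- g + log(d_resid / n)           # small-sample bias correction
    m0 <- stats::median(g_corr[usable])
    v_med <- stats::median(vg[usable])
    tau2 <- max(stats::var(g_corr[usable]) - v_med, 1e-8)
    d0 <- min(2 / tau2, 1e8)
    vg_f <- ifelse(usable, vg, v_med)
    g_mod <- (g_corr / vg_f + m0 / tau2) / (1 / vg_f + 1 / tau2)
    se_fib <- se_fib * exp((g - g_mod) / 2)  # Var(b) scales as 1/phi
    z <- coef_fib / se_fib
    p <- 2 * stats::pt(-abs(z), df = d_resid + d0)
  } else {
    z <- coef_fib / se_fib
    p <- 2 * stats::pnorm(-abs(z))
  }
  ok <- fit$converged & is.finite(p)
  p[!ok] <- NA_real_
  z[!ok] <- NA_real_

  ## beta-scale difference at cohort-mean covariates
  ref <- c(1, 0, mean(design[, "age"]), mean(design[, "smoker_ever"]),
           mean(design[, "chemotherapy"]))
  eta0 <- drop(fit$coefficients[, seq_len(k)] %*% ref)
  diff <- invlogit(eta0 + coef_fib) - invlogit(eta0)
  diff[!ok] <- NA_real_

  ann <- clean$annotation
  out <- data.frame(
    probe_id = rownames(beta),
    fibrosis_coefficient = coef_fib,
    se = se_fib,
    wald_z = z,
    p_value = p,
    p_adjusted = adjust_bh(p),
    estimated_difference = diff,
    converged = as.logical(fit$converged),
    gene_symbols = ann$gene_symbols[match(rownames(beta), ann$probe_id)],
    region_relation = ann$region_relation[match(rownames(beta), ann$probe_id)],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_failed") <- sum(!ok)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate. Missing
#' values are ignored (they propagate as missing and do not count toward
#' the number of tests).
#'
#' @param p_values numeric vector in \[0,1\], `NA` allowed.
#' @return adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p_values) {
  out <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Beta-scale group difference implied by a fitted beta regression
#'
#' Inverse-logit of the linear predictor for cases minus controls, with the
#' remaining covariates fixed at reference values (typically cohort means).
#'
#' @param coefficients named coefficient vector on the logit scale
#'   (including the intercept).
#' @param group_coef name of the group indicator coefficient.
#' @param reference named values for the remaining non-intercept
#'   covariates; names must match coefficient names.
#' @return the difference on the beta-value scale, in \[-1,1\].
#' @export
estimate_group_difference <- function(coefficients, group_coef = "fibrosis",
                                      reference = NULL) {
  stopifnot(group_coef %in% names(coefficients))
  eta0 <- coefficients[[1]]
  if (!is.null(reference)) {
    bad <- setdiff(names(reference), names(coefficients))
    if (length(bad)) stopf("estimate_group_difference: unknown reference covariates: %s",
                           paste(bad, collapse = ", "))
    eta0 <- eta0 + sum(coefficients[names(reference)] * reference)
  }
  unname(invlogit(eta0 + coefficients[[group_coef]]) - invlogit(eta0))
}

# split multi-gene annotations ("A;B") into per-gene rows
split_gene_symbols <- function(gene_symbols) strsplit(gene_symbols, ";", fixed = TRUE)

#' Candidate-site selection
#'
#' Significant probes (`p_adjusted < alpha`) are retained when the absolute
#' estimated methylation difference reaches `delta_min`, or when their gene
#' locus carries at least `min_cpgs_per_locus` significant probes. A probe
#' annotated to several genes counts toward each; probes without gene
#' annotation form singleton loci and can only enter via the difference
#' rule.
#'
#' @param dmp a [dmp_scan()] result.
#' @param alpha FDR level (default 0.05).
#' @param delta_min minimum absolute beta-scale difference (default 0.10;
#'   the comparison is `>=`).
#' @param min_cpgs_per_locus minimum significant CpGs for the locus rule
#'   (default 2).
#' @return list with `candidates` (data.frame `probe_id`, `reason` in
#'   difference/locus/both, plus the dmp columns) and `locus_table`
#'   (gene -> significant member count).
#' @export
select_candidates <- function(dmp, alpha = 0.05, delta_min = 0.10,
                              min_cpgs_per_locus = 2) {
  sig <- !is.na(dmp$p_adjusted) & dmp$p_adjusted < alpha
  sig_idx <- which(sig)
  genes <- split_gene_symbols(dmp$gene_symbols[sig_idx])
  locus_counts <- table(unlist(genes[!is.na(dmp$gene_symbols[sig_idx])]))
  by_diff <- sig & !is.na(dmp$estimated_difference) &
    abs(dmp$estimated_difference) >= delta_min
  by_locus <- rep(FALSE, nrow(dmp))
  if (length(locus_counts)) {
    hot <- names(locus_counts)[locus_counts >= min_cpgs_per_locus]
    if (length(hot)) {
      by_locus[sig_idx] <- vapply(genes, function(g)
        any(!is.na(g) & g %in% hot), logical(1))
    }
  }
  sel <- by_diff | by_locus
  reason <- ifelse(by_diff & by_locus, "both",
                   ifelse(by_diff, "difference", "locus"))[sel]
  candidates <- cbind(dmp[sel, , drop = FALSE], reason = reason)
  rownames(candidates) <- NULL
  locus_table <- data.frame(gene = names(locus_counts),
                            n_significant = as.integer(locus_counts),
                            stringsAsFactors = FALSE)
  list(candidates = candidates, locus_table = locus_table)
}

#' Mean methylation per amplicon
#'
#' Arithmetic mean over the available (non-missing) CpG-unit methylation
#' values within each amplicon and sample, the summary used for
#' mass-spectrometry (EpiTYPER-style) validation data.
#'
#' @param panel data frame with columns `amplicon_id`, `sample_id`,
#'   `methylation` (one row per CpG unit, values in \[0,1\] or `NA`).
#' @return data frame `amplicon_id`, `sample_id`, `mean_methylation`,
#'   `n_cpgs` (non-missing units); all-missing combinations yield `NA` with
#'   a warning.
#' @export
amplicon_mean_methylation <- function(panel) {
  stopifnot(all(c("amplicon_id", "sample_id", "methylation") %in% names(panel)))
  v <- panel$methylation
  if (any(!is.na(v) & (v < 0 | v > 1)))
    stopf("amplicon_mean_methylation: methylation values must lie in [0,1]")
  key <- interaction(panel$amplicon_id, panel$sample_id, drop = TRUE)
  mm <- tapply(v, key, function(z) mean(z, na.rm = TRUE))
  nn <- tapply(v, key, function(z) sum(!is.na(z)))
  mm[nn == 0] <- NA_real_
  if (any(nn == 0))
    warnf("amplicon_mean_methylation: %d amplicon/sample pairs have no available CpGs", sum(nn == 0))
  first <- !duplicated(key)
  out <- data.frame(amplicon_id = panel$amplicon_id[first],
                    sample_id = panel$sample_id[first],
                    mean_methylation = as.numeric(mm[as.character(key[first])]),
                    n_cpgs = as.integer(nn[as.character(key[first])]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Two-group Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of methylation levels between groups:
#' exact enumeration when the combined sample size is at most 12 and there
#' are no ties, normal approximation (with tie/continuity correction)
#' otherwise.
#'
#' @param values numeric vector.
#' @param group_labels vector with exactly two distinct labels.
#' @return list with `statistic` (rank-sum W of the first group) and
#'   `p_value`.
#' @export
wilcoxon_group_test <- function(values, group_labels) {
  groups <- split(values, group_labels)
  if (length(groups) != 2L) stopf("wilcoxon_group_test: need exactly two groups")
  if (any(lengths(groups) == 0L)) stopf("wilcoxon_group_test: a group is empty")
  n_tot <- length(values)
  has_ties <- anyDuplicated(values) > 0
  wt <- suppressWarnings(stats::wilcox.test(
    groups[[1]], groups[[2]],
    exact = (n_tot <= 12 && !has_ties), correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1   # fully tied data carry no ordering evidence
  list(statistic = unname(wt$statistic), p_value = min(p, 1))
}

#' Pearson correlation with F-test of the regression slope
#'
#' Pearson r together with the least-squares slope, its 95% confidence
#' interval, and the F-test p-value for slope = 0 (identical to the
#' two-sided t-test; F = t^2).
#'
#' @param x,y numeric vectors; pairs with missing values are dropped.
#' @return list `r`, `slope`, `slope_ci` (length 2), `F`, `p_value`, `n`.
#' @export
correlate_with_ftest <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("correlate_with_ftest: need at least 3 complete pairs")
  if (stats::sd(x) == 0) stopf("correlate_with_ftest: x has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  tval <- sm$coefficients["x", "t value"]
  list(r = stats::cor(x, y),
       slope = unname(stats::coef(fit)["x"]),
       slope_ci = unname(stats::confint(fit, "x", level = 0.95)[1, ]),
       F = unname(tval^2),
       p_value = unname(sm$coefficients["x", "Pr(>|t|)"]),
       n = length(x))
}
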