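---
title: "Methods behind fibromark: models, parameters and design choices"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`fibromark` re-implements, as a tested and reusable pipeline, the
statistical machinery of a fibrosis-biomarker methylation study: 450K-style
array preprocessing, per-CpG beta-regression differential methylation with
candidate filtering, a shrinkage Gaussian graphical model over a protein
panel, Bliss-independence drug-synergy scoring, and the small
quantification formulas (ΔΔct, ChIP input normalization, SRM ratios,
Holm–Šidák). Patient array data of this kind are controlled-access, so the
package ships seeded synthetic-data generators that emit every input the
pipeline consumes together with the planted ground truth, and the whole
pipeline is validated by recovery and calibration experiments against that
truth.

# The synthetic cohort

`simulate_methylation_cohort()` draws per-probe baseline methylation means
from a three-component beta mixture (defaults: Beta(2,10), Beta(10,2),
Beta(5,5) with weights 0.35/0.35/0.30), reproducing the bimodal shape of
array methylomes. Given a probe mean μ and precision φ, sample values are
Beta(μφ, (1−μ)φ); the default φ = 50 gives a between-sample standard
deviation of about 0.07 at μ = 0.5 — the upper range of inter-individual
variability at variable CpGs, where a 5% standard-deviation filter still
retains a substantial probe set.

Effects are planted on the logit-mean scale for case samples only. When a
locus is configured with a beta-scale target difference δ, the logit shift
is solved per probe as `logit(m + δ) − logit(m)`, and covariate
contributions (age ~ Uniform(40, 70) years with coefficient 0.01/year;
ever-smoking ~ Bernoulli(0.4) and chemotherapy ~ Bernoulli(0.5), each with
coefficient 0.15 on the logit scale) are centred, so the recorded ground
truth difference is exact at cohort-mean covariates. Baselines for which
m + δ would leave (0.02, 0.98) are redrawn uniformly on an interior range
so every configured effect is attainable. The paper-scale experiments use
12 cases vs 12 controls, 20,000 probes, and 10 planted loci of 2–4 CpGs
with |δ| between 0.12 and 0.20.

Array artifacts are layered on top of the latent betas, in this order:

* **Type II compression.** 70% of probes are "type II" and their values
  are shrunk toward 0.5 by a factor 0.8 (`beta' = 0.5 + c(beta − 0.5)`),
  emulating the reduced dynamic range of that chemistry. This is what
  makes beta-mixture quantile normalization testable.
* **Dye bias.** When enabled (default 0.1), channel intensities are
  emitted (total intensity ~ lognormal around 5000) and every red-channel
  signal is inflated by the factor 1.1; type I probes read both signals in
  one channel, type II probes read methylated in green and unmethylated in
  red. Observed betas are then M/(M+U+100).
* **Detection failures** (rate 0.005) get detection p-values above 0.01
  and a noise beta; **low-bead measurements** (rate 0.002) get bead counts
  below 3; 2% of probes carry an SNP flag.

What the generator does *not* emulate: chip/position batch effects,
probe cross-hybridization, cell-type composition, and spatially
correlated failures. Passing recovery tests therefore demonstrate the
statistical machinery under the model's own assumptions, not robustness
to every artifact of real arrays.

# Preprocessing

`run_preprocess()` executes the filtering and normalization stages in a
fixed order: bead filter (counts < 3 set the detection p to 1) →
detection mask (p > 0.01, strictly, sets the beta to missing) → drop of
probes with > 0.3 missing → drop of SNP-flagged probes → kNN imputation →
two-colour correction → BMIQ → variance filter (across-sample s.d.
< 0.05, strictly, on the normalized values). The variance filter runs
last because it is defined on the values entering the regression; whether
its cut is strict at exactly 0.05 is a boundary nobody's data ever sits
on, and we use the strict reading.

**kNN imputation** treats probes as items and samples as the feature
axis: distances are squared Euclidean over co-observed samples, rescaled
by the full sample count for comparability across overlap sizes; each
missing entry is the inverse-distance-weighted mean of the k = 10 nearest
probes observed at that sample, with the probe mean as fallback. The
computation is exact (no clustering approximation) and runs in compiled
code.

**Two-colour correction** maps both channels' intensities onto their
pooled average quantile function by monotone interpolation over 512
quantile knots, per sample — a symmetric choice, since no reference
channel is canonical — and recomputes betas as M/(M+U+100) with the
platform's conventional stabilizing offset 100 (configurable). Ranks
within a channel are preserved; imputed cells are protected from being
overwritten by the recomputation.

**BMIQ.** A three-state beta mixture (unmethylated / hemimethylated /
methylated) is fitted by EM separately to the type I and type II values
of each sample. Responsibilities initialize from fixed thresholds (≤ 0.25
U, ≥ 0.75 M), the M-step uses weighted method-of-moments shape updates,
the tolerance is 1e-4 on the relative log-likelihood with a cap of 100
iterations (the best iterate is used, with a warning, if the cap is hit),
and fits use a deterministic thinning to at most 5000 values — mixture
parameters are stable well below that. Type II values are then passed
through the monotone quantile map `F_I^{-1}(F_II(x))` built from the two
fitted mixture distribution functions (inverted on a 4001-point grid), so
the type II distribution matches the type I reference; type I values are
returned bit-identical. We chose the whole-mixture quantile map over the
original class-wise construction (class-conditional maps for U and M, a
dilation for the middle class) because it is strictly monotone by
construction, has no class-boundary seams, and achieves the same goal the
acceptance property tests: the Kolmogorov–Smirnov distance between type II
and type I distributions strictly decreases in ≥ 95% of samples under
compression 0.7.

# Differential methylation

Each probe is fitted by maximum-likelihood beta regression with a logit
mean link (intercept + fibrosis + age + smoking + chemotherapy) and an
intercept-only log-link precision φ, with betas clamped to
[1e-6, 1 − 1e-6]. Fitting is Fisher scoring with step halving; standard
errors come from the observed information at the optimum; the fibrosis
coefficient is tested two-sided and Benjamini–Hochberg adjusted. The
fitter is verified against an independent general-purpose maximizer of the
same log-likelihood to 1e-4 on random small datasets, and the reported
optimum is never below the oracle's.

**Small-sample calibration.** At two dozen samples, the per-probe ML
precision estimate is noisy and biased upward, which deflates the Wald
standard errors: in null simulations at n = 24 the plain normal-reference
Wald test rejects at roughly twice the nominal 5% level and several-fold
in the far tail, while a simple `t_{n-k}` correction overshoots in the
opposite direction and costs most of the power at genome-wide thresholds.
`dmp_scan()` therefore defaults to an empirical-Bayes moderated Wald
test: each probe's log-precision is bias-corrected by the residual-df
factor (n − k)/n, then shrunk toward the cohort-wide centre with weights
given by its sampling variance and the across-probe excess variance τ²;
standard errors are rescaled to the moderated precision and the statistic
is referred to Student t with (n − k) + d0 degrees of freedom, d0 = 2/τ².
When probes genuinely share a precision scale, d0 grows large and the
reference approaches the normal; when they do not, the reference stays
appropriately heavy-tailed. This is the same information-sharing idea
used routinely for expression-array variance moderation, transplanted to
the beta-regression precision. Null simulations confirm approximate
uniformity of the resulting p-values and zero candidate sites at the 5%
FDR level; `moderate = FALSE` restores the plain asymptotic test.

**Candidate filter.** Significant probes (adjusted p < 0.05) are kept
when the model-estimated beta-scale difference (cases − controls, other
covariates at cohort means) reaches 10% in absolute value, or when their
gene locus carries at least 2 significant CpGs. Loci are annotated gene
symbols; a probe listing several genes counts toward each; intergenic
probes form singleton loci and can only enter via the difference rule.
The model-estimated difference is used rather than raw group means
(a raw-mean mode is one flag away) because it is covariate-adjusted.

# The protein network

Protein panels (log relative signals, irradiated vs untreated; ratio
inputs can be log-transformed with `transform = "log"`) are analysed with
an analytic-shrinkage correlation estimator: the sample correlation is
blended with the identity, `(1 − λ)R + λI`, with λ chosen as the ratio of
the summed sampling variances of the off-diagonal correlations to their
summed squares, clamped to [0, 1]. This guarantees positive definiteness
in the p = 22, n = 7 regime of the motivating panel. Partial correlations
follow by matrix inversion and standardization.

Edge significance has two layers. Two-sided p-values use the null density
of a sample partial correlation with κ degrees of freedom (equivalently,
r² ~ Beta(1/2, (κ−1)/2)); because shrinkage inflates the effective sample
size, κ is fitted from the data rather than fixed at n − p − 1 (which is
also negative in the motivating regime; the density requires κ > 1, so
the non-fitted fallback uses max(n − p − 1, 2)). The edge posterior comes
from a two-component empirical-Bayes mixture over the observed partial
correlations — η0 times the null density with fitted κ plus (1 − η0)
times a uniform alternative on [−1, 1] — maximized by Nelder–Mead from a
small grid of starts; the local FDR of an edge is η0 f0/f and its
posterior probability of presence is one minus that. Edges are reported
when the posterior reaches 0.6, i.e. local FDR at most 0.4 — we read the
study's "upper bound for the posterior probability equal to 0.6" in the
only direction consistent with local FDR = 1 − posterior producing a
sparse network, and expose the threshold as a parameter. The p < 0.1
reporting threshold is carried as an annotation, not as the selection
rule.

# Synergy

Viability signals are converted to fractions affected relative to the
(0,0) control, per replicate, clamped to [0, 1]. The Bliss expectation
for a combination is `fa + fb − fa·fb` computed from the
replicate-averaged single-agent marginals of the same grid; the synergy
score is observed minus expected fraction affected (positive = more
suppression than independence predicts), with its replicate standard
error; the same surface is exposed on the viability scale with the
opposite sign. Per-combination one-sample t-tests against zero,
Holm–Šidák-corrected across the grid, flag interior combinations as
synergistic or antagonistic at family-wise level 0.05; single-agent
margins and the control are not tested, since their delta is identically
zero by construction. The tests account for the fact that the Bliss
expectation is built from *estimated* marginals: the marginal sampling
noise propagates into delta with the delta-method variance factor
1 + (1 − fa)² + (1 − fb)², without which the null flag rate exceeds its
nominal level. Because a viability plate is read
with one noise level, the replicate variance is pooled across the grid by
default, giving the t statistics `(cells)·(replicates − 1)` degrees of
freedom — with per-combination variance and quadruplicate wells the
family-wise threshold needs |t| above ten on three degrees of freedom,
which makes detection hostage to the variance draw rather than to the
effect; a `per_combination` mode keeps that conservative variant
available. Replicate fractions are averaged after the per-replicate delta
computation, so standard errors reflect replicate scatter; grids need at
least two replicates for flags.

# Numerical choices and degenerate inputs

* Beta values exactly 0 or 1 are clamped at 1e-6 before any likelihood.
* A constant probe cannot identify a finite precision: the single-fit
  interface returns the exact logit solution for the mean with the
  convergence flag lowered; the scan excludes such probes and counts them.
* Mixture EM ties are avoided by seeding every component with a small
  uniform responsibility sliver; a zero-variance type II distribution
  falls back to an empirical-CDF map (constant in, constant out).
* The local-FDR fit caps η0 away from 1 only through its logistic
  parameterization; an all-zero partial-correlation vector short-circuits
  to η0 = 1 with all posteriors 0.
* `flag_synergy` treats replicate deltas with zero spread as
  non-evidence (p = 1) unless their common value is nonzero beyond
  floating-point epsilon.
* All generators are pure functions of (config, seed); the preprocessing
  and inference stages contain no randomness, so the end-to-end pipeline
  is bit-reproducible.

# Problem sizes used in validation

The packaged experiments run the recovery study at 20,000 probes × 24
samples over 25 seeds (test suite) or 10 seeds (acceptance script), null
calibration at 5,000 probes over 20 (suite) or 8 (script) seeds, the
graphical-model recovery at p = 22 with n = 200 over 25/15 simulations,
and the synergy experiments on 5 × 5 grids in quadruplicate over 20
seeds. These sizes were chosen to estimate the reported rates with
Monte-Carlo standard errors comfortably below the margins being tested.

# Known limitations

* The moderated test assumes probes share information about precision;
  grossly heteroscedastic probe families would reduce d0 and power, not
  validity.
* The colour correction equalizes whole-channel distributions; it cannot
  correct probe-specific dye effects.
* Gene-locus grouping follows annotation only; no coordinate-window DMR
  segmentation is attempted.
* The network module infers partial correlations, not directions or
  causal structure, and at n = 7 its power is intrinsically low — on
  paper-shaped panels expect few or no edges to clear the posterior
  threshold unless couplings are strong.
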