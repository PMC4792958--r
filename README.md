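# fibromark

Differential DNA methylation, protein partial-correlation networks and
drug-synergy analysis for radiation-induced fibrosis studies — an
end-to-end, simulation-validated R implementation.

## The problem

Late fibrosis is a common toxicity of breast-cancer radiotherapy, and
patient-derived fibroblasts show fibrosis-associated differences in DNA
methylation measurable on Illumina 450K-style arrays. Finding those
differences robustly requires a chain of statistical steps — array QC
filtering, imputation, two-colour and probe-chemistry normalization,
covariate-adjusted regression on (0,1)-bounded beta values, multiplicity
control and effect-size filtering — followed, in the motivating study
design, by partial-correlation network inference over a small protein
panel and Bliss-independence scoring of drug-combination experiments.
`fibromark` implements that chain for analysts who want to run it on
matrix-level array exports, and — because such patient data are
controlled-access — ships seeded generators that produce statistically
faithful synthetic cohorts *with known ground truth*, so every stage is
validated by recovery and calibration experiments rather than by eye.

## The core statistics

* **Per-CpG beta regression.** Each probe's beta values are modelled as
  Beta(μφ, (1−μ)φ) with logit(μ) = β₀ + β_fib·fibrosis + β_age·age +
  β_smk·smoking + β_chemo·chemotherapy and log-link intercept-only
  precision φ, fitted by Fisher scoring (compiled, thousands of probes per
  second). The fibrosis coefficient is Wald-tested two-sided; p-values are
  Benjamini–Hochberg adjusted. By default the test is *moderated*: probe
  log-precisions are bias-corrected and shrunk empirical-Bayes style
  across probes, and the statistic uses a t reference with
  (n−k) + 2/τ² degrees of freedom — calibrated at small n where the plain
  asymptotic Wald test is not.
* **Candidate sites** are significant probes with a model-estimated
  methylation difference ≥ 10%, or whose gene locus carries ≥ 2
  significant CpGs.
* **Preprocessing**: bead-count filter (< 3), detection-p mask (> 0.01),
  missingness cap (0.3), SNP-probe drop, kNN imputation (k = 10,
  probes × samples), smooth quantile colour correction, and beta-mixture
  quantile normalization (BMIQ) of Infinium type II probes.
* **Gaussian graphical model**: analytic-shrinkage correlation
  (1−λ)R + λI, partial correlations by inversion, per-edge p-values from
  the pcor null density, and an empirical-Bayes local FDR whose posterior
  (≥ 0.6) selects network edges.
* **Bliss synergy**: observed minus expected fraction affected,
  fa + fb − fa·fb, from replicated dose grids, with Holm–Šidák-corrected
  replicate t-tests flagging synergistic/antagonistic combinations.
* **Bench formulas**: 2^−ΔΔct relative expression averaged over the
  ACTB/GAPDH/HPRT1 housekeeping trio, ChIP percent-input, SRM light/heavy
  transition ratios, Holm–Šidák and BH corrections, exact Wilcoxon
  rank-sum, Pearson r with slope F-test.

## A worked example

```r
library(fibromark)

## a 24-sample cohort, 5,000 probes, three planted differentially
## methylated loci (two CpGs each, +/-15% methylation difference)
planted <- lapply(1:3, function(i)
  list(locus = sprintf("GENE%04d", i), delta = c(0.15, 0.15, -0.15)[i],
       n_affected = 2))
sim <- simulate_methylation_cohort(meth_cohort_config(
  n_probes = 5000, n_loci = 400, planted_loci = planted, seed = 42))

clean <- run_preprocess(sim$cohort)           # filters + impute + normalize
unlist(clean$qc)
#>              probes_in                samples         cells_low_bead
#>                   5000                     24                    236
#>           cells_masked probes_dropped_missing     probes_dropped_snp
#>                    830                      0                     94
#>          cells_imputed  probes_dropped_low_sd             probes_out
#>                    823                   1781                   3125

dmp  <- dmp_scan(clean)                        # moderated beta-regression scan
cand <- select_candidates(dmp)                 # FDR 5% + effect/locus rules
cand$candidates[, c("probe_id", "p_adjusted", "estimated_difference", "reason")]
#>     probe_id   p_adjusted estimated_difference     reason
#> 1 cg00000758 0.0004556094            0.1490606 difference
#> 2 cg00001641 0.0021067720            0.1437415 difference
#> 3 cg00002136 0.0010245763           -0.1324997 difference

sim$truth$true_dmp_ids                         # ground truth
#> [1] "cg00000758" "cg00001477" "cg00001641" "cg00002136"
```

Four planted CpGs survive locus assignment on this seed; the scan
recovers three of them with zero false positives. Each candidate clears
the 5% FDR level and the 10% estimated-difference rule (`reason =
"difference"`); the missed CpG's difference falls under the genome-wide
threshold at 12-vs-12 — averaged over many seeds at the full 20,000-probe
scale the selection attains sensitivity above 0.8 at an empirical FDR
under 0.1 (see the acceptance script below).

The same package drives the network and synergy stages:

```r
panel <- simulate_protein_panel(diag(22), n_samples = 7, seed = 1)$panel
net   <- ggm_network(panel)                    # p = 22, n = 7 works (shrinkage)

grid  <- simulate_dose_grid(c(0, .1, .2, .35, .5), c(0, .1, .2, .3, .45),
                            interaction = 0.0, noise_sd = 0.02,
                            n_replicates = 4, seed = 1)$grid
flag_synergy(synergy_map(grid))                # nothing flagged on a null grid
```

## Package layout

* `R/`, `src/` — implementation (simulators, preprocessing, beta
  regression in RcppArmadillo, scan + candidate filter, GGM, synergy,
  bench formulas, pipeline driver).
* `tests/testthat/` — unit, property and end-to-end recovery tests.
* `inst/cli/fibromark.R` — thin command-line front end over
  `run_pipeline()` (YAML config mirroring `default_run_config()`).
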