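Package: fibromark
Title: Differential DNA Methylation, Protein Networks and Drug Synergy for
    Radiation-Induced Fibrosis Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, simulation-validated pipeline for
    fibrosis-biomarker discovery from Illumina 450K-style methylation
    arrays: raw-data filtering (bead counts, detection p-values,
    missingness, SNP probes), k-nearest-neighbour imputation, two-colour
    smooth quantile normalization, beta-mixture quantile normalization of
    Infinium type II probes, per-CpG multivariable beta regression with
    Wald tests and Benjamini-Hochberg control, and candidate-site filtering
    by effect size or gene-locus clustering. Companion modules infer
    shrinkage-based Gaussian graphical models with empirical-Bayes local
    false discovery rates over protein panels, score drug-combination
    synergy under the Bliss independence model, and provide the small
    quantification formulas (delta-delta-Ct expression, ChIP input
    normalization, SRM light/heavy ratios, Holm-Sidak correction) used
    around such studies. Seeded synthetic-data generators with exported
    ground truth support recovery and calibration testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
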