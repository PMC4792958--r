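# On-disk layouts: probes x samples matrices as TSV with probe_id in the
# first column and sample ids in the header; annotation and sample sheet as
# CSV; reports as JSON.

matrix_to_dt <- function(m) {
  data.table::data.table(probe_id = rownames(m), as.data.frame(m))
}

dt_to_matrix <- function(dt) {
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' Write a methylation cohort to a directory
#'
#' Emits `beta.tsv`, `detection_p.tsv`, `beads.tsv`, optional
#' `signal_meth.tsv` / `signal_unmeth.tsv`, `annotation.csv`, `samples.csv`.
#'
#' @param cohort a `MethylationCohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fw <- function(x, f, ...) data.table::fwrite(x, file.path(dir, f), sep = "\t", ...)
  fw(matrix_to_dt(cohort$beta), "beta.tsv")
  fw(matrix_to_dt(cohort$detection_p), "detection_p.tsv")
  fw(matrix_to_dt(cohort$bead_count), "beads.tsv")
  if (!is.null(cohort$signal_meth)) {
    fw(matrix_to_dt(cohort$signal_meth), "signal_meth.tsv")
    fw(matrix_to_dt(cohort$signal_unmeth), "signal_unmeth.tsv")
  }
  data.table::fwrite(cohort$annotation, file.path(dir, "annotation.csv"))
  data.table::fwrite(cohort$samples, file.path(dir, "samples.csv"))
  invisible(dir)
}

#' Read a methylation cohort from a directory
#'
#' Counterpart of [write_cohort()]; missing optional intensity files yield
#' `NULL` layers.
#'
#' @param dir directory with the cohort files.
#' @return a `MethylationCohort`.
#' @export
read_cohort <- function(dir) {
  fr <- function(f) data.table::fread(file.path(dir, f), sep = "\t")
  beta <- dt_to_matrix(fr("beta.tsv"))
  cohort <- list(
    beta = beta,
    detection_p = dt_to_matrix(fr("detection_p.tsv")),
    bead_count = dt_to_matrix(fr("beads.tsv")),
    signal_meth = NULL, signal_unmeth = NULL,
    annotation = as.data.frame(data.table::fread(file.path(dir, "annotation.csv"))),
    samples = as.data.frame(data.table::fread(file.path(dir, "samples.csv")))
  )
  if (file.exists(file.path(dir, "signal_meth.tsv"))) {
    cohort$signal_meth <- dt_to_matrix(fr("signal_meth.tsv"))
    cohort$signal_unmeth <- dt_to_matrix(fr("signal_unmeth.tsv"))
  }
  structure(cohort, class = "MethylationCohort")
}

#' Write candidate sites as a BED track
#'
#' Converts the 1-based annotation positions to 0-based half-open
#' single-base intervals; the score column is `-10 * log10(p_adjusted)`
#' capped at 1000.
#'
#' @param candidates candidate table from [select_candidates()].
#' @param annotation probe annotation with `probe_id`, `chromosome`,
#'   `position`, `strand`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_candidates_bed <- function(candidates, annotation, path) {
  i <- match(candidates$probe_id, annotation$probe_id)
  score <- pmin(round(-10 * log10(pmax(candidates$p_adjusted, 1e-100))), 1000)
  bed <- data.table::data.table(
    chrom = annotation$chromosome[i],
    start = annotation$position[i] - 1L,
    end = annotation$position[i],
    name = candidates$probe_id,
    score = score,
    strand = annotation$strand[i]
  )
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
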