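#' Write / read a scan's time series as TSV
#'
#' One file per scan: rows = regions, columns = time points, tab-separated,
#' no header; the TR (seconds) and scan id travel in the cohort manifest.
#'
#' @param ts a [RegionalTimeSeries-class].
#' @param path file path.
#' @param trSeconds,scanId metadata to attach when reading.
#' @return `writeTimeSeries` returns `path` invisibly; `readTimeSeries`
#'   returns a [RegionalTimeSeries-class].
#' @export
writeTimeSeries <- function(ts, path) {
  utils::write.table(tsMatrix(ts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeTimeSeries
#' @export
readTimeSeries <- function(path, trSeconds = 3, scanId = basename(path)) {
  m <- tryCatch(
    as.matrix(utils::read.table(path, sep = "\t", header = FALSE)),
    error = function(e) stopf("malformed time-series TSV '%s': %s",
                              path, conditionMessage(e)))
  if (!is.numeric(m) || anyNA(m))
    stopf("malformed time-series TSV '%s': non-numeric or missing entries", path)
  dimnames(m) <- NULL
  regionalTimeSeries(m, trSeconds = trSeconds, scanId = scanId)
}

#' Write a synthetic cohort to disk
#'
#' Produces the on-disk layout consumed by the pipeline:
#' `parcellation.tsv` (region table), `subjects.tsv` (covariates),
#' `manifest.tsv` (scan id, file, TR, subject id) and one
#' `timeseries/<scan>.tsv` per scan.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  writeParcellation(cohortScheme(cohort), file.path(dir, "parcellation.tsv"))
  utils::write.table(cohortSubjects(cohort), file.path(dir, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  scans <- cohortScans(cohort)
  man <- data.frame(
    scan_id = vapply(scans, scanId, ""),
    file = file.path("timeseries",
                     paste0(vapply(scans, scanId, ""), ".tsv")),
    tr_seconds = vapply(scans, trSeconds, 0),
    subject_id = cohortSubjects(cohort)$subject_id,
    stringsAsFactors = FALSE)
  for (i in seq_along(scans))
    writeTimeSeries(scans[[i]], file.path(dir, man$file[i]))
  utils::write.table(man, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort manifest
#'
#' @param dir directory written by [writeCohort()] (or laid out the same
#'   way).
#' @return List with `manifest` (data.frame), `subjects` (data.frame) and
#'   `scheme` ([ParcellationScheme-class]).
#' @export
readCohortDir <- function(dir) {
  manPath <- file.path(dir, "manifest.tsv")
  if (!file.exists(manPath)) stopf("no manifest.tsv in '%s'", dir)
  man <- utils::read.table(manPath, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  subj <- utils::read.table(file.path(dir, "subjects.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  scheme <- readParcellation(file.path(dir, "parcellation.tsv"))
  list(manifest = man, subjects = subj, scheme = scheme, dir = dir)
}
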