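#' Serialise an atom stack as text
#'
#' Writes the N x N x 16 array as a TSV of 16 vertically stacked N x N
#' planes (N * 16 rows of N columns) plus a JSON sidecar
#' (`<path>.json`) recording the scan id, N and the plane order, which is
#' the canonical [atomNames()] order.
#'
#' @param stack an [AtomStack-class].
#' @param path output TSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
writeAtomStack <- function(stack, path) {
  v <- atomValues(stack)
  n <- dim(v)[1]
  flat <- do.call(rbind, lapply(atomNames(), function(a) v[, , a]))
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  sidecar <- list(scan_id = scanId(stack), n_regions = n,
                  atom_order = atomNames())
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeAtomStack
#' @export
readAtomStack <- function(path) {
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(sc$atom_order, atomNames()))
    stopf("sidecar of '%s' lists an unexpected atom order", path)
  n <- sc$n_regions
  flat <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  if (!all(dim(flat) == c(n * 16L, n)))
    stopf("'%s' has dimensions %d x %d, expected %d x %d",
          path, nrow(flat), ncol(flat), n * 16L, n)
  v <- array(0, dim = c(n, n, 16L))
  for (a in seq_len(16L))
    v[, , a] <- flat[((a - 1L) * n + 1L):(a * n), ]
  atomStack(v, scanId = sc$scan_id)
}
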