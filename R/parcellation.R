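#' Build a synthetic extended parcellation
#'
#' Constructs a [ParcellationScheme-class] in the style of the extended
#' Schaefer atlases: `nCortical` cortical regions partitioned across the
#' seven Yeo networks plus `nSubcortical` regions labelled Subcortex. The
#' reference sizes are 200 + 32 = 232 and 100 + 16 = 116.
#'
#' Cortical regions are allocated proportionally (equal shares, remainder to
#' Visual) in contiguous blocks, so the layout is deterministic and
#' size-agnostic; `seed` is accepted for interface symmetry with the other
#' generators but does not influence the result.
#'
#' @param nCortical number of cortical regions (>= 8, so every network is
#'   non-empty).
#' @param nSubcortical number of subcortical regions (>= 1).
#' @param seed integer, unused (allocation is deterministic).
#' @return A [ParcellationScheme-class] with `nCortical + nSubcortical`
#'   regions.
#' @examples
#' scheme <- buildParcellation(200, 32)
#' nRegions(scheme)    # 232
#' table(networkLabels(scheme))
#' @export
buildParcellation <- function(nCortical, nSubcortical, seed = NULL) {
  if (nCortical < 8 || nSubcortical < 1)
    stopf("need nCortical >= 8 and nSubcortical >= 1 (got %d, %d)",
          nCortical, nSubcortical)
  nCortical <- as.integer(nCortical)
  nSubcortical <- as.integer(nSubcortical)
  nets <- yeoNetworks()[1:7]
  base <- nCortical %/% 7L
  counts <- rep(base, 7L)
  counts[1] <- counts[1] + nCortical %% 7L   # remainder to Visual
  labels <- c(rep(nets, counts), rep("Subcortex", nSubcortical))
  names_c <- unlist(lapply(seq_along(nets), function(k)
    sprintf("CTX_%s_%02d", nets[k], seq_len(counts[k]))), use.names = FALSE)
  names_s <- sprintf("SUBC_%02d", seq_len(nSubcortical))
  n <- nCortical + nSubcortical
  methods::new("ParcellationScheme",
    regionIds = seq_len(n) - 1L,
    regionNames = c(names_c, names_s),
    networkLabels = labels,
    nCortical = nCortical,
    nSubcortical = nSubcortical)
}

#' Region indices of one network
#'
#' @param scheme a [ParcellationScheme-class].
#' @param network one of [yeoNetworks()].
#' @return Integer vector of 1-based region indices.
#' @export
networkRegions <- function(scheme, network) {
  if (!network %in% yeoNetworks())
    stopf("unknown network '%s'; expected one of: %s",
          network, paste(yeoNetworks(), collapse = ", "))
  which(networkLabels(scheme) == network)
}

#' Write / read a parcellation table
#'
#' TSV with columns `region_id`, `region_name`, `network`.
#'
#' @param scheme a [ParcellationScheme-class].
#' @param path file path.
#' @return `writeParcellation` returns `path` invisibly; `readParcellation`
#'   returns a [ParcellationScheme-class].
#' @export
writeParcellation <- function(scheme, path) {
  df <- data.frame(region_id = scheme@regionIds,
                   region_name = scheme@regionNames,
                   network = scheme@networkLabels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeParcellation
#' @export
readParcellation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  labels <- df$network
  methods::new("ParcellationScheme",
    regionIds = as.integer(df$region_id),
    regionNames = as.character(df$region_name),
    networkLabels = labels,
    nCortical = sum(labels != "Subcortex"),
    nSubcortical = sum(labels == "Subcortex"))
}
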