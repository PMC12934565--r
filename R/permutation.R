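#' Network-label permutation test for functional modulation
#'
#' Tests, for each of the eight networks, whether the network's mean
#' per-region change deviates from the global mean change by more than a
#' whole-brain effect would produce. The null distribution is built by
#' shuffling the region-to-network labels (`nResamples` times, default
#' 10000); the two-tailed p-value uses the add-one estimator
#' `p = (1 + #{|null| >= |obs|}) / (1 + n)`, which cannot return zero at
#' finite resamples. One BH correction is applied across the eight
#' networks.
#'
#' @param deltaPerRegion numeric vector of per-region changes (length N).
#' @param scheme a [ParcellationScheme-class]; all eight networks must be
#'   present.
#' @param nResamples number of label shuffles (>= 100).
#' @param seed integer RNG seed.
#' @return data.frame with one row per network: `network`, `observed`
#'   (network mean minus global mean), `p`, `q`, `n_resamples`, `seed`.
#' @export
networkPermutationTest <- function(deltaPerRegion, scheme,
                                   nResamples = 10000L, seed = 1L) {
  stopifnot(methods::is(scheme, "ParcellationScheme"))
  if (nResamples < 100) stopf("need at least 100 resamples")
  labs <- networkLabels(scheme)
  if (length(deltaPerRegion) != length(labs))
    stopf("delta length (%d) must match the parcellation (%d regions)",
          length(deltaPerRegion), length(labs))
  nets <- yeoNetworks()
  missing <- setdiff(nets, unique(labs))
  if (length(missing))
    stopf("parcellation lacks network(s): %s", paste(missing, collapse = ", "))
  g <- mean(deltaPerRegion)
  obs <- vapply(nets, function(nw)
    mean(deltaPerRegion[labs == nw]) - g, 0)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  exceed <- numeric(length(nets))
  for (b in seq_len(nResamples)) {
    sl <- sample(labs)
    nullStat <- vapply(nets, function(nw)
      mean(deltaPerRegion[sl == nw]) - g, 0)
    exceed <- exceed + as.numeric(abs(nullStat) >= abs(obs))
  }
  p <- (1 + exceed) / (1 + nResamples)
  data.frame(network = nets, observed = unname(obs), p = unname(p),
             q = bhFdr(p), n_resamples = nResamples, seed = seed,
             row.names = NULL)
}
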