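#' The four taxonomic information modes
#'
#' Groupings of the sixteen atoms into qualitative classes of information
#' dynamics. The six elementary classes (storage, copy, transfer, erasure,
#' downward causation, upward causation) are collapsed into four dominant
#' modes because copy/erasure and upward/downward causation are directional
#' duals that behave alike under stationarity:
#'
#' * storage — `rtr, xtx, yty, sts`: structure completely preserved over
#'   time;
#' * transfer — `xty, ytx`: data exchanged between the two regions;
#' * copy_erasure — `xtr, ytr, rtx, rty`: data duplicated into both
#'   regions, or duplicated data losing its duplicate;
#' * multi_scale_causation — `stx, sty, str, xts, yts, rts`: higher-order
#'   features becoming lower-order and vice versa.
#'
#' @return Named list of character vectors of atom names.
#' @examples
#' phiidModes()
#' @export
phiidModes <- function() {
  list(
    storage = c("rtr", "xtx", "yty", "sts"),
    transfer = c("xty", "ytx"),
    copy_erasure = c("xtr", "ytr", "rtx", "rty"),
    multi_scale_causation = c("stx", "sty", "str", "xts", "yts", "rts"))
}

#' Taxonomic mode signature of one scan
#'
#' Sums each mode's atom planes and averages them within each network
#' (ordered pairs over `|S|^2`, the network-mean normalisation), giving a
#' 4-mode signature per network per scan.
#'
#' @param stack an [AtomStack-class].
#' @param scheme a matching [ParcellationScheme-class].
#' @return data.frame with columns `scan_id`, `network`, `mode`, `value`
#'   (bits), 8 networks x 4 modes rows.
#' @export
modeSignature <- function(stack, scheme) {
  stopifnot(methods::is(stack, "AtomStack"))
  v <- atomValues(stack)
  modes <- phiidModes()
  planes <- lapply(modes, function(at)
    Reduce(`+`, lapply(at, function(a) v[, , a])))
  rows <- list()
  for (nw in yeoNetworks()) {
    for (m in names(modes)) {
      rows[[length(rows) + 1L]] <- data.frame(
        scan_id = scanId(stack), network = nw, mode = m,
        value = intranetworkMean(stack, scheme, nw, planes[[m]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Mode signatures for a list of stacks
#'
#' @param stacks list of [AtomStack-class] objects.
#' @param scheme a matching [ParcellationScheme-class].
#' @return Long data.frame as in [modeSignature()], one block per scan.
#' @export
modeSignatures <- function(stacks, scheme) {
  do.call(rbind, lapply(stacks, modeSignature, scheme = scheme))
}

#' Omnibus ANOVA over modes and networks with FDR-corrected post-hocs
#'
#' For each of the 4 modes x 8 networks = 32 cells, a classic one-way
#' (equal-variance) ANOVA tests for modulation of the per-scan intranetwork
#' mode value across groups, with one BH correction across all 32 tests.
#' For every cell significant at `alpha`, post-hoc Welch tests compare each
#' pair of groups; the post-hoc family (all comparisons spawned by all
#' significant cells) receives its own BH correction.
#'
#' @param signatures long data.frame from [modeSignatures()].
#' @param groups named character vector mapping `scan_id` to group label
#'   (>= 2 groups, >= 2 scans each).
#' @param alpha FDR level for the omnibus screen (default 0.05).
#' @return List with `omnibus` (data.frame: `network`, `mode`, `F`, `p`,
#'   `q`, `n_groups`) and `posthoc` (data.frame: `network`, `mode`,
#'   `group_a`, `group_b`, `delta`, `t`, `p`, `q`, `hedges_g`).
#' @export
modeAnova <- function(signatures, groups, alpha = 0.05) {
  sig <- signatures
  sig$group <- groups[sig$scan_id]
  if (anyNA(sig$group))
    stopf("scans without a group label: %s",
          paste(unique(sig$scan_id[is.na(sig$group)]), collapse = ", "))
  tb <- table(unique(sig[, c("scan_id", "group")])$group)
  if (length(tb) < 2) stopf("need at least 2 groups")
  if (any(tb < 2)) stopf("every group needs at least 2 scans")
  cells <- unique(sig[, c("network", "mode")])
  om <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    cc <- sig[sig$network == cells$network[k] & sig$mode == cells$mode[k], ]
    ft <- stats::oneway.test(value ~ group, data = cc, var.equal = TRUE)
    data.frame(network = cells$network[k], mode = cells$mode[k],
               F = unname(ft$statistic), p = ft$p.value,
               n_groups = length(tb), stringsAsFactors = FALSE)
  }))
  om$q <- bhFdr(om$p)
  om <- om[, c("network", "mode", "F", "p", "q", "n_groups")]

  ph <- list()
  gl <- sort(names(tb))
  for (k in which(om$q <= alpha)) {
    cc <- sig[sig$network == om$network[k] & sig$mode == om$mode[k], ]
    for (i in seq_len(length(gl) - 1)) for (j in (i + 1):length(gl)) {
      wt <- welchTest(cc$value[cc$group == gl[i]],
                      cc$value[cc$group == gl[j]])
      ph[[length(ph) + 1L]] <- data.frame(
        network = om$network[k], mode = om$mode[k],
        group_a = gl[i], group_b = gl[j],
        delta = wt$delta, t = wt$t, p = wt$p, hedges_g = wt$hedgesG,
        stringsAsFactors = FALSE)
    }
  }
  posthoc <- if (length(ph)) {
    ph <- do.call(rbind, ph)
    ph$q <- bhFdr(ph$p)
    ph[, c("network", "mode", "group_a", "group_b", "delta", "t", "p",
           "q", "hedges_g")]
  } else {
    data.frame(network = character(), mode = character(),
               group_a = character(), group_b = character(),
               delta = numeric(), t = numeric(), p = numeric(),
               q = numeric(), hedges_g = numeric())
  }
  list(omnibus = om, posthoc = posthoc)
}
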