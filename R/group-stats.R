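#' Regional sums of an atom plane
#'
#' Reduces a pairwise atom matrix to one value per region by summing down
#' the matrix column: `value(i) = sum_j stack[j, i, atom]`, i.e. region i's
#' total over its interactions with all partners j (self-terms are zero by
#' construction). For the symmetric redundancy and synergy planes the
#' column/row choice is inert; the column orientation is fixed here and
#' used throughout.
#'
#' @param stack an [AtomStack-class].
#' @param atom one of [atomNames()] (typically `"rtr"` for the regional
#'   Redundancy or `"sts"` for the regional Synergy).
#' @return Numeric vector of length N, in bits.
#' @export
regionalSums <- function(stack, atom) {
  colSums(atomPlane(stack, atom))
}

#' Regional summed measures for a list of stacks
#'
#' @param stacks list of [AtomStack-class] objects.
#' @param atom one of [atomNames()].
#' @return scans x regions numeric matrix; rownames are scan ids.
#' @export
regionalSumsMatrix <- function(stacks, atom) {
  out <- t(vapply(stacks, regionalSums, numeric(nRegions(stacks[[1]])),
                  atom = atom))
  rownames(out) <- vapply(stacks, scanId, "")
  out
}

#' Region-wise z-scores against a reference group
#'
#' Scores each region's group mean by how unusual it would be in the
#' reference (cognitively normal) distribution:
#' `z(i) = (mean_group(i) - mean_ref(i)) / sd_ref(i)`, region by region,
#' with the sample (n-1) standard deviation.
#'
#' @param groupValues scans x regions matrix of the comparison group.
#' @param referenceValues scans x regions matrix of the reference group
#'   (>= 2 scans).
#' @return Numeric vector of z-scores, one per region.
#' @export
zscoreVsReference <- function(groupValues, referenceValues) {
  groupValues <- as.matrix(groupValues)
  referenceValues <- as.matrix(referenceValues)
  if (ncol(groupValues) != ncol(referenceValues))
    stopf("region counts differ (%d vs %d)",
          ncol(groupValues), ncol(referenceValues))
  if (nrow(referenceValues) < 2)
    stopf("need at least 2 reference scans")
  sdRef <- apply(referenceValues, 2, stats::sd)
  zero <- which(sdRef == 0)
  if (length(zero))
    stopf("zero reference standard deviation in region(s): %s",
          paste(zero, collapse = ", "))
  (colMeans(groupValues) - colMeans(referenceValues)) / sdRef
}

#' Projection of redundancy/synergy z-scores onto the first principal
#' component
#'
#' Centres the two-column `(z_red, z_syn)` configuration, extracts the
#' leading eigenvector of its 2 x 2 covariance and returns each region's
#' score along it plus the fraction of variance it explains. The component
#' is oriented so that increasing redundancy-z loads positively.
#'
#' @param zRed,zSyn numeric vectors of per-region z-scores (length >= 2,
#'   finite).
#' @return List with `scores` (length N), `varianceExplained` (in
#'   `[0.5, 1]` for two variables) and `loadings` (length-2 named vector).
#' @export
pc1Projection <- function(zRed, zSyn) {
  if (length(zRed) != length(zSyn))
    stopf("z-score vectors differ in length")
  if (!all(is.finite(zRed)) || !all(is.finite(zSyn)))
    stopf("z-scores must be finite")
  M <- cbind(z_red = zRed, z_syn = zSyn)
  if (sum(apply(M, 2, stats::var)) == 0)
    stopf("zero total variance; no principal axis")
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  flip <- if (pc$rotation["z_red", 1] < 0) -1 else 1
  list(scores = flip * pc$x[, 1],
       varianceExplained = pc$sdev[1]^2 / sum(pc$sdev^2),
       loadings = flip * pc$rotation[, 1])
}

#' Welch's unequal-variance t-test with Hedges' g
#'
#' Two-tailed Welch test (Welch-Satterthwaite degrees of freedom) of
#' `mean(b) - mean(a)`, plus the small-sample-corrected standardized mean
#' difference Hedges' g (pooled sd, correction factor
#' `J = 1 - 3 / (4 df - 1)` at `df = n_a + n_b - 2`). The signs of `t`,
#' `delta` and `g` all follow `mean(b) - mean(a)`; with the package's group
#' ordering conventions (a = earlier stage, b = later stage) a positive
#' delta means a higher value at the later disease stage.
#'
#' @param a,b numeric samples of size >= 2.
#' @return List with `delta`, `t`, `df`, `p`, `hedgesG`, `nA`, `nB`.
#' @export
welchTest <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stopf("each sample needs at least 2 observations")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(delta = 0, t = 0, df = length(a) + length(b) - 2,
                  p = 1, hedgesG = 0, nA = length(a), nB = length(b)))
    stopf("zero variance in both samples with unequal means: t undefined")
  }
  ht <- stats::t.test(b, a, var.equal = FALSE)
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df)
  g <- if (sp == 0) 0 else (1 - 3 / (4 * df - 1)) * (mean(b) - mean(a)) / sp
  list(delta = mean(b) - mean(a),
       t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, hedgesG = g, nA = na, nB = nb)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; rejecting at level alpha is
#' equivalent to `q <= alpha`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs are passed through).
#' @return Vector of q-values, same length and order as `p`.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))   # all 0.04
#' @export
bhFdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Region-wise Welch tests with FDR correction
#'
#' One Welch test per region comparing per-scan summed measures between two
#' groups, with one BH correction across regions.
#'
#' @param valuesA,valuesB scans x regions matrices (group a = reference /
#'   earlier stage, group b = comparison / later stage).
#' @param groupA,groupB labels recorded in the output.
#' @return data.frame with one row per region: `region`, `delta`, `t`,
#'   `p`, `q`, `hedges_g`, `group_a`, `group_b`.
#' @export
regionwiseTests <- function(valuesA, valuesB, groupA = "A", groupB = "B") {
  valuesA <- as.matrix(valuesA); valuesB <- as.matrix(valuesB)
  stopifnot(ncol(valuesA) == ncol(valuesB))
  res <- lapply(seq_len(ncol(valuesA)), function(i)
    welchTest(valuesA[, i], valuesB[, i]))
  out <- data.frame(
    region = seq_len(ncol(valuesA)),
    delta = vapply(res, `[[`, 0, "delta"),
    t = vapply(res, `[[`, 0, "t"),
    p = vapply(res, `[[`, 0, "p"),
    hedges_g = vapply(res, `[[`, 0, "hedgesG"))
  out$q <- bhFdr(out$p)
  out$group_a <- groupA
  out$group_b <- groupB
  out[, c("region", "delta", "t", "p", "q", "hedges_g",
          "group_a", "group_b")]
}

#' Pooled-variance t-tests over the full pairwise atom grid
#'
#' Independent two-tailed t-tests (pooled variance) for every
#' (region i, region j, atom) cell between two groups of stacks, with one
#' BH correction across all `N * N * 16` tests. Diagonal (self-pair) cells
#' are structurally zero in both groups and enter as degenerate cells
#' (NA t, skipped by the correction), mirroring the grid's nominal size.
#'
#' @param stacksA,stacksB lists of [AtomStack-class] objects (>= 2 scans
#'   each).
#' @param groupA,groupB labels recorded in the output.
#' @param alpha significance level used by [significantCells()].
#' @return List of class `"pairwiseAtomTests"` with arrays `delta`, `t`,
#'   `p`, `q` (N x N x 16), the group labels, `nTests = N * N * 16` and
#'   the per-group scan counts.
#' @export
pairwiseAtomTests <- function(stacksA, stacksB, groupA = "A", groupB = "B",
                              alpha = 0.05) {
  nA <- length(stacksA); nB <- length(stacksB)
  if (nA < 2 || nB < 2) stopf("need at least 2 scans per group")
  arrA <- lapply(stacksA, atomValues)
  arrB <- lapply(stacksB, atomValues)
  sumA <- Reduce(`+`, arrA); sumB <- Reduce(`+`, arrB)
  sqA <- Reduce(`+`, lapply(arrA, function(v) v * v))
  sqB <- Reduce(`+`, lapply(arrB, function(v) v * v))
  mA <- sumA / nA; mB <- sumB / nB
  vA <- (sqA - nA * mA^2) / (nA - 1)
  vB <- (sqB - nB * mB^2) / (nB - 1)
  df <- nA + nB - 2
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tArr <- (mB - mA) / se
  tArr[se == 0] <- NA_real_
  pArr <- 2 * stats::pt(-abs(tArr), df)
  qArr <- pArr
  ok <- !is.na(pArr)
  qArr[ok] <- bhFdr(pArr[ok])
  structure(list(delta = mB - mA, t = tArr, p = pArr, q = qArr,
                 groupA = groupA, groupB = groupB,
                 nTests = prod(dim(tArr)), nScansA = nA, nScansB = nB,
                 alpha = alpha),
            class = "pairwiseAtomTests")
}

#' @export
print.pairwiseAtomTests <- function(x, ...) {
  cat(sprintf("pairwiseAtomTests %s vs %s: %d tests (%d x %d x 16)\n",
              x$groupA, x$groupB, x$nTests, dim(x$t)[1], dim(x$t)[2]))
  cat(sprintf("  significant at q <= %.3g: %d increases, %d decreases\n",
              x$alpha,
              sum(x$q <= x$alpha & x$delta > 0, na.rm = TRUE),
              sum(x$q <= x$alpha & x$delta < 0, na.rm = TRUE)))
  invisible(x)
}

#' Significant cells of a pairwise grid, increases and decreases separated
#'
#' @param tests result of [pairwiseAtomTests()].
#' @param alpha FDR level (defaults to the one stored on the result).
#' @return data.frame with columns `i`, `j`, `atom`, `direction`
#'   (increase/decrease), `delta`, `t`, `p`, `q`.
#' @export
significantCells <- function(tests, alpha = tests$alpha) {
  idx <- which(!is.na(tests$q) & tests$q <= alpha, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(i = integer(), j = integer(), atom = character(),
                      direction = character(), delta = numeric(),
                      t = numeric(), p = numeric(), q = numeric()))
  d <- tests$delta[idx]
  out <- data.frame(i = idx[, 1], j = idx[, 2],
                    atom = atomNames()[idx[, 3]],
                    direction = ifelse(d > 0, "increase", "decrease"),
                    delta = d, t = tests$t[idx], p = tests$p[idx],
                    q = tests$q[idx])
  out[order(out$q, out$p), ]
}

#' Intranetwork mean of an atom plane
#'
#' Mean over all ordered region pairs of a network S, including the zero
#' diagonal terms, i.e. `sum_{i,j in S} plane[i, j] / |S|^2` — the exact
#' normalisation of the network-level redundancy/synergy definition.
#'
#' @param stack an [AtomStack-class].
#' @param scheme a [ParcellationScheme-class] matching the stack.
#' @param network one of [yeoNetworks()].
#' @param atom one of [atomNames()], or an N x N matrix to average (e.g. a
#'   mode plane).
#' @return Numeric scalar, in bits.
#' @export
intranetworkMean <- function(stack, scheme, network, atom = "rtr") {
  idx <- networkRegions(scheme, network)
  if (length(idx) < 2) stopf("network '%s' has fewer than 2 regions", network)
  plane <- if (is.matrix(atom)) atom else atomPlane(stack, atom)
  sum(plane[idx, idx]) / length(idx)^2
}

#' Percentile bootstrap confidence interval of the mean
#'
#' @param values numeric sample (size >= 2).
#' @param nResamples bootstrap resamples (default 10000; below 100 a
#'   warning is issued).
#' @param seed integer RNG seed.
#' @param level confidence level (default 0.95).
#' @return Named numeric `c(low, high)` percentile interval.
#' @export
bootstrapCI <- function(values, nResamples = 10000L, seed = 1L,
                        level = 0.95) {
  if (length(values) < 2) stopf("need at least 2 observations")
  if (nResamples < 100) warning("fewer than 100 bootstrap resamples")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n <- length(values)
  means <- vapply(seq_len(nResamples), function(k)
    mean(values[sample.int(n, n, replace = TRUE)]), 0)
  qs <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  c(low = qs[1], high = qs[2])
}
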