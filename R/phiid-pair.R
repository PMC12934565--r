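#' Construct a lagged-pair model from a 4 x 4 covariance
#'
#' Conditions the covariance by adding a ridge of
#' `ridge * mean(diag(cov4))` to the diagonal before it is used in any
#' determinant computation (near-duplicate regional signals otherwise break
#' the log-determinants).
#'
#' @param cov4 symmetric 4 x 4 covariance of `(x_t, y_t, x_{t+1}, y_{t+1})`.
#' @param nSamples number of lagged sample pairs behind the estimate (`NA`
#'   for analytic covariances).
#' @param ridge relative ridge (default 1e-10).
#' @return A [LaggedPairModel-class].
#' @export
laggedPairModel <- function(cov4, nSamples = NA_integer_, ridge = 1e-10) {
  cov4 <- as.matrix(cov4)
  if (!all(dim(cov4) == c(4L, 4L))) stopf("cov4 must be 4 x 4")
  cov4 <- (cov4 + t(cov4)) / 2
  cov4 <- cov4 + diag(ridge * mean(diag(cov4)), 4L)
  methods::new("LaggedPairModel", cov4 = cov4,
               nSamples = as.integer(nSamples))
}

#' Lagged-pair model estimated from two observed series
#'
#' Demeans each series and estimates the 4 x 4 covariance of
#' `(x_t, y_t, x_{t+1}, y_{t+1})` from the T-1 lagged sample pairs; the lag
#' is one sample (one TR, about 3 s at the harmonised sampling rate).
#' Only demeaning is applied, no variance normalisation: Gaussian mutual
#' information is scale-invariant, so the decomposition is unchanged, but
#' the covariance itself is reported on the data's scale.
#'
#' @param x,y numeric vectors of equal length `T >= minLength`.
#' @param minLength minimum usable series length (default 30).
#' @param ridge relative diagonal ridge, see [laggedPairModel()].
#' @return A [LaggedPairModel-class] with `nSamples = T - 1`.
#' @export
pairModelFromSeries <- function(x, y, minLength = 30L, ridge = 1e-10) {
  if (length(x) != length(y))
    stopf("series lengths differ (%d vs %d)", length(x), length(y))
  Tn <- length(x)
  if (Tn < minLength)
    stopf("series too short: %d < minimum %d", Tn, minLength)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("constant series cannot be decomposed")
  Z <- cbind(x[-Tn], y[-Tn], x[-1L], y[-1L])
  laggedPairModel(stats::cov(Z), nSamples = Tn - 1L, ridge = ridge)
}

#' Analytic lagged-pair model of two regions of a VAR(1)
#'
#' Builds the exact stationary 4 x 4 covariance of
#' `(x_t, y_t, x_{t+1}, y_{t+1})` for regions `i` and `j` from the model's
#' stationary covariances (`cov(X_t, X_{t+1}) = Sigma0 A'`). This is the
#' ground-truth oracle against which estimated decompositions converge.
#'
#' @param model a [VarModel-class], or the list returned by
#'   [stationaryCovariances()] augmented with... (use a VarModel).
#' @param i,j distinct region indices (1-based).
#' @param ridge relative diagonal ridge, see [laggedPairModel()].
#' @return A [LaggedPairModel-class] with `nSamples = NA`.
#' @export
pairModelFromVar <- function(model, i, j, ridge = 1e-10) {
  stopifnot(methods::is(model, "VarModel"))
  if (i == j) stopf("need two distinct regions (got i = j = %d)", i)
  sc <- stationaryCovariances(model)
  ix <- c(i, j)
  S0 <- sc$Sigma0[ix, ix]
  C01 <- (sc$Sigma0 %*% t(model@A))[ix, ix]   # cov(X_t, X_{t+1})
  cov4 <- rbind(cbind(S0, C01), cbind(t(C01), S0))
  laggedPairModel(cov4, ridge = ridge)
}

#' Decompose a lagged pair into the sixteen atoms
#'
#' Computes the cumulative lattice values under the minimum-mutual-
#' information rule and Moebius-inverts them. The atoms sum exactly to the
#' pair's TDMI; the redundancy (`rtr`) and synergy (`sts`) atoms are
#' non-negative by construction, other atoms may be negative and are
#' analysed through group differences rather than absolute values.
#'
#' @param model a [LaggedPairModel-class].
#' @return Named numeric vector of 16 atoms (bits) in [atomNames()] order.
#' @examples
#' m <- laggedPairModel(diag(4))       # white noise: all atoms zero
#' phiidAtoms(m)
#' @export
phiidAtoms <- function(model) {
  stopifnot(methods::is(model, "LaggedPairModel"))
  cum <- .cumulativeFromMIs(.pairBlockMIs(model@cov4))
  drop(.phiidMoebiusMatrix() %*% cum)[atomNames()] |>
    stats::setNames(atomNames())
}

#' Decompose two observed series
#'
#' Convenience wrapper: [pairModelFromSeries()] then [phiidAtoms()].
#' Exchanging the two inputs leaves `rtr` and `sts` unchanged and swaps the
#' x- and y-atoms.
#'
#' @inheritParams pairModelFromSeries
#' @return Named numeric vector of 16 atoms (bits).
#' @export
phiidPair <- function(x, y, minLength = 30L, ridge = 1e-10) {
  phiidAtoms(pairModelFromSeries(x, y, minLength = minLength, ridge = ridge))
}

#' Construct an AtomStack
#'
#' @param values numeric N x N x 16 array (third dimension in [atomNames()]
#'   order; names are attached if absent).
#' @param scanId scan identifier.
#' @return An [AtomStack-class].
#' @export
atomStack <- function(values, scanId = "scan") {
  dimnames(values) <- list(NULL, NULL, atomNames())
  methods::new("AtomStack", values = values, scanId = scanId)
}

#' One atom plane of a stack
#'
#' @param stack an [AtomStack-class].
#' @param atom one of [atomNames()].
#' @return N x N numeric matrix.
#' @export
atomPlane <- function(stack, atom) {
  if (!atom %in% atomNames())
    stopf("unknown atom '%s'", atom)
  atomValues(stack)[, , atom]
}

#' Decompose every region pair of a scan
#'
#' Estimates the lag-1 covariance structure of the whole scan once, then
#' decomposes every unordered region pair and fills both orientations of
#' the N x N x 16 stack using the x/y exchange symmetry. Self-pairs are set
#' to zero by convention. The result is deterministic.
#'
#' @param ts a [RegionalTimeSeries-class] with at least 2 regions.
#' @param minLength minimum number of time points (default 30).
#' @param ridge relative diagonal ridge for each pair covariance.
#' @param onError `"abort"` (default) stops at the first failing pair,
#'   naming it; `"skip"` zeroes the failing pair and records it in the
#'   `"failedPairs"` attribute of the returned stack's values.
#' @return An [AtomStack-class].
#' @examples
#' ts <- regionalTimeSeries(matrix(rnorm(3 * 200), 3), trSeconds = 3)
#' st <- phiidAllPairs(ts)
#' st
#' @export
phiidAllPairs <- function(ts, minLength = 30L, ridge = 1e-10,
                          onError = c("abort", "skip")) {
  stopifnot(methods::is(ts, "RegionalTimeSeries"))
  onError <- match.arg(onError)
  X <- tsMatrix(ts)
  n <- nrow(X)
  Tn <- ncol(X)
  if (n < 2) stopf("need at least 2 regions")
  if (Tn < minLength)
    stopf("scan '%s' too short: %d < minimum %d", scanId(ts), Tn, minLength)
  X1 <- t(X[, -Tn, drop = FALSE])
  X2 <- t(X[, -1L, drop = FALSE])
  C00 <- stats::cov(X1)
  C11 <- stats::cov(X2)
  C01 <- stats::cov(X1, X2)
  sdz <- which(diag(C00) == 0)
  if (length(sdz))
    stopf("constant region(s) in scan '%s': %s", scanId(ts),
          paste(sdz, collapse = ", "))
  vals <- array(0, dim = c(n, n, 16L))
  swap <- .atomSwapPermutation()
  Minv <- .phiidMoebiusMatrix()
  failed <- character(0)
  S <- matrix(0, 4L, 4L)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      S[1, 1] <- C00[i, i]; S[1, 2] <- C00[i, j]
      S[2, 1] <- C00[i, j]; S[2, 2] <- C00[j, j]
      S[3, 3] <- C11[i, i]; S[3, 4] <- C11[i, j]
      S[4, 3] <- C11[i, j]; S[4, 4] <- C11[j, j]
      S[1, 3] <- C01[i, i]; S[1, 4] <- C01[i, j]
      S[2, 3] <- C01[j, i]; S[2, 4] <- C01[j, j]
      S[3, 1] <- S[1, 3]; S[4, 1] <- S[1, 4]
      S[3, 2] <- S[2, 3]; S[4, 2] <- S[2, 4]
      Sc <- S + diag(ridge * mean(diag(S)), 4L)
      atoms <- tryCatch(
        drop(Minv %*% .cumulativeFromMIs(.pairBlockMIs(Sc))),
        error = function(e) e)
      if (inherits(atoms, "error")) {
        if (onError == "abort")
          stopf("decomposition failed for pair (%d, %d) of scan '%s': %s",
                i, j, scanId(ts), conditionMessage(atoms))
        failed <- c(failed, sprintf("(%d,%d)", i, j))
        atoms <- numeric(16L)
      }
      vals[i, j, ] <- atoms
      vals[j, i, ] <- atoms[swap]
    }
  }
  st <- atomStack(vals, scanId = scanId(ts))
  if (length(failed)) attr(st@values, "failedPairs") <- failed
  st
}

#' Analytic all-pairs atom stack of a VAR(1) model
#'
#' Ground-truth counterpart of [phiidAllPairs()]: decomposes every region
#' pair from the model's exact stationary covariances instead of data.
#'
#' @param model a [VarModel-class].
#' @param ridge relative diagonal ridge.
#' @param scanId identifier for the resulting stack.
#' @return An [AtomStack-class].
#' @export
phiidAllPairsAnalytic <- function(model, ridge = 1e-10, scanId = "analytic") {
  stopifnot(methods::is(model, "VarModel"))
  sc <- stationaryCovariances(model)
  S0 <- sc$Sigma0
  C01 <- S0 %*% t(model@A)
  n <- nrow(S0)
  vals <- array(0, dim = c(n, n, 16L))
  swap <- .atomSwapPermutation()
  Minv <- .phiidMoebiusMatrix()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ix <- c(i, j)
      cov4 <- rbind(cbind(S0[ix, ix], C01[ix, ix]),
                    cbind(t(C01[ix, ix]), S0[ix, ix]))
      cov4 <- cov4 + diag(ridge * mean(diag(cov4)), 4L)
      atoms <- drop(Minv %*% .cumulativeFromMIs(.pairBlockMIs(cov4)))
      vals[i, j, ] <- atoms
      vals[j, i, ] <- atoms[swap]
    }
  }
  atomStack(vals, scanId = scanId)
}
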