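## ---- the product lattice ---------------------------------------------------
##
## Each side (past sources, future targets) of the decomposition carries the
## four-node redundancy lattice of two variables:
##
##      {12}        "s"  (the joint pair, synergistic level)
##     /    \
##   {1}    {2}     "x", "y" (single sources, unique level; incomparable)
##     \    /
##    {1}{2}        "r"  (both singletons, redundant level)
##
## A full atom lives on the product of the past lattice and the future
## lattice: 4 x 4 = 16 nodes, named by past-letter `t` future-letter
## (rtr, rtx, ..., sts).

.NODES <- c("r", "x", "y", "s")
.NODE_RANK <- c(r = 0L, x = 1L, y = 1L, s = 2L)

## a <= b in the single-side lattice r <= {x,y} <= s, x and y incomparable
.nodeLeq <- function(a, b) a == b | a == "r" | b == "s"

#' Canonical names of the sixteen atoms
#'
#' Past-major order over the node letters (r, x, y, s): redundant, unique to
#' the first region, unique to the second region, synergistic. The letter
#' before `t` is the past-side node, the letter after is the future-side
#' node; e.g. `rts` is information redundant in the past that becomes
#' synergistic in the future, `sts` is the synergy and `rtr` the redundancy
#' of the pair.
#'
#' @return Character vector of length 16.
#' @examples
#' atomNames()
#' @export
atomNames <- function() {
  as.vector(t(outer(.NODES, .NODES, function(p, f) paste0(p, "t", f))))
}

## past/future letter of each canonical atom
.atomPast <- function() rep(.NODES, each = 4L)
.atomFuture <- function() rep(.NODES, times = 4L)

## 16 x 16 zeta (accumulation) matrix over the canonical order:
## cumulative = Z %*% atoms, Z[n, m] = 1 iff node m lies at or below node n
## in the product order.
.phiidZeta <- function() {
  p <- .atomPast(); f <- .atomFuture()
  Z <- outer(seq_len(16L), seq_len(16L), function(n, m)
    as.numeric(.nodeLeq(p[m], p[n]) & .nodeLeq(f[m], f[n])))
  dimnames(Z) <- list(atomNames(), atomNames())
  Z
}

.phidynCache <- new.env(parent = emptyenv())

## inverse of the zeta matrix (the Moebius matrix); integer-valued
.phiidMoebiusMatrix <- function() {
  if (is.null(.phidynCache$minv)) {
    M <- solve(.phiidZeta())
    .phidynCache$minv <- round(M)   # entries are exact small integers
  }
  .phidynCache$minv
}

## permutation of the 16 atoms under exchange of the two regions (x <-> y
## in both the past and the future letter)
.atomSwapPermutation <- function() {
  if (is.null(.phidynCache$swap)) {
    sw <- c(r = "r", x = "y", y = "x", s = "s")
    nm <- paste0(sw[.atomPast()], "t", sw[.atomFuture()])
    .phidynCache$swap <- match(atomNames(), nm)
  }
  .phidynCache$swap
}

## ---- Gaussian information quantities --------------------------------------

#' Differential entropy of a Gaussian (bits)
#'
#' `H = 1/2 log2((2 pi e)^k det(cov))` for a k-dimensional Gaussian. All
#' information quantities in the package are in bits (base-2 logarithms).
#'
#' @param cov symmetric positive-definite covariance matrix (a scalar is
#'   taken as a 1 x 1 variance).
#' @return Entropy in bits.
#' @examples
#' gaussianEntropy(1)          # ~2.0471 bits
#' gaussianEntropy(diag(2))    # twice that
#' @export
gaussianEntropy <- function(cov) {
  cov <- as.matrix(cov)
  k <- nrow(cov)
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stopf("covariance not positive definite (smallest eigenvalue %.3e)",
          min(ev))
  0.5 * (k * log2(2 * pi * exp(1)) + sum(log2(ev)))
}

#' Mutual information between two coordinate blocks of a Gaussian (bits)
#'
#' `I(A; B) = H(A) + H(B) - H(A, B)` computed from the joint covariance.
#' Invariant under separate rescaling of the A and B coordinates.
#'
#' @param cov joint covariance matrix.
#' @param idxA,idxB disjoint, non-empty index sets into `cov`.
#' @return Mutual information in bits (non-negative up to rounding).
#' @examples
#' S <- matrix(c(1, 0.5, 0.5, 1), 2)
#' gaussianMI(S, 1, 2)   # -0.5 * log2(1 - 0.25)
#' @export
gaussianMI <- function(cov, idxA, idxB) {
  if (length(idxA) == 0 || length(idxB) == 0)
    stopf("index sets must be non-empty")
  if (length(intersect(idxA, idxB)))
    stopf("index sets must be disjoint (shared: %s)",
          paste(intersect(idxA, idxB), collapse = ", "))
  cov <- as.matrix(cov)
  if (max(c(idxA, idxB)) > nrow(cov))
    stopf("index out of range for a %d x %d covariance", nrow(cov), ncol(cov))
  ld <- function(ix) determinant(cov[ix, ix, drop = FALSE],
                                 logarithm = TRUE)$modulus / log(2)
  as.numeric(0.5 * (ld(idxA) + ld(idxB) - ld(c(idxA, idxB))))
}

#' Time-delayed mutual information of a region pair (bits)
#'
#' `TDMI = I(x_t, y_t ; x_{t+1}, y_{t+1})`, the total information the pair's
#' present carries about its state one TR later; the quantity the sixteen
#' atoms partition.
#'
#' @param model a [LaggedPairModel-class].
#' @return TDMI in bits.
#' @export
tdmi <- function(model) {
  stopifnot(methods::is(model, "LaggedPairModel"))
  gaussianMI(model@cov4, 1:2, 3:4)
}

## the nine block mutual informations of a 4x4 lagged-pair covariance,
## computed from closed-form determinants (hot path: no eigen/determinant
## calls). Order: m11 m12 m21 m22 m1J m2J mJ1 mJ2 mJJ, where 1/2 index the
## single channels and J the joint pair on each side.
.pairBlockMIs <- function(S) {
  s11 <- S[1, 1]; s22 <- S[2, 2]; s33 <- S[3, 3]; s44 <- S[4, 4]
  d2 <- function(i, j) S[i, i] * S[j, j] - S[i, j]^2
  d3 <- function(i, j, k)
    S[i, i] * (S[j, j] * S[k, k] - S[j, k]^2) -
    S[i, j] * (S[i, j] * S[k, k] - S[j, k] * S[i, k]) +
    S[i, k] * (S[i, j] * S[j, k] - S[j, j] * S[i, k])
  dP <- d2(1, 2); dF <- d2(3, 4)
  ## det of the full 4x4 by cofactor expansion on the first row
  m1 <- d3(2, 3, 4)
  m2 <- S[1, 2] * (S[3, 3] * S[4, 4] - S[3, 4]^2) -
        S[2, 3] * (S[1, 3] * S[4, 4] - S[3, 4] * S[1, 4]) +
        S[2, 4] * (S[1, 3] * S[3, 4] - S[3, 3] * S[1, 4])
  m3 <- S[1, 2] * (S[2, 3] * S[4, 4] - S[2, 4] * S[3, 4]) -
        S[2, 2] * (S[1, 3] * S[4, 4] - S[1, 4] * S[3, 4]) +
        S[2, 4] * (S[1, 3] * S[2, 4] - S[1, 4] * S[2, 3])
  m4 <- S[1, 2] * (S[2, 3] * S[3, 4] - S[2, 4] * S[3, 3]) -
        S[2, 2] * (S[1, 3] * S[3, 4] - S[1, 4] * S[3, 3]) +
        S[2, 3] * (S[1, 3] * S[2, 4] - S[1, 4] * S[2, 3])
  d4 <- S[1, 1] * m1 - S[1, 2] * m2 + S[1, 3] * m3 - S[1, 4] * m4
  if (d4 <= 0 || dP <= 0 || dF <= 0)
    stopf("lagged-pair covariance is singular after conditioning")
  h <- 0.5 / log(2)
  c(m11 = h * log(s11 * s33 / d2(1, 3)),
    m12 = h * log(s11 * s44 / d2(1, 4)),
    m21 = h * log(s22 * s33 / d2(2, 3)),
    m22 = h * log(s22 * s44 / d2(2, 4)),
    m1J = h * log(s11 * dF / d3(1, 3, 4)),
    m2J = h * log(s22 * dF / d3(2, 3, 4)),
    mJ1 = h * log(dP * s33 / d3(1, 2, 3)),
    mJ2 = h * log(dP * s44 / d3(1, 2, 4)),
    mJJ = h * log(dP * dF / d4))
}

## cumulative lattice values from the nine block MIs (minimum-mutual-
## information rule: the value at a node pair is the smallest block MI over
## the collections the two nodes contain)
.cumulativeFromMIs <- function(m) {
  c(rtr = min(m[["m11"]], m[["m12"]], m[["m21"]], m[["m22"]]),
    rtx = min(m[["m11"]], m[["m21"]]),
    rty = min(m[["m12"]], m[["m22"]]),
    rts = min(m[["m1J"]], m[["m2J"]]),
    xtr = min(m[["m11"]], m[["m12"]]),
    xtx = m[["m11"]],
    xty = m[["m12"]],
    xts = m[["m1J"]],
    ytr = min(m[["m21"]], m[["m22"]]),
    ytx = m[["m21"]],
    yty = m[["m22"]],
    yts = m[["m2J"]],
    str = min(m[["mJ1"]], m[["mJ2"]]),
    stx = m[["mJ1"]],
    sty = m[["mJ2"]],
    sts = m[["mJJ"]])
}

#' Cumulative lattice values of a lagged pair under the MMI rule
#'
#' For every pair (past node, future node) of the two four-node redundancy
#' lattices, the cumulative value is the minimum over the collections the
#' nodes contain of the Gaussian mutual information between the past
#' collection and the future collection:
#' `cum(alpha, beta) = min_{a in alpha, b in beta} I(a_t ; b_{t+1})`,
#' where a collection is a single channel or the joint pair. The bottom
#' value is the double redundancy and the top value equals the pair's TDMI.
#' Values are monotone non-decreasing along the product order.
#'
#' @param model a [LaggedPairModel-class].
#' @return Named numeric vector of 16 cumulative values (bits) in the
#'   canonical [atomNames()] order.
#' @seealso [moebiusInvert()], [phiidAtoms()]
#' @export
mmiCumulativeLattice <- function(model) {
  stopifnot(methods::is(model, "LaggedPairModel"))
  .cumulativeFromMIs(.pairBlockMIs(model@cov4))
}

#' Moebius inversion on the product lattice
#'
#' Recovers the sixteen atoms from the cumulative lattice values: each atom
#' equals its node's cumulative value minus the atoms at all nodes strictly
#' below in the product order, computed in a topological sweep.
#' Re-accumulating the atoms reproduces the input exactly, and the atoms sum
#' to the top (TDMI-level) cumulative value.
#'
#' @param cumulative named numeric vector of 16 cumulative values in
#'   [atomNames()] order (names, if present, are checked).
#' @return Named numeric vector of the 16 atoms (bits).
#' @examples
#' cum <- setNames(numeric(16), atomNames())
#' cum["sts"] <- 1
#' moebiusInvert(cum)["sts"]   # the whole bit is synergy-to-synergy
#' @export
moebiusInvert <- function(cumulative) {
  if (length(cumulative) != 16L)
    stopf("expected 16 cumulative values, got %d", length(cumulative))
  if (!is.null(names(cumulative)) &&
      !identical(names(cumulative), atomNames()))
    cumulative <- cumulative[atomNames()]
  p <- .atomPast(); f <- .atomFuture()
  atoms <- numeric(16L)
  ord <- order(.NODE_RANK[p] + .NODE_RANK[f])
  for (n in ord) {
    below <- .nodeLeq(p, p[n]) & .nodeLeq(f, f[n])
    below[n] <- FALSE
    atoms[n] <- cumulative[n] - sum(atoms[below])
  }
  stats::setNames(atoms, atomNames())
}
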