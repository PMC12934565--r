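test_that("Gaussian entropy matches its closed forms", {
  h1 <- 0.5 * log2(2 * pi * exp(1))
  expect_equal(gaussianEntropy(1), h1, tolerance = 1e-12)
  expect_equal(gaussianEntropy(diag(2)), 2 * h1, tolerance = 1e-12)
  ## scaling a variance by 4 adds exactly one bit
  expect_equal(gaussianEntropy(4) - gaussianEntropy(1), 1, tolerance = 1e-12)
  expect_error(gaussianEntropy(matrix(c(1, 2, 2, 1), 2)),
               "smallest eigenvalue")
})

test_that("Gaussian mutual information matches the bivariate closed form", {
  mi <- function(r) gaussianMI(matrix(c(1, r, r, 1), 2), 1, 2)
  expect_equal(mi(0), 0, tolerance = 1e-12)
  expect_equal(mi(0.5), -0.5 * log2(1 - 0.25), tolerance = 1e-12)
  expect_equal(mi(0.9), -0.5 * log2(1 - 0.81), tolerance = 1e-12)
  ## invariant under separate rescaling of the two blocks
  S <- matrix(c(1, 0.6, 0.6, 1), 2)
  D <- diag(c(3, 0.2))
  expect_equal(gaussianMI(D %*% S %*% D, 1, 2), mi(0.6), tolerance = 1e-10)
  expect_error(gaussianMI(diag(3), c(1, 2), 2), "disjoint")
})

test_that("TDMI closed forms and monotonicity hold", {
  expect_equal(tdmi(laggedPairModel(diag(4))), 0, tolerance = 1e-8)
  a <- 0.8
  m <- varModel(diag(a, 2), diag(1 - a^2, 2), nTime = 50L)
  pm <- pairModelFromVar(m, 1, 2)
  expect_equal(tdmi(pm), 2 * (-0.5 * log2(1 - a^2)), tolerance = 1e-9)
  set.seed(31)
  for (rep in 1:20) {
    pv <- randomPairVar()
    S <- pv$pair@cov4
    full <- tdmi(pv$pair)
    expect_gte(full + 1e-12, gaussianMI(S, 1, 3))
    expect_gte(full + 1e-12, gaussianMI(S, 2, 4))
  }
})

test_that("cumulative lattice values are monotone along the product order", {
  nodes <- c("r", "x", "y", "s")
  leq <- function(a, b) a == b | a == "r" | b == "s"
  past <- rep(nodes, each = 4); fut <- rep(nodes, times = 4)
  set.seed(32)
  for (rep in 1:50) {
    cum <- mmiCumulativeLattice(randomPairVar()$pair)
    for (n in 1:16) for (m in 1:16)
      if (leq(past[m], past[n]) && leq(fut[m], fut[n]))
        expect_lte(cum[m], cum[n] + 1e-12)
  }
  ## white noise: every cumulative value vanishes
  expect_lt(max(abs(mmiCumulativeLattice(laggedPairModel(diag(4))))), 1e-8)
})

test_that("Moebius inversion agrees with the brute-force linear solve", {
  expect_equal(unname(moebiusInvert(numeric(16))), numeric(16))
  cum <- stats::setNames(numeric(16), atomNames())
  cum["sts"] <- 0.7
  at <- moebiusInvert(cum)
  expect_equal(unname(at["sts"]), 0.7)
  expect_equal(sum(abs(at[setdiff(atomNames(), "sts")])), 0)
  set.seed(33)
  worst <- 0
  for (rep in 1:300) {
    v <- rnorm(16)
    worst <- max(worst, max(abs(moebiusInvert(v) - bruteForceInvert(v))))
  }
  expect_lt(worst, 1e-10)
})

test_that("independent identical AR(1) channels decompose as MMI prescribes", {
  ## cross MIs vanish, each self MI is m; the MMI rule then forces the
  ## unique rows/columns of the atom matrix to sum to zero (both marginal
  ## contributions tie), which places m in the redundant-to-synergistic
  ## band rather than leaving only the unique self atoms.
  a <- 0.8
  m <- -0.5 * log2(1 - a^2)
  mod <- varModel(diag(a, 2), diag(1 - a^2, 2), nTime = 50L)
  at <- phiidAtoms(pairModelFromVar(mod, 1, 2))
  ## independent oracle: brute-force inversion of the analytic cumulative
  ## values (all block MIs are m or 0 here)
  cum <- stats::setNames(numeric(16), atomNames())
  cum[c("rts", "xtx", "xts", "yty", "yts", "str", "stx", "sty")] <- m
  cum["sts"] <- 2 * m
  expect_equal(at, bruteForceInvert(cum)[atomNames()], tolerance = 1e-9)
  expect_equal(unname(at["xtx"]), m, tolerance = 1e-9)
  expect_equal(unname(at["yty"]), m, tolerance = 1e-9)
  expect_equal(unname(at["rtr"]), 0, tolerance = 1e-9)
  ## cumulative values: self node carries the lagged MI, bottom node zero
  cl <- mmiCumulativeLattice(pairModelFromVar(mod, 1, 2))
  expect_equal(unname(cl["xtx"]), m, tolerance = 1e-9)
  expect_equal(unname(cl["rtr"]), 0, tolerance = 1e-9)
})

test_that("atoms conserve TDMI and satisfy the MMI structural constraints", {
  set.seed(34)
  for (rep in 1:100) {
    pm <- randomPairVar()$pair
    at <- phiidAtoms(pm)
    expect_lt(abs(sum(at) - tdmi(pm)), 1e-9)
    ## redundancy and synergy atoms are non-negative by construction
    expect_gte(at[["rtr"]], -1e-12)
    expect_gte(at[["sts"]], -1e-12)
    ## minimum unique information vanishes in at least one direction,
    ## past-side rows and future-side columns
    rowX <- at["xtr"] + at["xts"] + at["xtx"] + at["xty"]
    rowY <- at["ytr"] + at["yts"] + at["ytx"] + at["yty"]
    colX <- at["rtx"] + at["stx"] + at["xtx"] + at["ytx"]
    colY <- at["rty"] + at["sty"] + at["xty"] + at["yty"]
    expect_lt(min(abs(rowX), abs(rowY)), 1e-9)
    expect_lt(min(abs(colX), abs(colY)), 1e-9)
  }
})

test_that("exchanging the two inputs swaps the x and y atoms", {
  set.seed(35)
  m <- varModel(matrix(c(0.5, 0.3, -0.1, 0.4), 2, 2),
                matrix(c(1, 0.3, 0.3, 1), 2), nTime = 4000L)
  X <- tsMatrix(simulateVar(m, seed = 8))
  a12 <- phiidPair(X[1, ], X[2, ])
  a21 <- phiidPair(X[2, ], X[1, ])
  expect_equal(a12[["rtr"]], a21[["rtr"]], tolerance = 1e-12)
  expect_equal(a12[["sts"]], a21[["sts"]], tolerance = 1e-12)
  swaps <- c(xtx = "yty", xty = "ytx", rtx = "rty", xtr = "ytr",
             xts = "yts", stx = "sty")
  for (nm in names(swaps))
    expect_equal(a12[[nm]], a21[[swaps[[nm]]]], tolerance = 1e-12)
})

test_that("degenerate series are rejected", {
  expect_error(phiidPair(rep(1, 100), rnorm(100)), "constant")
  expect_error(phiidPair(rnorm(20), rnorm(20)), "too short")
  expect_error(pairModelFromVar(varModel(diag(0.5, 3), diag(3), nTime = 50L),
                                2, 2), "distinct")
})

test_that("all-pairs stacks have zero diagonal and conserve TDMI per pair", {
  set.seed(36)
  ts <- regionalTimeSeries(matrix(rnorm(4 * 500), 4), trSeconds = 3)
  st <- phiidAllPairs(ts)
  v <- atomValues(st)
  for (i in 1:4) expect_equal(max(abs(v[i, i, ])), 0)
  X <- tsMatrix(ts)
  for (i in 1:3) for (j in (i + 1):4) {
    pm <- pairModelFromSeries(X[i, ], X[j, ])
    expect_lt(abs(sum(v[i, j, ]) - tdmi(pm)), 1e-6)
    expect_equal(v[i, j, "sts"], v[j, i, "sts"], tolerance = 1e-12)
  }
})

test_that("independent channels carry their self-MI in the unique planes", {
  a <- c(0.6, 0.4, 0.7)
  mod <- varModel(diag(a), diag(1 - a^2), nTime = 50L)
  st <- phiidAllPairsAnalytic(mod)
  v <- atomValues(st)
  selfMI <- -0.5 * log2(1 - a^2)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    expect_equal(v[i, j, "xtx"], selfMI[i], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(v[i, j, "yty"], selfMI[j], tolerance = 1e-8,
                 ignore_attr = TRUE)
    ## no cross-channel dependence: double redundancy, transfer and the
    ## copy/erasure atoms all vanish
    expect_lt(max(abs(v[i, j, c("rtr", "rtx", "rty", "xtr", "ytr",
                                "xty", "ytx")])), 1e-8)
    ## independent oracle for the full pattern: brute-force inversion of
    ## the analytic block MIs under the MMI minimum rule
    mi <- selfMI[c(i, j)]
    cum <- c(rtr = 0, rtx = 0, rty = 0, rts = min(mi),
             xtr = 0, xtx = mi[1], xty = 0, xts = mi[1],
             ytr = 0, ytx = 0, yty = mi[2], yts = mi[2],
             str = min(mi), stx = mi[1], sty = mi[2], sts = sum(mi))
    expect_equal(v[i, j, ], bruteForceInvert(cum)[atomNames()],
                 tolerance = 1e-8)
  }
})

test_that("estimated atoms converge to the analytic decomposition", {
  set.seed(37)
  A <- matrix(c(0.5, 0.2, 0, 0,
                0.1, 0.4, 0.15, 0,
                0, 0.2, 0.5, -0.1,
                0.1, 0, 0.1, 0.3), 4, 4, byrow = TRUE)
  Q <- diag(4); Q[1, 2] <- Q[2, 1] <- 0.3
  truth <- atomValues(phiidAllPairsAnalytic(
    varModel(A, Q, nTime = 50L)))
  err <- function(Tn) {
    m <- varModel(A, Q, nTime = Tn)
    est <- atomValues(phiidAllPairs(simulateVar(m, seed = 71)))
    mean(abs(est - truth))
  }
  e1 <- err(1000L); e2 <- err(16000L)
  expect_lt(e2, e1 / 2)   # roughly 1/sqrt(T) decay over a 16x span
})
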