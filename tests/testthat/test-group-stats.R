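test_that("regional sums reduce a plane column-wise", {
  st <- zeroStack(3)
  v <- atomValues(st)
  v[, , "rtr"] <- 0.1
  for (i in 1:3) v[i, i, ] <- 0
  st <- atomStack(v)
  expect_equal(regionalSums(st, "rtr"), rep(0.2, 3))
  expect_equal(regionalSums(zeroStack(5), "sts"), rep(0, 5))
  expect_error(regionalSums(st, "zzz"), "unknown atom")
  ## symmetric plane: column sums equal row sums
  set.seed(41)
  M <- matrix(rnorm(16), 4); M <- M + t(M); diag(M) <- 0
  v2 <- array(0, dim = c(4, 4, 16)); v2[, , 16] <- M
  st2 <- atomStack(v2)
  expect_equal(regionalSums(st2, "sts"), rowSums(atomPlane(st2, "sts")))
})

test_that("z-scoring against the reference group follows its definition", {
  set.seed(42)
  ref <- matrix(rnorm(60, mean = 5), 12, 5)
  expect_equal(zscoreVsReference(ref, ref), rep(0, 5), tolerance = 1e-12)
  shift <- sweep(ref, 2, apply(ref, 2, sd), `+`)
  expect_equal(zscoreVsReference(shift, ref), rep(1, 5), tolerance = 1e-12)
  grp <- matrix(rnorm(40, mean = 4), 8, 5)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(zscoreVsReference(grp[, perm], ref[, perm]),
               zscoreVsReference(grp, ref)[perm])
  constRef <- matrix(1, 3, 2)
  expect_error(zscoreVsReference(matrix(0, 2, 2), constRef), "region")
})

test_that("PC1 projection captures the synergy-redundancy axis", {
  set.seed(43)
  z <- rnorm(30)
  anti <- pc1Projection(z, -z)
  expect_equal(anti$varianceExplained, 1.0, tolerance = 1e-12)
  ## orthogonal equal-variance configuration: exactly half the variance
  n <- 32
  u <- rep(c(1, -1), n / 2)
  v <- rep(c(1, 1, -1, -1), n / 4)
  iso <- pc1Projection(u, v)
  expect_equal(iso$varianceExplained, 0.5, tolerance = 1e-12)
  r <- pc1Projection(rnorm(20), rnorm(20))
  expect_gte(r$varianceExplained, 0.5)
  expect_lte(r$varianceExplained, 1.0)
  expect_gte(r$loadings[["z_red"]], 0)   # orientation convention
  expect_error(pc1Projection(rep(1, 5), rep(2, 5)), "variance")
})

test_that("Welch test matches stats::t.test and Hedges' g behaves", {
  x <- c(1, 2, 3, 4, 5)
  same <- welchTest(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$hedgesG, 0)
  set.seed(44)
  a <- rnorm(12, 0, 1); b <- rnorm(17, 0.8, 1.5)
  wt <- welchTest(a, b)
  ref <- stats::t.test(b, a, var.equal = FALSE)
  expect_equal(wt$t, unname(ref$statistic))
  expect_equal(wt$p, ref$p.value)
  expect_equal(wt$delta, mean(b) - mean(a))
  ## antisymmetry
  sw <- welchTest(b, a)
  expect_equal(sw$t, -wt$t)
  expect_equal(sw$hedgesG, -wt$hedgesG)
  expect_equal(sw$p, wt$p)
  ## unit-sd unit-shift: g approaches 1 at large n
  a2 <- rnorm(4000); b2 <- rnorm(4000, 1)
  expect_lt(abs(welchTest(a2, b2)$hedgesG - 1), 0.1)
  expect_error(welchTest(c(1, 1), c(2, 2)), "undefined")
})

test_that("BH q-values match the hand step-up oracle", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.37), 0.37)
  expect_equal(bhFdr(rep(1, 6)), rep(1, 6))
  expect_error(bhFdr(c(0.1, 1.2)), "0, 1")
  set.seed(45)
  for (rep in 1:50) {
    p <- runif(sample(1:10, 1))
    expect_equal(bhFdr(p), bhStepUp(p), tolerance = 1e-12)
  }
})

test_that("the pairwise grid counts, calibrates and localises effects", {
  set.seed(46)
  mk <- function(shift = 0, n = 4, N = 6) {
    lapply(seq_len(n), function(k) {
      v <- array(rnorm(N * N * 16, sd = 0.05), dim = c(N, N, 16))
      v[, , 16] <- v[, , 16] + shift
      for (i in seq_len(N)) v[i, i, ] <- 0
      atomStack(v, scanId = sprintf("s%d", k))
    })
  }
  null <- pairwiseAtomTests(mk(), mk(), "CN", "AD")
  expect_equal(null$nTests, 6 * 6 * 16)
  expect_lte(sum(null$q <= 0.05, na.rm = TRUE), 0.05 * null$nTests)
  ## a planted shift in one atom plane concentrates the rejections there
  eff <- pairwiseAtomTests(mk(), mk(shift = 1), "CN", "AD")
  sig <- significantCells(eff)
  expect_gt(nrow(sig), 0)
  expect_gt(mean(sig$atom == "sts" & sig$direction == "increase"), 0.8)
  offdiag <- 6 * 5   # every off-diagonal sts cell carries the shift
  expect_equal(sum(sig$atom == "sts"), offdiag)
  ## one cell cross-checked against stats::t.test
  A <- mk(); B <- mk(shift = 1)
  g <- pairwiseAtomTests(A, B)
  aa <- vapply(A, function(s) atomValues(s)[1, 2, 3], 0)
  bb <- vapply(B, function(s) atomValues(s)[1, 2, 3], 0)
  ref <- stats::t.test(bb, aa, var.equal = TRUE)
  expect_equal(unname(g$t[1, 2, 3]), unname(ref$statistic),
               tolerance = 1e-10)
  expect_equal(unname(g$p[1, 2, 3]), ref$p.value, tolerance = 1e-10)
})

test_that("intranetwork means divide by the squared network size", {
  scheme <- buildParcellation(8, 2)
  n <- nRegions(scheme)
  idx <- networkRegions(scheme, "Subcortex")
  v <- array(0, dim = c(n, n, 16))
  v[idx[1], idx[2], 1] <- 0.3   # rtr
  v[idx[2], idx[1], 1] <- 0.3
  st <- atomStack(v)
  expect_equal(intranetworkMean(st, scheme, "Subcortex", "rtr"), 0.6 / 4)
  expect_equal(intranetworkMean(zeroStack(n), scheme, "Subcortex", "rtr"), 0)
  st2 <- atomStack(v * 5)
  expect_equal(intranetworkMean(st2, scheme, "Subcortex", "rtr"), 5 * 0.6 / 4)
  expect_error(intranetworkMean(st, scheme, "Thalamus", "rtr"),
               "unknown network")
})

test_that("bootstrap intervals are reproducible, centred and calibrated", {
  expect_warning(ci0 <- bootstrapCI(c(3, 3, 3), nResamples = 50), "100")
  expect_equal(unname(ci0), c(3, 3))
  set.seed(47)
  x <- rnorm(40, 2)
  ci <- bootstrapCI(x, nResamples = 2000, seed = 9)
  expect_identical(ci, bootstrapCI(x, nResamples = 2000, seed = 9))
  expect_gt(mean(x), ci[["low"]])
  expect_lt(mean(x), ci[["high"]])
  ## coverage of the true mean over repeated Gaussian samples
  hits <- 0
  for (rep in 1:200) {
    y <- rnorm(30)
    ci2 <- bootstrapCI(y, nResamples = 400, seed = rep)
    hits <- hits + (ci2[["low"]] <= 0 && 0 <= ci2[["high"]])
  }
  expect_gt(hits / 200, 0.88)
  expect_lt(hits / 200, 0.99)
})
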