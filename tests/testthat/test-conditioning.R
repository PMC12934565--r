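test_that("band-pass removes DC and keeps the pass band", {
  tr <- 3
  tt <- seq(0, by = tr, length.out = 1200)
  const <- regionalTimeSeries(matrix(5, 1, length(tt)), trSeconds = tr)
  expect_lt(max(abs(tsMatrix(bandpass(const)))), 1e-8)

  inband <- sin(2 * pi * 0.01 * tt)
  flt <- bandpass(regionalTimeSeries(rbind(inband), trSeconds = tr))
  ## amplitude via the dominant Fourier coefficient, edges trimmed
  core <- 101:1100
  amp <- function(x, f) {
    n <- length(core)
    2 * Mod(sum(x[core] * exp(-2i * pi * f * tt[core]))) / n
  }
  expect_gt(amp(drop(tsMatrix(flt)), 0.01), 0.90)

  outband <- sin(2 * pi * 0.15 * tt)
  flt2 <- bandpass(regionalTimeSeries(rbind(outband), trSeconds = tr))
  expect_lt(amp(drop(tsMatrix(flt2)), 0.15), 0.10)
})

test_that("band edges outside (0, Nyquist) are rejected by name", {
  ts <- regionalTimeSeries(matrix(rnorm(100), 1), trSeconds = 3)
  expect_error(bandpass(ts, 0, 0.05), "positive")
  expect_error(bandpass(ts, 0.01, 0.2), "0.2 Hz")
  expect_error(bandpass(ts, 0.05, 0.01), "exceed")
})

test_that("conditioning confines spectral energy to the pass band", {
  tr <- 3
  tt <- seq(0, by = tr, length.out = 4000)
  ## mixture of in-band and out-of-band components
  x <- sin(2 * pi * 0.01 * tt) + 0.8 * sin(2 * pi * 0.002 * tt) +
    0.8 * sin(2 * pi * 0.12 * tt)
  flt <- drop(tsMatrix(bandpass(regionalTimeSeries(rbind(x), trSeconds = tr))))
  core <- flt[201:3800]
  sp <- Mod(stats::fft(core - mean(core)))^2
  freqs <- (seq_along(sp) - 1) / (length(sp) * tr)
  half <- freqs <= 1 / (2 * tr)
  outside <- half & (freqs < 0.0025 * 0.5 | freqs > 0.05 * 2)
  expect_lt(sum(sp[half & outside]) / sum(sp[half]), 0.01)
})

test_that("downsampling picks the nearest-slice stride", {
  X <- matrix(seq_len(2 * 100), 2, 100, byrow = TRUE)
  ts06 <- regionalTimeSeries(X, trSeconds = 0.6)
  d <- downsampleToTr(ts06, 3)
  expect_equal(trSeconds(d), 3.0)
  expect_equal(tsMatrix(d)[1, 1:3], c(1, 6, 11))   # stride 5 from index 0

  ts3 <- regionalTimeSeries(X, trSeconds = 3)
  expect_identical(tsMatrix(downsampleToTr(ts3, 3)), X)

  ts08 <- regionalTimeSeries(X, trSeconds = 0.8)
  d2 <- downsampleToTr(ts08, 3)
  expect_equal(trSeconds(d2), 3.2)                 # round(3.75) = 4 slices
  expect_error(downsampleToTr(ts3, 1), "below native TR")
})

test_that("nuisance regression is exact, orthogonal and idempotent", {
  set.seed(21)
  n <- 40
  cov1 <- rnorm(n)
  y <- rnorm(n)
  yo <- y - mean(y)
  co <- cov1 - mean(cov1)
  co <- co - sum(co * yo) / sum(yo^2) * yo   # covariate orthogonal to data
  out <- regressNuisance(yo, cbind(co))
  expect_equal(out, yo, tolerance = 1e-10)

  ## data exactly linear in a covariate collapses to its mean
  lin <- 2 + 3 * cov1
  expect_equal(regressNuisance(lin, cbind(cov1)), rep(mean(lin), n),
               tolerance = 1e-10)

  C <- cbind(rnorm(n), rnorm(n))
  V <- matrix(rnorm(n * 3), n, 3)
  res <- regressNuisance(V, C)
  centered <- sweep(res, 2, colMeans(V))
  expect_lt(max(abs(crossprod(C, centered))), 1e-8)
  expect_equal(regressNuisance(res, C), res, tolerance = 1e-10)
})

test_that("a collinear nuisance design is rejected with the column named", {
  x <- rnorm(20)
  expect_error(regressNuisance(rnorm(20), cbind(a = x, b = 2 * x)),
               "collinear")
})
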