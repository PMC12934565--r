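#' Zero-phase band-pass filter of regional time series
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to every
#' region independently, after removing each region's mean. The defaults are
#' the study band 0.0025-0.05 Hz. Zero-phase filtering preserves timing, a
#' requirement for the lag-1 decomposition downstream.
#'
#' @param ts a [RegionalTimeSeries-class].
#' @param lowHz,highHz pass-band edges in Hz; `0 < lowHz < highHz <`
#'   Nyquist (`1 / (2 TR)`).
#' @param order Butterworth order of the underlying recursive filter
#'   (default 2; forward-backward application squares the magnitude
#'   response).
#' @return A filtered [RegionalTimeSeries-class] of the same shape.
#' @examples
#' ts <- regionalTimeSeries(matrix(rnorm(2 * 400), 2), trSeconds = 3)
#' flt <- bandpass(ts)
#' @export
bandpass <- function(ts, lowHz = 0.0025, highHz = 0.05, order = 2) {
  stopifnot(methods::is(ts, "RegionalTimeSeries"))
  nyq <- 1 / (2 * trSeconds(ts))
  if (lowHz <= 0) stopf("low edge %g Hz must be positive", lowHz)
  if (highHz <= lowHz) stopf("high edge %g Hz must exceed low edge %g Hz",
                             highHz, lowHz)
  if (highHz >= nyq)
    stopf("high edge %g Hz at or above Nyquist %g Hz", highHz, nyq)
  bf <- signal::butter(order, c(lowHz, highHz) / nyq, type = "pass")
  X <- tsMatrix(ts)
  X <- X - rowMeans(X)
  Y <- t(apply(X, 1, function(x) signal::filtfilt(bf, x)))
  methods::new("RegionalTimeSeries", data = Y, trSeconds = trSeconds(ts),
               scanId = scanId(ts))
}

#' Downsample a scan to a target TR
#'
#' Keeps every k-th time point with `k = round(targetTr / TR)`, starting at
#' the first sample, so that all scans reach a comparable effective TR
#' "to the nearest slice" (e.g. native 0.6 s to target 3 s gives k = 5;
#' native 0.8 s gives k = 4 and an effective TR of 3.2 s).
#'
#' @param ts a [RegionalTimeSeries-class].
#' @param targetTr target sampling interval in seconds (>= native TR).
#' @return A [RegionalTimeSeries-class] with `trSeconds = k * native TR`.
#' @export
downsampleToTr <- function(ts, targetTr = 3) {
  stopifnot(methods::is(ts, "RegionalTimeSeries"))
  tr <- trSeconds(ts)
  if (targetTr < tr)
    stopf("target TR %g s below native TR %g s", targetTr, tr)
  k <- max(1L, as.integer(round(targetTr / tr)))
  keep <- seq(1L, ncol(tsMatrix(ts)), by = k)
  methods::new("RegionalTimeSeries",
               data = tsMatrix(ts)[, keep, drop = FALSE],
               trSeconds = k * tr, scanId = scanId(ts))
}

#' Regress nuisance covariates out of observation-level values
#'
#' Least-squares residualisation against a design of nuisance covariates
#' (age, education, sex, intracranial volume in the study design) with an
#' intercept added automatically. The intercept's fitted mean is added back,
#' so values stay on their original scale. The operation is deterministic
#' and idempotent.
#'
#' @param values numeric vector or matrix; rows are observations (e.g.
#'   scans), columns are measures (e.g. regions).
#' @param covariates numeric matrix/data.frame of nuisance covariates, rows
#'   aligned with `values`.
#' @return Residualised values, same shape as `values`.
#' @export
regressNuisance <- function(values, covariates) {
  v <- as.matrix(values)
  C <- as.matrix(covariates)
  if (nrow(C) != nrow(v))
    stopf("covariate rows (%d) must match observations (%d)", nrow(C), nrow(v))
  X <- cbind(`(Intercept)` = 1, C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("rank-deficient nuisance design; collinear column(s): %s",
          paste(drop, collapse = ", "))
  }
  beta <- qr.coef(qrX, v)
  res <- v - X %*% beta
  out <- sweep(res, 2, colMeans(v), `+`)
  if (is.vector(values)) drop(out) else out
}
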