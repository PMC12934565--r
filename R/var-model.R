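#' Construct a stationary VAR(1) model
#'
#' @param A N x N coupling matrix; spectral radius must be strictly below 1.
#' @param Q N x N innovation covariance, symmetric positive semi-definite.
#' @param nTime number of time points simulations should return.
#' @param trSeconds sampling interval in seconds (default 3, the harmonised
#'   effective TR of the study design).
#' @return A [VarModel-class].
#' @examples
#' m <- varModel(diag(0.5, 3), diag(3), nTime = 200)
#' stationaryCovariances(m)$Sigma0
#' @export
varModel <- function(A, Q, nTime = 200L, trSeconds = 3) {
  methods::new("VarModel", A = as.matrix(A), Q = as.matrix(Q),
               nTime = as.integer(nTime), trSeconds = trSeconds)
}

#' Stationary covariances of a VAR(1) model
#'
#' Solves the discrete Lyapunov identity
#' `Sigma0 = A Sigma0 A' + Q` for the stationary (lag-0) covariance and
#' returns the lag-1 cross-covariance `Sigma1 = A Sigma0`.
#'
#' Orientation convention, used consistently throughout the package:
#' `cov(X_t, X_{t+1}) = Sigma0 A'`, equivalently
#' `Sigma1 = A Sigma0 = cov(X_{t+1}, X_t)`.
#'
#' The solver is the quadratically convergent doubling iteration
#' (`S <- S + A S A'`, `A <- A A`), which handles the 232-region case where
#' the naive N^2 x N^2 Kronecker linear system is infeasible.
#'
#' @param model a [VarModel-class] (or a list with elements `A` and `Q`).
#' @param tol convergence tolerance on the update's max-norm.
#' @return List with `Sigma0` (N x N, symmetric PSD) and `Sigma1 = A Sigma0`.
#' @export
stationaryCovariances <- function(model, tol = 1e-14) {
  A <- if (methods::is(model, "VarModel")) model@A else as.matrix(model$A)
  Q <- if (methods::is(model, "VarModel")) model@Q else as.matrix(model$Q)
  rho <- spectralRadius(A)
  if (rho >= 1)
    stopf("unstable VAR: spectral radius %.6f >= 1", rho)
  S <- Q
  Ak <- A
  scale <- max(abs(Q), 1)
  for (k in 1:200) {
    upd <- Ak %*% S %*% t(Ak)
    S <- S + upd
    if (max(abs(upd)) < tol * scale) break
    Ak <- Ak %*% Ak
  }
  S <- (S + t(S)) / 2
  list(Sigma0 = S, Sigma1 = A %*% S)
}

#' Simulate a stationary VAR(1) time series
#'
#' Draws `X_{t+1} = A X_t + e_t` with `e_t ~ N(0, Q)` from a zero start,
#' discards a burn-in, and returns `nTime` samples as a
#' [RegionalTimeSeries-class]. Reproducible: the same seed yields identical
#' output.
#'
#' @param model a [VarModel-class].
#' @param seed integer RNG seed.
#' @param burnin samples discarded before recording (default 500, enough to
#'   forget the zero initial state at the coupling strengths used here).
#' @param scanId scan identifier stored on the result.
#' @return A [RegionalTimeSeries-class] with `nRegions(model)` rows and
#'   `model@nTime` columns.
#' @export
simulateVar <- function(model, seed, burnin = 500L, scanId = "sim") {
  stopifnot(methods::is(model, "VarModel"))
  if (model@nTime < 10L) stopf("nTime must be >= 10 (got %d)", model@nTime)
  rho <- spectralRadius(model@A)
  if (rho >= 1) stopf("unstable VAR: spectral radius %.6f >= 1", rho)
  n <- nRegions(model)
  Ttot <- model@nTime + burnin
  ## innovation factor: eigen square root tolerates PSD (rank-deficient) Q
  eg <- eigen(model@Q, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  L <- eg$vectors %*% (sqrt(ev) * t(eg$vectors))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  E <- L %*% matrix(stats::rnorm(n * Ttot), n, Ttot)
  X <- matrix(0, n, Ttot)
  x <- numeric(n)
  A <- model@A
  for (t in seq_len(Ttot)) {
    x <- drop(A %*% x) + E[, t]
    X[, t] <- x
  }
  methods::new("RegionalTimeSeries",
               data = X[, (burnin + 1L):Ttot, drop = FALSE],
               trSeconds = model@trSeconds, scanId = scanId)
}

#' Construct a RegionalTimeSeries
#'
#' @param data numeric matrix, regions x time points.
#' @param trSeconds sampling interval in seconds.
#' @param scanId scan identifier.
#' @return A [RegionalTimeSeries-class].
#' @export
regionalTimeSeries <- function(data, trSeconds = 3, scanId = "scan") {
  methods::new("RegionalTimeSeries", data = as.matrix(data),
               trSeconds = trSeconds, scanId = scanId)
}
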