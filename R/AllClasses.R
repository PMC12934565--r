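#' @include AllGenerics.R
NULL

#' The eight canonical network labels
#'
#' Seven resting-state cortical networks in the Yeo scheme plus a subcortical
#' grouping, the macroscopic units used throughout the network-level
#' analyses.
#'
#' @return Character vector of length 8.
#' @examples
#' yeoNetworks()
#' @export
yeoNetworks <- function() {
  c("Visual", "Somatomotor", "DorsalAttention", "Salience",
    "Limbic", "Control", "DefaultMode", "Subcortex")
}

#' ParcellationScheme: region identities and network membership
#'
#' Maps each region index to a name and one of the eight canonical network
#' labels (seven Yeo cortical networks plus Subcortex). The extended
#' parcellations used here are the Schaefer 200/100 cortical schemes plus
#' 32/16 subcortical regions, i.e. 232 or 116 regions in total.
#'
#' @slot regionIds integer vector, 0-based region indices 0..N-1.
#' @slot regionNames character vector of region names.
#' @slot networkLabels character vector, one label from [yeoNetworks()] per
#'   region.
#' @slot nCortical integer, number of cortical regions.
#' @slot nSubcortical integer, number of subcortical regions.
#' @seealso [buildParcellation()]
#' @export
setClass("ParcellationScheme",
  representation(
    regionIds = "integer",
    regionNames = "character",
    networkLabels = "character",
    nCortical = "integer",
    nSubcortical = "integer"
  )
)

setValidity("ParcellationScheme", function(object) {
  n <- length(object@regionIds)
  msg <- character(0)
  if (n != object@nCortical + object@nSubcortical)
    msg <- c(msg, "N must equal nCortical + nSubcortical")
  if (length(object@regionNames) != n || length(object@networkLabels) != n)
    msg <- c(msg, "regionNames and networkLabels must have length N")
  if (!identical(object@regionIds, seq_len(n) - 1L))
    msg <- c(msg, "regionIds must be 0..N-1")
  bad <- setdiff(unique(object@networkLabels), yeoNetworks())
  if (length(bad))
    msg <- c(msg, paste0("unknown network labels: ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' VarModel: a stationary first-order vector autoregression
#'
#' Ground-truth generative model for one synthetic scan:
#' `X_{t+1} = A X_t + e_t`, `e_t ~ N(0, Q)`. Stationarity requires the
#' spectral radius of `A` to be strictly below 1.
#'
#' @slot A N x N lag-1 coupling matrix (unitless).
#' @slot Q N x N innovation covariance (signal-variance units), symmetric
#'   positive semi-definite.
#' @slot nTime integer, number of time points a simulation should return.
#' @slot trSeconds numeric, sampling interval in seconds.
#' @seealso [varModel()], [stationaryCovariances()], [simulateVar()]
#' @export
setClass("VarModel",
  representation(
    A = "matrix",
    Q = "matrix",
    nTime = "integer",
    trSeconds = "numeric"
  )
)

setValidity("VarModel", function(object) {
  msg <- character(0)
  n <- nrow(object@A)
  if (ncol(object@A) != n) msg <- c(msg, "A must be square")
  if (!all(dim(object@Q) == n)) msg <- c(msg, "Q must match A's dimension")
  if (max(abs(object@Q - t(object@Q))) > 1e-8 * (1 + max(abs(object@Q))))
    msg <- c(msg, "Q must be symmetric")
  if (object@nTime < 2L) msg <- c(msg, "nTime must be at least 2")
  if (object@trSeconds <= 0) msg <- c(msg, "trSeconds must be positive")
  rho <- spectralRadius(object@A)
  if (rho >= 1)
    msg <- c(msg, sprintf("unstable VAR: spectral radius %.6f >= 1", rho))
  if (length(msg)) msg else TRUE
})

#' RegionalTimeSeries: one scan's regions x time matrix
#'
#' Parcellated regional signal for a single scan: `data[i, t]` is region i's
#' value at time point t, sampled every `trSeconds` seconds.
#'
#' @slot data numeric matrix, N regions x T time points.
#' @slot trSeconds numeric, sampling interval in seconds.
#' @slot scanId character scan identifier.
#' @seealso [regionalTimeSeries()], [bandpass()], [downsampleToTr()],
#'   [phiidAllPairs()]
#' @export
setClass("RegionalTimeSeries",
  representation(
    data = "matrix",
    trSeconds = "numeric",
    scanId = "character"
  )
)

setValidity("RegionalTimeSeries", function(object) {
  msg <- character(0)
  if (ncol(object@data) < 2) msg <- c(msg, "need at least 2 time points")
  if (anyNA(object@data)) msg <- c(msg, "data must not contain missing values")
  if (object@trSeconds <= 0) msg <- c(msg, "trSeconds must be positive")
  if (length(msg)) msg else TRUE
})

#' LaggedPairModel: joint Gaussian model of a region pair and its next step
#'
#' The 4 x 4 covariance of the stacked vector
#' `(x_t, y_t, x_{t+1}, y_{t+1})` for one ordered region pair, either
#' estimated from the T-1 lagged sample pairs of a scan or derived
#' analytically from a [VarModel-class]. All Gaussian information quantities
#' of the pair decomposition are functions of this covariance alone.
#'
#' @slot cov4 numeric 4 x 4 covariance matrix; coordinate order
#'   `(x_t, y_t, x_{t+1}, y_{t+1})`.
#' @slot nSamples integer, number of lagged sample pairs used in estimation
#'   (`NA` for analytic models).
#' @seealso [laggedPairModel()], [pairModelFromSeries()],
#'   [pairModelFromVar()], [phiidAtoms()]
#' @export
setClass("LaggedPairModel",
  representation(
    cov4 = "matrix",
    nSamples = "integer"
  )
)

setValidity("LaggedPairModel", function(object) {
  msg <- character(0)
  if (!all(dim(object@cov4) == c(4L, 4L)))
    msg <- c(msg, "cov4 must be 4 x 4")
  else {
    if (max(abs(object@cov4 - t(object@cov4))) >
        1e-8 * (1 + max(abs(object@cov4))))
      msg <- c(msg, "cov4 must be symmetric")
    if (any(diag(object@cov4) <= 0))
      msg <- c(msg, "cov4 diagonal must be strictly positive")
  }
  if (length(msg)) msg else TRUE
})

#' AtomStack: all-pairs atom array for one scan
#'
#' N x N x 16 array holding the sixteen information atoms for every ordered
#' region pair of a scan. Plane `a` at `[i, j, ]` is the decomposition of the
#' pair with region i as the first (x) channel and region j as the second (y)
#' channel; all self-pairs `[i, i, ]` are zero by convention.
#'
#' @slot values numeric N x N x 16 array, third dimension named by
#'   [atomNames()].
#' @slot scanId character scan identifier.
#' @seealso [phiidAllPairs()], [atomPlane()], [regionalSums()],
#'   [writeAtomStack()]
#' @export
setClass("AtomStack",
  representation(
    values = "array",
    scanId = "character"
  )
)

setValidity("AtomStack", function(object) {
  d <- dim(object@values)
  msg <- character(0)
  if (length(d) != 3 || d[1] != d[2] || d[3] != 16L)
    msg <- c(msg, "values must be an N x N x 16 array")
  if (!identical(dimnames(object@values)[[3]], atomNames()))
    msg <- c(msg, "third dimension must be named by the 16 canonical atoms")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "atom values must be finite")
  n <- d[1]
  if (length(msg) == 0 && n > 0) {
    dg <- vapply(seq_len(n), function(i) max(abs(object@values[i, i, ])), 0)
    if (max(dg) > 0) msg <- c(msg, "self-pair (diagonal) atoms must be zero")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: scans, subjects and ground truth of one simulated study
#'
#' Container returned by [generateCohort()]: the simulated scans, the
#' subject covariate table, the per-subject ground-truth VAR models (the
#' analytic oracle for the decomposition), and the parcellation they share.
#'
#' @slot scans list of [RegionalTimeSeries-class], one per subject.
#' @slot subjects data.frame of subject covariates.
#' @slot models named list of [VarModel-class], one per subject.
#' @slot scheme the common [ParcellationScheme-class].
#' @seealso [generateCohort()], [writeCohort()]
#' @export
setClass("SyntheticCohort",
  representation(
    scans = "list",
    subjects = "data.frame",
    models = "list",
    scheme = "ParcellationScheme"
  )
)

setValidity("SyntheticCohort", function(object) {
  msg <- character(0)
  ns <- nrow(object@subjects)
  if (length(object@scans) != ns || length(object@models) != ns)
    msg <- c(msg, "scans, models and subjects must agree in length")
  need <- c("subject_id", "group", "moca", "moca_category",
            "age", "education", "sex", "icv")
  miss <- setdiff(need, names(object@subjects))
  if (length(miss))
    msg <- c(msg, paste0("subject table lacks columns: ",
                         paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @rdname nRegions
#' @export
setMethod("nRegions", "ParcellationScheme",
          function(x) length(x@regionIds))
#' @rdname nRegions
#' @export
setMethod("nRegions", "RegionalTimeSeries", function(x) nrow(x@data))
#' @rdname nRegions
#' @export
setMethod("nRegions", "VarModel", function(x) nrow(x@A))
#' @rdname nRegions
#' @export
setMethod("nRegions", "AtomStack", function(x) dim(x@values)[1])

#' @rdname networkLabels
#' @export
setMethod("networkLabels", "ParcellationScheme", function(x) x@networkLabels)

#' @rdname regionNames
#' @export
setMethod("regionNames", "ParcellationScheme", function(x) x@regionNames)

#' @rdname trSeconds
#' @export
setMethod("trSeconds", "RegionalTimeSeries", function(x) x@trSeconds)

#' @rdname scanId
#' @export
setMethod("scanId", "RegionalTimeSeries", function(x) x@scanId)
#' @rdname scanId
#' @export
setMethod("scanId", "AtomStack", function(x) x@scanId)

#' @rdname tsMatrix
#' @export
setMethod("tsMatrix", "RegionalTimeSeries", function(x) x@data)

#' @rdname atomValues
#' @export
setMethod("atomValues", "AtomStack", function(x) x@values)

#' @rdname cohortScans
#' @export
setMethod("cohortScans", "SyntheticCohort", function(x) x@scans)
#' @rdname cohortSubjects
#' @export
setMethod("cohortSubjects", "SyntheticCohort", function(x) x@subjects)
#' @rdname cohortModels
#' @export
setMethod("cohortModels", "SyntheticCohort", function(x) x@models)
#' @rdname cohortScheme
#' @export
setMethod("cohortScheme", "SyntheticCohort", function(x) x@scheme)

## ---- show methods ----

setMethod("show", "ParcellationScheme", function(object) {
  cat(sprintf("ParcellationScheme with %d regions (%d cortical + %d subcortical)\n",
              nRegions(object), object@nCortical, object@nSubcortical))
  tb <- table(factor(object@networkLabels, levels = yeoNetworks()))
  cat("networks:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
})

setMethod("show", "VarModel", function(object) {
  cat(sprintf("VarModel: %d regions, %d time points, TR = %g s, spectral radius %.3f\n",
              nRegions(object), object@nTime, object@trSeconds,
              spectralRadius(object@A)))
})

setMethod("show", "RegionalTimeSeries", function(object) {
  cat(sprintf("RegionalTimeSeries '%s': %d regions x %d time points, TR = %g s\n",
              object@scanId, nrow(object@data), ncol(object@data),
              object@trSeconds))
})

setMethod("show", "LaggedPairModel", function(object) {
  cat(sprintf("LaggedPairModel (n = %s lagged samples)\n",
              ifelse(is.na(object@nSamples), "analytic", object@nSamples)))
  print(round(object@cov4, 4))
})

setMethod("show", "AtomStack", function(object) {
  n <- dim(object@values)[1]
  cat(sprintf("AtomStack '%s': %d x %d x 16 atoms (bits)\n",
              object@scanId, n, n))
  cat(sprintf("  mean redundancy (rtr) %.4f, mean synergy (sts) %.4f\n",
              mean(object@values[, , "rtr"]), mean(object@values[, , "sts"])))
})

setMethod("show", "SyntheticCohort", function(object) {
  tb <- table(object@subjects$group)
  cat(sprintf("SyntheticCohort: %d scans on %d regions (%s)\n",
              length(object@scans), nRegions(object@scheme),
              paste(sprintf("%s=%d", names(tb), tb), collapse = " ")))
})
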