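#' @include AllGenerics.R
NULL

#' Number of regions in an object
#'
#' @param x a [ParcellationScheme-class], [RegionalTimeSeries-class],
#'   [VarModel-class] or [AtomStack-class] object.
#' @return Integer scalar, the number of regions N.
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' Network labels of a parcellation
#'
#' @param x a [ParcellationScheme-class].
#' @return Character vector of length N with one of the eight canonical
#'   network labels per region.
#' @export
setGeneric("networkLabels", function(x) standardGeneric("networkLabels"))

#' Region names
#' @param x a [ParcellationScheme-class].
#' @return Character vector of region names.
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' Sampling interval (TR) in seconds
#' @param x a [RegionalTimeSeries-class].
#' @return Numeric scalar, seconds between consecutive samples.
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' Scan identifier
#' @param x a [RegionalTimeSeries-class] or [AtomStack-class].
#' @return Character scalar.
#' @export
setGeneric("scanId", function(x) standardGeneric("scanId"))

#' Time-series matrix (regions x time points)
#' @param x a [RegionalTimeSeries-class].
#' @return Numeric matrix, rows = regions, columns = time points.
#' @export
setGeneric("tsMatrix", function(x) standardGeneric("tsMatrix"))

#' Atom array of a stack
#' @param x an [AtomStack-class].
#' @return Numeric N x N x 16 array; `x[i, j, a]` is atom `a` for the ordered
#'   pair with region i as the first (x) channel and region j as the second
#'   (y) channel.
#' @export
setGeneric("atomValues", function(x) standardGeneric("atomValues"))

#' Scans of a synthetic cohort
#' @param x a [SyntheticCohort-class].
#' @return List of [RegionalTimeSeries-class] objects, one per scan.
#' @export
setGeneric("cohortScans", function(x) standardGeneric("cohortScans"))

#' Subject table of a synthetic cohort
#' @param x a [SyntheticCohort-class].
#' @return data.frame with one row per subject (subject_id, group, moca,
#'   moca_category, age, education, sex, icv).
#' @export
setGeneric("cohortSubjects", function(x) standardGeneric("cohortSubjects"))

#' Ground-truth VAR models of a synthetic cohort
#' @param x a [SyntheticCohort-class].
#' @return Named list of [VarModel-class] objects, one per subject.
#' @export
setGeneric("cohortModels", function(x) standardGeneric("cohortModels"))

#' Parcellation of a synthetic cohort
#' @param x a [SyntheticCohort-class].
#' @return The [ParcellationScheme-class] the cohort was generated on.
#' @export
setGeneric("cohortScheme", function(x) standardGeneric("cohortScheme"))
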