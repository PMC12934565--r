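#' Default structural parameters of the synthetic cohort generator
#'
#' The generator builds, for every subject, a stationary VAR(1) whose
#' coupling matrix carries network structure and whose innovation covariance
#' carries common-input (shared-noise) structure:
#'
#' * `aDiag` — lag-1 self-coupling of every region (temporal
#'   autocorrelation of slow BOLD-like signal at TR = 3 s).
#' * `wWithin` — total cross-coupling a region receives from its own
#'   network, split equally across network peers.
#' * `wBetween` — total cross-coupling received from all other regions.
#' * `qWithin` — innovation correlation between same-network regions
#'   (common input; drives redundancy).
#' * `qBetween` — innovation correlation between any two regions.
#' * `subjectSdA`, `subjectSdQ` — standard deviations of the per-subject
#'   log-normal jitter applied to coupling entries and to the within-network
#'   innovation blocks.
#'
#' Group-level modifiers in [generateCohort()]'s `groupSpec` act on top:
#' `couplingScale` multiplies all cross-region coupling (synergy is carried
#' by cross-prediction, so scaling it below 1 lowers synergy), while
#' `sharedInnovationScale` multiplies all innovation correlations (raising
#' redundancy), optionally boosted further within named networks via
#' `networkEffects`.
#'
#' @return Named list of the defaults described above.
#' @export
cohortDefaults <- function() {
  list(aDiag = 0.35, wWithin = 0.25, wBetween = 0.10,
       qWithin = 0.10, qBetween = 0.05,
       subjectSdA = 0.10, subjectSdQ = 0.05)
}

## network-structured coupling matrix before group scaling / jitter
.baseCoupling <- function(scheme, p) {
  n <- nRegions(scheme)
  labs <- networkLabels(scheme)
  A <- matrix(p$wBetween / (n - 1), n, n)
  for (net in unique(labs)) {
    idx <- which(labs == net)
    m <- length(idx)
    if (m > 1) A[idx, idx] <- p$wWithin / (m - 1)
  }
  diag(A) <- p$aDiag
  A
}

## innovation covariance as a sum of PSD pieces:
## qBetween * J_N  +  per-network (qWithin_net - qBetween) * J_net  +  diag
.baseInnovation <- function(scheme, p, qWithinNet) {
  n <- nRegions(scheme)
  labs <- networkLabels(scheme)
  Q <- matrix(p$qBetween, n, n)
  dg <- rep(1 - p$qBetween, n)
  for (net in unique(labs)) {
    idx <- which(labs == net)
    extra <- qWithinNet[[net]] - p$qBetween
    if (extra < 0)
      stopf("within-network innovation correlation below the global level in '%s'", net)
    Q[idx, idx] <- Q[idx, idx] + extra
    dg[idx] <- dg[idx] - extra
  }
  if (any(dg < 0))
    stopf("innovation correlations too large (effective within-network value >= 1)")
  diag(Q) <- 1
  Q
}

#' Generate a synthetic cohort of parcellated scans
#'
#' Simulates, for each subject of each diagnostic group, a stationary VAR(1)
#' regional time series on a common parcellation, together with a covariate
#' table (age, education, sex, intracranial volume, MoCA). The per-subject
#' generative models are returned as the analytic ground truth for the
#' information decomposition.
#'
#' Group entries in `groupSpec` are named lists with fields:
#' `n` (subjects, >= 2), `couplingScale` (multiplier on all cross-region
#' coupling, default 1), `sharedInnovationScale` (multiplier on all
#' innovation correlations, default 1), and `networkEffects` (named list of
#' additional within-network shared-innovation multipliers, e.g.
#' `list(DefaultMode = 1.6)`). A disease-like group is obtained with
#' `couplingScale < 1` (synergy loss) and `sharedInnovationScale > 1`
#' (redundancy gain).
#'
#' MoCA scores are drawn around group-typical means (CN 27, MCI 23, AD 17,
#' sd 2-3, clipped to 0-30) and categorised by `mocaThresholds`
#' (High >= `high`, Low < `low`, Medium in between).
#'
#' @param scheme a [ParcellationScheme-class].
#' @param groupSpec named list keyed by group label (`CN`, `MCI`, `AD`); see
#'   Details.
#' @param nTime time points per scan.
#' @param seed integer master seed; every subject derives its own
#'   sub-seed, so the whole cohort (covariates included) is reproducible.
#' @param trSeconds sampling interval of the simulated scans (default 3 s).
#' @param burnin burn-in samples discarded per scan.
#' @param params structural parameters, see [cohortDefaults()].
#' @param mocaThresholds numeric `c(high =, low =)` category cut-offs
#'   (defaults: High >= 26, Low < 18).
#' @return A [SyntheticCohort-class].
#' @examples
#' scheme <- buildParcellation(16, 2)
#' ch <- generateCohort(scheme,
#'   list(CN = list(n = 2), AD = list(n = 2, couplingScale = 0.7)),
#'   nTime = 60, seed = 1)
#' ch
#' @export
generateCohort <- function(scheme, groupSpec, nTime = 200L, seed = 1L,
                           trSeconds = 3, burnin = 500L,
                           params = cohortDefaults(),
                           mocaThresholds = c(high = 26, low = 18)) {
  stopifnot(methods::is(scheme, "ParcellationScheme"))
  knownGroups <- c("CN", "MCI", "AD")
  bad <- setdiff(names(groupSpec), knownGroups)
  if (length(bad))
    stopf("unknown group label(s): %s (expected %s)",
          paste(bad, collapse = ", "), paste(knownGroups, collapse = ", "))
  labs <- networkLabels(scheme)
  p <- utils::modifyList(cohortDefaults(), params)
  mocaMean <- c(CN = 27, MCI = 23, AD = 17)
  mocaSd <- c(CN = 2, MCI = 2.5, AD = 3)

  scans <- list(); models <- list(); rows <- list()
  k <- 0L
  for (g in names(groupSpec)) {
    gs <- groupSpec[[g]]
    if (is.null(gs$n) || gs$n < 2)
      stopf("group '%s' needs at least 2 subjects", g)
    cs <- gs$couplingScale %||% 1
    is <- gs$sharedInnovationScale %||% 1
    ne <- gs$networkEffects %||% list()
    badNet <- setdiff(names(ne), unique(labs))
    if (length(badNet))
      stopf("networkEffects names not in parcellation: %s",
            paste(badNet, collapse = ", "))
    qWithinNet <- stats::setNames(as.list(rep(p$qWithin * is, length(unique(labs)))),
                                  unique(labs))
    for (net in names(ne)) qWithinNet[[net]] <- qWithinNet[[net]] * ne[[net]]
    Abase <- .baseCoupling(scheme, p)
    off <- row(Abase) != col(Abase)
    Abase[off] <- Abase[off] * cs
    pScaled <- utils::modifyList(p, list(qBetween = p$qBetween * is))

    for (s in seq_len(gs$n)) {
      k <- k + 1L
      sid <- sprintf("%s_%03d", g, s)
      covSeed <- childSeed(seed, 1000L + k)
      simSeed <- childSeed(seed, 2000L + k)
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      set.seed(covSeed)
      A <- Abase
      A[off] <- A[off] * exp(stats::rnorm(sum(off), 0, p$subjectSdA))
      qSubj <- lapply(qWithinNet, function(q)
        min(q * exp(stats::rnorm(1, 0, p$subjectSdQ)), 0.9))
      Q <- .baseInnovation(scheme, pScaled, qSubj)
      moca <- round(stats::rnorm(1, mocaMean[[g]], mocaSd[[g]]))
      moca <- max(0L, min(30L, as.integer(moca)))
      rows[[k]] <- data.frame(
        subject_id = sid, group = g, moca = moca,
        moca_category = mocaCategory(moca, mocaThresholds),
        age = round(stats::rnorm(1, 73, 7), 1),
        education = round(stats::rnorm(1, 16, 3), 1),
        sex = stats::rbinom(1, 1, 0.5),
        icv = round(stats::rnorm(1, 1.5e6, 1.5e5)),
        stringsAsFactors = FALSE)
      if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
      rho <- spectralRadius(A)
      if (rho >= 0.99)
        stopf("subject '%s' model unstable after scaling (spectral radius %.3f)",
              sid, rho)
      m <- varModel(A, Q, nTime = nTime, trSeconds = trSeconds)
      models[[sid]] <- m
      scans[[k]] <- simulateVar(m, seed = simSeed, burnin = burnin, scanId = sid)
    }
  }
  methods::new("SyntheticCohort",
               scans = scans,
               subjects = do.call(rbind, rows),
               models = models,
               scheme = scheme)
}

#' MoCA score to cognitive category
#'
#' @param moca integer score 0-30.
#' @param thresholds numeric `c(high =, low =)`; High for `moca >= high`,
#'   Low for `moca < low`, Medium otherwise.
#' @return `"High"`, `"Medium"` or `"Low"`.
#' @export
mocaCategory <- function(moca, thresholds = c(high = 26, low = 18)) {
  ifelse(moca >= thresholds[["high"]], "High",
         ifelse(moca < thresholds[["low"]], "Low", "Medium"))
}
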