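#' Default pipeline configuration
#'
#' Nested list mirroring the YAML configuration consumed by the pipeline
#' stages. Defaults: band 0.0025-0.05 Hz, target TR 3 s, alpha 0.05,
#' 10000 permutation resamples, 10000 bootstrap resamples, grouping by
#' diagnosis, confound regression enabled.
#'
#' @return Named nested list.
#' @export
defaultPipelineConfig <- function() {
  list(
    paths = list(data_dir = "data", output_dir = "results"),
    simulate = list(
      n_cortical = 24L, n_subcortical = 8L,
      n_time = 400L, tr_seconds = 3, burnin = 500L,
      groups = list(
        CN = list(n_subjects = 10L),
        AD = list(n_subjects = 10L, coupling_scale = 0.7,
                  shared_innovation_scale = 1.3,
                  network_effects = list(Subcortex = 2.0)))),
    conditioning = list(apply_bandpass = TRUE,
                        band_low_hz = 0.0025, band_high_hz = 0.05,
                        target_tr = 3),
    decomposition = list(ridge = 1e-10, min_length = 30L),
    analysis = list(alpha = 0.05, permutation_n = 10000L,
                    bootstrap_n = 10000L, grouping = "diagnosis",
                    regress_confounds = TRUE,
                    moca_thresholds = list(high = 26, low = 18)),
    seeds = list(simulate = 1L, permutation = 2L, bootstrap = 3L))
}

## recursive merge of a partial user config into the defaults
.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(user[[nm]])) && nm != "groups" &&
        nm != "network_effects")
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    else
      base[[nm]] <- user[[nm]]
  }
  base
}

#' Read a pipeline configuration
#'
#' Loads a YAML file and merges it over [defaultPipelineConfig()]; missing
#' fields keep their defaults. Relative paths are interpreted relative to
#' the configuration file's directory.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated nested configuration list.
#' @export
readPipelineConfig <- function(path = NULL) {
  cfg <- defaultPipelineConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- .mergeConfig(cfg, user)
    root <- dirname(normalizePath(path))
    for (p in names(cfg$paths))
      if (!grepl("^(/|[A-Za-z]:)", cfg$paths[[p]]))
        cfg$paths[[p]] <- file.path(root, cfg$paths[[p]])
  }
  a <- cfg$analysis
  if (a$alpha <= 0 || a$alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (!a$grouping %in% c("diagnosis", "moca_category"))
    stopf("grouping must be 'diagnosis' or 'moca_category'")
  if (cfg$conditioning$band_low_hz >= cfg$conditioning$band_high_hz)
    stopf("invalid band edges")
  cfg
}

.logMsg <- function(...) message(sprintf("[phidyn] %s", sprintf(...)))

#' Simulate stage: write a synthetic cohort to disk
#'
#' Generates the configured cohort and writes the TSV layout of
#' [writeCohort()] into `paths$data_dir`, plus a `config.yaml` snapshot.
#' Deterministic: rerunning with the same configuration reproduces the
#' files byte for byte.
#'
#' @param config configuration list from [readPipelineConfig()].
#' @return The data directory, invisibly.
#' @export
runSimulate <- function(config = defaultPipelineConfig()) {
  sm <- config$simulate
  scheme <- buildParcellation(sm$n_cortical, sm$n_subcortical)
  groupSpec <- lapply(sm$groups, function(g)
    list(n = g$n_subjects,
         couplingScale = g$coupling_scale %||% 1,
         sharedInnovationScale = g$shared_innovation_scale %||% 1,
         networkEffects = g$network_effects %||% list()))
  th <- unlist(config$analysis$moca_thresholds)
  cohort <- generateCohort(scheme, groupSpec, nTime = sm$n_time,
                           seed = config$seeds$simulate,
                           trSeconds = sm$tr_seconds, burnin = sm$burnin,
                           mocaThresholds = th)
  dir <- config$paths$data_dir
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
    .logMsg("created data directory %s", dir)
  }
  writeCohort(cohort, dir)
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  .logMsg("wrote %d scans to %s", length(cohortScans(cohort)), dir)
  invisible(dir)
}

#' Decompose stage: all-pairs atom stacks for every scan
#'
#' Reads the manifest in `paths$data_dir`, conditions each scan (band-pass
#' if enabled, then downsampling to the target TR) and writes one atom
#' stack per scan under `paths$output_dir/stacks`, with a JSON run report
#' listing skipped scans.
#'
#' @param config configuration list from [readPipelineConfig()].
#' @return The stacks directory, invisibly.
#' @export
runDecompose <- function(config = defaultPipelineConfig()) {
  cd <- readCohortDir(config$paths$data_dir)
  outDir <- file.path(config$paths$output_dir, "stacks")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cn <- config$conditioning
  dc <- config$decomposition
  skipped <- list()
  for (k in seq_len(nrow(cd$manifest))) {
    row <- cd$manifest[k, ]
    ts <- readTimeSeries(file.path(cd$dir, row$file),
                         trSeconds = row$tr_seconds, scanId = row$scan_id)
    if (ncol(tsMatrix(ts)) < dc$min_length) {
      .logMsg("skipping scan %s: %d < %d time points",
              row$scan_id, ncol(tsMatrix(ts)), dc$min_length)
      skipped[[length(skipped) + 1L]] <-
        list(scan_id = row$scan_id, reason = "too short")
      next
    }
    if (isTRUE(cn$apply_bandpass))
      ts <- bandpass(ts, cn$band_low_hz, cn$band_high_hz)
    if (cn$target_tr > trSeconds(ts))
      ts <- downsampleToTr(ts, cn$target_tr)
    st <- phiidAllPairs(ts, minLength = dc$min_length, ridge = dc$ridge)
    writeAtomStack(st, file.path(outDir, paste0(row$scan_id, ".tsv")))
  }
  jsonlite::write_json(
    list(n_scans = nrow(cd$manifest), n_skipped = length(skipped),
         skipped = skipped),
    file.path(config$paths$output_dir, "decompose-report.json"),
    auto_unbox = TRUE)
  .logMsg("decomposed %d scans (%d skipped)",
          nrow(cd$manifest) - length(skipped), length(skipped))
  invisible(outDir)
}

## stage ordering of the two grouping schemes; contrasts are (earlier,
## later) so positive deltas mean higher at the later stage
.groupOrder <- function(grouping) {
  if (grouping == "diagnosis") c("CN", "MCI", "AD")
  else c("High", "Medium", "Low")
}

#' Analyze stage: full group-comparison battery
#'
#' For every ordered contrast of the configured grouping (diagnosis
#' CN/MCI/AD or MoCA High/Medium/Low) with at least 2 scans per side,
#' computes: region-wise Welch+FDR tests of the summed redundancy (`rtr`)
#' and synergy (`sts`); network-level Welch tests of intranetwork means;
#' z-scores against the first (reference) group with the PC1 projection;
#' and the network-label permutation test of the per-region changes.
#' Across all groups it runs the taxonomic mode ANOVA battery. Per-scan
#' summed measures and intranetwork means are residualised against age,
#' education, sex and intracranial volume first unless
#' `analysis$regress_confounds` is disabled. Tables are written as TSV and
#' a JSON summary (carrying seeds and contrasts) under
#' `paths$output_dir`.
#'
#' @param config configuration list from [readPipelineConfig()].
#' @return Invisible list of all result tables.
#' @export
runAnalyze <- function(config = defaultPipelineConfig()) {
  outDir <- config$paths$output_dir
  stacksDir <- file.path(outDir, "stacks")
  if (!dir.exists(stacksDir) ||
      !length(list.files(stacksDir, pattern = "\\.tsv$")))
    stopf("no atom stacks found under '%s'; run the decompose stage first",
          stacksDir)
  cd <- readCohortDir(config$paths$data_dir)
  a <- config$analysis
  files <- list.files(stacksDir, pattern = "\\.tsv$", full.names = TRUE)
  stacks <- lapply(files, readAtomStack)
  names(stacks) <- vapply(stacks, scanId, "")
  subj <- cd$subjects
  rownames(subj) <- subj$subject_id
  scanSubj <- stats::setNames(cd$manifest$subject_id, cd$manifest$scan_id)
  ids <- names(stacks)
  groupOf <- if (a$grouping == "diagnosis") {
    stats::setNames(subj[scanSubj[ids], "group"], ids)
  } else {
    stats::setNames(subj[scanSubj[ids], "moca_category"], ids)
  }
  covars <- as.matrix(subj[scanSubj[ids], c("age", "education", "sex", "icv")])

  measures <- c(Redundancy = "rtr", Synergy = "sts")
  sums <- lapply(measures, function(atom) regionalSumsMatrix(stacks, atom))
  netMeans <- lapply(measures, function(atom) {
    m <- vapply(yeoNetworks(), function(nw)
      vapply(stacks, intranetworkMean, 0, scheme = cd$scheme,
             network = nw, atom = atom), numeric(length(stacks)))
    rownames(m) <- ids
    m
  })
  if (isTRUE(a$regress_confounds)) {
    sums <- lapply(sums, regressNuisance, covariates = covars)
    netMeans <- lapply(netMeans, regressNuisance, covariates = covars)
  }

  ord <- .groupOrder(a$grouping)
  present <- ord[ord %in% groupOf]
  counts <- table(factor(groupOf, levels = present))
  usable <- names(counts)[counts >= 2]
  if (length(usable) < length(present))
    .logMsg("contrast(s) skipped: group(s) with < 2 scans: %s",
            paste(setdiff(present, usable), collapse = ", "))
  contrasts <- list()
  if (length(usable) >= 2)
    for (i in seq_len(length(usable) - 1)) for (j in (i + 1):length(usable))
      contrasts[[length(contrasts) + 1L]] <- c(usable[i], usable[j])

  regional <- list(); network <- list(); permut <- list(); pc1 <- list()
  for (ct in contrasts) {
    ga <- ct[1]; gb <- ct[2]
    tag <- paste0(ga, "_vs_", gb)
    idsA <- ids[groupOf == ga]; idsB <- ids[groupOf == gb]
    for (ms in names(measures)) {
      va <- sums[[ms]][idsA, , drop = FALSE]
      vb <- sums[[ms]][idsB, , drop = FALSE]
      rt <- regionwiseTests(va, vb, ga, gb)
      rt$measure <- ms; rt$contrast <- tag
      regional[[length(regional) + 1L]] <- rt

      na <- netMeans[[ms]][idsA, , drop = FALSE]
      nb <- netMeans[[ms]][idsB, , drop = FALSE]
      wt <- lapply(yeoNetworks(), function(nw)
        welchTest(na[, nw], nb[, nw]))
      nt <- data.frame(network = yeoNetworks(),
                       delta = vapply(wt, `[[`, 0, "delta"),
                       t = vapply(wt, `[[`, 0, "t"),
                       p = vapply(wt, `[[`, 0, "p"),
                       hedges_g = vapply(wt, `[[`, 0, "hedgesG"))
      nt$q <- bhFdr(nt$p)
      ci <- t(vapply(yeoNetworks(), function(nw)
        bootstrapCI(nb[, nw] - mean(na[, nw]),
                    nResamples = a$bootstrap_n,
                    seed = childSeed(config$seeds$bootstrap,
                                     match(nw, yeoNetworks()))),
        numeric(2)))
      nt$ci_low <- ci[, 1]; nt$ci_high <- ci[, 2]
      nt$measure <- ms; nt$contrast <- tag
      network[[length(network) + 1L]] <- nt

      delta <- colMeans(vb) - colMeans(va)
      pm <- networkPermutationTest(delta, cd$scheme,
                                   nResamples = a$permutation_n,
                                   seed = config$seeds$permutation)
      pm$measure <- ms; pm$contrast <- tag
      permut[[length(permut) + 1L]] <- pm
    }
    zr <- zscoreVsReference(sums$Redundancy[idsB, , drop = FALSE],
                            sums$Redundancy[idsA, , drop = FALSE])
    zs <- zscoreVsReference(sums$Synergy[idsB, , drop = FALSE],
                            sums$Synergy[idsA, , drop = FALSE])
    pj <- pc1Projection(zr, zs)
    pc1[[length(pc1) + 1L]] <- data.frame(
      contrast = tag, region = seq_along(zr),
      network = networkLabels(cd$scheme),
      z_red = zr, z_syn = zs, pc1_score = pj$scores,
      variance_explained = pj$varianceExplained)
  }

  modes <- NULL
  if (length(usable) >= 2) {
    keep <- ids[groupOf[ids] %in% usable]
    sigs <- modeSignatures(stacks[keep], cd$scheme)
    modes <- modeAnova(sigs, groupOf[keep], alpha = a$alpha)
  }

  res <- list(regional = do.call(rbind, regional),
              network = do.call(rbind, network),
              permutation = do.call(rbind, permut),
              pc1 = do.call(rbind, pc1),
              mode_omnibus = modes$omnibus,
              mode_posthoc = modes$posthoc)
  for (nm in names(res)) if (!is.null(res[[nm]]))
    utils::write.table(res[[nm]], file.path(outDir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(grouping = a$grouping, alpha = a$alpha,
         contrasts = vapply(contrasts, paste, "", collapse = "_vs_"),
         seeds = config$seeds,
         n_scans = length(ids),
         groups = as.list(table(groupOf))),
    file.path(outDir, "analysis-summary.json"), auto_unbox = TRUE)
  .logMsg("analysis written to %s (%d contrasts)", outDir, length(contrasts))
  invisible(res)
}

#' Report stage: plain-text summary of an analysis directory
#'
#' Collates the headline numbers (significant regions per contrast,
#' network-level effects, permutation results) from a completed analyze
#' stage into `report.md`.
#'
#' @param config configuration list from [readPipelineConfig()].
#' @return The report path, invisibly.
#' @export
runReport <- function(config = defaultPipelineConfig()) {
  outDir <- config$paths$output_dir
  need <- file.path(outDir, c("regional.tsv", "network.tsv",
                              "permutation.tsv"))
  if (!all(file.exists(need)))
    stopf("analysis tables missing under '%s'; run the analyze stage first",
          outDir)
  rd <- function(f) utils::read.table(file.path(outDir, f), sep = "\t",
                                      header = TRUE, stringsAsFactors = FALSE)
  regional <- rd("regional.tsv"); network <- rd("network.tsv")
  permut <- rd("permutation.tsv")
  alpha <- config$analysis$alpha
  lines <- c("# phidyn analysis report", "")
  for (ct in unique(regional$contrast)) {
    lines <- c(lines, sprintf("## %s", ct), "")
    for (ms in unique(regional$measure)) {
      rr <- regional[regional$contrast == ct & regional$measure == ms, ]
      lines <- c(lines, sprintf(
        "- %s: %d/%d regions significant (q <= %g); %d increases, %d decreases",
        ms, sum(rr$q <= alpha), nrow(rr), alpha,
        sum(rr$q <= alpha & rr$delta > 0),
        sum(rr$q <= alpha & rr$delta < 0)))
      nn <- network[network$contrast == ct & network$measure == ms, ]
      sig <- nn[nn$q <= alpha, ]
      if (nrow(sig))
        lines <- c(lines, sprintf(
          "  - networks: %s",
          paste(sprintf("%s (delta=%.4f bits, q=%.3g, g=%.3f)",
                        sig$network, sig$delta, sig$q, sig$hedges_g),
                collapse = "; ")))
      pp <- permut[permut$contrast == ct & permut$measure == ms &
                     permut$q <= alpha, ]
      if (nrow(pp))
        lines <- c(lines, sprintf(
          "  - beyond-global modulation: %s",
          paste(pp$network, collapse = ", ")))
    }
    lines <- c(lines, "")
  }
  path <- file.path(outDir, "report.md")
  writeLines(lines, path)
  .logMsg("report written to %s", path)
  invisible(path)
}
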