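test_that("network permutation test handles constants and planted shifts", {
  scheme <- buildParcellation(24, 8)
  n <- nRegions(scheme)
  const <- networkPermutationTest(rep(0.3, n), scheme,
                                  nResamples = 500, seed = 1)
  expect_equal(const$observed, rep(0, 8))
  expect_equal(const$p, rep(1, 8))
  ## a shift confined to one network is that network's to win
  set.seed(51)
  wins <- 0
  for (rep in 1:20) {
    delta <- rnorm(n, sd = 0.1)
    idx <- networkRegions(scheme, "Subcortex")
    delta[idx] <- delta[idx] + 0.5
    pm <- networkPermutationTest(delta, scheme, nResamples = 500, seed = rep)
    wins <- wins + (pm$network[which.min(pm$q)] == "Subcortex")
  }
  expect_gte(wins / 20, 0.95)
})

test_that("permutation p-values are calibrated for exchangeable deltas", {
  scheme <- buildParcellation(24, 8)
  n <- nRegions(scheme)
  set.seed(52)
  rej <- 0; tests <- 0
  for (rep in 1:30) {
    pm <- networkPermutationTest(rnorm(n), scheme,
                                 nResamples = 400, seed = 100 + rep)
    rej <- rej + sum(pm$p <= 0.05)
    tests <- tests + nrow(pm)
  }
  rate <- rej / tests   # 240 draws; binomial sd ~ 0.014
  expect_lt(rate, 0.10)
  expect_error(networkPermutationTest(rnorm(5), scheme, 500, 1), "match")
})

test_that("mode signatures follow the grouping table", {
  modes <- phiidModes()
  expect_setequal(unlist(modes), atomNames())
  expect_equal(modes$storage, c("rtr", "xtx", "yty", "sts"))
  expect_equal(modes$transfer, c("xty", "ytx"))

  scheme <- buildParcellation(16, 4)
  n <- nRegions(scheme)
  idx <- networkRegions(scheme, "Somatomotor")   # exactly two regions
  v <- array(0, dim = c(n, n, 16))
  v[idx[1], idx[2], match("xty", atomNames())] <- 0.1
  v[idx[1], idx[2], match("ytx", atomNames())] <- 0.2
  st <- atomStack(v, scanId = "toy")
  sig <- modeSignature(st, scheme)
  tr <- sig$value[sig$network == "Somatomotor" & sig$mode == "transfer"]
  expect_equal(tr, 0.3 / 4)
  expect_equal(sum(sig$value[sig$mode != "transfer" |
                               sig$network != "Somatomotor"]), 0)

  ## the four modes partition TDMI: their sum is the intranetwork TDMI mean
  set.seed(53)
  ts <- regionalTimeSeries(matrix(rnorm(20 * 400), 20), trSeconds = 3)
  st2 <- phiidAllPairs(ts)
  sig2 <- modeSignature(st2, scheme)
  tdmiPlane <- apply(atomValues(st2), c(1, 2), sum)
  for (nw in c("Visual", "Subcortex")) {
    got <- sum(sig2$value[sig2$network == nw])
    expect_equal(got, intranetworkMean(st2, scheme, nw, tdmiPlane),
                 tolerance = 1e-10)
  }
})

test_that("mode ANOVA emits 32 omnibus tests and localises a planted shift", {
  scheme <- buildParcellation(16, 4)
  n <- nRegions(scheme)
  mkStack <- function(id, bump = 0) {
    v <- array(abs(rnorm(n * n * 16, sd = 0.03)), dim = c(n, n, 16))
    idx <- networkRegions(scheme, "Control")
    v[idx, idx, match("rtr", atomNames())] <-
      v[idx, idx, match("rtr", atomNames())] + bump
    for (i in seq_len(n)) v[i, i, ] <- 0
    atomStack(v, scanId = id)
  }
  set.seed(54)
  stacks <- c(lapply(sprintf("cn%d", 1:6), mkStack),
              lapply(sprintf("mci%d", 1:6), mkStack),
              lapply(sprintf("ad%d", 1:6), mkStack, bump = 0.5))
  names(stacks) <- vapply(stacks, scanId, "")
  groups <- stats::setNames(rep(c("CN", "MCI", "AD"), each = 6),
                            names(stacks))
  res <- modeAnova(modeSignatures(stacks, scheme), groups)
  expect_equal(nrow(res$omnibus), 32L)
  expect_equal(unique(res$omnibus$n_groups), 3L)
  top <- res$omnibus[which.min(res$omnibus$q), ]
  expect_equal(top$network, "Control")
  expect_equal(top$mode, "storage")
  ## post-hocs exist only for significant omnibus cells and implicate AD
  expect_gt(nrow(res$posthoc), 0)
  sigCells <- res$omnibus[res$omnibus$q <= 0.05, c("network", "mode")]
  expect_true(all(paste(res$posthoc$network, res$posthoc$mode) %in%
                    paste(sigCells$network, sigCells$mode)))
  best <- res$posthoc[res$posthoc$q <= 0.05, ]
  expect_true(all(best$group_a == "AD" | best$group_b == "AD"))
})

test_that("mode ANOVA is quiet when groups are exchangeable", {
  scheme <- buildParcellation(16, 4)
  n <- nRegions(scheme)
  set.seed(55)
  stacks <- lapply(sprintf("s%d", 1:12), function(id) {
    v <- array(rnorm(n * n * 16, sd = 0.05), dim = c(n, n, 16))
    for (i in seq_len(n)) v[i, i, ] <- 0
    atomStack(v, scanId = id)
  })
  names(stacks) <- sprintf("s%d", 1:12)
  groups <- stats::setNames(rep(c("CN", "AD"), each = 6), names(stacks))
  res <- modeAnova(modeSignatures(stacks, scheme), groups)
  expect_lte(sum(res$omnibus$q <= 0.05), 3)
})
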