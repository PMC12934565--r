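## shared fixtures and independent oracles, all built in code

## random stationary 2-node VAR; returns the analytic lagged-pair model and
## its ingredients
randomPairVar <- function(stableBelow = 0.95) {
  repeat {
    A <- matrix(stats::runif(4, -0.6, 0.6), 2, 2)
    diag(A) <- stats::runif(2, 0.1, 0.8)
    if (max(Mod(eigen(A, only.values = TRUE)$values)) < stableBelow) break
  }
  q12 <- stats::runif(1, -0.8, 0.8)
  Q <- matrix(c(1, q12, q12, 1), 2, 2)
  m <- varModel(A, Q, nTime = 100L)
  list(model = m, pair = pairModelFromVar(m, 1, 2))
}

## independent Lyapunov oracle: vectorised Kronecker solve (small N only)
lyapunovKronecker <- function(A, Q) {
  n <- nrow(A)
  matrix(solve(diag(n^2) - kronecker(A, A), as.vector(Q)), n, n)
}

## independent brute-force Moebius oracle: build the 16 x 16 accumulation
## (zeta) system from first principles and solve it
bruteForceInvert <- function(cumulative) {
  nodes <- c("r", "x", "y", "s")
  leq <- function(a, b) a == b | a == "r" | b == "s"
  past <- rep(nodes, each = 4)
  fut <- rep(nodes, times = 4)
  Z <- outer(1:16, 1:16, function(n, m)
    as.numeric(leq(past[m], past[n]) & leq(fut[m], fut[n])))
  stats::setNames(drop(solve(Z, cumulative)), paste0(past, "t", fut))
}

## independent BH step-up oracle, following the definition directly
bhStepUp <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    pi <- p[o[i]]
    ## smallest p(j) * m / rank(j) over j with p(j) >= p(i)
    cand <- vapply(i:m, function(j) p[o[j]] * m / j, 0)
    q[o[i]] <- min(1, min(cand))
  }
  q
}

## tiny deterministic atom stack with chosen entries on one plane
zeroStack <- function(n, scanId = "z") {
  atomStack(array(0, dim = c(n, n, 16L)), scanId = scanId)
}

## small two-group cohort pushed through conditioning + decomposition;
## returns stacks split by group plus the scheme and subject table
decomposedCohort <- function(scheme, groupSpec, nTime, seed,
                             condition = TRUE) {
  ch <- generateCohort(scheme, groupSpec, nTime = nTime, seed = seed)
  stacks <- lapply(cohortScans(ch), function(ts) {
    if (condition) ts <- downsampleToTr(bandpass(ts), 3)
    phiidAllPairs(ts)
  })
  names(stacks) <- vapply(stacks, scanId, "")
  subj <- cohortSubjects(ch)
  list(stacks = stacks, subjects = subj, scheme = scheme,
       byGroup = split(names(stacks), subj$group[match(names(stacks),
                                                       subj$subject_id)]))
}
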