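---
title: "Methods: Gaussian ΦID-MMI and the group-comparison pipeline"
author: "phidyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Gaussian ΦID-MMI and the group-comparison pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phidyn)
```

# The model

`phidyn` analyses parcellated regional time series under a joint-Gaussian
assumption. For an ordered pair of regional signals $(x, y)$ observed at a
sampling interval of one TR, the object of interest is the time-delayed
mutual information

$$\mathrm{TDMI} = I(x_t, y_t ;\, x_{t+1}, y_{t+1}),$$

everything the pair's present carries about its state one step later.
Integrated Information Decomposition splits the TDMI into sixteen
non-overlapping *atoms*, indexed by a past mode and a future mode drawn
from the four-node redundancy lattice of two variables:

* `r` — the redundant level, `{x}{y}`: content available from either
  region;
* `x`, `y` — the unique levels, single regions (incomparable with each
  other);
* `s` — the synergistic level, the joint pair `{xy}`.

Atom `atb` (written `rtr`, `xty`, `sts`, …) is the piece of information
occupying mode `a` in the past and mode `b` in the future. `rtr` is the
pair's *redundancy*, `sts` its *synergy*.

## The MMI rule and Möbius inversion

All Gaussian information quantities are functions of the $4 \times 4$
covariance of $(x_t, y_t, x_{t+1}, y_{t+1})$ (`LaggedPairModel`). Entropies
and mutual informations use base-2 logarithms throughout; every quantity in
the package is in bits.

The minimum-mutual-information (MMI) redundancy — exact for Gaussians and
standard practice for BOLD-like signals — assigns to every node pair
$(\alpha, \beta)$ of the product lattice the cumulative value

$$\mathrm{cum}(\alpha \to \beta)
  = \min_{a \in \alpha,\ b \in \beta} I(a_t ;\, b_{t+1}),$$

where a node's collections are single channels or the joint pair. The
bottom value is the double redundancy, the top value is the TDMI, and the
assignment is monotone along the product order. A Möbius inversion (each
atom equals its node's cumulative value minus all atoms strictly below,
swept in topological order) recovers the sixteen atoms. Two consequences
are guaranteed by construction and enforced as test invariants:

* **conservation** — the atoms sum exactly to the TDMI;
* **structural zeros** — the minimum unique information vanishes in each
  direction, so one past-unique *row* and one future-unique *column* of
  the $4\times4$ atom matrix sum to zero.

Under full non-negativity those two quadruples are zero atom-by-atom.
Because any row and any column of a $4\times4$ matrix intersect in exactly
one cell, the number of *distinct* atoms forced to zero is $4+4-1 = 7$; the
package's acceptance script reports the count it actually computes.

A point worth flagging for MMI newcomers: for two *independent* channels
with equal self-predictability $m$, MMI assigns $\min(m, m) = m$ of
"shared" information to the redundant-to-synergistic band
(`rts = str = m`, with compensating negative `xts`/`stx`-type atoms and
`sts = 2m`), rather than leaving only the unique self atoms. This is the
known behaviour of the minimum rule — it cannot distinguish "both regions
know the same thing" from "both regions know equally sized different
things" — and it is why downstream analyses compare *relative changes*
between groups rather than absolute atom values. Only `rtr` and `sts` are
sign-guaranteed; other atoms may legitimately be negative.

## Numerical choices

* **Estimation** — the pair covariance is estimated from the $T-1$ lagged
  sample pairs after demeaning each series; no variance normalisation
  (Gaussian MI is scale-invariant, so this is cosmetic, but it fixes the
  reported covariance scale). Lag is one sample; with TR-harmonised scans
  that is ≈ 3 s.
* **Conditioning** — a relative ridge of $10^{-10} \times$ mean diagonal is
  added to every pair covariance before determinants are taken;
  near-duplicate regional signals otherwise break the log-determinants.
  Covariances that remain singular raise an error naming the pair.
* **Ties** — the cumulative value is a minimum, so no tie-breaking is
  needed; atom values are continuous but not differentiable at ties.
* **Degenerate inputs** — constant series, too-short series (default
  minimum 30 samples) and self-pairs are rejected; in the all-pairs stack
  every self-pair is fixed at zero by convention.
* **Hot path** — `phiidAllPairs()` estimates the scan's lag-0 and lag-1
  covariance matrices once, assembles each pair's $4\times4$ covariance
  from them, evaluates the nine block MIs with closed-form determinants,
  and applies the precomputed inverse of the lattice's zeta matrix; the
  unordered half of the grid is filled via the x/y exchange symmetry.
* **Lyapunov solver** — analytic stationary covariances use the doubling
  iteration ($S \leftarrow S + A S A^\top$, $A \leftarrow A A$), which is
  quadratically convergent and handles 232 regions; the
  $N^2 \times N^2$ Kronecker solve is kept only as a small-$N$ oracle in
  the tests. Orientation convention, used consistently:
  $\mathrm{cov}(X_t, X_{t+1}) = \Sigma_0 A^\top$.

# Signal conditioning

Band-pass filtering uses a zero-phase (forward–backward) Butterworth
filter, order 2 by default, with pass band 0.0025–0.05 Hz — the slow
BOLD band. Zero-phase filtering preserves timing, which matters for a
lag-1 decomposition; each region is filtered independently and demeaned.
TR harmonisation keeps every $k$-th sample with
$k = \mathrm{round}(\mathrm{target\ TR} / \mathrm{TR})$ ("to the nearest
slice"), e.g. native 0.6 s → stride 5 at a 3 s target; native 0.8 s →
stride 4 and an effective TR of 3.2 s.

Nuisance regression (age, years of education, sex, intracranial volume)
residualises per-scan summary measures by least squares with an intercept,
adding the mean back so values keep their scale; it is deterministic and
idempotent, and a rank-deficient design fails loudly with the collinear
columns named. The pipeline applies it to per-scan regional sums and
intranetwork means before group statistics (flag
`analysis$regress_confounds` to disable). Regressing per-scan summaries —
rather than group-average matrices — is the reading adopted here because it
is well-defined per observation and testable; the alternative
(residualising group-mean matrices) collapses the subject dimension and
leaves nothing for the group tests to operate on.

# Group statistics

* **Regional reduction** — a region's Redundancy/Synergy is the column sum
  of the `rtr`/`sts` plane over all partners (self terms zero). For these
  symmetric planes the row/column choice is inert; the column orientation
  is fixed and documented.
* **z-scores** — region-wise against the reference (CN-like) group:
  $(\bar v_{\text{group}} - \bar v_{\text{ref}}) / s_{\text{ref}}$ with
  the $n-1$ standard deviation.
* **PC1** — the leading eigenvector of the centred
  $(z_{\text{red}}, z_{\text{syn}})$ configuration, oriented so increasing
  redundancy loads positively; the variance-explained share for two
  variables lies in $[0.5, 1]$.
* **Tests** — regional and network contrasts use Welch's unequal-variance
  $t$ with Hedges' $g$ (pooled sd, small-sample factor
  $J = 1 - 3/(4\,\mathrm{df}-1)$); the full pairwise $N \times N \times 16$
  grid uses pooled-variance $t$ tests, vectorised over the array, with one
  BH correction across the whole grid and increases/decreases separated
  for reporting. Deltas are later-stage minus earlier-stage
  (CN → MCI → AD; High → Medium → Low MoCA).
* **Permutation test** — per network, the statistic is the network's mean
  per-region change minus the global mean; the null shuffles
  region-to-network labels (default 10,000 resamples), the two-tailed
  p-value uses the add-one estimator (never exactly zero), and the eight
  networks share one BH correction per measure.
* **Modes** — storage (`rtr, xtx, yty, sts`), transfer (`xty, ytx`),
  copy/erasure (`xtr, ytr, rtx, rty`) and multi-scale causation
  (`stx, sty, str, xts, yts, rts`); mode planes are averaged within each
  network over all ordered pairs divided by $|S|^2$ exactly (zero diagonal
  included), so the four modes partition the intranetwork TDMI mean. The
  $4 \times 8$ cells get classic one-way ANOVAs with one BH correction
  across all 32; post-hoc Welch tests are spawned only by significant
  omnibus cells, and that spawned family receives its own BH correction
  (the post-hoc family definition is a design choice; no canonical one is
  published for this battery).
* **Bootstrap** — percentile intervals of the mean (default 10,000
  resamples, seeded).

# The synthetic cohort

The generator is the package's test bed and oracle, not a biophysical
model. Each subject gets a stationary VAR(1),
$X_{t+1} = A X_t + \varepsilon_t$, $\varepsilon_t \sim N(0, Q)$, on a
parcellation whose cortical regions are split proportionally across the
seven Yeo-style networks (remainder to Visual, deterministic) plus a
subcortical block.

Structural defaults (`cohortDefaults()`): self-coupling 0.35 (slow
BOLD-like autocorrelation at TR 3 s); total within-network cross-coupling
0.25 split over network peers; total between-network coupling 0.10;
innovation correlations 0.10 within network and 0.05 globally;
per-subject log-normal jitter (sd 0.10 on couplings, 0.05 on
within-network innovation blocks). The innovation matrix is assembled as a
sum of PSD pieces (global constant + within-network blocks + diagonal), so
positive-definiteness is structural. The within-network innovation level
was fixed by a design requirement of the module itself: with
parameter-identical groups the downstream battery must reject at nominal
rates, and stronger common input correlates regional deltas within
networks, which an exchangeability-based permutation null does not see;
0.10 satisfies the calibration contract while keeping a realistic
common-input level.

Group modifiers: `couplingScale` multiplies cross-region coupling —
synergy lives in cross-prediction, so 0.7 produces a disease-like synergy
loss; `sharedInnovationScale` multiplies innovation correlations
(redundancy gain); `networkEffects` boosts named networks further (the
planted, network-specific effect the permutation test should find).
Covariates are drawn from plausible magnitudes (age $N(73, 7)$ years,
education $N(16, 3)$ years, sex Bernoulli(0.5), ICV
$N(1.5\times10^6, 1.5\times10^5)$ mm³; MoCA around group-typical means 27 /
23 / 17, categorised High ≥ 26, Medium 18–25, Low < 18 — configurable,
since published category cut-offs vary); they exist to exercise the
regression plumbing, not as scientific claims. Simulations discard a
500-sample burn-in from the zero start. Every subject derives its own
sub-seed from the master seed, so cohorts are bit-reproducible, covariates
included.

What the generator does *not* emulate: haemodynamics, spatial structure,
scanner drift and motion artefacts, non-Gaussian or non-stationary
dynamics, and longitudinal structure. Passing tests therefore show the
*pipeline* recovers information-dynamic structure planted in
linear-Gaussian data at the stated sizes — they do not validate the
decomposition's assumptions on real BOLD.

# Simulation sizes and test design

The acceptance battery runs at fixed sizes chosen to make its Monte-Carlo
error bounds explicit: 1,000 random stationary pair models for
conservation and oracle equivalence; a fixed 4-region VAR with
$T \in \{10^3, 4\times10^3, 1.6\times10^4, 10^5\}$ for estimator
consistency (error roughly $\propto 1/\sqrt{T}$); and, for the calibration
and recovery suites, cohorts of 2 × 20 scans on 32 regions (24 + 8) with
$T = 400$ over 20 master seeds, using 2,000 permutation resamples per
test. At those sizes the null rejection-rate estimates carry a binomial
standard error of roughly 0.01–0.02, which the test tolerances state
explicitly. The planted disease-like condition scales cross-coupling by
0.7, shared innovations by 1.3, and doubles the subcortical within-network
innovation correlation; Subcortex is the planted network because it is the
largest network of the 32-region test parcellation — a network-mean
statistic over a 3-region network is intrinsically underpowered, which is
a property of the statistic, not of the effect.

# Known limitations

* The MMI rule's treatment of independent-but-equal channels (above) means
  absolute values of mixed atoms need careful interpretation; group
  *differences* are the supported use.
* Only lag-1 decompositions are implemented; no discrete-variable
  estimators and no common-change-in-surprisal redundancy.
* The pairwise grid's pooled-variance $t$ assumes equal group variances
  cell-wise (the regional and network analyses use Welch); with strong
  group-wise heteroscedasticity the grid is the blunter instrument.
* The permutation test assumes per-region changes are exchangeable under
  the null; strongly correlated regional noise (e.g. heavy common input)
  makes it anti-conservative, which is why the generator's defaults were
  required to satisfy the calibration contract.
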