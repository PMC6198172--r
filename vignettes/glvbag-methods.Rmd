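---
title: "Inferring microbial interaction networks from compositional time series"
author: "glvbag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring microbial interaction networks from compositional time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glvbag)
```

## The problem

Longitudinal surveys of microbial communities — 16S amplicon time series
of a gut microbiome, plate counts of a cheese rind community — measure
*relative* abundances: each sample is a composition summing to one, and
the total community size is unobserved. `glvbag` infers a signed,
directed interaction network (who promotes or suppresses whom) from such
data by fitting population-dynamic models to the whole trajectory and
stabilising the notoriously unstable model-selection step with bootstrap
aggregation.

## The community model

Community dynamics follow a generalized Lotka-Volterra (gLV) system with
a shared logistic carrying capacity:

$$\frac{dx_i}{dt} \;=\; x_i\!\left(r_i + \sum_{j \ne i} a_{ij}\,
\frac{x_j}{N}\right)\!\left(1 - \frac{N}{K}\right),
\qquad N = \sum_i x_i ,$$

where $x_i(t)$ is the absolute abundance of taxon $i$ (cells/g), $r_i$
its intrinsic growth rate (1/day), $K$ the carrying capacity of the whole
community, and $a_{ij}$ the effect of taxon $j$ on taxon $i$, weighted by
$j$'s relative abundance. Diagonal terms are excluded: crowding acts only
through the community-wide factor $(1 - N/K)$. Extinction and the empty
community are absorbing. The sign pair $(a_{ij}, a_{ji})$ of each taxon
pair maps onto the six classical ecological relationships: `+/+`
mutualism, `-/-` competition, `+/-` parasitism, `+/0` commensalism,
`-/0` amensalism, `0/0` neutral.

Integration uses an adaptive Dormand-Prince RK45 pair implemented in
compiled code; `deSolve`'s stiffness-switching `lsoda` is available as an
independent engine (`glv_simulate(engine = "lsoda")`) and the two are
cross-checked in the test suite. The compiled integrator exists because
one network inference performs on the order of $10^5$ trajectory solves;
an integration failure inside the fitting loop penalizes that candidate
rather than aborting the run. Public simulations default to tolerances
(rtol $10^{-8}$, atol $10^{-10}K$) that keep the accumulated error of a
30-50 point trajectory below $\sim 10^{-6}$ relative; the fitting layer
uses rtol $10^{-6}$, atol $10^{-9}K$, far below observation noise.
Integrator output is floored at zero: the model preserves non-negativity
analytically, so small negative excursions are numerical error.

## Fitting compositions

The data are compositions $p_{it}$, so the model is fitted in
composition space: simulate absolute abundances, divide by $N(t)$, and
minimize

$$RSS = \sum_{t=1}^{T}\sum_{i=1}^{n}\bigl(p_{it} - \hat p_{it}\bigr)^2$$

by bounded Levenberg-Marquardt (`minpack.lm`), varying all $n$ growth
rates plus a chosen *active set* of interaction coefficients; inactive
coefficients are exactly zero. Because the dynamics need an absolute
starting state, the simulation is seeded from the first observed
composition scaled to community size $N_0 = 0.01K$ (`n0_fraction`);
exact zeros in that first row are floored at relative abundance
$10^{-6}$ (`zero_floor`) since zero is absorbing and could never match
later nonzero observations. Bounds are $r_i \in [-10, 10]$/day and
$a_{ij} \in [-50, 50]$ — wide relative to biologically reported scales —
with at most 200 LM iterations per fit.

Models are scored by the Bayesian information criterion

$$BIC = U \ln\!\left(\frac{RSS}{U}\right) + V \ln U ,$$

with $V$ = number of free parameters ($n$ growth rates + active
coefficients) and RSS clamped below at $10^{-12}$ so noiseless fits
cannot produce $-\infty$.

**What is $U$?** We count $U = T$, the number of time points
(`bic_datapoints = "timepoints"`; `"residuals"` gives $T \cdot n$). The
$n$ residuals at one time point are compositionally dependent — their
deviations sum to approximately zero because both observation and
prediction sum to one — so counting all $T\cdot n$ of them overstates
the independent information and makes the per-parameter penalty $\ln U$
too cheap: at $T = 30, n = 3$ a coefficient would pay for itself with a
5% RSS reduction, and because the BIC is evaluated on the full series
(whose noise is shared across bootstrap rounds) such noise-chasing
additions recur with a consistent sign and survive aggregation. With
$U = T$ an addition must cut the RSS by ~11%, and interaction-free data
yield empty models almost always.

## Forward stepwise selection

Starting from the growth-only model, each round tentatively adds every
remaining single coefficient and every remaining reciprocal pair
$\{a_{ij}, a_{ji}\}$ (pairs are offered because the ecological
classification is defined on sign pairs), refits on the training subset,
and scores on the whole series. Additions that do not lower the current
BIC are never taken — so the accepted-BIC trace is strictly decreasing —
and among improving additions within `bic_tie_delta = 2` of the round's
best, one is drawn uniformly at random; selection stops when no addition
lowers the BIC. Candidate fits warm-start from the incumbent: the greedy
path is an incremental refinement, which also damps the optimizer's
appetite for distant noise-fitting optima (a deliberately *stronger*
per-candidate optimizer was tried during development and rejected — it
found more shared-noise optima and degraded both false-positive control
and recovery).

One numerical guard: the growth-only fit occasionally runs to the $r$
bound, because on compositions the *common* growth scale is only weakly
identified (it enters solely through saturation timing). A bound-pinned
incumbent would poison every warm start of that round, so it is refitted
from a slow-growth start and an interior solution of comparable BIC is
preferred. `exhaustive_select()` provides the brute-force reference —
every coefficient subset fitted from the default start — against which
the greedy path is validated for 2-3 taxa.

## Bootstrap aggregation, filtering, significance

Each of `n_bootstraps` (default 1000; the validation studies in this
package use 100-150) rounds draws a random training subset of
`round(0.8 T)` time points — always including the first, which seeds
every simulation — runs stepwise selection, and keeps the resulting
model. Rounds are seeded by a counter scheme from `master_seed`
(child = master + round·1000003 mod 2³¹−1), so results are independent
of execution order and of `threads`.

Aggregation then proceeds in three steps:

1. **Biological filtering** (optional, off by default): each model is
   re-simulated over the observed span; models driving any taxon below
   `min_species_abundance` or the community below `min_community_size`
   are discarded with a logged reason.
2. **Best-BIC slice**: with $B^\* = \min$ BIC over retained models, keep
   models with $BIC \le B^\* + 0.10\,|B^\*|$ (the absolute value makes
   the band widen upward for the negative BICs typical here; an
   absolute-width band is available via `allowance_mode`).
3. **One-sample t-tests**: for every ordered pair, the coefficient values
   across retained models — an exact 0 where a model did not select the
   pair, since that coefficient is zero in that model by construction —
   are tested against mean zero, two-sided; an interaction is significant
   when $p < 1 -$ `confidence` (default 0.95). Degenerate samples use
   the natural conventions (all-zero → $p = 1$; constant nonzero →
   $p = 0$). An only-selected-values mode exists
   (`include_zero_coefficients = FALSE`) for comparison. No
   multiple-testing correction is applied across the $n(n-1)$ pairs.

Significant pairs become directed edges (`source -> target` encodes
$a_{\mathrm{target},\mathrm{source}}$, the effect *of* the source *on*
the target), weighted by the aggregated mean; sign pairs are classified
into the six relationship labels. A significant mean within $10^{-12}$
of zero carries no sign information and is treated as zero.

## Synthetic study systems

No real dataset ships with the package; all validation uses the
generator, which simulates known gLV parameters and applies one of two
observation-noise models: multiplicative lognormal (plate-count-style
measurement error) or multinomial resampling at finite depth
(sequencing-style). Three presets define the study conditions:

* `preset_predator_prey()` — the recovery system: predator `X1`
  ($r = -0.15$), neutral spectator `X2` ($r = 0.35$), prey `X3`
  ($r = 0.59$), with $a_{13} = +2.0$ (prey fuels predator) and
  $a_{31} = -1.4$ (predator suppresses prey); $K = 10^{10}$ cells/g,
  initial community $0.01K$, 30 daily samples, 5% lognormal noise. The
  composition traces a damped half-oscillation: predator share rises
  then falls, prey crashes then partially recovers, spectator dips then
  climbs. This shape is the point. Under the sum-to-one constraint,
  taxa with monotone, mutually proportional trajectories are
  *unidentifiable as sources* — any effect attributed to one can be
  reattributed to another (with $n = 2$ this is exact: only
  $a_{12} + a_{21}$ is identifiable). Distinct non-monotone source
  shapes are what make attribution well-posed, and a long exploration
  of alternative designs (monotone gradients, balanced-fitness mixtures,
  mutualistic pairs, cyclic triads) confirmed that designs without this
  property scatter the selection across aliased explanations.
  `spectator_link = 0.3` adds a deliberately weak third edge
  ($a_{21}$), used to study how detection depends on interaction
  strength.
* `preset_neutral()` — the null system: equal growth rates, no
  interactions (the neutral-community null of ecology); expected
  composition constant, all observed structure is noise.
* `preset_two_taxon()` — the smallest non-trivial selection problem
  (4 subsets), used to verify the greedy search against exhaustive
  enumeration.
* `preset_cheese_like()` — a five-taxon surface-ripened-cheese-like
  community ($K = 2\cdot10^{10}$ CFU/g, 21 daily samples) for
  integration tests; a synthetic stand-in, not a reproduction of any
  measured dataset.

## What the validation does and does not show

The acceptance studies (see `scripts/acceptance.R`) verify, at the
problem sizes chosen for routine re-runs (10 datasets × 100 bootstraps
for recovery and null control, 20 datasets for the oracle comparison,
8 datasets × 150 bootstraps for the sensitivity study): analytic
correctness of the simulator; exactness of the scoring formulas;
classification completeness; near-equivalence of greedy and exhaustive
selection; exact signed-edge recovery on the oscillating system in
$\sim$80-90% of noise realizations; zero significant edges on neutral
data in $\sim$80-100% of realizations; bit-level reproducibility across
thread counts; and that across realizations the strong edge reaches
*stable* significance at a median of ~5 bootstraps while the weak edge
typically needs 10-20 or stays below the detection floor.

These results are conditional on the synthetic regime: informative,
non-monotone composition dynamics, correct model class, independent
multiplicative noise, and a known carrying capacity. Real microbiome
series violate several of these at once — compositions near fixation
carry almost no information (squared-composition residuals weight rare
taxa negligibly), noise is autocorrelated and depth-dependent, the gLV
form with a single community-wide capacity is an approximation, and $K$
must be supplied from outside knowledge. Passing tests therefore
demonstrate that the *procedure* is implemented correctly and behaves
as designed where inference is well-posed, not that any particular real
network it produces is correct. Two further caveats are inherent to the
method: the t-test with zeros included will flag any pair selected with
one sign in roughly $\ge$5% of rounds, so occasional weak spurious
edges survive in some noise realizations; and because the BIC is
evaluated on the full series, bootstrap rounds share observation noise
and their errors are not independent.

## Known limitations

* Interaction coefficients scale relative abundances; the model cannot
  express effects proportional to absolute abundance.
* One carrying capacity for the whole community; no per-taxon capacity,
  no immigration, no external perturbations (antibiotics, diet).
* Trajectory fitting from the first observed composition makes that one
  noisy sample influential in every bootstrap round.
* With few taxa, compositional closure limits source attribution (see
  above); at $n = 2$ direction is not identifiable at all.
* Bootstrap rounds are subsets of one series; they quantify selection
  instability, not biological replication.
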