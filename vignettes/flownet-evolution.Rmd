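---
title: "Flowing networks, systemic indexes, and greedy evolution: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flowing networks, systemic indexes, and greedy evolution: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcdnet)
```

## The model and its assumptions

`fcdnet` models an open natural system as a *flowing connected
directed network* (FCDN): a digraph on `N` core nodes (internal energy
forms) plus one input and one output node.  Entry `A[i, j]` of the
adjacency matrix is the share of node `i`'s outflow routed to `j`, so
input and core rows sum to one, the output row is zero, self-loops are
forbidden, nothing flows back into the input, every core node is
reachable from the input, and the output is reachable from every core
node.  Reachability of the output from everywhere plus row
normalization makes the core block strictly substochastic (spectral
radius below one): all energy eventually dissipates, which is the
mathematical expression of the system being open and dissipative.

The model is pure flow: nodes have no storage, capacities or
saturation, and all transformations are conservative.  One input and
one output suffice because several sources or sinks can always be
merged into one by adjusting shares.

Flow follows the synchronous discrete-time map

$$x(t+1) = x(t)\,A_{\mathrm{core}} + u(t),$$

with $u$ the input delivery vector.  We use this convention because it
makes the two central quantities exact: the steady state is
$x^* = u (I - A_{\mathrm{core}})^{-1}$ (computed by a linear solve,
and cross-checked in the tests against plain fixed-point iteration),
and after the input is cut, total energy decays asymptotically at the
rate $b = E_{\max}(A_{\mathrm{core}}) - 1$, the package's scarcity
tolerance index.

The input rate defaults to 1 energy unit per iteration everywhere.
Its magnitude is immaterial for the science: every index used for
selection is either invariant to it (AMI, EDiff, Finn, `b`) or exactly
linear in it (TST, ASC, flows), so selection decisions do not depend
on it.

Pulsed inputs are described by `input_schedule(rate, period, phase,
t_off)`: with period `p` the input fires on iterations
`t ≡ phase (mod p + 1)`, i.e. it *misses* `p` iterations between
firings.  An alternative reading (input active `p` of every `p + 1`
iterations) can be emulated with the `phase` argument and a
complementary schedule; we default to the literal "misses p" reading.
`t_off` cuts the input permanently, which is the scarcity scenario.

## Systemic indexes

All information-theoretic indexes use base-2 logarithms (units: bits),
with the convention $0 \log 0 = 0$.  Four choices deserve comment.

* **TST** sums core-to-core fluxes only, following the core-restricted
  double sum that defines it here.  The conventional whole-network
  total (including boundary flows) is available via
  `tst(..., include_boundary = TRUE)` for sensitivity checks; it is
  never used by the evolution machinery.
* **AMI/ASC marginals** are likewise taken over the core block only,
  consistent with TST.
* **EDiff** is defined as $S_{\mathrm{out}} - S_{\mathrm{in}}$ and
  maximized, so the orientor grows when the exported flow distribution
  carries more entropy than the imported one — the direction suggested
  by the "systems export entropy" motivation.  $S_{\mathrm{in}}$ is
  the entropy of the *throughflows* of the input-adjacent core nodes
  (not of the input arcs themselves); with extra inflows into those
  nodes the two differ, and we follow the throughflow definition.
* **Finn** uses the diagonal of the Leontief inverse:
  $\mathrm{Finn}_i = (\sum_j T_{ji}/\mathrm{TST}) (L_{ii}-1)/L_{ii}$,
  summed for the total.  Acyclic cores give exactly zero, and the
  total always lies in $[0, 1)$ — both property-tested.

Directed simple cycles are counted (never materialized) with a
Johnson-style blocked backtracking search in C++, anchored at each
cycle's smallest vertex.  Counts explode combinatorially
($\sum_k \binom{n}{k}(k-1)!$ on the complete digraph, over $10^6$ at
$n = 10$), so exhaustive counting is guarded at 12 nodes by default.

## The random-network generator

`random_fcdn(n_core, connectance, seed)` is the source of every
ensemble in the package, so its defaults *are* the study conditions:

* each ordered core pair carries an arc independently with probability
  `connectance` (default 0.20, the density regime typical of natural
  flow networks);
* each core node leaks directly to the output with the same
  probability — so dissipation points are sparse, as in real systems
  where only some energy forms dissipate directly;
* the input feeds `max(1, round(connectance * n_core))` random core
  nodes;
* weights are U(0,1) draws, row-normalized.

A repair pass then enforces validity with as few changes as possible:
dangling core nodes are wired to the output, unreachable nodes receive
an arc from a uniformly chosen already-reachable core node, nodes that
cannot reach the output get an output arc, and touched rows are
renormalized.  Repair is idempotent and consumes no randomness on
already-valid networks; the input row is never altered during
evolution-time repairs.

What the generator does *not* emulate: degree heterogeneity and
trophic structure of empirical food webs, weight correlations,
modularity, or any biology of specific energy forms.  Passing tests
therefore demonstrate the internal consistency of the model and the
behaviour of random dissipative flow networks under the stated
evolutionary algorithms — not quantitative claims about any empirical
ecosystem.

## Mutation, selection, and the two time-scales

Evolution is hill-climbing (structural dynamic modelling): per
iteration, exactly one mutation is proposed, and it is fixed if and
only if the goal function *strictly* increases.  Ties are rejected to
keep "maximization" meaningful and to prevent neutral drift from
confounding the comparison of goal functions.  One mutation per
iteration keeps iteration counts comparable across policies.

**Short time-scale** (ecological change): one existing core-outgoing
arc (core–core or core–output, never an input arc) has its weight
multiplied by a U(1 − v, 1 + v) factor, `v = 0.10` by default, and the
row is renormalized.  The arc set is exactly preserved over the whole
run — property-tested.

**Large time-scale** (evolutionary change): with probability 0.5 the
move is structural (add or delete a core–core arc), otherwise a
reweight, which is a fresh U(0,1) draw half the time and a ±10% local
tweak otherwise.  New-arc weights are U(0,1).  Deletions that orphan a
node are allowed and followed by the repair pass; if repair would
simply re-add the deleted arc the mutation retries a different target
(three attempts, then the iteration proposes nothing).

*Connectance anchoring.*  The natural first reading of "equal
probability of losing and creating links" is symmetric proposal
probabilities.  Under selection, however, symmetric proposals do not
yield constant connectance: goals that reward recirculation (TST above
all) accept adds far more often than deletes, and measured density
drifted upward by several percentage points over 500 iterations.
Since the model specification calls for connectance held roughly
constant in time, structural moves are anchored instead: below the
run's reference density (the starting network's) a structural move is
an add, above it a delete, and at the reference the drawn type stands.
Creation and loss thus remain equally probable *around the reference*,
and realized connectance stays within a fraction of a percentage point
of it regardless of the goal.  The drift bound (±5 points over 500
iterations at N = 30) is enforced in the acceptance tests.

**Greedy goals.**  `ABS_FLOW` sums steady-state throughflows over the
greedy set; `PROP_FLOW` divides by total core throughflow;
`ABS_FINN`/`PROP_FINN` do the same with per-node Finn cycling.  The
proportional denominators use network *totals* rather than
"rest-of-network" remainders: $x/T$ and $x/(T-x)$ are monotone
transforms of each other, so every selection decision is identical,
and totals are numerically stabler.  Greedy node sets are uniform
samples of `round(fraction * n_core)` nodes (round half up, floor of
one node), drawn independently per replicate and experimental cell.

## Experiment design

`run_experiment()` mirrors the two-phase design: (1) *natural
history* — ensembles (default 100 replicates of 30/50/70/100 core
nodes) evolve 500 large time-scale iterations under each systemic
goal; (2) *branching* — every evolved network starts one control
branch (same systemic goal) and one greedy branch per (scenario,
fraction) cell, each 5000 short time-scale iterations.  Both endpoints
are scored on the decay rate and on the *systemic* goal — the
performance comparison asks whether the greedy branch still serves the
orientor the system had been evolving toward, not whether it serves
the greedy objective.  Differences are normalized as
$(c - g)/(|c| + |g|)$, lying in $(-1, 1)$, negative when greedy
surpasses control; if both values are zero the difference is zero.
Because the control branch does not depend on the greedy cell, it is
computed once per replicate and shared across cells — semantics are
unchanged, work drops several-fold.

Randomness is organized as one master seed per experiment; child seeds
for ensembles, replicates and branches are derived by seeding R's
generator and drawing integers below $2^{31}-1$, making every
replicate individually reproducible and the whole grid deterministic
given the master seed (bit-for-bit, tested).

Per-iteration decay-rate recording is available in `evolve()`
(`record_b = TRUE`) but costs one eigendecomposition per iteration;
the experiment driver records `b` at branch endpoints only, which is
all the comparison statistics need.  A trace's acceptance rate is
returned so plateaus of the 5000-iteration branches can be inspected.

## Numerical choices

* Steady states by LAPACK linear solve of
  $(I - A_{\mathrm{core}})^\top x = u$; the tests verify agreement
  with fixed-point iteration to $10^{-6}$, sizing the oracle's
  iteration budget from the contraction rate so slowly mixing networks
  (spectral radius within $10^{-3}$ of one, common after TST
  evolution) are iterated long enough for the comparison to be
  meaningful.
* The decay rate takes the eigenvalue of largest modulus; among
  modulus ties (imprimitive cores, e.g. damped 2-cycles with spectrum
  $\pm r$) the one with the largest real part is chosen, and its
  imaginary part is asserted below $10^{-9}$ — by Perron–Frobenius the
  spectral radius of a nonnegative matrix is attained at a real
  nonnegative eigenvalue.
* Row sums are validated to $10^{-9}$; renormalization divides a row
  by its sum, so weights stay in $[0, 1]$ exactly.
* Indexes on networks with zero core throughflow (possible only for
  degenerate star topologies) raise an "undefined index" error rather
  than returning 0/0; during evolution such candidate evaluations
  count as rejections.
* `repair_fcdn()` errors on negative weights instead of clipping.

## Problem sizes used in the shipped tests

The full published grid (four sizes × four goals × four scenarios ×
three fractions × 100 replicates) is hours of compute; the package's
own test battery uses the smallest published ensemble size.  The
acceptance tests run the headline cell — N = 30, TST orientor,
absolute-flow greedy scenario, 50% greedy fraction, 100 replicates at
the published iteration counts (500 + 5000 + 5000) — plus a 20-replicate
grid over both flow scenarios and all three fractions for the
qualitative orderings (absolute > proportional; surpass percentage
non-decreasing in greedy fraction).  Property-style invariants use
1000 random networks (sizes 2–100) for conservation/dissipativity
checks and 100 evolution runs for the drift and monotonicity
contracts.  `scripts/acceptance.R` reruns the headline cell from
scratch at 100 replicates.

## Known limitations

* The original study's mutation-type probabilities, new-weight
  distribution and exact pulse convention are not published; the
  defaults here are declared, configurable choices, so exact
  replication of those ensembles is not guaranteed — reduced-scale
  comparisons land near the published one-third surpass mark, with
  seed-to-seed spread of a few percentage points at 100 replicates.
* Hill climbing with single mutations cannot model populations,
  crossover, annealing or multi-objective selection.
* Cycle counting is exhaustive and guarded at 12 nodes; counts for
  larger dense graphs require the closed form (complete digraphs) or
  sampling methods not implemented here.
* The resilience reading of the spectral gap ($R = -b$) is computable
  trivially from `decay_rate()` but is deliberately not an analysis
  axis of the experiment driver.
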