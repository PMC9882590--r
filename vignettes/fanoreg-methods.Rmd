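---
title: "Inferring autoregulation from the Fano factor: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring autoregulation from the Fano factor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fanoreg)
```

## The model

A single gene's copy number `X` is modelled as a continuous-time birth-death
chain on the non-negative integers: the transition `n−1 → n` (synthesis)
occurs at rate `f_n`, indexed by the *target* state, and `n → n−1`
(degradation) at total rate `n · g_n`, with `g_n` the per-molecule rate.
The ratio `h_n = f_n / g_n` is the **relative growth rate**. Autoregulation
is a statement about `h`: constant `h` means none (and the stationary law is
Poisson(`h`)), a rise `h_n > h_{n−1}` anywhere means positive
autoregulation, a fall anywhere negative; both can occur in one schedule at
different expression levels.

At stationarity `P_n = P_{n−1} · h_n / n`. Two results connect `h` to the
Fano factor `VMR = σ²(X) / E(X)`:

1. **Autonomous gene.** If `h` is non-decreasing for all `n`, then
   `VMR ≥ 1`, with equality iff `h` is constant; symmetrically for
   non-increasing `h`. Contrapositively, an observed `VMR > 1` certifies a
   rise in `h` somewhere (positive autoregulation), `VMR < 1` a fall.
   This needs the expression to be *autonomous*: the count process itself
   Markovian, not driven by a hidden promoter state.
2. **Gene in a network.** For a gene embedded in a one-step multi-gene
   chain, not contained in any directed cycle, with degradation rate
   unregulated (constant in the other genes), *no autoregulation implies
   `VMR ≥ 1`*: conditionally on its (ancestral) environment the gene is
   Poisson, and environment switching only adds variance. Hence `VMR < 1`
   implies autoregulation without any autonomy assumption — the more
   reliable direction.

Both directions are informative only one way: a VMR compatible with 1
never establishes the absence of autoregulation, and the workflow has no
such verdict.

### Worked models and the limits of the theory

Four families are built in, each an exact target for the solvers and
simulators and together a map of the theory's boundary:

* `poisson_gene_model(lambda)` — the null. `linear_feedback_model(k, b, c)`
  — `f_n = k + b(n−1)`, `g_n = c`, valid for `c > 0`, `c − b > 0`, with
  closed form `VMR = 1 + b/(c−b)`. For `b < 0` the synthesis schedule is
  clipped at zero (with a warning); the closed form is exact for `b ≥ 0`
  and for `b < 0` whenever `k/|b|` is an integer (the schedule then reaches
  zero exactly and the law is binomial-type). At non-integer `k/|b|` the
  clip perturbs the VMR at the percent level — the package's property tests
  choose grids accordingly.
* `example2_model()` — two genes, each synthesised *and degraded* only
  while the other sits at count 2, started at (2, 2). The reachable states
  are two arms `{(k,2)} ∪ {(2,m)}` with stationary mass `∝ 2/k!` per arm
  state, giving marginal `VMR = 2e/(4e−1) ≈ 0.5506` for both genes with no
  `h`-schedule autoregulation anywhere: *regulated degradation* violates
  result 2's assumption, which is why the assumption is surfaced as an
  explicit caveat on every negative call.
* `environment_driven_model(q, synth, deg)` — a gene whose synthesis
  follows a finite upstream environment chain; the setting of result 2,
  used for the `VMR ≥ 1` property suite.
* `multistep_cycle_model(k_stages, deg_rate)` — the promoter cycle
  `G1 → … → Gk → G1 + M`, `M → ∅`. The final transition changes stage and
  mRNA *simultaneously* (multistep). With `k = 100` stages at rate 100 the
  cycle time is nearly deterministic (Erlang with unit mean and variance
  `1/k`), and at degradation rate 0.01 the count concentrates near 100 with
  `VMR ≈ 0.5` despite zero autoregulation. The stationary solver refuses
  this model by construction — the refusal documents that result 2 lives
  strictly inside the one-step class. The degradation specification
  "probability 0.01 per unit time" is implemented as a continuous rate
  0.01; the alternative reading `−ln(0.99) ≈ 0.01005` differs by 0.5%,
  far below simulation resolution.

## The significance test

For `n` i.i.d. Poisson samples the sample VMR (unbiased variance over
mean) is asymptotically `Γ[shape = (n−1)/2, scale = 2/(n−1)]` — mean
exactly 1 for every `n`. The test takes the equal-tail `α/2` and `1−α/2`
quantiles; equal tails reproduce the ~2.5%/2.5% error split of the
calibration tables this test is known by, and the interval always brackets
1. Defaults: `α = 0.05`, per-gene with no multiplicity correction (the
workflow's reference behaviour); Benjamini–Hochberg adjustment is available
behind a flag and only ever makes calls more conservative. The Gamma
approximation is asymptotic: below `n = 30` the package warns but does not
refuse. Degenerate samples are handled explicitly: zero variance with
positive mean is a legitimate `below` (VMR 0, prominently logged since it
often signals pipeline problems); zero mean makes the VMR undefined
(0/0) and is flagged, never silently reported as 0.

A mixture identity supports robustness to cell-type heterogeneity: by the
law of total variance, any mixture of components with `σ² ≥ μ` keeps
`VMR ≥ 1`, so a population VMR below 1 implies a sub-Poissonian component.
`vmr_decomposition()` splits a labelled sample's VMR into intrinsic
(within-environment) and extrinsic (between-environment) parts using
population variances throughout, so the parts sum exactly to the pooled
VMR; the conditional-on-environment intrinsic part approaches 1 only in
the slow-switching limit, which the tests check against exact solver
conditionals rather than against 1.

## The inference workflow

Per measured gene, with the GRN's structural report in hand:

1. in network, **not in a directed cycle**, VMR test `below` →
   `negative_autoregulation` (caveats: `one_step_assumed`,
   `degradation_constant_assumed`);
2. else **no ancestor** in the network and `above` →
   `positive_autoregulation` (caveat `autonomy_assumed` — unverifiable
   from snapshot data, hence the weaker branch);
3. else `undetermined`.

Branch 1 is evaluated first: when a root gene shows `VMR < 1` both results
could apply, and the network-aware one wins because it does not assume
autonomy. Genes absent from the network are undetermined
(`not_in_network`) — with no structural information, neither eligibility
pattern can be established. Self-loops in the input GRN are reported and
treated as declared autoregulation rather than re-inferred. Non-integer
counts are an error by default (the theory is about molecule counts);
`allow_noninteger = TRUE` rounds with a warning for users with carefully
converted data.

Cycle membership is "strongly connected component of size ≥ 2 or
self-loop"; ancestors are directed-path predecessors, the gene itself
included only via a cycle. Both are served by igraph and cross-checked in
the tests against brute-force adjacency-power oracles.

## Numerical choices

* **Single-gene solver.** The recurrence is evaluated in log space.
  With `max_state = "auto"` the support grows until the unnormalised term
  stays below `tail_tol ×` (running normaliser) for 10 consecutive states
  (hard cap 10⁶); the excluded mass is certified by a geometric bound from
  the last term ratio. A model whose terms are still growing at the cap is
  declared non-normalizable — a practical surrogate for the finiteness
  assumptions of the theory (bounded `h` suffices), not their exact
  boundary.
* **Coupled solver.** States reachable from `initial_state` inside the
  truncation box are enumerated; the stationary distribution is solved on
  the closed communicating class (sparse direct solve with one row replaced
  by normalisation; power iteration on the uniformised chain as fallback).
  Multiple closed classes raise an error asking for an initial state. The
  reported tail certificate is the stationary probability flux blocked at
  the box boundary, scaled by the slowest exit rate; doubling the box moves
  no probability beyond `tail_tol` in the tests.
* **Simulation.** Exact SSA in compiled code over a tabulated lattice
  (plus a dedicated O(1)-per-event simulator for the promoter cycle, whose
  acceptance-scale runs take ~10⁸ events). Snapshots are independent
  replicate chains — never a thinned trajectory — because the test assumes
  i.i.d. samples. Each cell's random stream is derived from
  (seed, cell counter), so enlarging `n_cells` extends rather than
  reshuffles a dataset. Default horizon `100/min(g)` is a deliberately
  generous mixing heuristic; the benchmark fixture uses `t_end = 20` with
  unit-scale degradation rates (relaxation times ≤ 1, so ≥ 20 relaxation
  times) to keep the 50-seed evaluation affordable.
* **Tolerances.** Rate-schedule equality uses relative tolerance 1e−9
  (float configs); exact identities are tested at 1e−9; stochastic checks
  use Monte-Carlo standard errors at the stated sample sizes.

## The synthetic benchmark

`benchmark_fixture()` plants ten genes: two in-network acyclic genes with
strong negative feedback (`b = −3`, `c = 1`, `k = 8`: true VMR 0.25), two
root genes with positive feedback (`b = 0.5`, `c = 1`, `k = 1`: true VMR
2), six Poisson nulls (`λ = 10`), in a small acyclic GRN. At
`n_cells = 10000` and `α = 0.05` the null interval is ≈ (0.973, 1.028), so
the planted effects are far outside it while each null gene stays inside
with probability ≈ 0.95. What passing shows: the pipeline recovers strong,
well-separated effects under its own model assumptions. What it does not
show: robustness to measurement noise, normalisation artefacts, dependent
cells, non-stationarity, or mis-specified networks — real single-cell data
violate several of these (the caveat flags on every call exist precisely
because the assumptions travel with the verdict).

## Known limitations

* The positive branch leans on autonomy; transcriptional bursting alone
  can push VMR far above 1, so positive calls are weaker evidence than
  negative ones.
* `VMR = 1` is observationally compatible with both "no autoregulation"
  and canceling positive + negative regulation; the workflow therefore
  never reports absence.
* The below-1 branch inherits three assumptions (one-step dynamics,
  unregulated degradation, no feedback loop); the packaged counterexamples
  show each is load-bearing.
* The Gamma null is asymptotic and per-gene; heavy multiple testing across
  thousands of genes should enable the BH flag at the cost of power.
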