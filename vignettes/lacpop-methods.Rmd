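---
title: "Simulating heterogeneous cell populations carrying an artificial lac operon switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating heterogeneous cell populations carrying an artificial lac operon switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lacpop)
```

## The biological system and the model

`lacpop` simulates populations of growing, dividing bacteria that carry an
artificial lac operon circuit: a single functional operator, constitutive
LacI expression, and the LacY permease whose facilitated import of a
gratuitous, non-metabolizable inducer (TMG) de-represses its own expression.
This positive feedback makes the single cell a bistable switch over a window
of extracellular inducer concentrations; the package's purpose is to
propagate that single-cell switch through every source of population-level
stochasticity — random reaction events, random DNA-duplication and division
times, and random partitioning of molecules and volume between daughters —
and to compare the resulting population statistics with cheaper lumped
descriptions.

The reaction network has 10 species (lacI mRNA `MR`, LacI monomer `R` and
dimer `R2`, free and repressor-bound operator `O`/`R2O`, intracellular
inducer `I`, the sequestered complex `I2R2`, lacY mRNA `MY`, permease `Y`
and the loaded carrier `YIex`) connected by 25 elementary reactions:
dimerisation, repression, two inducer-mediated derepression routes
(stripping the repressor off the operator, and sequestering free repressor),
transcription from the free operator plus a small leak from the repressed
operator, translation, carrier-mediated and passive inducer transport, and
first-order decay of all unstable species (`reaction_table()`).
Two conventions matter and are fixed package-wide:

* The tabulated units of the two reverse-derepression constants force the
  nM⁻¹min⁻¹ constant onto the bimolecular reverse step
  (`I2R2 + O -> 2I + R2O`) and the min⁻¹ constant onto the unimolecular one
  (`I2R2 -> 2I + R2`). This assignment uniquely closes the repression cycle
  thermodynamically: `(k_r/k_-r)(k_dr1/k_-dr2) = k_dr2/k_-dr1 = 2.5e-8 nM⁻²`
  exactly at the default constants (tested).
* TMG is not metabolized, so decay of `I2R2` returns two inducer molecules
  to the cytoplasm, while decay of `YIex` returns its inducer to the
  (unmodelled, constant) extracellular reservoir. The extracellular level
  `I_ex` is a fixed parameter — the bifurcation parameter of the switch —
  never a dynamic species.

Stochastic propensities follow standard volume-scaled mass action with
`Ω = molecules_per_nM(V)`: zeroth order `kΩ`, identical-pair
`(k/Ω)X(X−1)`, trimolecular `2I + B` as `(k/Ω²)I(I−1)X_B`, so that
`a_j/Ω` converges to the deterministic rate as `Ω → ∞` at fixed
concentrations (a property test sweeps all 25 reactions).

## Cell physiology: growth, duplication, division, partitioning

Cells are rods of fixed radius `R0` whose volume grows exponentially,
`V(t) = V_birth e^{g t}`, with `g = 0.0231` min⁻¹ (doubling time
`ln 2/g ≈ 30` min). The membrane area follows the cylinder-plus-caps
geometry, `A(V) = (2/R0)(V − (4/3)πR0³) + 4πR0²`, which enters the passive
transport terms through `A/V`.

DNA duplication and division are stochastic events with volume-dependent
hazards. The detailed functional forms behind the tabulated sharpness
exponents are not uniquely determined by their description, so the package
adopts the power-law family

> `a(V) = g · n · (V/V_crit)^n`,

chosen because (i) it consumes exactly the tabulated parameters
(`n_s = n_d = 25`, critical volumes), (ii) event volumes concentrate near
`V_crit` with a few-percent CV at `n = 25`, (iii) under exponential growth
the cumulative hazard `Λ(t) = (V0/V_crit)^n (e^{ngt} − 1)` inverts in closed
form, giving exact event-time sampling (`sample_event_time()`, verified
against a brute-force thinning simulation), and (iv) it reproduces the
30-min mean interdivision time. Division is gated on completed duplication,
so no daughter is ever born without a chromosome. The tabulated critical
volumes are read in 1e-16 L units (`V_s_crit = 1.0` fL,
`V_d_crit = 1.5` fL), which keeps cells in the 0.75–1.5 fL *E. coli* range
of the tabulated geometry and makes the closed-form cycle-average operator
concentration come out at 2.40 nM (below).

At division the volume splits by a symmetric `Beta(q, q)` fraction
(`q = 80`, daughter-size CV ≈ 3.9%). In the stochastic engine every
non-chromosomal species partitions binomially with success probability equal
to the volume fraction — this, not 1/2, is what makes expected daughter
concentrations equal the mother's — and the two operator units (each
carrying its own repression state) are split exactly one per daughter by
hypergeometric assignment. In the deterministic (hybrid) engine partitioning
is a Dirac delta in concentration space; operator concentrations are
recomputed from the integer bookkeeping (1 copy per daughter) over the
daughter volume, preserving the mother's bound fraction, which keeps every
concentration exactly continuous across a symmetric division. Where the
division is forced to be asymmetric, the daughters inherit equal
concentrations but different operator concentrations — the lever behind the
forced-transition experiments below.

## The two population engines and the cell chain

**Stochastic engine** (`simulate_cell_stochastic()`, `simulate_population()`
with `mode = "stochastic"`): an exact SSA over the 25 reactions in which
the volume-dependent propensity prefactors are held piecewise-constant and
re-evaluated on an absolute 0.5-min grid (`refresh_dt`), while the
duplication/division hazards enter the same total hazard. The volume moves
by `g·δ ≈ 1%` between refreshes, far below the kinetic noise; a refresh
convergence test halves `δ` and checks summary statistics within Monte
Carlo error. The inner loop is a C++ kernel with incremental propensity
updates and a xoshiro256++ substream seeded per cell from R's RNG, so runs
are bit-reproducible under `set.seed()`; division-level draws (beta,
binomial, operator assignment) use R's own RNG.

**Hybrid engine** (`simulate_cell_deterministic()`): between stochastic
duplication/division events the 10 mass-action ODEs are integrated with a
dilution term `−g[X]` on every species and the geometric `A/V(t)`
(a piecewise-deterministic Markov process). The fast carrier cycle
(`k_ft = 6·10⁴` min⁻¹) makes the system stiff, so integration uses
`deSolve::lsoda` on a compiled right-hand side (relative tolerance 1e-8,
absolute 1e-10 nM; negative round-off is clipped at zero and counted).
Event times are drawn with the exact closed-form sampler, so integration
segments have known endpoints and no event localisation is needed. At
duplication the free-operator concentration jumps by `1/Ω(V)` — the new
operator unit cannot have repressor pre-bound — reproducing the
promoter-concentration sawtooth: `[O]_T` decays as `1/V` during growth,
doubles at duplication, and is continuous across a symmetric division.
Dilution is applied to the operator species too (their amounts are restored
by the discrete jumps); whether the reference model did the same per cell is
not recoverable from its description, but any other choice would break the
`1/V` decay of a conserved amount.

**Population bookkeeping** (`simulate_population()`): cells evolve
independently between divisions, so each cell is simulated to its own
division and divisions are processed chronologically; each replaces the
mother by two daughters. Once the census reaches `N_cellsmax` the
constant-number technique removes one uniformly chosen cell after each
division, holding the census exactly at the cap without biasing
distribution estimates (the removal-per-division variant was chosen over
periodic down-sampling for simplicity; both are unbiased in expectation).
`run_batches()` pools independent batches.

**Cell chain** (`simulate_chain()`): keeps exactly one daughter per
division by a fair Bernoulli trial and samples periodically in time. For
intensive observables (concentrations) the stationary chain PDF
approximates the population NDF, because mothers and daughters share the
same concentrations on average. The default burn-in is 500 min (~17
generations); sensitivity to the burn-in is limited to the initial
transient and is exercised in the tests.

## The structured continuum model and its two lumped characteristics

The continuum model lumps the population into one expanding biotic phase:
10 ODEs for average concentrations with dilution `−g[X]` on every species
*except* the operator-carrying ones, whose total `⟨[O]_T⟩` is a fixed cell
characteristic maintained by ongoing DNA duplication, and a fixed
surface-to-volume ratio `⟨A/V⟩`. Both characteristics are either measured
from a geometry-only population run (`geometry_only_population()`) or
estimated in closed form over one division cycle of a cell growing from
`V_d_crit/2` to `V_d_crit`:

* `estimate_A_over_V()`: `⟨A/V⟩ = 2/R0 + (4/3)πR0² / (2 ln2 · V_d_crit/2)`
  = **5.645 μm⁻¹** at the default geometry (an independent quadrature
  oracle agrees to ≥ 10 digits). The reference analysis prints 5.69 μm⁻¹
  for this quantity; the ~0.8% difference is within the reconstruction
  uncertainty of the area formula, and both values are well inside the
  few-percent band of the simulated average.
* `estimate_O_T()`: one operator copy until `V_s_crit`, two after, giving
  `⟨[O]_T⟩ = 1/(V_s_crit ln 2)` copies/fL — independent of `V_d_crit` —
  = **2.396 nM ≈ 2.40 nM**.

The corresponding *population* averages weight young cells more
(exponential age distribution `2g e^{−ga}`); in that stationary-age limit
they have closed forms too (`predicted_population_averages()`). Two caveats
both stem from cell-cycle phase: the age-distribution argument presumes a
desynchronized population, yet the per-cycle timing noise at the default
sharpness values is only a few minutes, so a population founded by
synchronized newborns decorrelates its phases slowly (random-walk spreading
over tens of generations). Pooling many independent batches (each with an
independent final phase) and, optionally, snapshots spread over one cycle
averages the residual phase ripple out. In the fully sharp limit
(`n, q → ∞`) the population *never* desynchronizes, and the per-snapshot
population means averaged uniformly over one cycle reproduce the
*chain* cycle averages instead — that identity is used as a test oracle.
With the default stochastic hazards the simulated averages land ~1–2%
above the stationary-age limit (≈ 5.69–5.70 μm⁻¹ and ≈ 2.42–2.44 nM).

Steady states of the continuum model are found by damped Newton iteration
in the 9-dimensional reduced space with `[O]` eliminated through the
conserved operator total (the full 10-dim Jacobian is structurally
singular along that direction), started from both attractors (forward
integration), from linear and log-space interpolants between them, and from
the neighbouring grid point during bifurcation sweeps; roots are
deduplicated at 1e-5 relative tolerance and stability is labelled by the
leading eigenvalue of the finite-difference reduced Jacobian. At the
default characteristics the switch is bistable on roughly 22–28 μM
extracellular TMG: three states at 24 μM (off ≈ 10.7, saddle ≈ 84.5,
on ≈ 221.6 nM total LacY), one repressed state at 0 μM and one induced
state at 60 μM. Rescaling the repressor-operator association constant with
the equilibrium constant held fixed leaves the diagram quantitatively
unchanged (tested), as it must.

## Forced-transition interventions

With deterministic reactions no spontaneous transition between the two
attractors occurs on multi-thousand-minute horizons (tested). Transitions
can be *forced* through the physiological noise channels:

* `intervention_asymmetric_division(at, ratio = 0.15)` makes one division
  grossly asymmetric and follows the smaller daughter, which concentrates
  the operator (DNA splits one copy per daughter regardless of volume) and
  can ignite the positive feedback. In this reconstruction the off→on
  outcome at ratio 0.15 is knife-edge — the daughter-volume threshold sits
  at ≈ 0.21–0.22 fL, so roughly half of the realizations switch (all do at
  ratio ≤ 0.13), while *unforced* chains never switch. The acceptance test
  therefore asserts the contrast (interventions enable a transition that
  never occurs spontaneously) over several independent realizations rather
  than one particular trajectory.
* `intervention_delayed_division(at, delay = 50)` postpones one division to
  50 min after the preceding duplication; the prolonged growth dilutes the
  operator, weakens LacY production, and robustly drops the cell to the
  off state.

## Analysis layer

`ndf()` histograms any observable (default total LacY, `[Y]_T = [Y] +
[YIex]`) as counts or unit-area density (60 equal-width bins spanning
`[0, 1.05·max]` by default; the raw samples ride along so binning never
hides information). `split_modes()` locates the deepest internal minimum of
a kernel-smoothed density (Silverman bandwidth) and accepts it only if the
valley is below 50% of the lower flanking peak — the threshold rejects
sampling dips — then reports per-mode means, SDs and weights from the raw
samples. `tail_and_shape_stats()` quantifies heavy tails (skewness, excess
kurtosis, mass above mean + 3 SD). `distribution_distance()` is the
two-sample Kolmogorov–Smirnov statistic evaluated on the pooled support, so
heavy ties at zero LacY are handled exactly. `division_time_histogram()`
summarises interdivision intervals.

## Problem sizes, tolerances and what the tests show

The package's test suite exercises every engine at deliberately moderate
problem sizes chosen by compute cost of the stochastic kernel (the on-state
of the switch turns over ~1e6 reaction events per cell-minute, dominated by
inducer transport). The main choices, stated here as the package's own:

* Geometry-only population averages: 20 batches × 500 cells to 600 min
  (~20 generations), compared with the printed population averages within
  a 5% band — the documented hazard-form uncertainty (the sharp-threshold
  analytic limit itself sits ~1.5–3% below the simulated values) — and
  with the package's own closed-form age-distribution oracle under
  sharpened hazards at sub-percent tolerance.
* Interdivision times: ≥ 2000 reaction-free division cycles, mean within
  2 standard errors of `ln 2/g`.
* Population-vs-continuum: deterministic-reaction populations (census cap
  in the several-hundreds) at a few inducer levels inside the bistable
  window; mode averages must lie within one subpopulation SD of the
  continuum branches. Switching transients (0 → 60 μM) are compared to the
  continuum trajectory by RMS deviation normalized to the plateau within
  10% — the RMS metric is the package's operationalization of a tolerance
  band: a pointwise metric is dominated by trivial timing offsets on the
  near-vertical rise.
* Chain-vs-population distribution agreement (stochastic mode, 24 μM):
  the Kolmogorov–Smirnov distance between the stationary chain PDF
  (7,000 min, 10-min sampling, 1,000-min burn-in) and the population NDF
  pooled from two 26-cell constant-number batches with snapshots every
  10 min across 250–350 min must stay below 0.1. The slow statistical
  variable is the on-mode weight (integrated autocorrelation time of
  `[Y]_T` about 30 min along a lineage), so snapshots of already-simulated
  cells are pooled densely — free variance reduction that brings the KS
  sampling floor to roughly half the threshold. The full-scale comparison
  (chain 1e5 min, 20 × 500-cell batches — preset `fig8a`) is available for
  definitive runs outside the test suite's time budget.
* The synthetic-data side of every distribution test (Gaussian mixtures,
  exponential tails) uses closed-form moments as oracles.

What passing does *not* show about real bacteria: the generator emulates
exponential single-cell growth with a constant rate, a single chromosome
duplication per cycle, no cell-cell coupling through the medium (the
extracellular inducer is an infinite reservoir), no metabolic burden of
LacY expression, and an artificial operon without DNA looping, multiple
operators or catabolite repression. Distributions measured on real
populations fold in all of those.

## Numerical choices collected

* SSA: propensity prefactors refreshed on an absolute 0.5-min grid
  (configurable); incremental propensity updates with the running total
  rebuilt at every refresh; event selection by magnitude-sorted linear
  scan, with the order re-sorted at refreshes.
* Hybrid/continuum integration: `lsoda`, rtol 1e-8 / atol 1e-10 (1e-10 /
  1e-12 for continuum equilibration), compiled right-hand side; negative
  round-off clipped at zero with a package-level counter
  (`integration_clip_count()`).
* Newton steady-state polishing: FD Jacobian with relative step 1e-6,
  damped line search, acceptance residual 1e-7 relative, root
  deduplication 1e-5 relative; stability from the reduced 9×9 Jacobian.
* Event sampling: exact inverse-CDF for power-law hazards; `u` drawn in
  (0, 1), waiting time via `log1p` for numerical stability.
* Reproducibility: one R-session RNG stream; the population scheduler
  processes divisions in deterministic chronological order, so a run is a
  pure function of the seed.
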