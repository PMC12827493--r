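---
title: "Simulating the evolution of root architecture under below-ground competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the evolution of root architecture under below-ground competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rootarch` couples a functional–structural root model — plants with explicit
3-D, segment-based root systems foraging for water in a voxelized soil — with
an evolutionary algorithm that selects root-architecture genotypes under
intraspecific competition of varying intensity, and with factorial
competition experiments that quantify the competitive effect and competitive
response of the evolved "species". This vignette is the package's account of
the model, its assumptions, the open design choices we had to make, and what
the reduced problem sizes used in checks do and do not demonstrate.

## The soil world

The soil is a lattice of `nx × ny × nz` cubic voxels (default 10 × 10 × 70 of
20 mm side, a 20 × 20 × 140 cm volume). Each voxel holds up to
`voxel_side³ × whc` mm³ of water — 800 mm³ with the defaults. Four daily
processes act on the grid:

* **Recharge** refills every voxel to capacity every `recharge_interval`
  days (default: daily).
* **Evaporation** removes a fraction `evaporation_rate` (default 0.5) of the
  top layer's water.
* **Diffusion** moves a fraction `diffuse_per_day` (default 0.1) of each
  voxel's water, 1/6 of it to each face neighbour. Horizontal borders wrap
  around (a toroidal world, which removes edge artefacts); the top and
  bottom faces are closed.
* **Uptake** serves the plants' per-segment demands, rationing each voxel's
  water proportionally to demand whenever demand exceeds supply.

Numerical choices: diffusion uses a synchronous (Jacobi-style) update — all
fluxes are computed from the pre-update state and then applied — because it
is the only convention whose result is independent of voxel enumeration
order; flux that would cross a closed top/bottom face stays in its source
voxel, the simplest exactly-conservative convention. Voxels cover half-open
intervals `[k·side, (k+1)·side)`, z increases downward from the surface, and
the within-day order is recharge → evaporation → diffusion → uptake →
growth. The model states the order of resource renewal, uptake and growth,
but not where evaporation and diffusion fall within it; our order is an
assumption and `run_simulation(step_order = )` exposes it so its sensitivity
can be tested. With daily recharge the vertical water structure is set by
same-day evaporation and uptake alone; `recharge_interval` allows drier
regimes without code changes.

## Plants

A plant is two biomass compartments: a structureless shoot (g) and a root
system of branches, each a chain of 2 mm segments. It starts as a single
downward segment with no shoot. Each day:

1. Every segment demands `water_uptake_per_root_length × segment_length`
   (20 mm³) from the voxel containing its midpoint; the realized uptake
   depends on the voxel's water and on all other segments — of any plant —
   demanding from it. This shared rationing is the only interaction between
   plants.
2. Delivered water is the sum of realized uptakes, each discounted by
   `(1 − water_trans_efficiency)^L` where `L` is the segment's path length
   (mm) to the base. The constant (default 0.002 per mm) is defined as a
   transport efficiency; applying it as a per-mm multiplicative discount
   along the path is our functional-form assumption — it prices deep, long
   roots realistically and setting it to 0 recovers a plain sum.
3. Delivered water converts to allocable biomass at `water_to_biomass`
   (10⁻⁵ g mm⁻³). A fraction `plogis(kshoot1 + kshoot2 × allocable_mg)` goes
   to the shoot, the rest to root growth. The allocation function's exact
   form is inherited from prior work we did not have access to; a logistic
   of an affine function is our choice, motivated by the evolvable ranges of
   `kshoot1` ([−5, 5]) and `kshoot2` ([−0.1, 0.03]) straddling zero, which
   suits a logistic argument; expressing the day's allocable biomass in
   milligrams makes `kshoot2`'s range numerically meaningful. **This is the
   package's largest modelling assumption.**
4. Root growth: every branch tip can elongate up to `max_elongation_rate`
   (5 mm) per day, at a biomass cost per mm set by a cylinder of radius
   `root_radius` (default 0.5 mm — the tissue-density constant is per volume
   but no radius is specified anywhere, so the radius is a config constant;
   only linearity of cost in length matters to the dynamics). When the
   summed demand exceeds the day's root budget, the budget is shared among
   tips proportionally to `orderweightings^order` — a power form, chosen
   over a per-order lookup for parsimony; values above 1 favour high-order
   laterals, below 1 the main axes. Shares are capped at each tip's
   potential with no redistribution and no sequential priority, so the
   outcome is independent of branch enumeration order. Funded length
   accumulates per tip; whole segments are appended and the remainder (< one
   segment) carries over — so the biomass ledger closes exactly up to that
   bounded carryover.
5. New segments point along the previous heading plus a downward pull of
   strength `gravitrop`, renormalized — the simplest operator with the
   documented monotone effect. At each new junction a lateral may start:
   with probability `basezonep` within `basezonelength` mm of the branch
   origin, and with probability `branch_probability` (a constant, default 1)
   beyond it — the evolvable parameter is defined only inside the base zone.
   A lateral's heading is the parent heading tilted by `branchang` and
   rotated about the parent axis by the cumulative phase
   `laterals_emitted × rotang`. Laterals never exceed order `maxorder`.

Branching draws are the only randomness in growth. Each plant owns a private
RNG stream seeded from (run seed, plant id), so plants are bit-reproducible
independently of scheduling order, and a simulation is a pure function of
(genotypes, seed, configuration).

## Evolution and species

Fitness is the target plant's final shoot biomass after 150 days, grown with
`k` clonal neighbours (scenario S_k, k = 0…4; neighbours 50 mm from the
target at fixed compass points — deterministic placement removes positional
variance from between-scenario comparisons). Each generation the N = 15
genotypes are duplicated, every copy mutated in all parameters, all 2N
evaluated (parents re-evaluated too — fitness is noisy and the procedure is
followed literally, accepting that recorded maxima can fluctuate), and the
top N kept, ties resolved oldest-first. Mutation is Gaussian per parameter,
clipped at the hard limits, with `maxorder` mutated continuously and
rounded; the per-parameter magnitudes come from an unavailable supplement,
so the default is 5% of each parameter's founder sampling-range width —
scale-aware and small enough for gradual trajectories — and fully
configurable. After 5 replicate runs the final populations are pooled and
the 30 fittest genotypes form the scenario's species (the publication
reports this pool as 150 genotypes where 5 × 15 = 75; every count involved
is configurable and the defaults follow the stated N and species size).

A note on a selection subtlety: because offspring are exact copies under
zero mutation and ties resolve oldest-first, truncation selection collapses
a heterogeneous population onto its best member in about log₂(N)
generations; the population is a fixed point only once homogeneous. The
tests assert this actual behaviour.

## Morphology and experiments

Seven emergent measures summarize a root system grown alone: maximum
horizontal length, depth, root biomass, length per biomass, branches per
length, biomass per occupied voxel, and the box-counting fractal dimension.
The fractal dimension rasterizes segments at 1 mm, counts occupied cubes at
dyadic sides 40/20/10/5 mm, and fits log N(s) against log s; we count 3-D
boxes on the native 3-D structure rather than 2-D image projections (the
classical method is image-based; whether the original analysis projected is
not stated). "Density per voxel" is biomass divided by the count of occupied
voxels, identical to the mean per-occupied-voxel biomass. A PCA of the
z-scored measures (constant columns dropped, each component's
largest-magnitude loading made positive) summarizes species differences, and
a PCoA (classical MDS) of z-scored genotype parameters tracks evolutionary
trajectories.

The factorial experiment crosses target species × neighbour species ×
neighbour count 1–4, plus one alone condition per target: (5 × 5 × 4) + 5 =
105 conditions, 100 replicates each (the publication's figure captions say
50; both are config). Every plant draws its genotype uniformly from its
species pool, on a stream separate from the growth streams so neighbour
draws never consume the target's randomness. From the per-condition means we
compute ratio-to-alone indices (the index formulas are package-defined — the
underlying notions are verbal in the literature): **competitive response** of
T = mean over neighbours N of biomass(T | 4 × N) / biomass(T alone), and
**competitive effect** of N = mean over targets T of 1 − that ratio.

## Problem sizes used in routine checks

`study_settings("full")` is the headline configuration above; a full
5-scenario study at that size is an overnight computation. Routine checks
and the bundled acceptance analysis use `study_settings("desk")`: an
8 × 8 × 15 world, 80-day simulations, N = 8 evolved for 50 generations, 3
replicate runs, species of 10, and 6 experiment replicates. Desk-scale
plants reach only ~15–20 mm horizontally, so the neighbour spacing scales to
20 mm to preserve the mechanism — root-system overlap in shared voxels — at
the smaller plant size. Desk-scale results demonstrate the direction of the
published contrasts (fitness increase under selection, deeper/sparser roots
under stronger competition, the growth-potential vs tolerance trade-off),
not their magnitudes in grams; magnitudes additionally depend on the
allocation-form and mutation-scale assumptions flagged above.

## Known limitations

No root death or turnover, no secondary thickening, no hydraulic
architecture beyond the per-mm transport discount, no nutrient fields or
soil heterogeneity, no above-ground competition, no more than five plants
per world, simultaneous emergence only. The generated root systems emulate
architectural variety via nine parameters; they do not emulate
plasticity — a genotype cannot respond to local water status except through
the budget its uptake provides.
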