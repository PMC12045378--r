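---
title: "Multilevel selection of cooperators and cheaters: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel selection of cooperators and cheaters: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlsel)
```

## The model

`mlsel` simulates competition between groups composed of two individual
types: social individuals (A, cooperators) that carry a costly trait which
lowers their group's death probability, and asocial individuals (B,
cheaters) that reproduce faster without contributing. Selection acts at two
levels at once — cheaters beat cooperators within groups, while groups with
more cooperators outlive groups with fewer — and the package exists to
explore what that tension does to the long-term fate of cooperation.

Each group owns `K` sites holding individuals or untapped resources; a
group's resources are fixed at its birth (`K - nA - nB` remain). In each
discrete time step three things can happen:

* **Reproduction.** Within every group, one birth occurs with probability
  proportional to the free resources: an A-birth with probability
  `(nA/K)(1 - n/K)` and a B-birth with probability `b (nB/K)(1 - n/K)`,
  where `n = nA + nB` and `b ∈ [1, 4]` is the cheater's reproduction
  advantage (`b ≤ 4` keeps the two probabilities summing below 1, the
  worst case being a half-full all-B group). All groups update in parallel
  from their pre-step compositions.
* **Group death.** With probability `mu` a death event is attempted. The
  victim distribution encodes the social trait with strength `a ∈ [0, 1]`
  in one of three regimes: `neutral` (uniform), `relative` (weights
  `1 - a nA_j/n_j`, renormalized over the current groups — a group's fate
  depends on everyone else's composition), and `absolute` (the same weight
  divided by the group count without renormalization, so the residual mass
  means no death at all; a group's risk is its own business).
* **Splitting.** If any group has filled all `K` sites and the group count
  is below the environmental carrying capacity `Kg`, exactly one full group
  (chosen uniformly; splitting is composition-blind) divides. Each daughter
  receives `mA ~ U{0..nA}`, `mB ~ U{0..nB}` of the parent's individuals and
  a fresh complement of resources. A daughter born empty is discarded
  immediately — an abortive split that leaves the full parent intact and
  split-eligible.

### Ordering and other fixed conventions

The model statement does not dictate a within-step event order. The package
fixes reproduction → death → splitting: death weights then act on the
compositions just produced, and the `Ng ≤ Kg` cap holds at every step
boundary. An abortive split consumes the step's single splitting
opportunity. Extinction is absorbing and trajectory records are padded with
zeros to the horizon. A degenerate corner is pinned by symmetry: in
relative mode with `a = 1` and every group all-A the victim weights are
0/0, and the uniform limit is used.

Homogeneous-group experiments draw each group's initial size uniformly on
`{1, .., K-1}` (the stationary mix a parent's random allocation produces),
overridable via `init_population(sizes =)`; heterogeneous experiments draw
`nA, nB ~ U{0 .. K/2}` independently, redrawing the rare empty pair, so the
initial social fraction is 1/2 on average. Replicate `i` of an ensemble is
seeded `seed + i` and sweep cell `c` owns the block `seed + c*1e5`, so
ensembles can be extended without perturbing earlier replicates.

## Survival theory

The analytic layer treats one group as a birth-death chain on its size with
a constant per-step survival probability `delta` (for a population of `Ng`
groups under death pressure `mu`, `delta = 1 - mu/Ng`). The probability of
reaching the splitting threshold from size `n` before dying is the product

```
psi_n = prod_{l=n}^{K-1}  delta T_l / (1 - delta + delta T_l),
T_l = (b l / K)(1 - l / K)
```

computed in log space ([psi_n()]); its average over initial sizes
(`psi_avg()`) is the per-daughter renewal probability, and a population of
groups proliferates when it exceeds 1/2. Near `delta = 1` the average has
the first-order form `1 - (1-delta) H_{K-1} K^2 / (b(K-1))`
(`psi_avg_high_survival()`, with `H` the harmonic number), giving the
critical survival probability `delta*` and the neutral threshold
`mu* = Ng (K-1) b / (2 H_{K-1} K^2)` in closed form.

A caution that the package tests encode: the expansion parameter at the
threshold equals 1/2 by construction, so the first-order threshold never
converges to the exact (`numeric_threshold()`, bracketed bisection at
tolerance 1e-10) one even as `K` grows — the two are genuinely a
lower/upper bound pair that brackets the empirical extinction boundary,
and that bracketing, not convergence, is what simulations confirm. For
small `K` the exact condition can even sit at a formal `mu > 1`; the
solver accepts an extended bracket for exactly that use.

For homogeneous all-A/all-B populations, `survival_probs()` gives each
type's `delta` under either fitness regime, from which threshold curves for
the trait strength (`a*`) and the cheater advantage (`b*(a)`) follow
(`threshold_curves()`). In the rare-death limit with the population pinned
at `Kg`, the group-level dynamics reduce to a Moran-type chain whose
backward/forward ratio is `1 - a` in both regimes (`moran_transitions()`),
hence the gambler's-ruin fixation probability
`(1 - (1-a)^NgA0) / (1 - (1-a)^Kg)` (`fixation_prob_moran()`; the closed
form is the textbook consequence of the constant ratio and is
cross-validated in the tests by a linear solve of the chain).

## What the simulations show

Three headline behaviors, each reproduced by the test suite at reduced
replication:

1. **Neutral extinction boundary.** For `Ng = 50`, `b = 1` and
   `K ∈ {10, 20, 40}`, the empirical 50% survival crossing in `mu`
   (M = 10 replicates per point, horizon 1000) falls between the
   first-order and exact threshold curves.
2. **Cheaters enable cooperation (relative fitness).** At
   `mu = 0.7, K = 10, Ng = 20, Kg = 70` with 10 all-A and 10 all-B groups,
   a trait strength inside the social-survival pocket (`a = 0.9`) fixes
   cooperators only when the cheater advantage is large: the composition
   statistic `S` at `b = 4` exceeds its value at `b = 1.5`, where the
   population simply dies out. Cheaters carry the population to a viable
   size; cooperators then take over.
3. **Sociality-driven extinction.** With a carrying capacity too small for
   all-A proliferation (`mu = 0.5, a = 0.75, b = 4, K = 20, Ng = 30,
   Kg = 45`), mixed populations surge to near `Kg`, homogenize toward A,
   and collapse; all-B populations persist.

The Moran-limit recovery runs the full stochastic model at `mu = 0.01`,
`Kg = Ng = 8`, `a = 0.4` with homogeneous groups started at the splitting
threshold and `K = 6` — small groups keep the daughter-renewal probability
near 1, which is the regime the limit assumes; `b = 1` makes the two types
symmetric apart from the trait, which the limit says is the only thing that
matters. Observed all-A fixation frequencies over 2000 replicates sit
within Monte-Carlo error of the gambler's-ruin prediction in both fitness
regimes, which also agree with each other conditional on non-extinction.

## The biofilm instantiation

The agent-based module replaces abstract groups with an off-lattice biofilm
in which the social trait is extracellular-matrix (ECM) production. Cells
feel pairwise pseudo-forces `H/d^6 - ((G_p + G_q)/2)/d^2` and anchor terms
with `G_p/2`; the asocial attraction constant is calibrated so the pair
force vanishes at the anchor spacing `D` (`G = H/D^4`), and ECM production
multiplies a cell's attraction constant 100-fold while dividing its
division rate by 5. Motion is fixed-speed (`D` per step) along the
normalized blend `(1-F) u_force + F u_rand` with a reflective substrate;
division is phenotype-wise logistic Poisson (`n r (1 - N/K_BF) dt`);
removal takes Poisson-many cells from the predation interface — the
topmost cell in each substrate window of width `D`. The default geometry is
3-D over a 20×20 anchor grid (400 anchors, spanning roughly twice a mature
colony's footprint); a 2-D cross-section mode exists for fast tests. Jitter
magnitudes (1e-6 D for position uniqueness, 1e-2 D after division) are
configurable constants.

What the emulation does and does not capture: the biofilm realizes the
paper-level story — the interface (the subset of cells that can die) grows
more slowly than the bulk, ECM cells cluster low and are buried by their
neighbors, and cheaters free-ride on that cohesion — but it has no explicit
ECM particles, no nutrient field, and logistic growth in place of any real
resource dynamics, so passing tests speak to the mechanism, not to any
particular organism.

Two quantitative notes from this implementation, recorded here because
they shape what the tests assert:

* **Seeding.** Founder-lineage survival is bounded below by a
  branching-process argument: per-capita death never exceeds `L` (the
  interface is a subset of the colony) while per-capita asocial division
  is at least `r(1 - 300/500) ≈ 0.28` per unit time up to the 300-cell
  success threshold, so asocial seeding success cannot fall below ~0.85
  under the standard parameter set; this implementation measures ~0.87
  for non-producers and ~0.33 for producers (the 4-fold producer
  disadvantage, and its mechanism — a five-fold slower division racing the
  same predation clock — are robust; the absolute rates are what the
  stated parameters imply).
* **Mutant invasion.** A single ECM mutant in an asocial biofilm at
  capacity divides at the capacity-limited rate `r_s(1 - N/K_BF)` yet is
  buried by the cells its own cohesion attracts: its measured interface
  exposure sits several-fold below both the colony average and the
  division-cost break-even threshold `(m/N)/5` (a unit test asserts
  this), so the mutant lineage is positively selected and expands. In
  this implementation the expansion saturates: instrumented runs show the
  social cluster growing to a stable minority (roughly 5–10% of the
  colony) and persisting for as long as we have simulated (≥ 2.5×10^5
  steps) without either fixing or being lost — a protected-polymorphism
  outcome rather than homogenization. The packaged fixation check
  therefore runs a reduced configuration chosen by measuring the
  mechanism rather than the outcome (mound deep enough that exposure
  clears the threshold, first at `K_BF = 300`; `L` raised to 1 since the
  selective margin is L-invariant while time shortens as 1/L), scores
  fixation against the neutral `1/N` expectation, and is expected to be
  the suite's red flag whenever homogenization stays out of reach. The
  companion neutral control — ECM effects switched off — verifies that a
  relabeled mutant fixes at exactly the `1/N` drift rate, so the
  machinery of the experiment itself is sound. Both readings of the
  substrate-attraction term (`substrate_attraction = "phenotype"` or
  `"baseline"`) give this same picture.

## Numerical and testing choices

Hitting products are evaluated in log space; thresholds are found by plain
bisection on physical brackets (the maps are monotone and the cost is
trivial); harmonic numbers are summed directly. The stochastic core and
the biofilm inner loops are C++ (via Rcpp) drawing from R's RNG, so every
result is reproducible from `set.seed()`. Problem sizes in the tests —
replicate counts of 10–2000 for the group model, 100 seeding trials per
phenotype, 20 reduced-scale fixation trials — were chosen so the whole
suite completes on a laptop-class single core while keeping Monte-Carlo
bands (3 sigma binomial) meaningful.

## Known limitations

The theory layer treats `delta` as time-independent (the initial-`Ng`
bound), so its thresholds are bounds rather than exact boundaries; the
biofilm model's fixed-speed motion keeps colonies well mixed at small
sizes, which makes early-colony death rates sit at their theoretical
maximum; and the package deliberately omits within-group individual death,
resource intake between splits, more than two types, and any spatial
structure among groups.
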