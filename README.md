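# mlsel — multilevel selection dynamics of cooperators and cheaters

`mlsel` is an R package for studying the coevolution of cooperators and
cheaters under two-level (individual and group) selection. Populations are
collections of groups; each group holds `K` sites occupied by social
individuals (A, cooperators), asocial individuals (B, cheaters) or unused
resources. Within a group, a birth consumes a resource: an A-birth with
probability `(nA/K)(1 − n/K)`, a B-birth with probability
`b (nB/K)(1 − n/K)` (the cheater advantage `b ∈ [1, 4]`). Full groups split
into two daughters by uniform random allocation, capped by an environmental
carrying capacity of `Kg` groups. Each step, at most one group dies: with
total probability `μ`, and a victim distribution that the social trait
(strength `a ∈ [0, 1]`) skews under one of three regimes — `neutral`
(uniform), `relative` (weights `1 − a·nA_j/n_j` renormalized over all
groups) or `absolute` (the same weight, unnormalized, so total death risk
itself decreases with cooperation).

The package provides:

* the exact stochastic simulator (`run_model()`, with the per-step
  operations exposed for testing: `reproduction_step()`, `death_weights()`,
  `apply_group_death()`, `split_group()`, `splitting_step()`, `sim_step()`),
  with an Rcpp core;
* the survival theory: threshold-hitting probabilities
  `ψ_n = Π_l δT_l/(1−δ+δT_l)` (`psi_n()`, `psi_avg()`), the high-survival
  closed form `⟨ψ⟩ ≈ 1 − (1−δ)H_{K−1}K²/(b(K−1))` and the proliferation
  threshold `μ* = Ng(K−1)b/(2H_{K−1}K²)` (`psi_avg_high_survival()`,
  `delta_star()`, `neutral_threshold_mu()`), exact numeric thresholds by
  bisection (`numeric_threshold()`), homogeneous-group survival and
  threshold curves `a*`, `b*(a)` (`survival_probs()`, `threshold_curves()`),
  and the rare-death Moran limit with gambler's-ruin fixation probability
  `(1−(1−a)^n0)/(1−(1−a)^Kg)` (`moran_transitions()`,
  `fixation_prob_moran()`);
* replicate-ensemble drivers for phase portraits and trajectory panels
  (`param_sweep()`, `trajectory_ensemble()`, `theta_stat()`, `s_stat()`);
* an off-lattice agent-based biofilm model in which the social trait is
  extracellular-matrix production — 100× stronger cell-cell attraction at
  a 5× division cost — with predation restricted to the colony's top
  interface (`biofilm_params()`, `run_steady_state()`, `run_seeding()`,
  `run_fixation()`).

It is aimed at researchers in evolutionary dynamics who want a small,
reproducible sandbox in which "cheaters rescue cooperation" can be taken
apart: every experiment is a pure function of a parameter block and a seed.

## A worked example

Harsh environment (`μ = 0.7, K = 10, Ng = 20, Kg = 70`, relative fitness),
where homogeneous cooperator populations cannot proliferate on their own.
Theory first:

```r
library(mlsel)
sp <- survival_probs("relative", mu = 0.7, a = 0.9, Ng = 20, NgA = 10)
psi_avg(sp[["delta_A"]], b = 1,   K = 10)   # 0.824  cooperator groups viable
psi_avg(sp[["delta_B"]], b = 1.5, K = 10)   # 0.334  weak cheaters are not
psi_avg(sp[["delta_B"]], b = 4,   K = 10)   # 0.619  strong cheaters are
```

With `ψ_A > 1/2` the trait is strong enough for cooperator groups to renew
themselves — but only if the population survives long enough to homogenize.
Simulation, 50 replicates each, sampling the composition statistic
`S = 2·Ng_A/Ng − 1` (1 = all-cooperator, −1 = all-cheater, 0 on extinction)
at `T = 3000`:

```r
par_weak <- model_params(K = 10, Kg = 70, mu = 0.7, a = 0.9, b = 1.5,
                         mode = "relative", T = 3000, seed = 11)
par_strong <- model_params(K = 10, Kg = 70, mu = 0.7, a = 0.9, b = 4,
                           mode = "relative", T = 3000, seed = 11)
ens_weak <- trajectory_ensemble(par_weak,
  function() init_population(K = 10, n_A = 10, n_B = 10), M = 50,
  record = FALSE)
ens_strong <- trajectory_ensemble(par_strong,
  function() init_population(K = 10, n_A = 10, n_B = 10), M = 50,
  record = FALSE)
c(S_weak = s_stat(ens_weak$runs), S_strong = s_stat(ens_strong$runs))
#>   S_weak S_strong
#>     0.00     0.26
c(theta_weak = theta_stat(ens_weak$runs), theta_strong = theta_stat(ens_strong$runs))
#> theta_weak theta_strong
#>       0.00         0.26
```

With weak cheaters (`b = 1.5`) every replicate goes extinct (`S = 0` by
convention, survival fraction `⟨Θ⟩ = 0`). With strong cheaters (`b = 4`)
a quarter of the replicates survive — and every survivor is purely
social (`⟨S⟩ = ⟨Θ⟩`): the cheaters' fast growth carries the population to
the carrying capacity, after which the cooperator groups outlive them. The
cheater is the cooperator's ladder, and is discarded after the climb.

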