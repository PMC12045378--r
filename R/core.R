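#' Within-group reproduction probabilities
#'
#' An individual reproduction event in a group with composition `(nA, nB)` is
#' proportional to the free resources `1 - (nA + nB)/K`: an A-birth occurs
#' with probability `(nA/K) (1 - n/K)` and a B-birth with probability
#' `b (nB/K) (1 - n/K)`; otherwise the group is unchanged. Full groups
#' (`n = K`) never change.
#'
#' @param nA,nB group composition (vectors accepted).
#' @param K splitting threshold.
#' @param b asocial reproduction scale factor.
#' @return A list with numeric vectors `pA`, `pB` and `p_none`.
#' @export
#' @examples
#' reproduction_probs(nA = 2, nB = 3, K = 10, b = 2)  # 0.10, 0.30, 0.60
reproduction_probs <- function(nA, nB, K, b = 1) {
  n <- nA + nB
  if (any(n > K)) stop("group size exceeds the splitting threshold K")
  res <- 1 - n / K
  pA <- (nA / K) * res
  pB <- b * (nB / K) * res
  list(pA = pA, pB = pB, p_none = 1 - pA - pB)
}

#' Apply one stochastic reproduction step to every group
#'
#' All groups are updated in parallel using their pre-step compositions; at
#' most one birth occurs per group per step.
#'
#' @param groups population matrix (columns `nA`, `nB`).
#' @param params an [model_params()] object.
#' @return Updated population matrix.
#' @export
reproduction_step <- function(groups, params) {
  validate_population(groups, params$K)
  as_population(cpp_reproduction_step(groups, params$K, params$b))
}

#' Per-group death probabilities
#'
#' Returns the probability that each group dies in the coming step. With a
#' death event attempted with probability `mu`, the conditional choice of
#' victim depends on the fitness mode: uniform (`neutral`), weights
#' `(1 - a nA_j/n_j)` renormalized over groups (`relative`), or
#' `(1 - a nA_j/n_j)/Ng` without renormalization (`absolute`, where the
#' residual mass means no group dies). The weights sum to `mu` in the neutral
#' and relative modes and to at most `mu` in the absolute mode. The relative
#' normalizer vanishes only when every group is all-A with `a = 1`; the
#' symmetric limit (uniform weights) is used there.
#'
#' @inheritParams reproduction_step
#' @return Numeric vector of per-group death probabilities.
#' @export
#' @examples
#' p <- model_params(K = 10, Kg = 10, mu = 0.6, a = 0.5, mode = "relative")
#' death_weights(population(nA = c(10, 0), nB = c(0, 10)), p)  # 0.2, 0.4
death_weights <- function(groups, params) {
  validate_population(groups)
  cpp_death_weights(groups, params$mu, params$a, mode_code(params$mode))
}

#' Apply at most one group death
#'
#' With probability `mu` a death event is attempted; conditional on the
#' event, the victim is drawn from the [death_weights()] distribution (in
#' absolute mode the event may resolve to no death). The removed group's
#' individuals and resources are discarded.
#'
#' @inheritParams reproduction_step
#' @return Updated population matrix with attribute `removed` (index of the
#'   removed group, or `NA`).
#' @export
apply_group_death <- function(groups, params) {
  validate_population(groups)
  out <- cpp_apply_group_death(groups, params$mu, params$a,
                               mode_code(params$mode))
  structure(as_population(out$groups), removed = out$removed)
}

#' Split one full group into two daughters
#'
#' A parent at the splitting threshold (`nA + nB = K`) allocates
#' `mA ~ U{0..nA}` and `mB ~ U{0..nB}` individuals to the first daughter and
#' the rest to the second; each daughter's resources refill to `K - size`.
#' A daughter left empty is eliminated immediately (an abortive split): the
#' surviving daughter then equals the parent and remains split-eligible.
#'
#' @param group length-2 integer vector `(nA, nB)`.
#' @param K splitting threshold.
#' @return Integer matrix with one (abortive) or two daughter rows.
#' @export
split_group <- function(group, K) {
  if (sum(group) != K)
    stop("only groups at the splitting threshold (nA + nB = K) can split")
  cpp_split_group(as.integer(group))
}

#' Apply at most one group-splitting event
#'
#' If the population is below the carrying capacity `Kg` and at least one
#' group has reached size `K`, one such group (chosen uniformly; splitting is
#' composition-independent) splits via [split_group()]. An abortive split
#' consumes the step's single split opportunity.
#'
#' @inheritParams reproduction_step
#' @return Updated population matrix.
#' @export
splitting_step <- function(groups, params) {
  validate_population(groups, params$K)
  as_population(cpp_splitting_step(groups, params$K, params$Kg))
}

#' Advance the population by one time step
#'
#' One discrete step applies, in order: (i) parallel within-group
#' reproduction, (ii) at most one group death, (iii) at most one group split.
#' Death weights therefore see the compositions produced by the current
#' step's births, and the group count respects `Ng <= Kg` at the end of every
#' step. The model itself does not privilege an ordering; this default is
#' fixed here and documented so that runs are reproducible.
#'
#' @inheritParams reproduction_step
#' @return Updated population matrix.
#' @export
sim_step <- function(groups, params) {
  validate_population(groups, params$K)
  as_population(cpp_step(groups, params$K, params$Kg, params$mu, params$a,
                         params$b, mode_code(params$mode)))
}

#' Run a full trajectory of the group-structured model
#'
#' Iterates [sim_step()] from an initial population until the horizon
#' `params$T` or extinction (absorbing; the record is padded with zeros), or
#' optionally until the population homogenizes (`until = "absorption"`,
#' used for Moran-limit fixation experiments).
#'
#' @param params an [model_params()] object.
#' @param init initial population matrix (see [population()] and
#'   [init_population()]).
#' @param record logical; record the per-step series (set `FALSE` for long
#'   absorption runs where only the outcome is needed).
#' @param until `"horizon"` (default) or `"absorption"` (stop when all
#'   individuals are social, all are asocial, or the population is extinct).
#' @param seed optional seed overriding `params$seed`; `NULL` leaves the RNG
#'   state untouched (for use inside ensemble drivers).
#' @return A list of class `mlsel_run`: `trajectory` (data.frame with columns
#'   `t, Ng, Ng_A, nA_total, nB_total`), `groups` (final population),
#'   `extinct`, `outcome` (`"horizon"`, `"fixed_A"`, `"fixed_B"` or
#'   `"extinct"`), `t_end`, and the final summary counts.
#' @export
#' @examples
#' p <- model_params(K = 10, Kg = 20, mu = 0.3, T = 200, seed = 42)
#' r <- run_model(p, population(nA = 0, nB = rep(5, 10)))
#' tail(r$trajectory)
run_model <- function(params, init, record = TRUE,
                      until = c("horizon", "absorption"), seed = params$seed) {
  until <- match.arg(until)
  validate_population(init, params$K)
  if (nrow(init) > params$Kg)
    stop("initial group count exceeds the carrying capacity Kg")
  if (!is.null(seed)) set.seed(seed)
  out <- cpp_run(init, params$K, params$Kg, params$mu, params$a, params$b,
                 mode_code(params$mode), params$T,
                 record, until == "absorption")
  traj <- if (record) as.data.frame(out$trajectory) else NULL
  structure(
    list(trajectory = traj,
         groups = as_population(out$groups),
         extinct = out$extinct,
         outcome = c("horizon", "fixed_A", "fixed_B", "extinct")[out$outcome + 1L],
         t_end = out$t_end,
         Ng = out$Ng, Ng_A = out$Ng_A,
         nA_total = out$nA_total, nB_total = out$nB_total,
         params = params),
    class = "mlsel_run"
  )
}

#' @export
print.mlsel_run <- function(x, ...) {
  cat(sprintf("mlsel run: outcome %s at t = %d\n", x$outcome, x$t_end))
  cat(sprintf("  final state: Ng = %d (%d all-A), nA = %g, nB = %g\n",
              x$Ng, x$Ng_A, x$nA_total, x$nB_total))
  invisible(x)
}

#' Monte-Carlo hitting probability of the splitting threshold
#'
#' Simulates a single group held at a fixed per-step survival probability
#' `delta` (the group count frozen, so `delta` does not drift) and returns
#' the fraction of `M` replicates that reach size `K` before the group dies.
#' This is the simulation counterpart of [psi_n()] and is used to
#' cross-check the recursion against the stochastic dynamics.
#'
#' @param n0 initial group size.
#' @param K splitting threshold.
#' @param b reproduction scale factor.
#' @param delta per-step group survival probability.
#' @param M number of replicates.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @return Estimated hitting probability.
#' @export
single_group_hitting <- function(n0, K, b, delta, M = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cpp_single_group_hits(as.integer(n0), as.integer(K), b, delta,
                        as.integer(M)) / M
}
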