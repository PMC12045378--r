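#' Parameters for the agent-based biofilm model
#'
#' Off-lattice biofilm of extracellular-matrix (ECM) producing (social) and
#' non-producing (asocial) cells. Cells interact through a pairwise
#' pseudo-force `H/d^6 - ((G_p + G_q)/2)/d^2` (positive = repulsive) and are
#' attracted to substrate anchor points (for which the pair term uses
#' `G_p/2`). The asocial attraction constant is fixed by requiring zero net
#' pair force at the anchor spacing `D`: `G_asocial = H / D^4`. ECM
#' production multiplies the attraction constant by `G_social_factor` (100)
#' and the division rate by `r_social_factor` (1/5). Division is logistic
#' Poisson per phenotype; removal takes Poisson-many cells from the predation
#' interface (the topmost cell in each substrate window of width `D`).
#'
#' @param H repulsive pseudo-force constant.
#' @param D substrate anchor spacing (the unit of length; cells move a fixed
#'   distance `D` per step).
#' @param F weight of the random component of motion in `[0, 1]`.
#' @param r asocial division rate per unit time (`ln 2`: doubling time 1 far
#'   from capacity, i.e. 100 steps at `dt = 0.01`).
#' @param K_BF biofilm carrying capacity in cells.
#' @param L removal (predation) rate per interface cell per unit time.
#' @param dt timestep.
#' @param dim 3 (default; square anchor grid) or 2 (cross-section mode with a
#'   line of anchors, used for fast experiments).
#' @param n_side anchors per side (3-D grid has `n_side^2` anchors; the
#'   default 20 gives 400, spanning roughly twice a mature biofilm's
#'   footprint).
#' @param G_social_factor,r_social_factor phenotype effect sizes (ECM: 100
#'   and 1/5; set both to 1 to make the trait neutral).
#' @param substrate_attraction `"phenotype"` (default): the cell-anchor term
#'   uses the cell's own attraction constant, so ECM producers are also
#'   100-fold more strongly substrate-bound. `"baseline"`: the anchor term
#'   uses the calibrated `G_asocial/2` for every cell — ECM binds neighbors
#'   together while substrate adhesion stays phenotype-independent. The two
#'   readings give indistinguishable seeding and mutant-invasion outcomes
#'   in this model; the switch exists to make that checkable.
#' @param jitter_pos position-uniqueness jitter magnitude (fraction of `D`).
#' @param jitter_div post-division displacement magnitude (fraction of `D`).
#' @return Object of class `mlsel_biofilm_params`.
#' @export
biofilm_params <- function(H = 1, D = 1, F = 0.5, r = log(2), K_BF = 500,
                           L = 0.1, dt = 0.01, dim = 3, n_side = 20,
                           G_social_factor = 100, r_social_factor = 1 / 5,
                           substrate_attraction = c("phenotype", "baseline"),
                           jitter_pos = 1e-6, jitter_div = 1e-2) {
  stopifnot(dim %in% c(2, 3), F >= 0, F <= 1, H > 0, D > 0, K_BF >= 1)
  substrate_attraction <- match.arg(substrate_attraction)
  G_asocial <- H / D^4               # zero pair force at distance D
  G_social <- G_asocial * G_social_factor
  p <- list(H = H, D = D, F = F, r_asocial = r,
            r_social = r * r_social_factor,
            G_asocial = G_asocial, G_social = G_social,
            substrate_attraction = substrate_attraction,
            G_anchor_asocial = G_asocial,
            G_anchor_social = if (substrate_attraction == "baseline")
              G_asocial else G_social,
            K_BF = K_BF, L = L, dt = dt, dim = as.integer(dim),
            n_side = as.integer(n_side),
            jitter_pos = jitter_pos * D, jitter_div = jitter_div * D)
  p$anchors <- make_anchors(p)
  p$grid_length <- n_side * D
  structure(p, class = "mlsel_biofilm_params")
}

#' @export
print.mlsel_biofilm_params <- function(x, ...) {
  cat(sprintf("Biofilm parameters (%d-D, %d anchors)\n", x$dim,
              nrow(x$anchors)))
  cat(sprintf("  H = %g, G = %g (social %g), F = %g\n", x$H, x$G_asocial,
              x$G_social, x$F))
  cat(sprintf("  r = %g (social %g), K_BF = %g, L = %g, dt = %g\n",
              x$r_asocial, x$r_social, x$K_BF, x$L, x$dt))
  invisible(x)
}

make_anchors <- function(p) {
  g <- (seq_len(p$n_side) - 1) * p$D
  if (p$dim == 3) {
    a <- as.matrix(expand.grid(x = g, y = g))
    cbind(a, z = 0)
  } else {
    cbind(x = g, z = 0)
  }
}

grid_center <- function(p) {
  c0 <- (p$n_side - 1) * p$D / 2
  if (p$dim == 3) c(c0, c0, 0) else c(c0, 0)
}

#' Construct a biofilm state
#'
#' @param positions numeric matrix of cell coordinates (`dim` columns, the
#'   last one the height above the substrate).
#' @param social logical vector of phenotype flags.
#' @return Object of class `mlsel_biofilm`.
#' @export
biofilm_state <- function(positions, social) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == length(social),
            all(positions[, ncol(positions)] >= 0))
  structure(list(positions = positions, social = as.logical(social)),
            class = "mlsel_biofilm")
}

#' @export
print.mlsel_biofilm <- function(x, ...) {
  cat(sprintf("Biofilm of %d cells (%d social, %d asocial)\n",
              nrow(x$positions), sum(x$social), sum(!x$social)))
  invisible(x)
}

#' Net pseudo-forces on every cell
#'
#' Sums the pairwise cell-cell and cell-anchor pseudo-force terms and
#' returns both the raw net force vectors and their unit vectors (the
#' direction component of motion).
#'
#' @param state a [biofilm_state()].
#' @param params a [biofilm_params()] object.
#' @return List with matrices `force` and `unit`.
#' @export
pseudo_force <- function(state, params) {
  f <- cpp_bf_forces(state$positions, state$social, params$anchors,
                     params$H, params$G_asocial, params$G_social,
                     params$G_anchor_asocial, params$G_anchor_social)
  nrm <- sqrt(rowSums(f^2))
  u <- f / ifelse(nrm > 0, nrm, 1)
  list(force = f, unit = u)
}

#' Predation interface of a biofilm
#'
#' Partitions the substrate-tangent plane into windows of width `D` and
#' returns, for each occupied window, the index of the cell farthest from
#' the substrate. Only these cells are exposed to removal.
#'
#' @inheritParams pseudo_force
#' @return Integer vector of cell indices.
#' @export
predation_interface <- function(state, params) {
  cpp_bf_interface(state$positions, params$D)
}

#' Advance a biofilm by one or more steps
#'
#' Each step applies, in the order of the underlying dynamics: motion
#' (fixed speed `D` along the blend of force and random directions, with a
#' reflective substrate), logistic Poisson division per phenotype, and
#' Poisson removal from the predation interface. Sub-processes can be
#' switched off to isolate one mechanism (e.g. the force-relaxation phase
#' uses `F = 0` with division and removal disabled).
#'
#' @inheritParams pseudo_force
#' @param n_steps number of timesteps.
#' @param F override of the motion randomization weight (default
#'   `params$F`).
#' @param move,divide,remove logical switches for the three sub-processes.
#' @param stop_size stop early once the population exceeds this size
#'   (`Inf` to disable).
#' @param stop_homog stop early when the biofilm homogenizes.
#' @param record_every record `(step, n_cells, n_social)` every this many
#'   steps (0 = off).
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @return A [biofilm_state()] with attributes `outcome` (`"horizon"`,
#'   `"exceeded"`, `"extinct"`, `"social"`, `"asocial"`), `steps_done` and
#'   `record`.
#' @export
biofilm_run <- function(state, params, n_steps, F = params$F, move = TRUE,
                        divide = TRUE, remove = TRUE, stop_size = Inf,
                        stop_homog = FALSE, record_every = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- cpp_biofilm_run(state$positions, state$social, params$anchors,
                         params$H, params$G_asocial, params$G_social,
                         params$G_anchor_asocial, params$G_anchor_social, F,
                         params$r_asocial, params$r_social, params$K_BF,
                         params$L, params$dt, params$D, params$jitter_pos,
                         params$jitter_div, as.integer(n_steps), move,
                         divide, remove,
                         if (is.finite(stop_size)) as.integer(stop_size) else -1L,
                         stop_homog, as.integer(record_every))
  st <- biofilm_state(out$positions, out$social)
  attr(st, "outcome") <- c("horizon", "exceeded", "extinct", "social",
                           "asocial")[out$outcome + 1L]
  attr(st, "steps_done") <- out$steps_done
  attr(st, "record") <- as.data.frame(out$record)
  st
}

seed_cells <- function(params, n, phenotype) {
  ctr <- grid_center(params)
  w <- 0.05 * params$grid_length
  tang <- params$dim - 1L
  pos <- matrix(0, n, params$dim)
  for (k in seq_len(tang))
    pos[, k] <- ctr[k] + runif(n, -w / 2, w / 2)
  pos[, params$dim] <- runif(n, 0, params$jitter_pos)
  biofilm_state(pos, rep(identical(phenotype, "social"), n))
}

#' Steady-state, seeding and mutant-fixation biofilm experiments
#'
#' `run_steady_state()`: a homogeneous population of `n0` cells is placed
#' uniformly in a central square of width 5% of the grid length, relaxed for
#' `relax_steps` under forces only (`F = 0`, no division or removal), then
#' run with the full dynamics for `steps` timesteps.
#'
#' `run_seeding()`: a single founder cell of the given phenotype is placed
#' at the center and the full dynamics run until the colony exceeds
#' `stop_size` cells (survival) or goes extinct.
#'
#' `run_fixation()`: in an existing (steady-state) asocial biofilm, one
#' uniformly chosen cell is relabeled social and the dynamics run until the
#' biofilm homogenizes; runs hitting `max_steps` return `NA` (undecided).
#'
#' @param params a [biofilm_params()] object.
#' @param n0 initial cell count (default: the carrying capacity).
#' @param phenotype `"asocial"` or `"social"`.
#' @param relax_steps force-relaxation steps before the full dynamics.
#' @param steps full-dynamics steps for the steady-state run.
#' @param stop_size seeding success threshold (cells).
#' @param max_steps step cap for seeding/fixation runs.
#' @param state an existing biofilm (for `run_fixation()`).
#' @param record_every passed to [biofilm_run()].
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @return `run_steady_state()`: the final [biofilm_state()].
#'   `run_seeding()`: list with `survived` (logical, `NA` if undecided),
#'   `steps`, `n_cells`, `record`. `run_fixation()`: list with `fixed`
#'   (logical, `NA` if undecided), `steps`, `n_cells`.
#' @export
run_steady_state <- function(params, n0 = params$K_BF,
                             phenotype = c("asocial", "social"),
                             relax_steps = 1000, steps = 20000,
                             record_every = 0L, seed = NULL) {
  phenotype <- match.arg(phenotype)
  if (!is.null(seed)) set.seed(seed)
  st <- seed_cells(params, n0, phenotype)
  st <- biofilm_run(st, params, relax_steps, F = 0, divide = FALSE,
                    remove = FALSE)
  biofilm_run(st, params, steps, record_every = record_every)
}

#' @rdname run_steady_state
#' @export
run_seeding <- function(params, phenotype = c("asocial", "social"),
                        stop_size = 300, max_steps = 200000,
                        record_every = 0L, seed = NULL) {
  phenotype <- match.arg(phenotype)
  if (!is.null(seed)) set.seed(seed)
  st <- seed_cells(params, 1L, phenotype)
  st <- biofilm_run(st, params, max_steps, stop_size = stop_size,
                    record_every = record_every)
  outcome <- attr(st, "outcome")
  list(survived = if (outcome == "exceeded") TRUE
                  else if (outcome == "extinct") FALSE else NA,
       steps = attr(st, "steps_done"), n_cells = nrow(st$positions),
       record = attr(st, "record"))
}

#' @rdname run_steady_state
#' @export
run_fixation <- function(params, state, max_steps = 500000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(state$positions)
  if (n < 2) stop("fixation requires an established biofilm")
  social <- rep(FALSE, n)
  social[sample.int(n, 1L)] <- TRUE
  st <- biofilm_state(state$positions, social)
  st <- biofilm_run(st, params, max_steps, stop_homog = TRUE)
  outcome <- attr(st, "outcome")
  list(fixed = if (outcome == "social") TRUE
               else if (outcome %in% c("asocial", "extinct")) FALSE else NA,
       steps = attr(st, "steps_done"), n_cells = nrow(st$positions))
}
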