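#' Build an initial population from an experiment specification
#'
#' Homogeneous experiments start from `n_A` all-A groups and `n_B` all-B
#' groups; each group's size is drawn uniformly on `{1, ..., K-1}` (mirroring
#' the average over all post-split states) unless `sizes` overrides it.
#' Heterogeneous experiments draw each group's `nA` and `nB` independently
#' and uniformly on `{0, ..., floor(K/2)}`, redrawing the rare all-zero pair,
#' so the initial social fraction is 1/2 on average.
#'
#' @param K splitting threshold.
#' @param n_A,n_B numbers of homogeneous all-A and all-B groups.
#' @param heterogeneous logical; draw `n_groups` mixed groups instead.
#' @param n_groups group count for the heterogeneous case.
#' @param sizes `"uniform"` (default), `"threshold"` (all groups start at
#'   size `K`, as in carrying-capacity/Moran-limit setups), or an integer
#'   vector of per-group sizes.
#' @param Kg optional carrying capacity used to validate the group count.
#' @return Population matrix (see [population()]).
#' @export
#' @examples
#' set.seed(1)
#' init_population(K = 10, n_A = 2, n_B = 2)
init_population <- function(K, n_A = 0, n_B = 0, heterogeneous = FALSE,
                            n_groups = NULL, sizes = "uniform", Kg = NULL) {
  if (heterogeneous) {
    if (is.null(n_groups)) stop("heterogeneous init requires n_groups")
    if (!is.null(Kg) && n_groups > Kg)
      stop("initial group count exceeds the carrying capacity Kg")
    half <- floor(K / 2)
    nA <- integer(n_groups); nB <- integer(n_groups)
    for (j in seq_len(n_groups)) {
      repeat {
        nA[j] <- sample.int(half + 1L, 1L) - 1L
        nB[j] <- sample.int(half + 1L, 1L) - 1L
        if (nA[j] + nB[j] > 0) break
      }
    }
    return(population(nA, nB, K))
  }
  ng <- n_A + n_B
  if (ng < 1) stop("at least one group is required")
  if (!is.null(Kg) && ng > Kg)
    stop("initial group count exceeds the carrying capacity Kg")
  sz <- if (is.numeric(sizes)) {
    as.integer(rep_len(sizes, ng))
  } else if (identical(sizes, "threshold")) {
    rep.int(as.integer(K), ng)
  } else if (identical(sizes, "uniform")) {
    sample.int(K - 1L, ng, replace = TRUE)
  } else {
    stop("sizes must be 'uniform', 'threshold' or an integer vector")
  }
  type_A <- c(rep(TRUE, n_A), rep(FALSE, n_B))
  population(nA = ifelse(type_A, sz, 0L), nB = ifelse(type_A, 0L, sz), K)
}

#' Extinction-survival and composition outcome statistics
#'
#' `theta_stat()` is the replicate average of the survival indicator
#' `1{Ng(T) > 0}`; 1 means extinction was never observed by the sampling
#' time. `s_stat()` is the replicate average of the composition statistic
#' `S = 2 NgA(T)/Ng(T) - 1` (group-based, for homogeneous-group experiments)
#' or `S = 2 nA/(nA + nB) - 1` over all individuals (`statistic =
#' "individual"`, for heterogeneous groups); extinct replicates contribute
#' `S = 0`. `S = 1` and `S = -1` mean social and asocial takeover.
#'
#' @param runs list of [run_model()] results sharing parameters and horizon.
#' @param statistic `"group"` or `"individual"` composition statistic.
#' @return Scalar statistic in `[0, 1]` (`theta_stat`) or `[-1, 1]`
#'   (`s_stat`).
#' @export
theta_stat <- function(runs) {
  mean(vapply(runs, function(r) r$Ng > 0, logical(1)))
}

#' @rdname theta_stat
#' @export
s_stat <- function(runs, statistic = c("group", "individual")) {
  statistic <- match.arg(statistic)
  mean(vapply(runs, function(r) {
    if (r$Ng == 0) return(0)
    if (statistic == "group") 2 * r$Ng_A / r$Ng - 1
    else 2 * r$nA_total / (r$nA_total + r$nB_total) - 1
  }, numeric(1)))
}

replicate_seed <- function(master, i) {
  # documented splitting scheme: replicate i of a block seeded with `master`
  # uses master + i, so growing M never perturbs earlier replicates
  as.integer((master + i) %% .Machine$integer.max)
}

#' Run a replicate ensemble of trajectories
#'
#' Runs `M` independent replicates of [run_model()] and collects their
#' trajectory records together with across-replicate means. Replicate `i`
#' is seeded with `seed + i`; when `init` is a function it is called after
#' seeding, so random initial populations are redrawn per replicate.
#'
#' @param params an [model_params()] object.
#' @param init population matrix, or a zero-argument function returning one.
#' @param M number of replicates.
#' @param seed master seed (default `params$seed`).
#' @param record logical; keep full per-step records (default `TRUE`).
#' @param until passed to [run_model()].
#' @return Object of class `mlsel_ensemble`: `runs` (list of run objects),
#'   `trajectories` (long data frame with a `replicate` column),
#'   `mean` (per-step means of `Ng`, `Ng_A`, `Ng_B`, and the social
#'   individual fraction `f_A` among surviving replicates), `M`, `seed`.
#' @export
trajectory_ensemble <- function(params, init, M = 50, seed = params$seed,
                                record = TRUE,
                                until = c("horizon", "absorption")) {
  until <- match.arg(until)
  runs <- vector("list", M)
  for (i in seq_len(M)) {
    set.seed(replicate_seed(seed, i))
    init_i <- if (is.function(init)) init() else init
    runs[[i]] <- run_model(params, init_i, record = record, until = until,
                           seed = NULL)
  }
  traj <- NULL
  mean_df <- NULL
  if (record) {
    traj <- do.call(rbind, lapply(seq_len(M), function(i) {
      cbind(replicate = i, runs[[i]]$trajectory)
    }))
    ts <- sort(unique(traj$t))
    acc <- function(f) vapply(split(traj, traj$t), f, numeric(1))[as.character(ts)]
    mean_df <- data.frame(
      t = ts,
      Ng = acc(function(d) mean(d$Ng)),
      Ng_A = acc(function(d) mean(d$Ng_A)),
      Ng_B = acc(function(d) mean(d$Ng - d$Ng_A)),
      f_A = acc(function(d) {
        tot <- d$nA_total + d$nB_total
        if (all(tot == 0)) return(NA_real_)
        mean(d$nA_total[tot > 0] / tot[tot > 0])
      })
    )
    rownames(mean_df) <- NULL
  }
  structure(list(runs = runs, trajectories = traj, mean = mean_df,
                 M = M, seed = seed, params = params),
            class = "mlsel_ensemble")
}

#' @export
print.mlsel_ensemble <- function(x, ...) {
  cat(sprintf("mlsel ensemble: %d replicates, theta = %.3f, S = %.3f\n",
              x$M, theta_stat(x$runs), s_stat(x$runs)))
  invisible(x)
}

#' Two-parameter phase-portrait sweep
#'
#' Runs an `M`-replicate ensemble of the model in every cell of a
#' two-parameter grid and reduces each cell to the outcome statistics
#' [theta_stat()] and [s_stat()]. Axes may range over any of `mu`, `a`, `b`,
#' `K`, `Kg`, or `Ng` (the initial group count, consumed by the init
#' specification). Cell `(i, j)` (column-major index `c`) derives its seed
#' block as `seed + c * 1e5`, and replicate `i` within the block adds `i`,
#' so results are reproducible and extensible in `M`.
#'
#' @param params base [model_params()] object (axis parameters override it
#'   per cell).
#' @param xaxis,yaxis named lists `list(name = <parameter>, values =
#'   <numeric vector>)`.
#' @param init a function `function(par, Ng)` returning an initial population
#'   for a cell (called after seeding; `par` is the cell's parameter object,
#'   `Ng` the cell's initial group count), or a static population matrix.
#' @param Ng initial group count used when an axis does not set it.
#' @param M replicates per cell.
#' @param statistic composition statistic passed to [s_stat()].
#' @param progress print one line per grid column.
#' @return Object of class `mlsel_sweep` with `x`, `y` (axis values),
#'   `theta` and `s` matrices (`length(x)` rows, `length(y)` columns), and
#'   the run metadata.
#' @export
param_sweep <- function(params, xaxis, yaxis, init, Ng = NULL, M = 10,
                        statistic = c("group", "individual"),
                        progress = FALSE) {
  statistic <- match.arg(statistic)
  nx <- length(xaxis$values); ny <- length(yaxis$values)
  theta <- matrix(NA_real_, nx, ny)
  s <- matrix(NA_real_, nx, ny)
  for (jx in seq_len(nx)) {
    for (jy in seq_len(ny)) {
      cell <- (jy - 1L) * nx + jx
      par <- params
      ng_cell <- Ng
      xval <- xaxis$values[jx]
      yval <- yaxis$values[jy]
      if (xaxis$name == "Ng") ng_cell <- xval else par[[xaxis$name]] <- xval
      if (yaxis$name == "Ng") ng_cell <- yval else par[[yaxis$name]] <- yval
      par <- model_params(K = par$K, Kg = par$Kg, mu = par$mu, a = par$a,
                          b = par$b, mode = par$mode, T = par$T,
                          seed = par$seed)
      cell_seed <- as.integer((params$seed + cell * 1e5) %%
                                .Machine$integer.max)
      runs <- vector("list", M)
      for (i in seq_len(M)) {
        set.seed(replicate_seed(cell_seed, i))
        init_i <- if (is.function(init)) init(par, ng_cell) else init
        runs[[i]] <- run_model(par, init_i, record = FALSE, seed = NULL)
      }
      theta[jx, jy] <- theta_stat(runs)
      s[jx, jy] <- s_stat(runs, statistic)
    }
    if (progress)
      message(sprintf("sweep: %s = %g done (%d/%d)", xaxis$name,
                      xaxis$values[jx], jx, nx))
  }
  structure(list(x = xaxis$values, y = yaxis$values,
                 xname = xaxis$name, yname = yaxis$name,
                 theta = theta, s = s, M = M, statistic = statistic,
                 params = params, seed = params$seed),
            class = "mlsel_sweep")
}

#' @export
print.mlsel_sweep <- function(x, ...) {
  cat(sprintf("mlsel sweep: %d x %d grid over (%s, %s), M = %d\n",
              length(x$x), length(x$y), x$xname, x$yname, x$M))
  invisible(x)
}

#' Average of the composition statistic over one sweep axis
#'
#' Averages the per-cell `S` statistic over all values of the social
#' trait axis at each fixed value of the other axis, exposing the
#' non-monotone dependence of social survival on the cheater advantage `b`.
#'
#' @param sweep an [param_sweep()] result.
#' @param over which axis to average over, `"x"` or `"y"` (default the
#'   `a` axis if present, else `"x"`).
#' @return Named numeric vector indexed by the retained axis values.
#' @export
s_row_average <- function(sweep, over = NULL) {
  if (is.null(over))
    over <- if (identical(sweep$xname, "a")) "x"
            else if (identical(sweep$yname, "a")) "y" else "x"
  if (over == "x") {
    out <- colMeans(sweep$s)
    names(out) <- sweep$y
  } else {
    out <- rowMeans(sweep$s)
    names(out) <- sweep$x
  }
  out
}
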