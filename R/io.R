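config_schema <- list(
  model = c("K", "Kg", "mu", "a", "b", "mode", "T", "seed"),
  init = c("n_A", "n_B", "heterogeneous", "n_groups", "sizes"),
  biofilm = c("H", "D", "F", "r", "K_BF", "L", "dt", "dim", "n_side",
              "G_social_factor", "r_social_factor", "jitter_pos",
              "jitter_div"),
  experiment = c("M", "statistic", "xaxis", "yaxis")
)

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with optional blocks `model`, `init`,
#' `biofilm` and `experiment`, validates every key against the model's
#' admissible ranges (for example `b` must lie in `[1, 4]` so that the two
#' reproduction probabilities sum to at most 1), rejects unknown keys, and
#' returns fully populated parameter objects with defaults filled in.
#'
#' @param path path to a YAML file.
#' @return List with elements `model` ([model_params()], if a `model` block
#'   is present), `init` (validated init spec), `biofilm`
#'   ([biofilm_params()], if present), `experiment`, and `raw` (the parsed
#'   document).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown_blocks <- setdiff(names(raw), names(config_schema))
  if (length(unknown_blocks))
    stop("unknown config block(s): ", paste(unknown_blocks, collapse = ", "))
  for (blk in names(raw)) {
    bad <- setdiff(names(raw[[blk]]), config_schema[[blk]])
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s' block: %s (admissible: %s)", blk,
                   paste(bad, collapse = ", "),
                   paste(config_schema[[blk]], collapse = ", ")))
  }
  out <- list(raw = raw)
  if (!is.null(raw$model))
    out$model <- do.call(model_params, raw$model)
  if (!is.null(raw$init)) {
    init <- raw$init
    if (isTRUE(init$heterogeneous) && is.null(init$n_groups))
      stop("init: heterogeneous groups require 'n_groups'")
    out$init <- init
  }
  if (!is.null(raw$biofilm))
    out$biofilm <- do.call(biofilm_params, raw$biofilm)
  out$experiment <- raw$experiment
  out
}

#' Write a configuration back to YAML in canonical form
#'
#' @param config a list as returned by [load_config()] (its `raw` element is
#'   used) or a raw configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  raw <- if (!is.null(config$raw)) config$raw else config
  raw <- raw[intersect(names(config_schema), names(raw))]
  raw <- lapply(raw, function(blk) blk[order(names(blk))])
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Build a run manifest
#'
#' A manifest captures everything needed to re-derive an output file:
#' the full parameter block, the master seed and seed-splitting scheme,
#' package version and timestamp.
#'
#' @param params parameter object(s) (any list; classed objects are
#'   unclassed for serialization).
#' @param seed master seed.
#' @param M replicate count (optional).
#' @param files character vector of produced files (optional).
#' @return List of class `mlsel_manifest`.
#' @export
run_manifest <- function(params, seed, M = NULL, files = character()) {
  flat <- function(x) {
    if (is.list(x)) lapply(unclass(x)[!vapply(x, is.function, logical(1)) &
                                        !vapply(x, is.matrix, logical(1))],
                           flat)
    else x
  }
  structure(list(params = flat(params), seed = seed, M = M,
                 seed_scheme = "replicate i uses seed + i; sweep cell c uses seed + c*1e5",
                 package = "mlsel",
                 version = as.character(utils::packageVersion("mlsel")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 files = files),
            class = "mlsel_manifest")
}

#' Write simulation results with a manifest
#'
#' Serializes a [param_sweep()] result (statistic matrices plus axis
#' tables), a [trajectory_ensemble()] (long-format trajectory table), or a
#' plain data frame to CSV files with a JSON manifest, using stable column
#' order and deterministic names derived from `prefix`.
#'
#' @param result object to serialize.
#' @param out_dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param force overwrite existing files (default `FALSE`).
#' @return Character vector of written file paths (the manifest last),
#'   invisibly.
#' @export
write_results <- function(result, out_dir, prefix = "mlsel", force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  target <- function(name) {
    path <- file.path(out_dir, paste0(prefix, "_", name))
    if (file.exists(path) && !force)
      stop("refusing to overwrite ", path, " (use force = TRUE)")
    path
  }
  files <- character()
  if (inherits(result, "mlsel_sweep")) {
    f1 <- target("theta.csv"); f2 <- target("s.csv"); f3 <- target("axes.csv")
    write.csv(as.data.frame(result$theta), f1, row.names = FALSE)
    write.csv(as.data.frame(result$s), f2, row.names = FALSE)
    axes <- data.frame(
      axis = c(rep(result$xname, length(result$x)),
               rep(result$yname, length(result$y))),
      which = c(rep("x", length(result$x)), rep("y", length(result$y))),
      value = c(result$x, result$y))
    write.csv(axes, f3, row.names = FALSE)
    files <- c(f1, f2, f3)
    manifest <- run_manifest(result$params, result$seed, result$M, files)
  } else if (inherits(result, "mlsel_ensemble")) {
    f1 <- target("trajectories.csv")
    write.csv(result$trajectories, f1, row.names = FALSE)
    files <- f1
    manifest <- run_manifest(result$params, result$seed, result$M, files)
  } else if (is.data.frame(result)) {
    f1 <- target("table.csv")
    write.csv(result, f1, row.names = FALSE)
    files <- f1
    manifest <- run_manifest(list(), NA_integer_, NULL, files)
  } else {
    stop("unsupported result type: ", paste(class(result), collapse = "/"))
  }
  fm <- target("manifest.json")
  jsonlite::write_json(unclass(manifest), fm, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(files, fm))
}
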