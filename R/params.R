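#' Model parameters for the group-structured selection model
#'
#' Bundles and validates every parameter of the two-level selection model.
#' The constraint `b <= 4` guarantees that the two within-group reproduction
#' probabilities sum to at most 1 (their sum is maximal for a half-full all-B
#' group, where it equals `b/4`).
#'
#' @param K splitting threshold: number of sites per group (integer >= 2).
#' @param Kg environmental carrying capacity: maximum number of coexisting
#'   groups (integer >= 1). Group splitting is suppressed once `Kg` is reached.
#' @param mu per-step probability that any group-death event occurs, in
#'   `[0, 1]`.
#' @param a social trait strength in `[0, 1]`: factor by which a pure-A
#'   group's death weight is reduced.
#' @param b asocial reproduction scale factor in `[1, 4]`.
#' @param mode group-fitness regime: `"neutral"`, `"relative"` (death weights
#'   renormalized over all groups) or `"absolute"` (death probability of a
#'   group independent of the other groups).
#' @param T simulation horizon in time steps (integer >= 0).
#' @param seed RNG seed (integer), used by [run_model()] and the ensemble
#'   drivers.
#'
#' @return An object of class `mlsel_params` (a validated named list).
#' @seealso [run_model()], [sim_step()]
#' @export
#' @examples
#' model_params(K = 10, Kg = 50, mu = 0.6, a = 0.5, b = 2, mode = "relative")
model_params <- function(K = 10, Kg = 50, mu = 0.5, a = 0, b = 1,
                         mode = c("neutral", "relative", "absolute"),
                         T = 1000, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(
    "K must be an integer >= 2" = is.numeric(K) && K >= 2 && K == round(K),
    "Kg must be an integer >= 1" = is.numeric(Kg) && Kg >= 1 && Kg == round(Kg),
    "mu must lie in [0, 1]" = is.numeric(mu) && mu >= 0 && mu <= 1,
    "a must lie in [0, 1]" = is.numeric(a) && a >= 0 && a <= 1,
    "b must lie in [1, 4]" = is.numeric(b) && b >= 1 && b <= 4,
    "T must be an integer >= 0" = is.numeric(T) && T >= 0 && T == round(T)
  )
  structure(
    list(K = as.integer(K), Kg = as.integer(Kg), mu = mu, a = a, b = b,
         mode = mode, T = as.integer(T), seed = as.integer(seed)),
    class = "mlsel_params"
  )
}

mode_code <- function(mode) {
  match(mode, c("neutral", "relative", "absolute")) - 1L
}

#' @export
print.mlsel_params <- function(x, ...) {
  cat("Multilevel selection model parameters\n")
  cat(sprintf("  K = %d sites/group, Kg = %d groups max\n", x$K, x$Kg))
  cat(sprintf("  mu = %g, a = %g, b = %g, mode = %s\n", x$mu, x$a, x$b, x$mode))
  cat(sprintf("  horizon T = %d, seed = %d\n", x$T, x$seed))
  invisible(x)
}

#' Construct a population of groups
#'
#' A population is an integer matrix with one row per living group and columns
#' `nA` (social individuals) and `nB` (asocial individuals). Every group must
#' hold at least one individual and at most `K`; resources are implicit as
#' `K - nA - nB`.
#'
#' @param nA,nB integer vectors of per-group counts (recycled to a common
#'   length).
#' @param K splitting threshold used to validate group sizes (optional).
#' @return Integer matrix of class `mlsel_population`.
#' @export
#' @examples
#' population(nA = c(5, 0), nB = c(0, 3))
population <- function(nA, nB, K = NULL) {
  n <- max(length(nA), length(nB))
  groups <- cbind(nA = as.integer(rep_len(nA, n)),
                  nB = as.integer(rep_len(nB, n)))
  validate_population(groups, K)
  structure(groups, class = c("mlsel_population", "matrix", "array"))
}

validate_population <- function(groups, K = NULL) {
  if (!is.matrix(groups) || ncol(groups) != 2)
    stop("a population must be a two-column (nA, nB) matrix")
  if (any(groups < 0)) stop("group counts must be non-negative")
  sizes <- rowSums(groups)
  if (any(sizes < 1)) stop("empty groups are not allowed in a population")
  if (!is.null(K) && any(sizes > K))
    stop("group size exceeds the splitting threshold K")
  invisible(groups)
}

as_population <- function(groups) {
  structure(groups, class = c("mlsel_population", "matrix", "array"))
}

#' @export
print.mlsel_population <- function(x, ...) {
  cat(sprintf("Population of %d group(s): %d social, %d asocial individuals\n",
              nrow(x), sum(x[, "nA"]), sum(x[, "nB"])))
  if (nrow(x) > 0) print(unclass(x)[seq_len(min(nrow(x), 10L)), , drop = FALSE])
  if (nrow(x) > 10) cat(sprintf("  ... and %d more groups\n", nrow(x) - 10L))
  invisible(x)
}
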