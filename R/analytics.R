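#' Harmonic number
#'
#' `H_n = sum_{k=1}^{n} 1/k`, computed by direct summation (the regimes of
#' interest have `n` well below 1e4, so no asymptotic approximation is used).
#'
#' @param n non-negative integer (vectorized).
#' @return Numeric vector of harmonic numbers; `H_0 = 0`.
#' @export
harmonic <- function(n) {
  vapply(n, function(k) if (k < 1) 0 else sum(1 / seq_len(k)), numeric(1))
}

#' Probability of reaching the splitting threshold from size n
#'
#' For a single group whose per-step survival probability is held at `delta`
#' and whose size grows by one with probability `T_l = (b l / K)(1 - l/K)`,
#' the probability of reaching the absorbing threshold `K` before group death
#' is the birth-death hitting probability
#' \deqn{\psi_n = \prod_{l=n}^{K-1} \frac{\delta T_l}{1 - \delta + \delta T_l},}
#' with boundaries `psi_0 = 0` and `psi_K = 1`. The product is evaluated in
#' log space so that large `K` and small `delta` do not underflow.
#'
#' @param n initial group size(s), `0 <= n <= K` (vectorized).
#' @param delta per-step group survival probability in `[0, 1]`.
#' @param b reproduction scale factor.
#' @param K splitting threshold.
#' @return Numeric vector of hitting probabilities.
#' @export
#' @examples
#' psi_n(1:2, delta = 0.9, b = 1, K = 3)  # 4/9, 2/3
psi_n <- function(n, delta, b, K) {
  stopifnot(K >= 2, delta >= 0, delta <= 1, all(n >= 0), all(n <= K))
  if (delta == 1) return(ifelse(n >= 1, 1, 0))
  if (delta == 0) return(ifelse(n >= K, 1, 0))
  l <- seq_len(K - 1)                     # l = 1 .. K-1
  Tl <- (b * l / K) * (1 - l / K)
  logterm <- log(delta * Tl) - log(1 - delta + delta * Tl)
  logcum <- rev(cumsum(rev(logterm)))     # sum_{l=n}^{K-1}
  vapply(n, function(ni) {
    if (ni == 0) 0
    else if (ni >= K) 1
    else exp(logcum[ni])
  }, numeric(1))
}

#' Average probability of reaching the splitting threshold
#'
#' `psi_avg = (1/(K-1)) sum_{n=1}^{K-1} psi_n`, the threshold-hitting
#' probability averaged over all possible initial sizes (mirroring the
#' uniform allocation of a parent's individuals into daughters). Group
#' proliferation requires `psi_avg > 1/2`: a daughter must be more likely to
#' split again than to die.
#'
#' @inheritParams psi_n
#' @return Average hitting probability.
#' @export
psi_avg <- function(delta, b, K) {
  mean(psi_n(seq_len(K - 1), delta, b, K))
}

#' High-survival closed form of the average hitting probability
#'
#' First-order expansion of [psi_avg()] around `delta = 1`:
#' `1 - (1 - delta) H_{K-1} K^2 / (b (K - 1))` with `H` the harmonic number.
#'
#' @inheritParams psi_n
#' @return Approximate average hitting probability.
#' @export
psi_avg_high_survival <- function(delta, b, K) {
  1 - (1 - delta) * harmonic(K - 1) * K^2 / (b * (K - 1))
}

#' Critical survival probability and neutral proliferation threshold
#'
#' `delta_star(b, K)` is the survival probability at which the high-survival
#' average hitting probability equals 1/2:
#' `delta* = 1 - (K-1) b / (2 H_{K-1} K^2)`. Substituting
#' `delta = 1 - mu/Ng` gives the neutral proliferation threshold
#' `mu* = Ng (K-1) b / (2 H_{K-1} K^2)`: populations with `mu` below it
#' proliferate on average, above it they tend to extinction.
#'
#' @param b reproduction scale factor in `[1, 4]`.
#' @param K splitting threshold (>= 2).
#' @param Ng initial number of groups.
#' @return `delta_star()`: critical survival probability.
#'   `neutral_threshold_mu()`: critical death probability, with a warning
#'   (and attribute `in_domain = FALSE`) if it exceeds 1, i.e. lies outside
#'   the model's parameter range.
#' @export
#' @examples
#' neutral_threshold_mu(Ng = 50, b = 1, K = 10)  # ~0.7954
delta_star <- function(b, K) {
  1 - (K - 1) * b / (2 * harmonic(K - 1) * K^2)
}

#' @rdname delta_star
#' @export
neutral_threshold_mu <- function(Ng, b, K) {
  mu <- Ng * (K - 1) * b / (2 * harmonic(K - 1) * K^2)
  if (any(mu > 1)) {
    warning("threshold mu exceeds 1: parameter regime outside the model")
    attr(mu, "in_domain") <- mu <= 1
  }
  mu
}

#' Survival probabilities of homogeneous all-A and all-B groups
#'
#' Per-step survival probabilities for homogeneous groups in a population of
#' `Ng` groups of which `NgA` are all-A. Relative mode:
#' `delta_A = 1 - mu (1-a) / (Ng - a NgA)` and
#' `delta_B = 1 - mu / (Ng - a NgA)` (each group's fate depends on the whole
#' population's composition). Absolute mode: `delta_A = 1 - mu (1-a) / Ng`,
#' `delta_B = 1 - mu / Ng` (composition-independent; the social trait rescales
#' `mu` to `mu (1-a)`).
#'
#' @param mode `"relative"` or `"absolute"`.
#' @param mu group-death event probability.
#' @param a social trait strength.
#' @param Ng total number of groups.
#' @param NgA number of all-A groups (`0 <= NgA <= Ng`).
#' @return Named numeric vector `c(delta_A, delta_B)`.
#' @export
#' @examples
#' survival_probs("relative", mu = 0.7, a = 0.5, Ng = 20, NgA = 10)
survival_probs <- function(mode = c("relative", "absolute"), mu, a, Ng, NgA) {
  mode <- match.arg(mode)
  stopifnot(NgA >= 0, NgA <= Ng)
  if (mode == "relative") {
    denom <- Ng - a * NgA
    if (denom <= 0)
      stop("relative mode undefined: Ng - a * NgA must be positive")
    c(delta_A = 1 - mu * (1 - a) / denom, delta_B = 1 - mu / denom)
  } else {
    c(delta_A = 1 - mu * (1 - a) / Ng, delta_B = 1 - mu / Ng)
  }
}

#' High-survival threshold curves for the social trait and cheater advantage
#'
#' Threshold values solving `psi_A = psi_B = 1/2` in the high-survival limit.
#' Relative mode:
#' `a* = ((K-1) Ng - 2 mu H K^2) / ((K-1) NgA - 2 mu H K^2)` (independent of
#' `b`) and `b*(a) = 2 mu H K^2 / ((K-1)(Ng - a NgA))`. Absolute mode:
#' `a* = 1 - (K-1) Ng / (2 mu H K^2)` and `b* = 2 mu H K^2 / ((K-1) Ng)`
#' (both constants). `H = H_{K-1}` is the harmonic number. Values outside the
#' model domain (`a` in `[0,1]`, `b` in `[1,4]`) are returned with an
#' `in_domain` flag rather than an error.
#'
#' @inheritParams survival_probs
#' @param K splitting threshold.
#' @return List with `a_star` (scalar), `b_star` (a function of `a`; constant
#'   in absolute mode), and logical `a_star_in_domain`.
#' @export
#' @examples
#' threshold_curves("absolute", mu = 0.7, K = 10, Ng = 20)$a_star  # ~0.5455
threshold_curves <- function(mode = c("relative", "absolute"), mu, K, Ng,
                             NgA = NULL) {
  mode <- match.arg(mode)
  HK2 <- 2 * mu * harmonic(K - 1) * K^2
  if (mode == "relative") {
    if (is.null(NgA)) stop("relative mode requires NgA")
    a_star <- ((K - 1) * Ng - HK2) / ((K - 1) * NgA - HK2)
    b_star <- function(a) HK2 / ((K - 1) * (Ng - a * NgA))
  } else {
    a_star <- 1 - (K - 1) * Ng / HK2
    b_star <- local({
      val <- HK2 / ((K - 1) * Ng)
      function(a) rep_len(val, length(a))
    })
  }
  list(a_star = a_star, b_star = b_star,
       a_star_in_domain = is.finite(a_star) && a_star >= 0 && a_star <= 1)
}

#' Numeric proliferation threshold without the high-survival approximation
#'
#' Solves a hitting-probability condition (`psi_avg = 1/2` for the neutral
#' case, `psi_A = 1/2` or `psi_B = 1/2` for homogeneous social/asocial
#' groups) for one free parameter by bracketed bisection on the physical
#' parameter range. The survival probability entering the recursion is
#' `1 - mu/Ng` (neutral) or the matching component of [survival_probs()];
#' `psi_A` uses `b = 1` (all-A groups reproduce at the base rate), `psi_B`
#' uses the supplied `b`.
#'
#' @param solve_for one of `"mu"`, `"Ng"`, `"a"`, `"b"` — the parameter to
#'   solve for (its supplied value, if any, is ignored).
#' @param target `"psi_avg"`, `"psi_A"` or `"psi_B"`.
#' @param mode fitness mode used for `psi_A` / `psi_B` targets.
#' @param mu,a,b,K,Ng,NgA fixed model parameters.
#' @param bracket length-2 numeric search interval; defaults to the physical
#'   range of `solve_for` (`mu` in `[0,1]`, `a` in `[0,1]`, `b` in `[1,4]`,
#'   `Ng` in `[1, 1e6]`).
#' @param tol bisection tolerance on the parameter (default `1e-10`).
#' @return The threshold value. Errors with "no threshold in range" when the
#'   condition does not change sign over the bracket.
#' @export
#' @examples
#' mu_star <- numeric_threshold("mu", "psi_avg", Ng = 50, b = 1, K = 10)
numeric_threshold <- function(solve_for = c("mu", "Ng", "a", "b"),
                              target = c("psi_avg", "psi_A", "psi_B"),
                              mode = c("relative", "absolute"),
                              mu = NULL, a = NULL, b = 1, K, Ng = NULL,
                              NgA = NULL, bracket = NULL, tol = 1e-10) {
  solve_for <- match.arg(solve_for)
  target <- match.arg(target)
  mode <- match.arg(mode)

  objective <- function(x) {
    par <- list(mu = mu, a = a, b = b, Ng = Ng, NgA = NgA)
    par[[solve_for]] <- x
    if (target == "psi_avg") {
      delta <- 1 - par$mu / par$Ng
      psi_avg(max(0, min(1, delta)), par$b, K) - 0.5
    } else {
      sp <- survival_probs(mode, par$mu, par$a, par$Ng, par$NgA)
      delta <- if (target == "psi_A") sp[["delta_A"]] else sp[["delta_B"]]
      b_eff <- if (target == "psi_A") 1 else par$b
      psi_avg(max(0, min(1, delta)), b_eff, K) - 0.5
    }
  }

  if (is.null(bracket))
    bracket <- switch(solve_for, mu = c(0, 1), a = c(0, 1), b = c(1, 4),
                      Ng = c(1, 1e6))
  lo <- bracket[1]; hi <- bracket[2]
  flo <- objective(lo); fhi <- objective(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop("no threshold in range [", lo, ", ", hi, "]")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fmid <- objective(mid)
    if (fmid == 0) return(mid)
    if (flo * fmid < 0) { hi <- mid; fhi <- fmid } else { lo <- mid; flo <- fmid }
  }
  (lo + hi) / 2
}

#' Moran-limit transition probabilities between homogeneous group states
#'
#' In the rare-death limit (`mu << 1`) with the population at carrying
#' capacity `Kg` and all groups homogeneous, one step of the group-level
#' dynamics changes the all-A group count `NgA` by at most one. Relative
#' mode: `T_down = mu ((Kg-NgA)/Kg) NgA(1-a) / (NgA(1-a) + Kg - NgA)` and
#' `T_up = mu (NgA/Kg) (Kg-NgA) / (NgA(1-a) + Kg - NgA)` (a B group splits
#' and an A group dies, or vice versa). Absolute mode:
#' `T_down = mu (1-a) (NgA/Kg)((Kg-NgA)/Kg)`,
#' `T_up = mu (NgA/Kg)((Kg-NgA)/Kg)`. In both modes
#' `T_down / T_up = 1 - a`, so fixation depends only on `a`, not on `mu` or
#' the mode.
#'
#' @param NgA all-A group count(s), `0 <= NgA <= Kg` (vectorized).
#' @param Kg group carrying capacity.
#' @param mu group-death probability.
#' @param a social trait strength.
#' @param mode `"relative"` or `"absolute"`.
#' @return Data frame with columns `NgA`, `T_down`, `T_up`.
#' @export
moran_transitions <- function(NgA, Kg, mu, a,
                              mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(all(NgA >= 0), all(NgA <= Kg))
  fB <- (Kg - NgA) / Kg
  fA <- NgA / Kg
  if (mode == "relative") {
    denom <- NgA * (1 - a) + (Kg - NgA)
    T_down <- ifelse(denom > 0, mu * fB * NgA * (1 - a) / denom, 0)
    T_up <- ifelse(denom > 0, mu * fA * (Kg - NgA) / denom, 0)
  } else {
    T_down <- mu * (1 - a) * fA * fB
    T_up <- mu * fA * fB
  }
  data.frame(NgA = NgA, T_down = T_down, T_up = T_up)
}

#' Fixation probability of the social trait in the Moran limit
#'
#' The group-level birth-death chain of [moran_transitions()] has constant
#' backward/forward ratio `gamma = 1 - a`, so the probability that all-A
#' groups take over starting from `NgA0` of `Kg` is the standard gambler's
#' ruin expression `rho = (1 - gamma^NgA0) / (1 - gamma^Kg)`, reducing to
#' `NgA0 / Kg` for `a = 0`. (This closed form is the textbook consequence of
#' the constant transition ratio; the test suite cross-validates it against a
#' direct linear solve of the chain's absorption system.)
#'
#' @param NgA0 initial all-A group count (vectorized).
#' @param Kg group carrying capacity.
#' @param a social trait strength.
#' @return Fixation probability of the all-A state.
#' @export
#' @examples
#' fixation_prob_moran(1, Kg = 10, a = 0.5)  # ~0.50049
fixation_prob_moran <- function(NgA0, Kg, a) {
  stopifnot(all(NgA0 >= 0), all(NgA0 <= Kg), a >= 0, a <= 1)
  if (a == 0) return(NgA0 / Kg)
  g <- 1 - a
  (1 - g^NgA0) / (1 - g^Kg)
}
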