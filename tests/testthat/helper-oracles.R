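# Independent oracles used to cross-check the closed-form/package routes.

# Hitting probability of state K before 0 for the single-group size chain,
# solved as a plain linear system over the full transition matrix (states
# 0..K; per step the group dies w.p. 1-delta, grows w.p. delta*T_n, stays
# otherwise). Independent of the product formula in psi_n().
psi_linear_solve <- function(delta, b, K) {
  states <- 0:K
  P <- matrix(0, K + 1, K + 1)
  P[1, 1] <- 1                     # absorbed: dead
  P[K + 1, K + 1] <- 1             # absorbed: splitting threshold
  for (n in 1:(K - 1)) {
    Tn <- (b * n / K) * (1 - n / K)
    P[n + 1, 1] <- P[n + 1, 1] + (1 - delta)
    P[n + 1, n + 2] <- delta * Tn
    P[n + 1, n + 1] <- P[n + 1, n + 1] + delta * (1 - Tn)
  }
  # absorption probabilities h = P h with h(0)=0, h(K)=1
  trans <- 2:K
  Q <- P[trans, trans, drop = FALSE]
  rhs <- P[trans, K + 1]
  h <- solve(diag(K - 1) - Q, rhs)
  c(0, h, 1)                       # indexed by n = 0..K
}

# Absorption probability of the all-A state for a birth-death chain on
# NgA = 0..Kg with given per-state up/down probabilities, by linear solve.
chain_fixation_solve <- function(T_up, T_down, Kg) {
  stopifnot(length(T_up) == Kg + 1, length(T_down) == Kg + 1)
  if (Kg == 1) return(c(0, 1))
  idx <- 2:Kg                      # transient states 1..Kg-1
  A <- matrix(0, Kg - 1, Kg - 1)
  rhs <- numeric(Kg - 1)
  for (s in idx) {
    i <- s - 1
    up <- T_up[s]; dn <- T_down[s]
    A[i, i] <- up + dn
    if (s - 1 >= 2) A[i, i - 1] <- -dn
    if (s + 1 <= Kg) A[i, i + 1] <- -up
    if (s + 1 == Kg + 1) rhs[i] <- up
  }
  h <- solve(A, rhs)
  c(0, h, 1)
}

expect_within_3sigma <- function(observed_count, n, p_expected) {
  sigma <- sqrt(n * p_expected * (1 - p_expected))
  expect_lt(abs(observed_count - n * p_expected), 3 * sigma + 1e-9)
}
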