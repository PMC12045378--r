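# Agent-based biofilm model.

test_that("biofilm parameters satisfy the calibration identities", {
  p <- biofilm_params()
  expect_equal(p$H / p$D^6 - p$G_asocial / p$D^2, 0)
  expect_equal(p$G_social, 100 * p$G_asocial)
  expect_equal(p$r_social, p$r_asocial / 5)
  expect_equal(p$r_asocial, log(2))
  expect_equal(nrow(p$anchors), 400L)
  p2 <- biofilm_params(dim = 2)
  expect_equal(nrow(p2$anchors), 20L)
})

test_that("pairwise pseudo-forces vanish at D, repel below, attract above", {
  p <- biofilm_params()
  far <- 1e6  # isolate the pair from the substrate terms
  at_d <- biofilm_state(rbind(c(10, 10, far), c(11, 10, far)), c(FALSE, FALSE))
  f <- pseudo_force(at_d, p)$force
  expect_lt(max(abs(f[, 1:2])), 1e-12)
  # at D/2 the 1/d^6 term dominates: cells pushed apart
  close <- biofilm_state(rbind(c(10, 10, far), c(10.5, 10, far)), c(FALSE, FALSE))
  fc <- pseudo_force(close, p)$force
  expect_lt(fc[1, 1], 0); expect_gt(fc[2, 1], 0)
  expect_equal(fc[1, 1], -(p$H / 0.5^6 - p$G_asocial / 0.5^2) / 0.5 * 0.5)
  # beyond D the attraction wins
  apart <- biofilm_state(rbind(c(10, 10, far), c(12, 10, far)), c(FALSE, FALSE))
  fa <- pseudo_force(apart, p)$force
  expect_gt(fa[1, 1], 0); expect_lt(fa[2, 1], 0)
  # Newton's third law for the pair terms
  expect_equal(fa[1, ], -fa[2, ])
})

test_that("an isolated cell is attracted toward the substrate from above", {
  p <- biofilm_params()
  # directly above one anchor, beyond the cell-anchor equilibrium distance
  above <- biofilm_state(matrix(c(10, 10, 3), 1), FALSE)
  f <- pseudo_force(above, p)$force
  expect_lt(f[1, 3], 0)
})

test_that("the predation interface is the top cell of each occupied window", {
  p <- biofilm_params()
  # all cells in one window: exactly one interface cell (the highest)
  stack <- biofilm_state(rbind(c(10.1, 10.1, 0.5), c(10.2, 10.2, 2.0),
                               c(10.3, 10.3, 1.0)), rep(FALSE, 3))
  expect_identical(predation_interface(stack, p), 2L)
  # one cell per window: every cell is exposed
  spread <- biofilm_state(cbind(seq(2.5, 11.5, 1), 10.5, 0.3), rep(FALSE, 10))
  expect_identical(predation_interface(spread, p), 1:10)
  # a flat monolayer exposes more cells than a tower of the same size
  mono <- biofilm_state(cbind(seq(2.5, 11.5, 1), 10.5, 0.3), rep(FALSE, 10))
  tower <- biofilm_state(cbind(10.5, 10.5, seq(0.3, 9.3, 1)), rep(FALSE, 10))
  expect_gt(length(predation_interface(mono, p)),
            length(predation_interface(tower, p)))
})

test_that("motion keeps the fixed step length and the reflective boundary", {
  p <- biofilm_params()
  set.seed(5)
  n <- 40
  st <- biofilm_state(cbind(runif(n, 5, 15), runif(n, 5, 15), runif(n, 0, 0.2)),
                      rep(FALSE, n))
  # F = 1: purely random unit direction, step length D regardless of forces
  out <- biofilm_run(st, p, 1, F = 1, divide = FALSE, remove = FALSE)
  disp <- sqrt(rowSums((out$positions - st$positions)^2))
  # reflection can shorten the apparent displacement; cells away from the
  # substrate must move exactly D (up to the uniqueness jitter)
  interior <- st$positions[, 3] > p$D & out$positions[, 3] > 0
  expect_true(all(abs(disp - p$D) < 1e-4 | !interior))
  expect_true(all(out$positions[, 3] >= 0))
  # many steps never drive a cell below the substrate
  out2 <- biofilm_run(st, p, 50, divide = FALSE, remove = FALSE)
  expect_true(all(out2$positions[, 3] >= 0))
  expect_equal(nrow(out2$positions), n)  # no births or deaths when disabled
})

test_that("division is logistic, phenotype-specific and 5-fold slower for ECM producers", {
  p <- biofilm_params()
  # at carrying capacity the expected division count is zero
  set.seed(6)
  full <- biofilm_state(cbind(runif(500, 0, 20), runif(500, 0, 20),
                              runif(500, 0, 3)), rep(FALSE, 500))
  out <- biofilm_run(full, p, 30, move = FALSE, remove = FALSE)
  expect_equal(nrow(out$positions), 500L)

  # far from capacity: per-capita division rates r and r/5
  set.seed(7)
  mix <- biofilm_state(cbind(runif(100, 0, 20), runif(100, 0, 20),
                             runif(100, 0, 2)),
                       rep(c(TRUE, FALSE), each = 50))
  # short independent bursts keep the logistic factor near its initial value
  tot_s <- 0; tot_a <- 0; steps <- 40; reps <- 40
  for (rep in seq_len(reps)) {
    out <- biofilm_run(mix, p, steps, move = FALSE, remove = FALSE)
    tot_s <- tot_s + sum(out$social) - 50
    tot_a <- tot_a + sum(!out$social) - 50
  }
  # expected asocial births per burst: ~ 50 r (1 - 0.2) dt * 40 = 11
  exp_a <- 50 * p$r_asocial * 0.8 * p$dt * steps * reps
  expect_lt(abs(tot_a - exp_a), 4 * sqrt(exp_a) + 0.1 * exp_a)
  # per-capita division rate ratio 5:1 (within sampling error of the
  # smaller social count)
  expect_gt(tot_a / tot_s, 3.5)
  expect_lt(tot_a / tot_s, 7)
})

test_that("removal draws only from the predation interface", {
  p <- biofilm_params(L = 0)
  set.seed(8)
  st <- biofilm_state(cbind(runif(30, 8, 12), runif(30, 8, 12),
                            runif(30, 0, 2)), rep(FALSE, 30))
  out <- biofilm_run(st, p, 50, move = FALSE, divide = FALSE)
  expect_equal(nrow(out$positions), 30L)  # L = 0: no removal

  # stacked column: the bottom cells are shielded
  p2 <- biofilm_params(L = 10)           # high rate to force removals
  col <- biofilm_state(rbind(c(10.5, 10.5, 0.1), c(10.5, 10.5, 1.1),
                             c(10.5, 10.5, 2.1)), rep(FALSE, 3))
  set.seed(9)
  out2 <- biofilm_run(col, p2, 1, move = FALSE, divide = FALSE)
  # at most one cell (the top one) can be removed in a single step
  expect_gte(nrow(out2$positions), 2L)
  expect_true(any(abs(out2$positions[, 3] - 0.1) < 1e-9))
})

test_that("an ECM mutant is buried below the predation interface", {
  # the social trait's group benefit in the biofilm: cohesion pulls the
  # mutant under its neighbors, so its interface exposure falls well below
  # both the colony-average exposure and the division-cost break-even
  # threshold (m/N)/5
  p <- biofilm_params(K_BF = 300, n_side = 16, L = 1)
  ss <- run_steady_state(p, n0 = 300, "asocial", relax_steps = 300,
                         steps = 3000, seed = 5)
  N <- nrow(ss$positions)
  m <- length(predation_interface(ss, p))
  soc <- rep(FALSE, N)
  set.seed(6)
  soc[sample.int(N, 1)] <- TRUE
  st <- biofilm_state(ss$positions, soc)
  hits <- 0
  for (k in 1:100) {
    st <- biofilm_run(st, p, 50, divide = FALSE, remove = FALSE)
    hits <- hits + (which(st$social) %in% predation_interface(st, p))
  }
  exposure <- hits / 100
  expect_lt(exposure, (m / N) / 5)   # protected beyond the division cost
  expect_lt(exposure, (m / N) / 2)   # and far below average exposure
})

test_that("a neutral-trait mutant fixes at the 1/N drift rate", {
  # with the ECM effects switched off the phenotype labels are exchangeable
  p <- biofilm_params(dim = 2, K_BF = 12, G_social_factor = 1,
                      r_social_factor = 1)
  set.seed(10)
  base <- run_steady_state(p, n0 = 12, "asocial", relax_steps = 100,
                           steps = 500, seed = 10)
  n <- nrow(base$positions)
  fixed <- 0; decided <- 0
  for (i in 1:200) {
    fx <- run_fixation(p, base, max_steps = 60000, seed = 400 + i)
    if (!is.na(fx$fixed)) {
      decided <- decided + 1
      fixed <- fixed + fx$fixed
    }
  }
  expect_gt(decided, 190)
  expect_within_3sigma(fixed, decided, 1 / n)
})

test_that("seeding without predation always founds a colony", {
  p <- biofilm_params(L = 0, dim = 2)
  for (i in 1:3) {
    r <- run_seeding(p, "social", stop_size = 30, max_steps = 200000,
                     seed = 50 + i)
    expect_true(isTRUE(r$survived))
  }
})
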