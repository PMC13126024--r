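test_that("parameter validation rejects unphysical inputs", {
  expect_error(mechanism_params(-1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
               "rate constants")
  expect_error(mechanism_params(1, 1, 1, 1, 1, 1, 1, 1, 0, 1, 1),
               "> 0")
  expect_error(mechanism_params(1, 1, 1, 1, 1, 1, 0, 1, 1, 1, 1),
               "K_mg")
  expect_error(simulate_mechanism(default_mechanism_params(), c(5, 5)),
               "strictly increasing")
})

test_that("Mg scaling is a rectangular hyperbola with its midpoint at K_mg", {
  expect_equal(mg_scaled_rate(10, 2.5, 2.5), 5)        # [Mg] = K_mg: half max
  expect_equal(mg_scaled_rate(10, 1e9, 2.5), 10, tolerance = 1e-8)
  expect_equal(mg_scaled_rate(10, 0, 2.5), 0)
})

test_that("without an abortive branch all DNA ends as sealed product", {
  p <- mechanism_params(k_bind = 0.1, k_close = 20, k_open = 1.5,
                        k_diss = 0, k_transfer_max = 20, k_seal_max = 20,
                        K_mg_step2 = 0.1, K_mg_step3 = 1,
                        enzyme_total = 5, dna_total = 100, mg_free = 1)
  tc <- simulate_mechanism(p, times = c(10, 100, 2000))
  last <- tc[nrow(tc), ]
  expect_lt(last$F_i, 1e-8)
  expect_equal(last$F_p, 1, tolerance = 1e-7)
})

test_that("noiseless trajectories conserve mass and grow product monotonically", {
  p <- default_mechanism_params("K845N", "8oxoG:A", mg_free = 0.3,
                                enzyme_total = 2, dna_total = 500)
  tc <- simulate_mechanism(p, times = c(1, 5, 20, 50, 150, 400, 1000, 4000))
  expect_true(all(abs(tc$F_s + tc$F_i + tc$F_p - 1) <= 1e-8))
  expect_true(all(tc$F_p >= 0 & tc$F_p <= 1))
  expect_true(all(diff(tc$F_p) > -1e-10))
})

test_that("long-time branching matches the analytic absorbing-state oracle", {
  # constructed case: post-transfer open-state exit rates equal and
  # opening dominant, so the abortive split is large and analytic
  p <- mechanism_params(k_bind = 0.5, k_close = 1, k_open = 30,
                        k_diss = 8, k_transfer_max = 50, k_seal_max = 8,
                        K_mg_step2 = 0.1, K_mg_step3 = 0.5,
                        enzyme_total = 100, dna_total = 100, mg_free = 1e7)
  # mg saturating: effective k_seal = k_seal_max = k_diss
  tc <- simulate_mechanism(p, times = c(10, 5000))
  last <- tc[nrow(tc), ]
  f_abort_sim <- last$F_i / (last$F_i + last$F_p)
  expect_gt(last$F_i + last$F_p, 1 - 1e-9)   # fully absorbed
  oracle <- branching_oracle(p)
  expect_equal(f_abort_sim, unname(oracle["abort"]), tolerance = 1e-6)

  # property: >= 20 random schemes, relative error <= 1e-5
  set.seed(42)
  for (i in 1:20) {
    q <- mechanism_params(
      k_bind = runif(1, 0.05, 1), k_close = runif(1, 1, 50),
      k_open = runif(1, 0.5, 30), k_diss = runif(1, 0.5, 30),
      k_transfer_max = runif(1, 1, 50), k_seal_max = runif(1, 1, 50),
      K_mg_step2 = runif(1, 0.1, 2), K_mg_step3 = runif(1, 0.1, 2),
      enzyme_total = 200, dna_total = 100, mg_free = runif(1, 0.2, 5))
    T_end <- 3000
    repeat {
      tc <- simulate_mechanism(q, times = c(T_end / 2, T_end))
      last <- tc[nrow(tc), ]
      if (last$F_i + last$F_p > 1 - 1e-9 || T_end > 1e6) break
      T_end <- T_end * 10
    }
    f_sim <- last$F_i / (last$F_i + last$F_p)
    f_or <- unname(branching_oracle(q)["abort"])
    expect_equal(f_sim, f_or, tolerance = 1e-5)
    expect_true(all(abs(tc$F_s + tc$F_i + tc$F_p - 1) <= 1e-8))
  }
})

test_that("a pseudo-first-order trajectory matches a matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  # enzyme in vast excess: the DNA states follow a linear master equation
  # whose exact solution is expm(Q t); an independent route to the full
  # time course, not just its endpoint
  p <- mechanism_params(k_bind = 0.001, k_close = 5, k_open = 2,
                        k_diss = 3, k_transfer_max = 10, k_seal_max = 4,
                        K_mg_step2 = 0.2, K_mg_step3 = 1,
                        enzyme_total = 1e5, dna_total = 1, mg_free = 0.8)
  k2 <- 10 * 0.8 / (0.2 + 0.8); k3 <- 4 * 0.8 / (1 + 0.8)
  kbE <- 0.001 * 1e5
  # states: S, oES, cES, cEI, oEI, I, P (enzyme constant)
  Q <- matrix(0, 7, 7)
  Q[1, 2] <- kbE
  Q[2, 1] <- 3; Q[2, 3] <- 5
  Q[3, 2] <- 2; Q[3, 4] <- k2
  Q[4, 5] <- 2; Q[4, 7] <- k3
  Q[5, 4] <- 5; Q[5, 6] <- 3
  diag(Q) <- -rowSums(Q)
  times <- c(0.02, 0.1, 0.5, 2)
  tc <- simulate_mechanism(p, times)
  for (j in seq_along(times)) {
    probs <- as.numeric(c(1, rep(0, 6)) %*%
                          Matrix::expm(Q * times[j]))
    # 1e5-fold enzyme excess leaves a ~1e-5 pseudo-first-order bias
    expect_equal(tc$F_s[j], sum(probs[1:3]), tolerance = 1e-4)
    expect_equal(tc$F_i[j], sum(probs[4:6]), tolerance = 1e-4)
    expect_equal(tc$F_p[j], probs[7], tolerance = 1e-4)
  }
})

test_that("abortive ligation rises with intermediate release rate and falling Mg2+", {
  base <- list(k_bind = 0.1, k_close = 20, k_open = 2, k_diss = 4,
               k_transfer_max = 20, k_seal_max = 20,
               K_mg_step2 = 0.1, K_mg_step3 = 1.5)
  f_abort_at <- function(k_diss, mg) {
    p <- mechanism_params(base$k_bind, base$k_close, base$k_open, k_diss,
                          base$k_transfer_max, base$k_seal_max,
                          base$K_mg_step2, base$K_mg_step3,
                          enzyme_total = 100, dna_total = 100, mg_free = mg)
    tc <- simulate_mechanism(p, times = c(100, 8000))
    last <- tc[nrow(tc), ]
    last$F_i / (last$F_i + last$F_p)
  }
  # strictly increasing in k_diss at fixed Mg
  fa <- vapply(c(1, 4, 16, 64), f_abort_at, numeric(1), mg = 1)
  expect_true(all(diff(fa) > 0))
  # strictly increasing as Mg2+ falls (K_mg_step3 > K_mg_step2)
  fm <- vapply(c(5, 1, 0.4, 0.1), f_abort_at, numeric(1), k_diss = 4)
  expect_true(all(diff(fm) > 0))
})

test_that("the stochastic backend agrees with the ODE solution in bulk", {
  p <- default_mechanism_params("WT", "C:G", mg_free = 1,
                                enzyme_total = 10, dna_total = 100)
  times <- c(20, 60, 150)
  det <- simulate_mechanism(p, times)
  sto <- simulate_mechanism(p, times, method = "stochastic",
                            n_molecules = 5000L, seed = 11)
  expect_equal(sto$F_p, det$F_p, tolerance = 0.05)
  # determinism under a fixed seed
  sto2 <- simulate_mechanism(p, times, method = "stochastic",
                             n_molecules = 5000L, seed = 11)
  expect_identical(sto$F_p, sto2$F_p)
})
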