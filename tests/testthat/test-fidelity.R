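test_that("quadrature propagation matches hand-computed chains", {
  one <- propagate_quadrature(5, 0.4)
  expect_equal(unname(one), c(5, 0.4))                      # identity

  prod2 <- propagate_quadrature(c(2, 3), c(0.2, 0.3))
  expect_equal(unname(prod2["value"]), 6)
  expect_equal(unname(prod2["SE"]), 6 * sqrt(0.01 + 0.01), tolerance = 1e-12)

  ratio <- propagate_quadrature(c(60, 13.9), c(6, 1.7), ops = "/")
  expect_equal(unname(ratio["value"]), 60 / 13.9, tolerance = 1e-12)
  rel <- sqrt((6 / 60)^2 + (1.7 / 13.9)^2)
  expect_equal(unname(ratio["SE"]), 60 / 13.9 * rel, tolerance = 1e-12)

  expect_error(propagate_quadrature(c(2, -1), c(0.1, 0.1)), "> 0")
  expect_error(propagate_quadrature(c(2, 3), c(0.1, 0.1), ops = "+"),
               "\\*")
})

test_that("quadrature SEs track a large Monte-Carlo propagation", {
  # the sum-of-squares rule is the first-order result for multiplicative
  # (log-normally approximated) errors, so the oracle samples that model:
  # median-matched log-normal inputs with SD/mean = CV, spread summarised
  # by the central-68% half-width (the MC analogue of one SE; moment SDs
  # of ratio chains are tail-dominated)
  set.seed(12)
  n_mc <- 1e5
  for (rep in 1:6) {
    m <- sample(2:4, 1)
    vals <- 10^runif(m, -1, 2)
    cvs <- runif(m, 0.02, 0.3)
    ops <- sample(c("*", "/"), m - 1, replace = TRUE)
    q <- propagate_quadrature(vals, vals * cvs, ops = ops)
    sdlog <- sqrt(log(1 + cvs^2))
    draws <- matrix(rlnorm(n_mc * m, rep(log(vals), each = n_mc),
                           rep(sdlog, each = n_mc)), ncol = m)
    res <- draws[, 1]
    for (k in 2:m) {
      res <- if (ops[k - 1] == "*") res * draws[, k] else res / draws[, k]
    }
    spread <- diff(quantile(res, pnorm(c(-1, 1)), names = FALSE)) / 2
    expect_equal(unname(q["SE"]), spread, tolerance = 0.10)
  }
})

test_that("discrimination operations reproduce the published arithmetic", {
  # overall fidelity enhancement on lowering Mg2+ from 1.0 to 0.2 mM:
  # 110-fold over 5.1-fold, reported as ~21-fold
  enh <- propagate_quadrature(c(110, 5.1), c(0, 0), ops = "/")
  expect_equal(unname(enh["value"]), 110 / 5.1, tolerance = 1e-12)
  expect_equal(unname(enh["value"]), 21.57, tolerance = 1e-3)

  eq <- discrimination_overall(3, 3, 0.3, 0.3)
  expect_equal(eq$value, 1)
  expect_equal(eq$SE, sqrt(0.02), tolerance = 1e-12)

  r <- discrimination_overall(10, 2, 1, 0.2)
  expect_equal(r$value, 5)
  expect_equal(r$SE, 5 * sqrt(0.02), tolerance = 1e-12)

  # step 3 from sealed fractions: WT at 0.2 mM
  s3 <- discrimination_step3(0.96, 0.12)
  expect_equal(s3$value, 8)
  expect_equal(discrimination_step3(0.5, 0.5)$value, 1)
  # WT at 1.0 mM
  expect_equal(discrimination_step3(0.98, 0.49)$value, 2)

  # step 2 via the factorisation identity: WT at 1.0 mM
  s2 <- discrimination_step2(5.1, 2.0)
  expect_equal(s2$value, 2.55)

  s2b <- discrimination_step2(60, 13.9, 6, 1.7)
  expect_equal(s2b$value, 60 / 13.9, tolerance = 1e-12)   # 4.32
  expect_equal(signif(s2b$value, 3), 4.32)
  expect_equal(s2b$SE, 60 / 13.9 * sqrt((6 / 60)^2 + (1.7 / 13.9)^2),
               tolerance = 1e-9)                           # 0.68

  expect_equal(discrimination_step2(4, 4)$value, 1)
  expect_error(discrimination_overall(0, 2), "> 0")
})

test_that("a zero damaged sealed fraction yields a censored bound", {
  s3 <- discrimination_step3(0.9, 0, detection_limit = 0.01)
  expect_true(s3$censored)
  expect_equal(s3$value, 90)
  expect_error(discrimination_step2(100, s3), "censored")
})

test_that("the factorisation identity holds by construction", {
  set.seed(23)
  for (k in 1:25) {
    effs <- 10^runif(2, -3, 1)
    fs <- sort(runif(2, 0.02, 1))
    rep <- fidelity_report(eff_canonical = max(effs), eff_damaged = min(effs),
                           F_sealed_canonical = fs[2], F_sealed_damaged = fs[1],
                           se_eff_canonical = 0.1 * max(effs),
                           se_eff_damaged = 0.1 * min(effs),
                           sd_sealed_canonical = 0.02, sd_sealed_damaged = 0.02)
    expect_equal(rep$step2$value * rep$step3$value, rep$overall$value,
                 tolerance = 1e-12)
    expect_true(all(c(rep$overall$value, rep$step2$value,
                      rep$step3$value) > 0))
  }
})

test_that("overall discrimination falls as the damaged substrate improves", {
  effs_damaged <- c(0.5, 1, 2, 4)
  d <- vapply(effs_damaged,
              function(e) discrimination_overall(10, e)$value, numeric(1))
  expect_true(all(diff(d) < 0))
  # self-comparison is exactly 1
  expect_equal(discrimination_overall(7, 7)$value, 1)
  expect_equal(discrimination_step3(0.37, 0.37)$value, 1)
})

test_that("the direct step-2 route agrees with the identity route", {
  # abortive-inclusive efficiencies: eff_total = eff_sealed / F_sealed,
  # so eff_total_CG / eff_total_oxo = overall / step3 algebraically
  eff_c <- 2.4; eff_d <- 0.04
  fs_c <- 0.96; fs_d <- 0.12
  rep <- fidelity_report(eff_c, eff_d, fs_c, fs_d,
                         eff_total_canonical = eff_c / fs_c,
                         eff_total_damaged = eff_d / fs_d)
  expect_equal(rep$step2_direct$value, rep$step2$value, tolerance = 1e-12)
})
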