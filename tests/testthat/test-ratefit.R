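test_that("an exact linear time course gives the exact per-enzyme rate", {
  t <- seq(10, 100, by = 10)
  est <- initial_rate(t, 0.001 * t, dna_nM = 1000, enzyme_nM = 1)
  expect_equal(est$v_init_per_E, 1.0, tolerance = 1e-12)
  expect_equal(est$intercept, 0, tolerance = 1e-12)
  expect_gte(est$r_squared, 0.999)   # synthetic linear data
  expect_equal(est$n_points, 10L)
})

test_that("points beyond the product-fraction window never change the estimate", {
  t <- seq(10, 100, by = 10)
  est0 <- initial_rate(t, 0.001 * t, dna_nM = 1000, enzyme_nM = 1)
  t2 <- c(t, 300, 500, 900)
  fp2 <- c(0.001 * t, 0.3, 0.5, 0.9)
  est1 <- initial_rate(t2, fp2, dna_nM = 1000, enzyme_nM = 1)
  expect_identical(est0$v_init_per_E, est1$v_init_per_E)
  expect_identical(est0$slope_SE, est1$slope_SE)
  expect_equal(est1$n_points, 10L)
})

test_that("rate estimation enforces its data contracts", {
  expect_error(initial_rate(c(10, 20, 30), c(0.25, 0.3, 0.4), 1000, 1),
               "insufficient data")
  expect_error(initial_rate(c(10, 20, 30), c(0.01, 0.02, 0.03), 0, 1),
               "> 0")
  expect_warning(initial_rate(seq(10, 60, 10), 0.001 * seq(10, 60, 10),
                              dna_nM = 100, enzyme_nM = 50),
                 "5 enzyme turnovers")
  # clearly negative slope is flagged, not silently returned
  est <- initial_rate(c(10, 20, 30, 40), c(0.10, 0.08, 0.06, 0.04), 1000, 1)
  expect_true("negative_slope" %in% est$flags)
})

test_that("simulated initial rates match the steady-state flux oracle", {
  # saturating DNA, limiting enzyme: the windowed slope of F_p equals the
  # stationary sealing flux of the enzyme cycle (per enzyme, per total DNA)
  cases <- list(
    default_mechanism_params("WT", "C:G", mg_free = 1),
    default_mechanism_params("WT", "C:G", mg_free = 0.3),
    default_mechanism_params("K845N", "8oxoG:A", mg_free = 1,
                             enzyme_total = 2)
  )
  for (p in cases) {
    v_true <- flux_oracle(p)
    slope_frac <- v_true * p$enzyme_total / p$dna_total
    # stay in the linear phase of TOTAL adenylylation (sealed + abortive),
    # which is what depletes the substrate when abortion is frequent
    fa <- unname(branching_oracle(p)["abort"])
    t_max <- 0.1 * (1 - fa) / slope_frac
    times <- seq(t_max / 8, t_max, length.out = 8)
    tc <- simulate_mechanism(p, times)
    est <- initial_rate(tc$time_s, tc$F_p, dna_nM = p$dna_total,
                        enzyme_nM = p$enzyme_total)
    expect_equal(est$v_init_per_E, v_true, tolerance = 0.02)
    expect_gte(est$r_squared, 0.999)
  }
})

test_that("segmental regression recovers exact titration breakpoints", {
  e <- c(20, 40, 60, 80, 100, 120, 150)
  fit <- active_site_titration(e, pmin(e, 100))
  expect_equal(fit$breakpoint_nM, 100, tolerance = 1e-6)
  expect_equal(fit$rising_slope, 1, tolerance = 1e-8)
  expect_equal(fit$plateau_level, 100, tolerance = 1e-6)
  expect_equal(fit$active_fraction, 1, tolerance = 1e-6)

  # 50% active enzyme: products halve, breakpoint stays
  fit2 <- active_site_titration(e, pmin(e, 100) / 2)
  expect_equal(fit2$rising_slope, 0.5, tolerance = 1e-8)
  expect_equal(fit2$plateau_level, 50, tolerance = 1e-6)
  expect_equal(fit2$active_fraction, 0.5, tolerance = 1e-6)

  expect_equal(predict(fit, c(50, 140)), c(50, 100), tolerance = 1e-6)
})

test_that("noisy titrations agree with an exhaustive breakpoint-grid oracle", {
  e <- c(25, 50, 75, 100, 115, 130, 150)
  set.seed(31)
  y <- pmin(e, 100) + rnorm(length(e), sd = 2)
  fit <- active_site_titration(e, y)
  expect_lt(abs(fit$breakpoint_nM - 100), 10)
  oracle_c <- grid_search_breakpoint(e, y)
  expect_equal(fit$breakpoint_nM, oracle_c, tolerance = 1e-3)
})

test_that("titrations without a plateau are rejected with advice", {
  e <- c(10, 20, 30, 40, 50, 60)
  expect_error(active_site_titration(e, e * 0.8), "widen the titration")
  expect_error(active_site_titration(e[1:4], pmin(e[1:4], 35)), ">= 5")
})

test_that("initial_rates maps over condition-replicate groups", {
  des <- ligation_design(variant = "WT", substrate = "C:G", enzyme_nM = 1,
                         dna_nM = 1000, mg_free_mM = c(0.5, 2),
                         times = seq(20, 160, by = 20), replicates = 2L)
  des$times <- lapply(seq_len(nrow(des)), function(i) {
    p <- default_mechanism_params("WT", "C:G", mg_free = des$mg_free_mM[i],
                                  enzyme_total = 1, dna_total = 1000)
    pilot_times(p, n = 8, f_target = 0.1)
  })
  dat <- generate_dataset(des, noise_sigma = 0, seed = 3)
  rates <- initial_rates(band_fractions(dat))
  expect_equal(nrow(rates), 4L)
  expect_true(all(rates$v_init_per_E > 0))
  # higher Mg2+ condition turns over faster
  v_by_mg <- tapply(rates$v_init_per_E, rates$mg_free_mM, mean)
  expect_gt(v_by_mg["2"], v_by_mg["0.5"])
})
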