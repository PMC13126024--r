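# Independent oracles used across the suite. These re-derive expected
# values by routes that share no code with the package internals.

# Analytic long-time branching of the ligation scheme: absorbing-state
# probabilities of the per-encounter Markov chain over the transient
# states {open E.S, closed E.S, closed E.I, open E.I}, entered at open
# E.S. Unproductive exits recycle the DNA molecule, so the final split is
# abort/(abort + seal).
branching_oracle <- function(p) {
  k2 <- p$k_transfer_max * p$mg_free / (p$K_mg_step2 + p$mg_free)
  k3 <- p$k_seal_max * p$mg_free / (p$K_mg_step3 + p$mg_free)
  Q <- matrix(0, 4, 4)
  Q[1, ] <- c(-(p$k_close + p$k_diss), p$k_close, 0, 0)
  Q[2, ] <- c(p$k_open, -(p$k_open + k2), k2, 0)
  Q[3, ] <- c(0, 0, -(p$k_open + k3), p$k_open)
  Q[4, ] <- c(0, 0, p$k_close, -(p$k_close + p$k_diss))
  R <- matrix(0, 4, 3)  # columns: unproductive, abort, seal
  R[1, 1] <- p$k_diss
  R[4, 2] <- p$k_diss
  R[3, 3] <- k3
  B <- solve(-Q, R)
  probs <- B[1, ]
  c(abort = probs[2] / (probs[2] + probs[3]),
    seal = probs[3] / (probs[2] + probs[3]))
}

# Steady-state per-enzyme turnover (sealing flux) with the substrate pool
# held at its initial concentration: stationary distribution of the
# five-state enzyme cycle {E, oES, cES, cEI, oEI}, flux = k3 * pi(cEI).
flux_oracle <- function(p) {
  k2 <- p$k_transfer_max * p$mg_free / (p$K_mg_step2 + p$mg_free)
  k3 <- p$k_seal_max * p$mg_free / (p$K_mg_step3 + p$mg_free)
  kbS <- p$k_bind * p$dna_total
  # generator over {E, oES, cES, cEI, oEI}
  Q <- matrix(0, 5, 5)
  Q[1, 2] <- kbS
  Q[2, 1] <- p$k_diss; Q[2, 3] <- p$k_close
  Q[3, 2] <- p$k_open; Q[3, 4] <- k2
  Q[4, 5] <- p$k_open; Q[4, 1] <- k3
  Q[5, 4] <- p$k_close; Q[5, 1] <- p$k_diss
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, 5))
  pi_ss <- qr.solve(A, c(rep(0, 5), 1))
  unname(k3 * pi_ss[4])
}

# Exhaustive iteratively refined grid search for the rectangular
# hyperbola v = kcat * x / (K + x): minimises the (weighted) SSE over a
# log-spaced 2-D grid, zooming on the best cell.
grid_search_mm <- function(x, v, w = NULL, n_grid = 41L, n_zoom = 6L) {
  if (is.null(w)) w <- rep(1, length(v))
  k_lo <- max(v) * 0.5; k_hi <- max(v) * 4
  K_lo <- min(x) / 20; K_hi <- max(x) * 20
  best <- c(NA, NA)
  for (it in seq_len(n_zoom)) {
    ks <- exp(seq(log(k_lo), log(k_hi), length.out = n_grid))
    Ks <- exp(seq(log(K_lo), log(K_hi), length.out = n_grid))
    g <- expand.grid(kcat = ks, K = Ks)
    sse <- vapply(seq_len(nrow(g)), function(j) {
      sum(w * (v - g$kcat[j] * x / (g$K[j] + x))^2)
    }, numeric(1))
    j <- which.min(sse)
    best <- c(g$kcat[j], g$K[j])
    span_k <- (log(k_hi) - log(k_lo)) / (n_grid - 1)
    span_K <- (log(K_hi) - log(K_lo)) / (n_grid - 1)
    k_lo <- exp(log(best[1]) - 2 * span_k); k_hi <- exp(log(best[1]) + 2 * span_k)
    K_lo <- exp(log(best[2]) - 2 * span_K); K_hi <- exp(log(best[2]) + 2 * span_K)
  }
  c(kcat = best[1], K = best[2])
}

# Exhaustive breakpoint-grid oracle for the two-segment titration model
# y = a + b * min(x, c).
grid_search_breakpoint <- function(x, y, n_grid = 2001L) {
  cs <- seq(min(x) + 1e-9, max(x), length.out = n_grid)
  sse <- vapply(cs, function(cpt) {
    z <- pmin(x, cpt)
    sum(resid(lm(y ~ z))^2)
  }, numeric(1))
  cs[which.min(sse)]
}

# Quench times sampling the linear phase of a given parameter set: n
# evenly spaced points up to the time where the SEALED product fraction
# reaches f_target, allowing for the abortive side flux that also
# consumes substrate.
pilot_times <- function(p, n = 8, f_target = 0.1) {
  v <- flux_oracle(p)
  fa <- unname(branching_oracle(p)["abort"])
  slope_frac <- v * p$enzyme_total / p$dna_total
  t_max <- f_target * (1 - fa) / slope_frac
  seq(t_max / n, t_max, length.out = n)
}

# Parameter set whose effective turnover is hyperbolic in free Mg2+:
# nick sealing (step 3) is made rate-limiting by two orders of magnitude,
# so v ~= k_seal_max * Mg / (K_mg_step3 + Mg).
recovery_params <- function(mg, enzyme = 2, dna = 1000) {
  mechanism_params(k_bind = 1, k_close = 500, k_open = 0.01, k_diss = 5,
                   k_transfer_max = 500, k_seal_max = 1,
                   K_mg_step2 = 0.01, K_mg_step3 = 0.5,
                   enzyme_total = enzyme, dna_total = dna, mg_free = mg,
                   substrate_label = "C:G")
}

recovery_mg_grid <- c(0.1, 0.2, 0.3, 0.5, 1, 2, 5)

# Pilot-scaled sampling: 16 evenly spaced quench times reaching a product
# fraction of ~0.18. The density is set by a prospective power analysis:
# with fraction noise 0.02 and 3 replicate lanes, an n-point even grid to
# F_p = 0.18 gives a slope CV of ~0.02/(0.18 * 0.5 * sqrt(n)); n = 16
# yields ~5.6% per condition, hence ~8% on the fitted K_Mg, comfortably
# inside a +/-15% band at the 90% level.
recovery_times <- function(mg, enzyme = 2, dna = 1000) {
  v <- 1 * mg / (0.5 + mg)
  t_max <- 0.18 / (v * enzyme / dna)
  seq(t_max / 16, t_max, length.out = 16)
}

# Simulate the noiseless Mg-grid time courses once per session; the
# parameter-recovery checks only re-apply noise and refit.
recovery_noiseless <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- lapply(recovery_mg_grid, function(mg) {
        simulate_mechanism(recovery_params(mg), recovery_times(mg))
      })
    }
    cache
  }
})

# One noisy Mg-dependence experiment (3 replicate lanes per condition,
# gel noise sigma) assembled into a band-record table, then pushed through
# quantify -> rates -> Mg-hyperbola fit. Returns the fitted K_Mg.
recovery_trial_K <- function(trial_seed, sigma = 0.02, replicates = 3L) {
  tcs <- recovery_noiseless()
  rows <- list()
  for (ci in seq_along(recovery_mg_grid)) {
    for (r in seq_len(replicates)) {
      tc <- add_gel_noise(tcs[[ci]], sigma,
                          seed = (trial_seed * 1009 + ci * 131 + r) %% 2147483647)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = "WT", substrate = "C:G", replicate = r,
        time_s = tc$time_s, enzyme_nM = 2, dna_nM = 1000, atp_mM = 0.2,
        mg_free_mM = recovery_mg_grid[ci],
        intensity_s = tc$F_s * 10000, intensity_i = tc$F_i * 10000,
        intensity_p = tc$F_p * 10000)
    }
  }
  records <- do.call(rbind, rows)
  fr <- band_fractions(records)
  rates <- initial_rates(fr)
  fit <- fit_michaelis_menten(rates$mg_free_mM, rates$v_init_per_E,
                              se = rates$v_SE, model_kind = "mg")
  unname(coef(fit)["K_half"])
}
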