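# Linearly implicit (Rosenbrock) integrator for small stiff mass-action
# systems. Second-order L-stable scheme with an embedded third-stage error
# estimate (the classic ode23s triple), restricted to autonomous systems,
# which is all the mechanism module needs.

#' @noRd
.ros23_d <- 1 / (2 + sqrt(2))
.ros23_e32 <- 6 + sqrt(2)

# f: function(y) -> dy/dt; jac: function(y) -> d f / d y (dense matrix).
# Returns a matrix of states at the requested output times (rows = times).
# Dense output between accepted steps uses linear interpolation refined by
# taking steps that land exactly on output times, so no interpolation error
# enters: the step controller never steps across an output time.
.integrate_ros23 <- function(f, jac, y0, times, rtol = 1e-8, atol = 1e-12,
                             max_steps = 200000L, h_init = NULL) {
  n <- length(y0)
  nt <- length(times)
  out <- matrix(NA_real_, nrow = nt, ncol = n)
  t <- times[1L]
  y <- y0
  out[1L, ] <- y
  if (nt == 1L) return(out)

  d <- .ros23_d
  e32 <- .ros23_e32
  I_n <- diag(n)

  scale_rates <- max(abs(f(y0)), 1e-12)
  h <- if (is.null(h_init)) min(1e-4 / scale_rates, diff(range(times)) / 100) else h_init
  h <- max(h, 1e-14)

  next_out <- 2L
  steps <- 0L
  while (next_out <= nt) {
    t_target <- times[next_out]
    if (t + h > t_target) h <- t_target - t
    f0 <- f(y)
    J <- jac(y)
    W <- I_n - h * d * J
    Winv_ok <- TRUE
    k1 <- tryCatch(solve(W, f0), error = function(e) {
      Winv_ok <<- FALSE
      NULL
    })
    if (!Winv_ok) {
      stop("stiff integration failure: singular iteration matrix at t = ",
           signif(t, 6), "; check for extreme or unbalanced rate constants",
           call. = FALSE)
    }
    f1 <- f(y + 0.5 * h * k1)
    k2 <- solve(W, f1 - k1) + k1
    y_new <- y + h * k2
    f2 <- f(y_new)
    k3 <- solve(W, f2 - e32 * (k2 - f1) - 2 * (k1 - f0))
    err_vec <- (h / 6) * (k1 - 2 * k2 + k3)
    sc <- atol + rtol * pmax(abs(y), abs(y_new))
    err <- sqrt(mean((err_vec / sc)^2))

    if (!is.finite(err)) {
      h <- h / 10
      if (h < 1e-14) {
        stop("stiff integration failure: step size underflow at t = ",
             signif(t, 6), call. = FALSE)
      }
      next
    }

    if (err <= 1) {
      t <- t + h
      y <- y_new
      if (abs(t - t_target) < 1e-12 * max(1, abs(t_target))) {
        out[next_out, ] <- y
        next_out <- next_out + 1L
      }
      h <- h * min(5, max(0.2, 0.9 * err^(-1 / 3)))
    } else {
      h <- h * max(0.1, 0.9 * err^(-1 / 3))
    }
    steps <- steps + 1L
    if (steps > max_steps) {
      stop("stiff integration failure: step budget exhausted at t = ",
           signif(t, 6), " (", max_steps, " steps); the parameter regime ",
           "may be too stiff for the requested tolerance", call. = FALSE)
    }
  }
  out
}
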