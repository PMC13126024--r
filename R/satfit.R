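#' Fit a rectangular hyperbola to saturation kinetics
#'
#' Weighted nonlinear least squares of the single-site saturation model
#' \deqn{v = k_{cat}\,x / (K_{1/2} + x)}
#' where \eqn{x} is either the nicked DNA concentration (Michaelis-Menten,
#' \eqn{K_{1/2} = K_M} in nM) or the free Mg2+ concentration (cofactor
#' activation, \eqn{K_{1/2} = K_{Mg}} in mM), and \eqn{v} is the
#' per-enzyme initial velocity \eqn{v_{init}/[E]} in s\eqn{^{-1}}. The
#' ligase binds several Mg2+ ions, but the activation data behave as a
#' single essential cofactor, so no Hill coefficient is fitted by default
#' (set \code{hill = TRUE} to explore).
#'
#' Starting values come from the data (\eqn{k_{cat,0} =} max velocity;
#' \eqn{K_0 =} concentration at half-max by interpolation). Weights are
#' \eqn{1/SE^2} when velocity standard errors are supplied, otherwise the
#' fit is unweighted. Parameter standard errors come from the covariance
#' of the fit; the catalytic efficiency \eqn{k_{cat}/K_{1/2}} carries a
#' quadrature-propagated SE.
#'
#' @param conc concentrations (nM for DNA, mM for Mg2+).
#' @param v per-enzyme initial velocities, s^-1 (\code{>= 0}).
#' @param se optional velocity standard errors (same length as \code{v}).
#' @param model_kind \code{"dna"} (Michaelis-Menten over substrate) or
#'   \code{"mg"} (Mg2+ activation).
#' @param hill if \code{TRUE}, also fit a Hill exponent (exploratory).
#' @return An object of class \code{mm_fit} with components \code{k_cat},
#'   \code{K_half}, \code{k_cat_SE}, \code{K_half_SE}, \code{efficiency},
#'   \code{efficiency_SE}, \code{model_kind}, \code{n_conditions},
#'   \code{residuals}, \code{flags}, and (for \code{hill = TRUE})
#'   \code{hill_n}. Supports \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{plot} and \code{residuals}.
#' @examples
#' mg <- c(0.1, 0.2, 0.3, 0.5, 1, 2, 5)
#' v <- 0.95 * mg / (1.1 + mg)
#' fit <- fit_michaelis_menten(mg, v, model_kind = "mg")
#' coef(fit)
#' @export
fit_michaelis_menten <- function(conc, v, se = NULL,
                                 model_kind = c("dna", "mg"),
                                 hill = FALSE) {
  model_kind <- match.arg(model_kind)
  stopifnot(length(conc) == length(v))
  ok <- is.finite(conc) & is.finite(v)
  x <- conc[ok]; y <- v[ok]
  w <- NULL
  if (!is.null(se)) {
    stopifnot(length(se) == length(conc))
    se_ok <- se[ok]
    if (all(is.finite(se_ok)) && all(se_ok > 0)) w <- 1 / se_ok^2
  }
  if (length(unique(x)) < 4L) {
    stop("need >= 4 distinct concentrations to fit a saturation curve",
         call. = FALSE)
  }
  if (any(x <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (any(y < 0 & abs(y) > 1e-12)) {
    stop("velocities must be >= 0", call. = FALSE)
  }

  flags <- character(0)
  # degenerate saturated design: no concentration dependence to fit
  mu <- stats::weighted.mean(y, if (is.null(w)) rep(1, length(y)) else w)
  if (stats::sd(y) <= 1e-10 * max(abs(mu), 1e-300)) {
    flags <- c(flags, "K_half_not_identifiable")
    warning("velocities show no concentration dependence: design is ",
            "saturated, K_half is not identifiable", call. = FALSE)
    return(.new_mm_fit(k_cat = mu, K_half = NA_real_,
                       k_cat_SE = NA_real_, K_half_SE = NA_real_,
                       model_kind = model_kind, x = x, y = y,
                       fitted = rep(mu, length(y)), flags = flags,
                       hill_n = if (hill) NA_real_ else NULL))
  }

  kcat0 <- max(y)
  half <- kcat0 / 2
  K0 <- tryCatch(stats::approx(y, x, xout = half, ties = mean)$y,
                 error = function(e) NA_real_)
  if (!is.finite(K0) || K0 <= 0) K0 <- stats::median(x)
  dat <- data.frame(x = x, y = y)

  fit <- NULL
  if (!hill) {
    form <- y ~ kcat * x / (K + x)
    starts <- list(list(kcat = kcat0, K = K0),
                   list(kcat = kcat0 * 1.5, K = K0 * 3),
                   list(kcat = kcat0 * 1.1, K = K0 / 3))
    ctrl <- stats::nls.control(maxiter = 500, tol = 1e-12,
                               minFactor = 1 / 4096, warnOnly = FALSE)
    for (st in starts) {
      fit <- tryCatch(
        stats::nls(form, data = dat, start = st, weights = w,
                   algorithm = "port", lower = c(kcat = 0, K = 0),
                   control = ctrl),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (!is.null(fit)) {
      # polish: restart from the solution so the optimum is resolved well
      # beyond the port convergence test
      fit2 <- tryCatch(
        stats::nls(form, data = dat, start = as.list(stats::coef(fit)),
                   weights = w, algorithm = "port",
                   lower = c(kcat = 0, K = 0), control = ctrl),
        error = function(e) NULL)
      if (!is.null(fit2)) fit <- fit2
    }
  } else {
    form <- y ~ kcat * x^n / (K^n + x^n)
    fit <- tryCatch(
      stats::nls(form, data = dat,
                 start = list(kcat = kcat0, K = K0, n = 1),
                 weights = w, algorithm = "port",
                 lower = c(kcat = 0, K = 0, n = 0.1),
                 control = stats::nls.control(maxiter = 500,
                                              warnOnly = FALSE)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    stop("hyperbolic fit did not converge (initial guesses: k_cat = ",
         signif(kcat0, 4), ", K_half = ", signif(K0, 4),
         "); check that the design spans below and above K_half",
         call. = FALSE)
  }
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  k_cat <- unname(cf["kcat"]); K_half <- unname(cf["K"])
  k_cat_SE <- sqrt(vc[1, 1]); K_half_SE <- sqrt(vc[2, 2])
  if (K_half > 10 * max(x)) {
    flags <- c(flags, "K_half_extrapolated")
    warning("fitted K_half exceeds 10x the largest tested concentration; ",
            "the estimate is an extrapolation", call. = FALSE)
  }
  if (min(x) > K_half || max(x) < K_half) {
    flags <- c(flags, "K_half_outside_design")
  }
  .new_mm_fit(k_cat = k_cat, K_half = K_half, k_cat_SE = k_cat_SE,
              K_half_SE = K_half_SE, model_kind = model_kind,
              x = x, y = y, fitted = stats::fitted(fit), flags = flags,
              hill_n = if (hill) unname(cf["n"]) else NULL)
}

.new_mm_fit <- function(k_cat, K_half, k_cat_SE, K_half_SE, model_kind,
                        x, y, fitted, flags, hill_n = NULL) {
  eff <- k_cat / K_half
  eff_se <- if (is.finite(k_cat_SE) && is.finite(K_half_SE) &&
                is.finite(eff)) {
    abs(eff) * sqrt((k_cat_SE / k_cat)^2 + (K_half_SE / K_half)^2)
  } else NA_real_
  res <- y - fitted
  structure(
    list(k_cat = k_cat, K_half = K_half, k_cat_SE = k_cat_SE,
         K_half_SE = K_half_SE, efficiency = eff, efficiency_SE = eff_se,
         model_kind = model_kind, n_conditions = length(unique(x)),
         hill_n = hill_n,
         data = data.frame(conc = x, v = y, fitted = fitted),
         residuals = res, rmse = sqrt(mean(res^2)), flags = flags),
    class = "mm_fit"
  )
}

.mm_units <- function(model_kind) {
  if (model_kind == "dna") c(x = "nM", K = "K_M (nM)", eff = "s^-1 nM^-1")
  else c(x = "mM", K = "K_Mg (mM)", eff = "s^-1 mM^-1")
}

#' @export
print.mm_fit <- function(x, ...) {
  u <- .mm_units(x$model_kind)
  cat(sprintf("Saturation fit over %s (%d concentrations)\n",
              if (x$model_kind == "dna") "nicked DNA" else "free Mg2+",
              x$n_conditions))
  cat(sprintf("  k_cat    = %.4g +/- %.2g s^-1\n", x$k_cat, x$k_cat_SE))
  cat(sprintf("  %-8s = %.4g +/- %.2g\n", u["K"], x$K_half, x$K_half_SE))
  cat(sprintf("  k_cat/K  = %.4g +/- %.2g %s\n", x$efficiency,
              x$efficiency_SE, u["eff"]))
  if (!is.null(x$hill_n)) cat(sprintf("  Hill n   = %.3g\n", x$hill_n))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mm_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  residual RMSE = %.3g s^-1\n", object$rmse))
  invisible(object)
}

#' @export
coef.mm_fit <- function(object, ...) {
  out <- c(k_cat = object$k_cat, K_half = object$K_half)
  if (!is.null(object$hill_n)) out <- c(out, hill_n = object$hill_n)
  out
}

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$conc else {
    if (is.data.frame(newdata)) newdata$conc else newdata
  }
  n <- if (is.null(object$hill_n)) 1 else object$hill_n
  object$k_cat * x^n / (object$K_half^n + x^n)
}

#' @export
residuals.mm_fit <- function(object, ...) object$residuals

#' @export
plot.mm_fit <- function(x, ...) {
  u <- .mm_units(x$model_kind)
  graphics::plot(x$data$conc, x$data$v,
                 xlab = paste0(if (x$model_kind == "dna") "[nicked DNA]"
                               else "[free Mg2+]", " (", u["x"], ")"),
                 ylab = "v_init/[E] (s^-1)", ...)
  xx <- seq(0, max(x$data$conc), length.out = 300)
  graphics::lines(xx, predict(x, xx), col = "steelblue")
  if (is.finite(x$K_half)) {
    graphics::abline(v = x$K_half, lty = 3, col = "grey50")
  }
  invisible(x)
}

#' Compare two saturation fits
#'
#' Ratios of \eqn{k_{cat}}, \eqn{K_{1/2}} and catalytic efficiency between
#' two fits of the same kind, with standard errors propagated in
#' quadrature on the relative scale and values reported at two significant
#' figures (full precision is retained in the returned object).
#'
#' @param fit_a,fit_b \code{mm_fit} objects of the same \code{model_kind}
#'   (\code{fit_a} is the numerator).
#' @return A data frame of class \code{mm_fit_comparison} with one row per
#'   parameter: \code{ratio}, \code{ratio_SE}, and the rounded
#'   \code{ratio_2sf}.
#' @export
compare_fits <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "mm_fit"), inherits(fit_b, "mm_fit"))
  if (fit_a$model_kind != fit_b$model_kind) {
    stop("cannot compare fits over different saturating species (",
         fit_a$model_kind, " vs ", fit_b$model_kind, ")", call. = FALSE)
  }
  one <- function(va, sa, vb, sb) {
    r <- va / vb
    rse <- if (is.finite(sa) && is.finite(sb)) {
      abs(r) * sqrt((sa / va)^2 + (sb / vb)^2)
    } else NA_real_
    c(r, rse)
  }
  rows <- rbind(
    k_cat = one(fit_a$k_cat, fit_a$k_cat_SE, fit_b$k_cat, fit_b$k_cat_SE),
    K_half = one(fit_a$K_half, fit_a$K_half_SE, fit_b$K_half,
                 fit_b$K_half_SE),
    efficiency = one(fit_a$efficiency, fit_a$efficiency_SE,
                     fit_b$efficiency, fit_b$efficiency_SE)
  )
  out <- data.frame(parameter = rownames(rows), ratio = rows[, 1],
                    ratio_SE = rows[, 2],
                    ratio_2sf = signif(rows[, 1], 2))
  rownames(out) <- NULL
  class(out) <- c("mm_fit_comparison", "data.frame")
  out
}
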