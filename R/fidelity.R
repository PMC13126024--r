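#' Sum-of-squares (quadrature) error propagation for products and ratios
#'
#' Combines independent uncertainties through a chain of multiplications
#' and divisions: relative standard errors add in quadrature,
#' \deqn{SE_{rel} = \sqrt{\sum_k (SE_k / x_k)^2},}
#' which is exact for independent log-normally approximated errors and an
#' excellent approximation for coefficients of variation up to ~0.3.
#'
#' @param values positive values entering the chain, first value first.
#' @param ses standard errors, same length as \code{values}.
#' @param ops character vector of operations applied left to right:
#'   \code{"*"} or \code{"/"}, of length \code{length(values) - 1}. The
#'   default multiplies everything.
#' @return A named numeric vector \code{c(value, SE)}.
#' @examples
#' propagate_quadrature(c(2, 3), c(0.2, 0.3))           # product: 6 +/- 0.849
#' propagate_quadrature(c(10, 2), c(1, 0.2), ops = "/") # ratio: 5 +/- 0.707
#' @export
propagate_quadrature <- function(values, ses,
                                 ops = rep("*", length(values) - 1L)) {
  stopifnot(length(values) >= 1L, length(ses) == length(values))
  if (length(values) > 1L && length(ops) != length(values) - 1L) {
    stop("ops must have length(values) - 1 entries", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("all values in a product/ratio chain must be finite and > 0",
         call. = FALSE)
  }
  if (any(!is.finite(ses)) || any(ses < 0)) {
    stop("standard errors must be finite and >= 0", call. = FALSE)
  }
  if (length(values) > 1L && !all(ops %in% c("*", "/"))) {
    stop("ops must be \"*\" or \"/\"", call. = FALSE)
  }
  val <- values[1L]
  if (length(values) > 1L) {
    for (k in 2L:length(values)) {
      val <- if (ops[k - 1L] == "*") val * values[k] else val / values[k]
    }
  }
  rel <- sqrt(sum((ses / values)^2))
  c(value = val, SE = abs(val) * rel)
}

.disc <- function(value, SE, kind, inputs, censored = FALSE) {
  structure(list(value = value, SE = SE, kind = kind, inputs = inputs,
                 censored = censored),
            class = "discrimination")
}

#' @export
print.discrimination <- function(x, ...) {
  lab <- c(overall = "Overall", step2 = "Step-2 (AMP transfer)",
           step3 = "Step-3 (nick sealing)")[x$kind]
  if (x$censored) {
    cat(sprintf("%s discrimination: > %.3g-fold (censored: damaged-substrate signal at detection limit)\n",
                lab, x$value))
  } else {
    cat(sprintf("%s discrimination: %.3g-fold (SE %.2g); reported %s-fold\n",
                lab, x$value, x$SE, format(signif(x$value, 2))))
  }
  invisible(x)
}

#' Overall discrimination from catalytic efficiencies
#'
#' The fidelity of ligation against a damaged nick, defined as the ratio
#' of catalytic efficiencies for the canonical and damaged substrates:
#' \deqn{D_{overall} = (k_{cat}/K_M)_{C:G} \,/\, (k_{cat}/K_M)_{8oxoG:A}.}
#'
#' @param eff_canonical,eff_damaged catalytic efficiencies (> 0).
#' @param se_canonical,se_damaged their standard errors.
#' @return A \code{discrimination} object: \code{value}, \code{SE}
#'   (quadrature), \code{kind = "overall"}, \code{inputs}.
#' @export
discrimination_overall <- function(eff_canonical, eff_damaged,
                                   se_canonical = 0, se_damaged = 0) {
  r <- propagate_quadrature(c(eff_canonical, eff_damaged),
                            c(se_canonical, se_damaged), ops = "/")
  .disc(r[["value"]], r[["SE"]], "overall",
        list(eff_canonical = eff_canonical, eff_damaged = eff_damaged))
}

#' Step-3 (nick sealing) discrimination from sealed fractions
#'
#' \deqn{D_{step3} = F_{sealed}^{C:G} / F_{sealed}^{8oxoG:A}:} how much
#' more often the adenylylated canonical nick is sealed rather than
#' released than the damaged one. When the damaged sealed fraction is zero
#' (sealing below the detection limit) the discrimination is censored: a
#' lower bound is returned (computed against \code{detection_limit}),
#' flagged rather than reported as a number.
#'
#' @param F_sealed_canonical,F_sealed_damaged sealed fractions in (0, 1\]
#'   (damaged may be 0, triggering censoring).
#' @param sd_canonical,sd_damaged their standard deviations.
#' @param detection_limit smallest resolvable sealed fraction, used for
#'   the censored bound (default 0.01).
#' @return A \code{discrimination} object with \code{kind = "step3"}.
#' @export
discrimination_step3 <- function(F_sealed_canonical, F_sealed_damaged,
                                 sd_canonical = 0, sd_damaged = 0,
                                 detection_limit = 0.01) {
  if (!is.finite(F_sealed_canonical) || F_sealed_canonical <= 0 ||
      F_sealed_canonical > 1) {
    stop("canonical sealed fraction must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(F_sealed_damaged) || F_sealed_damaged < 0 ||
      F_sealed_damaged > 1) {
    stop("damaged sealed fraction must lie in [0, 1]", call. = FALSE)
  }
  if (F_sealed_damaged == 0) {
    return(.disc(F_sealed_canonical / detection_limit, NA_real_, "step3",
                 list(F_sealed_canonical = F_sealed_canonical,
                      F_sealed_damaged = 0,
                      detection_limit = detection_limit),
                 censored = TRUE))
  }
  r <- propagate_quadrature(c(F_sealed_canonical, F_sealed_damaged),
                            c(sd_canonical, sd_damaged), ops = "/")
  .disc(r[["value"]], r[["SE"]], "step3",
        list(F_sealed_canonical = F_sealed_canonical,
             F_sealed_damaged = F_sealed_damaged))
}

#' Step-2 (AMP transfer) discrimination from the factorisation identity
#'
#' Overall discrimination factorises into the two chemical steps,
#' \eqn{D_{overall} = D_{step2} \times D_{step3}}, so the AMP-transfer
#' component is recovered as \eqn{D_{step2} = D_{overall} / D_{step3}}.
#' Accepts either \code{discrimination} objects or bare numbers with SEs.
#'
#' @param overall overall discrimination (object or number).
#' @param step3 step-3 discrimination (object or number).
#' @param se_overall,se_step3 SEs, ignored when objects are supplied.
#' @return A \code{discrimination} object with \code{kind = "step2"}.
#' @export
discrimination_step2 <- function(overall, step3, se_overall = 0,
                                 se_step3 = 0) {
  if (inherits(overall, "discrimination")) {
    se_overall <- overall$SE; overall <- overall$value
  }
  if (inherits(step3, "discrimination")) {
    if (step3$censored) {
      stop("step-3 discrimination is censored; step 2 cannot be recovered",
           call. = FALSE)
    }
    se_step3 <- step3$SE; step3 <- step3$value
  }
  r <- propagate_quadrature(c(overall, step3), c(se_overall, se_step3),
                            ops = "/")
  .disc(r[["value"]], r[["SE"]], "step2",
        list(overall = overall, step3 = step3))
}

#' Overall discrimination from its step factors
#'
#' The forward direction of the factorisation identity:
#' \eqn{D_{overall} = D_{step2} \times D_{step3}}.
#'
#' @param step2,step3 step discriminations (objects or numbers).
#' @param se_step2,se_step3 SEs, ignored when objects are supplied.
#' @return A \code{discrimination} object with \code{kind = "overall"}.
#' @export
discrimination_overall_from_steps <- function(step2, step3, se_step2 = 0,
                                              se_step3 = 0) {
  if (inherits(step2, "discrimination")) {
    se_step2 <- step2$SE; step2 <- step2$value
  }
  if (inherits(step3, "discrimination")) {
    se_step3 <- step3$SE; step3 <- step3$value
  }
  r <- propagate_quadrature(c(step2, step3), c(se_step2, se_step3),
                            ops = "*")
  .disc(r[["value"]], r[["SE"]], "overall",
        list(step2 = step2, step3 = step3))
}

#' Full discrimination decomposition for one condition pair
#'
#' Combines catalytic efficiencies (canonical and damaged substrate) and
#' sealed fractions measured under the same conditions into the overall,
#' step-3 and step-2 discrimination factors with propagated errors. Step 2
#' is derived from the factorisation identity (overall / step 3); when
#' abortive-inclusive efficiencies are supplied (total adenylylated
#' product, sealed plus abortive), their ratio is the direct step-2
#' estimate and the report carries the cross-check.
#'
#' @param eff_canonical,eff_damaged catalytic efficiencies for sealed
#'   product formation, with SEs \code{se_eff_canonical},
#'   \code{se_eff_damaged}.
#' @param F_sealed_canonical,F_sealed_damaged sealed fractions with SDs
#'   \code{sd_sealed_canonical}, \code{sd_sealed_damaged}.
#' @param eff_total_canonical,eff_total_damaged optional abortive-inclusive
#'   efficiencies (for the direct step-2 cross-check), with SEs
#'   \code{se_eff_total_canonical}, \code{se_eff_total_damaged}.
#' @param condition optional label (e.g. \code{"WT, 0.2 mM Mg"}).
#' @return An object of class \code{fidelity_report} holding the three
#'   \code{discrimination} objects (the identity
#'   \code{overall = step2 * step3} holds to machine precision by
#'   construction), the inputs, and \code{step2_direct} when computable.
#' @export
fidelity_report <- function(eff_canonical, eff_damaged,
                            F_sealed_canonical, F_sealed_damaged,
                            se_eff_canonical = 0, se_eff_damaged = 0,
                            sd_sealed_canonical = 0, sd_sealed_damaged = 0,
                            eff_total_canonical = NULL,
                            eff_total_damaged = NULL,
                            se_eff_total_canonical = 0,
                            se_eff_total_damaged = 0,
                            condition = NULL) {
  overall <- discrimination_overall(eff_canonical, eff_damaged,
                                    se_eff_canonical, se_eff_damaged)
  step3 <- discrimination_step3(F_sealed_canonical, F_sealed_damaged,
                                sd_sealed_canonical, sd_sealed_damaged)
  step2 <- discrimination_step2(overall, step3)
  step2_direct <- NULL
  if (!is.null(eff_total_canonical) && !is.null(eff_total_damaged)) {
    r <- propagate_quadrature(c(eff_total_canonical, eff_total_damaged),
                              c(se_eff_total_canonical,
                                se_eff_total_damaged), ops = "/")
    step2_direct <- .disc(r[["value"]], r[["SE"]], "step2",
                          list(eff_total_canonical = eff_total_canonical,
                               eff_total_damaged = eff_total_damaged))
  }
  structure(
    list(overall = overall, step2 = step2, step3 = step3,
         step2_direct = step2_direct, condition = condition,
         inputs = list(eff_canonical = eff_canonical,
                       eff_damaged = eff_damaged,
                       F_sealed_canonical = F_sealed_canonical,
                       F_sealed_damaged = F_sealed_damaged)),
    class = "fidelity_report"
  )
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("Ligation fidelity decomposition")
  if (!is.null(x$condition)) cat(" [", x$condition, "]", sep = "")
  cat("\n")
  fmt <- function(d) {
    if (d$censored) sprintf("> %s (censored)", format(signif(d$value, 2)))
    else sprintf("%s +/- %.2g", format(signif(d$value, 2)), d$SE)
  }
  cat("  overall (efficiency ratio):      ", fmt(x$overall), "\n")
  cat("  step 2  (AMP transfer):          ", fmt(x$step2), "\n")
  cat("  step 3  (nick sealing):          ", fmt(x$step3), "\n")
  if (!is.null(x$step2_direct)) {
    cat("  step 2, direct (total-product):  ", fmt(x$step2_direct), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.fidelity_report <- function(x, ...) {
  d <- list(overall = x$overall, step2 = x$step2, step3 = x$step3)
  out <- data.frame(
    component = names(d),
    value = vapply(d, function(z) z$value, numeric(1)),
    SE = vapply(d, function(z) z$SE, numeric(1)),
    value_2sf = vapply(d, function(z) signif(z$value, 2), numeric(1)),
    censored = vapply(d, function(z) z$censored, logical(1))
  )
  if (!is.null(x$condition)) out$condition <- x$condition
  rownames(out) <- NULL
  out
}
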