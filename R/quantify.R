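#' Fraction of ligated product in a lane
#'
#' \eqn{F_p = p / (p + s + i)}: the sealed-product band over the total DNA
#' signal in the lane. Scale-invariant, so uncalibrated fluorescence units
#' are fine.
#'
#' @param s,i,p band intensities of nicked substrate, AMP-DNA intermediate
#'   and sealed product (arbitrary units, \code{>= 0}; vectorised).
#' @return \code{F_p} in \[0, 1\].
#' @export
fraction_product <- function(s, i, p) {
  .check_intensities(s, i, p)
  tot <- p + s + i
  if (any(tot <= 0)) {
    stop("undefined fraction: all band intensities are zero", call. = FALSE)
  }
  p / tot
}

#' Fraction of abortive ligation
#'
#' \eqn{F_{abort} = i / (p + i)}: of the DNA that received AMP (step 2
#' happened), the part released as the dead-end AMP-DNA intermediate
#' instead of being sealed. Undefined before any AMP transfer has occurred.
#'
#' @param i,p intermediate and product band intensities (vectorised).
#' @return \code{F_abort} in \[0, 1\].
#' @export
fraction_abortive <- function(i, p) {
  .check_intensities(i, p)
  tot <- p + i
  if (any(tot <= 0)) {
    stop("F_abort undefined: no AMP-DNA intermediate or product signal ",
         "(no AMP transfer has occurred yet)", call. = FALSE)
  }
  i / tot
}

#' Fraction of sealed product among adenylylated DNA
#'
#' The complement of the abortive fraction,
#' \eqn{F_{sealed} = 1 - F_{abort} = p / (p + i)}.
#'
#' @param F_abort abortive fraction(s) in \[0, 1\].
#' @return \code{F_sealed} in \[0, 1\].
#' @export
fraction_sealed <- function(F_abort) {
  if (any(!is.finite(F_abort)) || any(F_abort < 0) || any(F_abort > 1)) {
    stop("F_abort must lie in [0, 1]", call. = FALSE)
  }
  1 - F_abort
}

.check_intensities <- function(...) {
  for (v in list(...)) {
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("band intensities must be finite and >= 0", call. = FALSE)
    }
  }
  invisible(TRUE)
}

.condition_keys <- c("variant", "substrate", "enzyme_nM", "dna_nM",
                     "atp_mM", "mg_free_mM")

#' Convert band records to fraction observables
#'
#' Computes, per lane, the fraction product \eqn{F_p}; and per
#' condition-replicate, the abortive fraction \eqn{F_{abort}} and its
#' complement \eqn{F_{sealed}}. Two modes are offered for \eqn{F_{abort}}:
#' \describe{
#'   \item{\code{"linear_phase"} (default)}{intensities are pooled over the
#'     initial-rate window (lanes with \eqn{F_p \le} \code{fp_threshold})
#'     before taking \eqn{i/(p+i)}; the steady-state partitioning between
#'     sealing and abortion is constant in the linear phase, so pooling
#'     reduces quantification noise.}
#'   \item{\code{"per_timepoint"}}{\eqn{F_{abort}} is reported lane by
#'     lane.}
#' }
#'
#' @param records band-record table (schema of [generate_dataset()]).
#' @param mode abortive-fraction mode, see Details.
#' @param fp_threshold product-fraction ceiling of the linear-phase window
#'   (default 0.20).
#' @return A data frame with the condition key columns, \code{replicate},
#'   \code{time_s} (per-lane rows), \code{F_p}, and \code{F_abort},
#'   \code{F_sealed} (constant within a replicate in pooled mode;
#'   \code{NA} when no in-window lane has intermediate or product signal).
#' @export
band_fractions <- function(records, mode = c("linear_phase", "per_timepoint"),
                           fp_threshold = 0.20) {
  mode <- match.arg(mode)
  records <- validate_band_records(records)
  if (fp_threshold <= 0 || fp_threshold >= 1) {
    stop("fp_threshold must lie in (0, 1)", call. = FALSE)
  }
  out <- records[, c(.condition_keys, "replicate", "time_s")]
  out$F_p <- fraction_product(records$intensity_s, records$intensity_i,
                              records$intensity_p)
  if (mode == "per_timepoint") {
    tot <- records$intensity_i + records$intensity_p
    out$F_abort <- ifelse(tot > 0, records$intensity_i / tot, NA_real_)
  } else {
    grp <- interaction(records[, c(.condition_keys, "replicate")], drop = TRUE)
    out$F_abort <- NA_real_
    for (g in levels(grp)) {
      idx <- which(grp == g)
      win <- idx[out$F_p[idx] <= fp_threshold]
      if (!length(win)) win <- idx[which.min(out$F_p[idx])]
      isum <- sum(records$intensity_i[win])
      psum <- sum(records$intensity_p[win])
      out$F_abort[idx] <- if (isum + psum > 0) isum / (isum + psum) else NA_real_
    }
  }
  out$F_sealed <- 1 - out$F_abort
  out
}

#' Summarise replicate measurements
#'
#' Per-group mean and sample standard deviation (n - 1 denominator) of one
#' or more fraction or rate columns, with the replicate count. Groups with
#' a single observation report \code{NA} for the SD (flagged, not zero).
#'
#' @param records a data frame of per-replicate values.
#' @param value_cols character vector of columns to summarise.
#' @param by character vector of grouping columns (default: the condition
#'   key columns present in \code{records}).
#' @return A data frame with one row per group: the grouping columns,
#'   \code{n}, and \code{<col>_mean} / \code{<col>_sd} for each value
#'   column.
#' @export
summarize_replicates <- function(records, value_cols,
                                 by = intersect(.condition_keys,
                                                names(records))) {
  stopifnot(is.data.frame(records), length(value_cols) >= 1)
  missing_cols <- setdiff(c(value_cols, by), names(records))
  if (length(missing_cols)) {
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) stop("empty group: no records", call. = FALSE)
  grp <- interaction(records[, by, drop = FALSE], drop = TRUE, sep = "\r")
  levs <- levels(grp)
  key <- records[match(levs, grp), by, drop = FALSE]
  res <- key
  res$n <- as.integer(tapply(seq_along(grp), grp, length)[levs])
  for (vc in value_cols) {
    v <- records[[vc]]
    res[[paste0(vc, "_mean")]] <-
      as.numeric(tapply(v, grp, mean, na.rm = TRUE)[levs])
    sds <- as.numeric(tapply(v, grp, function(z) {
      z <- z[!is.na(z)]
      if (length(z) < 2L) NA_real_ else stats::sd(z)
    })[levs])
    res[[paste0(vc, "_sd")]] <- sds
  }
  rownames(res) <- NULL
  res
}
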