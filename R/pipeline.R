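#' Free Mg2+ from total Mg2+ and ATP
#'
#' Assay bookkeeping under the 1:1 tight-chelation model: ATP binds one
#' Mg2+ essentially stoichiometrically under the assay conditions, so the
#' free Mg2+ concentration is total minus ATP (e.g. 0.4 mM total Mg2+ with
#' 0.2 mM ATP leaves 0.2 mM free).
#'
#' @param total_mM total Mg2+, mM.
#' @param atp_mM ATP, mM (\code{total_mM >= atp_mM >= 0}).
#' @return Free Mg2+, mM.
#' @export
free_mg <- function(total_mM, atp_mM) {
  if (any(!is.finite(total_mM)) || any(!is.finite(atp_mM)) ||
      any(atp_mM < 0)) {
    stop("concentrations must be finite and ATP >= 0", call. = FALSE)
  }
  if (any(total_mM < atp_mM)) {
    stop("total Mg2+ is below the ATP concentration: no free Mg2+ under ",
         "the 1:1 chelation model", call. = FALSE)
  }
  total_mM - atp_mM
}

#' Pipeline configuration
#'
#' Collects the knobs of the end-to-end analysis into a validated list.
#'
#' @param input path to a band-record CSV (or a band-record data frame
#'   passed directly to [run_pipeline()]).
#' @param outdir output directory (created if missing).
#' @param seed integer seed recorded in the run manifest.
#' @param fp_threshold initial-rate window ceiling on fraction product
#'   (default 0.20).
#' @param mg_mode \code{"free"} when the \code{mg_free_mM} column already
#'   holds free Mg2+ (default), or \code{"total"} when it holds total
#'   Mg2+ to be corrected by the ATP column via [free_mg()].
#' @param replicate_mode \code{"pooled"}: each replicate's velocity enters
#'   the saturation fit as one point (default); \code{"averaged"}:
#'   replicate velocities are averaged per condition first.
#' @param signif_digits significant figures for reported fold-factors.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = NULL, outdir = tempfile("ligfid_run_"),
                            seed = 1L, fp_threshold = 0.20,
                            mg_mode = c("free", "total"),
                            replicate_mode = c("pooled", "averaged"),
                            signif_digits = 2L) {
  mg_mode <- match.arg(mg_mode)
  replicate_mode <- match.arg(replicate_mode)
  if (fp_threshold <= 0 || fp_threshold >= 1) {
    stop("fp_threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(list(input = input, outdir = outdir, seed = as.integer(seed),
                 fp_threshold = fp_threshold, mg_mode = mg_mode,
                 replicate_mode = replicate_mode,
                 signif_digits = as.integer(signif_digits)),
            class = "pipeline_config")
}

.log_stage <- function(...) message("[ligfid] ", ...)

#' Run the full analysis pipeline
#'
#' Band records to fidelity report in one deterministic pass:
#' \enumerate{
#'   \item quantify: band intensities to fraction observables;
#'   \item rates: per-replicate initial velocities in the linear phase;
#'   \item fits: for each variant-substrate group, a saturation fit over
#'     DNA concentration when the design varies DNA, and over free Mg2+
#'     when it varies Mg2+ (a group needs >= 4 distinct concentrations of
#'     the varying species);
#'   \item fidelity: for each (variant, Mg2+) with DNA fits for both the
#'     canonical and damaged substrate, the discrimination decomposition.
#'     Skipped, with a log line, when only one substrate is present.
#' }
#' Every stage logs row counts to stderr; outputs are written to
#' \code{config$outdir} as \code{fractions.csv}, \code{rates.csv},
#' \code{fits.json}/\code{fits.csv}, \code{fidelity.json}/
#' \code{fidelity.csv}, \code{manifest.json} and \code{summary.txt}.
#'
#' @param config a [pipeline_config()].
#' @param records optional band-record data frame overriding
#'   \code{config$input}.
#' @return Invisibly, a list with \code{fractions}, \code{rates},
#'   \code{fits} (list of \code{mm_fit} per group), \code{fidelity}
#'   (list of \code{fidelity_report}), and \code{outdir}.
#' @export
run_pipeline <- function(config, records = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(records)) {
    if (is.null(config$input)) stop("no input provided", call. = FALSE)
    records <- read_band_records(config$input)
  } else {
    records <- validate_band_records(records)
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  .log_stage("input: ", nrow(records), " band records")

  if (config$mg_mode == "total") {
    records$mg_free_mM <- free_mg(records$mg_free_mM, records$atp_mM)
    .log_stage("converted total Mg2+ to free Mg2+ (1:1 ATP chelation)")
  }

  fractions <- band_fractions(records, fp_threshold = config$fp_threshold)
  utils::write.csv(fractions, file.path(config$outdir, "fractions.csv"),
                   row.names = FALSE)
  .log_stage("quantify: ", nrow(fractions), " fraction records")

  rates <- initial_rates(fractions, fp_threshold = config$fp_threshold)
  utils::write.csv(rates, file.path(config$outdir, "rates.csv"),
                   row.names = FALSE)
  .log_stage("rates: ", nrow(rates), " replicate velocities")

  if (config$replicate_mode == "averaged") {
    agg <- summarize_replicates(rates, c("v_init_per_E", "F_abort"))
    rates_fit <- agg
    rates_fit$v_init_per_E <- agg$v_init_per_E_mean
    rates_fit$v_SE <- agg$v_init_per_E_sd
    rates_fit$F_abort <- agg$F_abort_mean
  } else {
    rates_fit <- rates
  }

  fits <- list()
  fit_rows <- list()
  for (variant in unique(rates_fit$variant)) {
    for (substrate in unique(rates_fit$substrate)) {
      sub <- rates_fit[rates_fit$variant == variant &
                         rates_fit$substrate == substrate, ]
      if (!nrow(sub)) next
      n_dna <- length(unique(sub$dna_nM))
      n_mg <- length(unique(sub$mg_free_mM))
      if (n_dna >= 4L) {
        for (mg in unique(sub$mg_free_mM)) {
          s2 <- sub[sub$mg_free_mM == mg, ]
          if (length(unique(s2$dna_nM)) < 4L) next
          key <- sprintf("%s|%s|dna|mg=%g", variant, substrate, mg)
          fits[[key]] <- tryCatch(
            fit_michaelis_menten(s2$dna_nM, s2$v_init_per_E, se = s2$v_SE,
                                 model_kind = "dna"),
            error = function(e) {
              .log_stage("fit skipped (", key, "): ", conditionMessage(e))
              NULL
            })
          if (!is.null(fits[[key]])) {
            fit_rows[[key]] <- .fit_row(fits[[key]], variant, substrate,
                                        "dna", mg)
          }
        }
      }
      if (n_mg >= 4L) {
        key <- sprintf("%s|%s|mg", variant, substrate)
        fits[[key]] <- tryCatch(
          fit_michaelis_menten(sub$mg_free_mM, sub$v_init_per_E,
                               se = sub$v_SE, model_kind = "mg"),
          error = function(e) {
            .log_stage("fit skipped (", key, "): ", conditionMessage(e))
            NULL
          })
        if (!is.null(fits[[key]])) {
          fit_rows[[key]] <- .fit_row(fits[[key]], variant, substrate,
                                      "mg", NA_real_)
        }
      }
    }
  }
  fits <- Filter(Negate(is.null), fits)
  .log_stage("fits: ", length(fits), " saturation fits")
  if (length(fit_rows)) {
    fits_df <- do.call(rbind, fit_rows)
    rownames(fits_df) <- NULL
    utils::write.csv(fits_df, file.path(config$outdir, "fits.csv"),
                     row.names = FALSE)
    jsonlite::write_json(fits_df, file.path(config$outdir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    fits_df <- NULL
  }

  # fidelity: per (variant, mg) with DNA-saturation fits for both substrates
  fidelity <- list()
  substrates <- unique(records$substrate)
  canonical <- intersect(c("C:G", "C.G", "CG"), substrates)
  damaged <- intersect(c("8oxoG:A", "8oxoG.A", "8oxoGA"), substrates)
  if (length(canonical) && length(damaged)) {
    fab <- summarize_replicates(
      fractions[!duplicated(fractions[, c(.condition_keys, "replicate")]), ],
      "F_sealed")
    for (variant in unique(rates_fit$variant)) {
      for (mg in unique(rates_fit$mg_free_mM)) {
        kc <- sprintf("%s|%s|dna|mg=%g", variant, canonical[1L], mg)
        kd <- sprintf("%s|%s|dna|mg=%g", variant, damaged[1L], mg)
        if (is.null(fits[[kc]]) || is.null(fits[[kd]])) next
        fs <- function(substr) {
          r <- fab[fab$variant == variant & fab$substrate == substr &
                     fab$mg_free_mM == mg, ]
          if (!nrow(r)) return(c(NA_real_, NA_real_))
          c(mean(r$F_sealed_mean, na.rm = TRUE),
            stats::median(r$F_sealed_sd, na.rm = TRUE))
        }
        fsc <- fs(canonical[1L]); fsd <- fs(damaged[1L])
        if (!is.finite(fsc[1]) || !is.finite(fsd[1])) next
        key <- sprintf("%s|mg=%g", variant, mg)
        fidelity[[key]] <- fidelity_report(
          eff_canonical = fits[[kc]]$efficiency,
          eff_damaged = fits[[kd]]$efficiency,
          F_sealed_canonical = fsc[1], F_sealed_damaged = max(fsd[1], 0),
          se_eff_canonical = fits[[kc]]$efficiency_SE,
          se_eff_damaged = fits[[kd]]$efficiency_SE,
          sd_sealed_canonical = ifelse(is.na(fsc[2]), 0, fsc[2]),
          sd_sealed_damaged = ifelse(is.na(fsd[2]), 0, fsd[2]),
          condition = sprintf("%s at %g mM free Mg2+", variant, mg))
      }
    }
    .log_stage("fidelity: ", length(fidelity), " condition pairs")
  } else {
    .log_stage("fidelity stage skipped: need both canonical and damaged ",
               "substrates (have: ", paste(substrates, collapse = ", "), ")")
  }
  if (length(fidelity)) {
    fid_df <- do.call(rbind, lapply(fidelity, as.data.frame))
    rownames(fid_df) <- NULL
    utils::write.csv(fid_df, file.path(config$outdir, "fidelity.csv"),
                     row.names = FALSE)
    jsonlite::write_json(fid_df, file.path(config$outdir, "fidelity.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  manifest <- list(
    package = "ligfid",
    version = as.character(utils::packageVersion("ligfid")),
    seed = config$seed,
    fp_threshold = config$fp_threshold,
    mg_mode = config$mg_mode,
    replicate_mode = config$replicate_mode,
    n_records = nrow(records), n_rates = nrow(rates),
    n_fits = length(fits), n_fidelity = length(fidelity)
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  summ <- c(
    sprintf("ligfid pipeline run (seed %d)", config$seed),
    sprintf("records: %d; rates: %d; fits: %d; fidelity pairs: %d",
            nrow(records), nrow(rates), length(fits), length(fidelity)),
    if (!is.null(fits_df)) {
      apply(fits_df, 1, function(r) {
        sprintf("fit %s %s over %s (mg=%s): k_cat=%s K_half=%s eff=%s",
                r[["variant"]], r[["substrate"]], r[["model_kind"]],
                r[["mg_free_mM"]], signif(as.numeric(r[["k_cat"]]), 3),
                signif(as.numeric(r[["K_half"]]), 3),
                signif(as.numeric(r[["efficiency"]]), 3))
      })
    },
    vapply(fidelity, function(f) {
      sprintf("fidelity [%s]: overall=%s step2=%s step3=%s",
              f$condition, signif(f$overall$value, config$signif_digits),
              signif(f$step2$value, config$signif_digits),
              signif(f$step3$value, config$signif_digits))
    }, character(1))
  )
  writeLines(summ, file.path(config$outdir, "summary.txt"))
  invisible(list(fractions = fractions, rates = rates, fits = fits,
                 fidelity = fidelity, fits_table = fits_df,
                 outdir = config$outdir))
}

.fit_row <- function(fit, variant, substrate, model_kind, mg) {
  data.frame(variant = variant, substrate = substrate,
             model_kind = model_kind, mg_free_mM = mg,
             k_cat = fit$k_cat, k_cat_SE = fit$k_cat_SE,
             K_half = fit$K_half, K_half_SE = fit$K_half_SE,
             efficiency = fit$efficiency, efficiency_SE = fit$efficiency_SE,
             n_conditions = fit$n_conditions,
             flags = paste(fit$flags, collapse = ";"))
}
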