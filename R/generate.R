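#' Add gel-quantification noise to a simulated time course
#'
#' Emulates the error of band quantification from a fluorescence gel image:
#' each band fraction is perturbed by independent Gaussian noise of the
#' stated standard deviation, clipped at zero, and renormalised so the
#' three bands again sum to one (quantification is relative within a lane).
#'
#' @param tc a \code{ligation_timecourse} from [simulate_mechanism()].
#' @param sigma noise standard deviation on the fraction scale
#'   (dimensionless, \code{>= 0}).
#' @param seed integer seed; the caller's RNG stream is left untouched.
#' @return A \code{ligation_timecourse} with perturbed fractions; the
#'   applied \code{sigma} and \code{seed} are stored as attributes.
#' @export
add_gel_noise <- function(tc, sigma, seed = NULL) {
  stopifnot(inherits(tc, "ligation_timecourse"))
  if (!is.finite(sigma) || sigma < 0) {
    stop("sigma must be finite and >= 0", call. = FALSE)
  }
  if (sigma == 0) return(tc)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- as.matrix(tc[, c("F_s", "F_i", "F_p")])
  noisy <- m + matrix(stats::rnorm(length(m), sd = sigma), nrow = nrow(m))
  noisy[noisy < 0] <- 0
  tot <- rowSums(noisy)
  # a lane with all three bands clipped to zero carries no signal; keep the
  # true fractions there (probability ~0 for realistic sigma)
  bad <- tot <= 0
  noisy[!bad, ] <- noisy[!bad, , drop = FALSE] / tot[!bad]
  noisy[bad, ] <- m[bad, , drop = FALSE]
  out <- tc
  out$F_s <- noisy[, 1]; out$F_i <- noisy[, 2]; out$F_p <- noisy[, 3]
  attr(out, "noise_sigma") <- sigma
  attr(out, "seed") <- seed
  out
}

#' Describe a grid of assay conditions
#'
#' Builds the experiment-design table consumed by [generate_dataset()]:
#' the Cartesian structure of conditions (one row per condition), each with
#' its own sampling times and replicate count. Mirrors the multiple-turnover
#' gel assay: limiting enzyme, excess nicked DNA, fixed ATP, and a grid
#' over free Mg2+ and/or DNA concentration.
#'
#' @param variant,substrate,enzyme_nM,dna_nM,atp_mM,mg_free_mM vectors
#'   recycled against each other (all full-length combinations are taken
#'   via \code{expand.grid} except \code{times}).
#' @param times either a numeric vector of timepoints (seconds) used for
#'   every condition, or a list with one numeric vector per condition row.
#' @param replicates number of replicate lanes per condition-timepoint.
#' @return A data frame of class \code{ligation_design}.
#' @export
ligation_design <- function(variant = "WT", substrate = "C:G",
                            enzyme_nM = 1, dna_nM = 1000, atp_mM = 0.2,
                            mg_free_mM = 1.0,
                            times = c(15, 30, 60, 120, 240),
                            replicates = 3L) {
  g <- expand.grid(variant = variant, substrate = substrate,
                   enzyme_nM = enzyme_nM, dna_nM = dna_nM,
                   atp_mM = atp_mM, mg_free_mM = mg_free_mM,
                   stringsAsFactors = FALSE)
  if (nrow(g) == 0L) stop("empty design", call. = FALSE)
  if (is.list(times) && !is.numeric(times)) {
    if (length(times) != nrow(g)) {
      stop("times list must have one entry per condition (",
           nrow(g), " conditions)", call. = FALSE)
    }
    g$times <- times
  } else {
    g$times <- rep(list(as.numeric(times)), nrow(g))
  }
  g$replicates <- as.integer(replicates)
  if (any(g$replicates < 1L)) stop("replicates must be >= 1", call. = FALSE)
  class(g) <- c("ligation_design", "data.frame")
  g
}

# deterministic per-lane seed derived from the top-level seed: hierarchical
# splitting keeps every (condition, replicate) stream independent of the
# order in which conditions are simulated; kept below 2^31
.derive_seed <- function(seed, condition_idx, replicate) {
  (as.double(seed) * 48271 + condition_idx * 69621 + replicate * 16807) %%
    2147483647
}

#' Generate a synthetic band-record table
#'
#' Runs the mechanism simulator over an experiment design, applies gel
#' noise, and emits one row per lane in the band-record schema consumed by
#' [band_fractions()]: the per-lane intensities of the nicked substrate,
#' AMP-DNA intermediate and sealed product bands (fractions scaled by a
#' total-signal constant).
#'
#' @param design a [ligation_design()] table.
#' @param params_by_condition either a single [mechanism_params()] object
#'   used for every condition (its concentrations and Mg2+ are overridden
#'   per condition), or a function
#'   \code{function(variant, substrate, mg_free, enzyme_nM, dna_nM)}
#'   returning a \code{mechanism_params}; the default dispatches to
#'   [default_mechanism_params()].
#' @param noise_sigma gel-noise standard deviation on the fraction scale.
#' @param seed top-level integer seed, split per condition and replicate.
#' @param total_signal arbitrary fluorescence units per lane.
#' @return A data frame with columns \code{variant, substrate, replicate,
#'   time_s, enzyme_nM, dna_nM, atp_mM, mg_free_mM, intensity_s,
#'   intensity_i, intensity_p}, with the generating parameters attached as
#'   attribute \code{"generator"}.
#' @export
generate_dataset <- function(design, params_by_condition = NULL,
                             noise_sigma = 0.02, seed = 1L,
                             total_signal = 10000) {
  stopifnot(inherits(design, "ligation_design"))
  get_params <- params_by_condition
  if (is.null(get_params)) {
    get_params <- function(variant, substrate, mg_free, enzyme_nM, dna_nM) {
      default_mechanism_params(variant, substrate, mg_free = mg_free,
                               enzyme_total = enzyme_nM, dna_total = dna_nM)
    }
  }
  rows <- vector("list", nrow(design))
  for (ci in seq_len(nrow(design))) {
    d <- design[ci, ]
    p <- if (inherits(get_params, "mechanism_params")) {
      mechanism_params(
        k_bind = get_params$k_bind, k_close = get_params$k_close,
        k_open = get_params$k_open, k_diss = get_params$k_diss,
        k_transfer_max = get_params$k_transfer_max,
        k_seal_max = get_params$k_seal_max,
        K_mg_step2 = get_params$K_mg_step2,
        K_mg_step3 = get_params$K_mg_step3,
        enzyme_total = d$enzyme_nM, dna_total = d$dna_nM,
        mg_free = d$mg_free_mM, substrate_label = get_params$substrate_label
      )
    } else {
      get_params(d$variant, d$substrate, d$mg_free_mM, d$enzyme_nM, d$dna_nM)
    }
    if (!inherits(p, "mechanism_params")) {
      stop("no mechanism parameters for condition row ", ci, call. = FALSE)
    }
    times <- d$times[[1L]]
    tc0 <- simulate_mechanism(p, times)
    reps <- d$replicates
    per_rep <- vector("list", reps)
    for (r in seq_len(reps)) {
      tc <- add_gel_noise(tc0, noise_sigma,
                          seed = .derive_seed(seed, ci, r))
      per_rep[[r]] <- data.frame(
        variant = d$variant, substrate = d$substrate, replicate = r,
        time_s = tc$time_s, enzyme_nM = d$enzyme_nM, dna_nM = d$dna_nM,
        atp_mM = d$atp_mM, mg_free_mM = d$mg_free_mM,
        intensity_s = tc$F_s * total_signal,
        intensity_i = tc$F_i * total_signal,
        intensity_p = tc$F_p * total_signal
      )
    }
    rows[[ci]] <- do.call(rbind, per_rep)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "generator") <- list(noise_sigma = noise_sigma, seed = seed,
                                 total_signal = total_signal)
  out
}

#' Write / read band-record tables
#'
#' Plain-CSV persistence of the band-record schema, with a JSON sidecar
#' (\code{<path>.json}) recording the generating parameters and seed when
#' the table came from [generate_dataset()].
#'
#' @param records a band-record data frame.
#' @param path CSV file path.
#' @return \code{write_band_records} returns \code{path} invisibly;
#'   \code{read_band_records} returns the validated data frame.
#' @export
write_band_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  gen <- attr(records, "generator")
  if (!is.null(gen)) {
    jsonlite::write_json(gen, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

.band_schema <- c("variant", "substrate", "replicate", "time_s", "enzyme_nM",
                  "dna_nM", "atp_mM", "mg_free_mM", "intensity_s",
                  "intensity_i", "intensity_p")

#' @rdname write_band_records
#' @export
read_band_records <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_band_records(x)
}

#' Validate a band-record table against the schema
#'
#' Checks column presence and per-row sanity (non-negative intensities,
#' at least one positive band per lane); errors name the offending column
#' or row.
#'
#' @param x a data frame in the band-record schema.
#' @return \code{x}, invisibly validated.
#' @export
validate_band_records <- function(x) {
  missing_cols <- setdiff(.band_schema, names(x))
  if (length(missing_cols)) {
    stop("band-record table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ints <- as.matrix(x[, c("intensity_s", "intensity_i", "intensity_p")])
  bad <- which(!is.finite(ints) | ints < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("negative or non-finite intensity in column ",
         c("intensity_s", "intensity_i", "intensity_p")[bad[1, 2]],
         ", row ", bad[1, 1], call. = FALSE)
  }
  zero <- which(rowSums(ints) <= 0)
  if (length(zero)) {
    stop("no signal in any band at row ", zero[1], call. = FALSE)
  }
  x
}
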