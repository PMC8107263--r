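#' Configuration for the synthetic challenge generator
#'
#' Defines the generative model for a synthetic tumor-cellularity reference
#' standard. Patches are organized hierarchically (patients own slides own
#' patches) so the patient-clustered bootstrap is meaningful. Each patch has
#' a latent true TC: exactly zero with probability `zero_inflation` (patches
#' with no tumor cells at all), otherwise drawn from a two-mode beta mixture
#' on (0, 1] that mimics the zero-inflated, full-range shape of pathologist
#' TC histograms — a broad low-cellularity mode and a concentrated
#' high-cellularity mode. Raters report the latent value snapped to a
#' discrete grid (pathologists score in coarse percentage steps); the second
#' rater additionally carries additive Gaussian noise before re-gridding,
#' and preserves an exact-zero patch with probability `zero_fidelity`.
#'
#' The defaults emulate the scale of a real challenge test set (18 patients,
#' 2 slides each, 31 patches per slide, about 1100 patches) and a rater
#' noise level (`rater_noise_sd = 0.12`) at which the two simulated raters
#' agree at an average interrater PK of about 0.926, the operating range of
#' experienced pathologists on this task.
#'
#' @param n_patients number of patients (bootstrap clusters).
#' @param slides_per_patient slides per patient.
#' @param patches_per_slide patches per slide.
#' @param zero_inflation probability a patch contains no tumor (TC exactly 0).
#' @param tc_distribution list with mixture weight `w_low` and beta shape
#'   pairs `low` and `high` for the non-zero TC distribution.
#' @param grid_step rater reporting grid; must divide 1 evenly (default 0.05,
#'   i.e. 5% steps).
#' @param rater_noise_sd SD of the second rater's additive noise (TC units).
#' @param zero_fidelity probability the second rater also scores an
#'   exact-zero patch as 0.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 18,
                             slides_per_patient = 2,
                             patches_per_slide = 31,
                             zero_inflation = 0.25,
                             tc_distribution = list(w_low = 0.45,
                                                    low = c(1.2, 3.5),
                                                    high = c(5, 1.8)),
                             grid_step = 0.05,
                             rater_noise_sd = 0.12,
                             zero_fidelity = 0.9) {
  stopifnot(n_patients >= 1, slides_per_patient >= 1, patches_per_slide >= 1)
  if (zero_inflation < 0 || zero_inflation > 1 ||
      zero_fidelity < 0 || zero_fidelity > 1) {
    stop_validation("probabilities must lie in [0, 1]", "pkeval_range_error")
  }
  k <- 1 / grid_step
  if (grid_step <= 0 || abs(k - round(k)) > 1e-9) {
    stop_validation("grid_step must divide 1 evenly", "pkeval_range_error")
  }
  if (rater_noise_sd < 0) {
    stop_validation("rater_noise_sd must be non-negative", "pkeval_range_error")
  }
  structure(list(n_patients = n_patients,
                 slides_per_patient = slides_per_patient,
                 patches_per_slide = patches_per_slide,
                 zero_inflation = zero_inflation,
                 tc_distribution = tc_distribution,
                 grid_step = grid_step,
                 rater_noise_sd = rater_noise_sd,
                 zero_fidelity = zero_fidelity),
            class = "synthetic_config")
}

#' Behavior profile of a simulated algorithm
#'
#' A simulated algorithm observes each patch's latent TC, applies a strictly
#' increasing calibration map, adds Gaussian noise, clamps to \[0, 1\], and
#' optionally discretizes its output into `n_bins` equal-width bins
#' (reported as bin midpoints) — the tie-inflation maneuver that games
#' tau-b.
#'
#' @param label algorithm/team label.
#' @param noise_sd additive noise SD in TC units.
#' @param calibration `"id"`, `list("power", gamma)` with `gamma > 0`, or
#'   `list("affine", a, b)` with `b > 0`; applied to the latent TC before
#'   noise and clamping.
#' @param n_bins `0` for continuous output, otherwise number (>= 2) of
#'   equal-width output bins.
#' @return object of class `algorithm_profile`.
#' @export
algorithm_profile <- function(label, noise_sd = 0.05, calibration = "id",
                              n_bins = 0) {
  if (noise_sd < 0) {
    stop_validation("noise_sd must be non-negative", "pkeval_range_error")
  }
  if (!(n_bins == 0 || n_bins >= 2)) {
    stop_validation("n_bins must be 0 (continuous) or at least 2",
                    "pkeval_range_error")
  }
  cal <- calibration_fun(calibration)  # validates
  structure(list(label = as.character(label), noise_sd = noise_sd,
                 calibration = calibration, n_bins = as.integer(n_bins)),
            class = "algorithm_profile")
}

calibration_fun <- function(calibration) {
  if (identical(calibration, "id")) return(identity)
  if (is.list(calibration) && length(calibration) >= 2 &&
      identical(calibration[[1]], "power")) {
    gamma <- calibration[[2]]
    if (gamma <= 0) {
      stop_validation("power calibration needs gamma > 0 (strictly increasing)",
                      "pkeval_range_error")
    }
    return(function(x) x^gamma)
  }
  if (is.list(calibration) && length(calibration) >= 3 &&
      identical(calibration[[1]], "affine")) {
    a <- calibration[[2]]; b <- calibration[[3]]
    if (b <= 0) {
      stop_validation("affine calibration needs slope b > 0",
                      "pkeval_range_error")
    }
    return(function(x) a + b * x)
  }
  stop_validation(
    "calibration must be \"id\", list(\"power\", gamma) or list(\"affine\", a, b)",
    "pkeval_type_error")
}

snap_to_grid <- function(x, step) round(x / step) * step

#' Generate a synthetic two-rater reference set
#'
#' Draws latent true TC values per patch under the configured zero-inflated
#' beta mixture, then derives two rater score columns: `path1` reports the
#' latent TC snapped to the grid; `path2` adds Gaussian noise before
#' clamping and re-gridding, preserving exact zeros with probability
#' `zero_fidelity`. The latent truth is returned alongside the reference so
#' simulated algorithms (and parameter-recovery tests) can use it; it is
#' never part of the reference CSV.
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed; output is a pure function of `(cfg, seed)`.
#' @return list with `reference` (a [reference_set()] with raters `path1`,
#'   `path2`) and `latent` (numeric vector of true TC, named by patch id).
#' @export
generate_reference <- function(cfg, seed = 1) {
  if (!inherits(cfg, "synthetic_config")) {
    stop_validation("cfg must be a synthetic_config", "pkeval_type_error")
  }
  set.seed(derive_seed(seed, 0))
  n <- cfg$n_patients * cfg$slides_per_patient * cfg$patches_per_slide
  patient <- rep(seq_len(cfg$n_patients),
                 each = cfg$slides_per_patient * cfg$patches_per_slide)
  slide <- rep(seq_len(cfg$n_patients * cfg$slides_per_patient),
               each = cfg$patches_per_slide)
  patch_id <- sprintf("patch%05d", seq_len(n))
  case_id <- sprintf("patient%03d", patient)
  slide_id <- sprintf("slide%04d", slide)

  is_zero <- runif(n) < cfg$zero_inflation
  td <- cfg$tc_distribution
  from_low <- runif(n) < td$w_low
  latent <- ifelse(from_low,
                   rbeta(n, td$low[1], td$low[2]),
                   rbeta(n, td$high[1], td$high[2]))
  latent[is_zero] <- 0

  rater1 <- snap_to_grid(latent, cfg$grid_step)
  noise <- rnorm(n, 0, cfg$rater_noise_sd)
  rater2 <- snap_to_grid(clamp01(latent + noise), cfg$grid_step)
  keep_zero <- runif(n) < cfg$zero_fidelity
  rater2[is_zero & keep_zero] <- 0

  ref <- reference_set(patch_id, slide_id, case_id,
                       cbind(path1 = rater1, path2 = rater2))
  list(reference = ref, latent = stats::setNames(latent, patch_id))
}

#' Generate a simulated algorithm submission
#'
#' Applies an [algorithm_profile()] to the latent TC of a generated
#' reference: calibration, additive noise, clamping to \[0, 1\], and
#' optional equal-width binning to midpoints.
#'
#' @param gen a [generate_reference()] result (reference plus latent truth).
#' @param profile an [algorithm_profile()].
#' @param seed integer seed.
#' @param entry_id entry identifier (defaults to the profile label).
#' @return a [submission()].
#' @export
generate_algorithm <- function(gen, profile, seed = 1,
                               entry_id = profile$label) {
  if (is.null(gen$latent)) {
    stop_validation("gen must carry latent TC (see generate_reference())",
                    "pkeval_type_error")
  }
  if (!inherits(profile, "algorithm_profile")) {
    stop_validation("profile must be an algorithm_profile",
                    "pkeval_type_error")
  }
  set.seed(derive_seed(seed, 1))
  cal <- calibration_fun(profile$calibration)
  x <- clamp01(cal(gen$latent) + rnorm(length(gen$latent), 0,
                                       profile$noise_sd))
  if (profile$n_bins >= 2) x <- bin_midpoints(x, profile$n_bins)
  submission(profile$label, entry_id,
             stats::setNames(x, names(gen$latent)))
}

## equal-width binning of [0,1] scores to bin midpoints
bin_midpoints <- function(x, k) {
  idx <- pmin(floor(x * k), k - 1)
  (idx + 0.5) / k
}
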