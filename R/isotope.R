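#' One gamma-counter measurement
#'
#' @param counts Raw counts accumulated over the counting window (>= 0).
#' @param duration Live counting time (s).
#' @param t_elapsed Minutes from the common reference time to the midpoint of
#'   the counting interval.
#' @param weight Sample weight (g, > 0).
#' @param dead_time_frac Detector dead-time fraction in [0, 1).
#' @param kind `"biopsy"`, `"plasma"` or `"whole_blood"`.
#' @return A `count_sample` object.
#' @export
count_sample <- function(counts, duration = 300, t_elapsed = 0, weight = 0.24,
                         dead_time_frac = 0,
                         kind = c("biopsy", "plasma", "whole_blood")) {
  kind <- match.arg(kind)
  if (counts < 0) stop("`counts` must be non-negative")
  if (duration <= 0) stop("`duration` must be positive (s)")
  if (!is.finite(t_elapsed)) stop("`t_elapsed` must be finite (min)")
  if (weight <= 0) stop("`weight` must be positive (g)")
  if (dead_time_frac < 0 || dead_time_frac >= 1) {
    stop("`dead_time_frac` must be in [0, 1)")
  }
  structure(list(counts = counts, duration = duration, t_elapsed = t_elapsed,
                 weight = weight, dead_time_frac = dead_time_frac, kind = kind),
            class = "count_sample")
}

#' Decay-correction settings for the tracer
#'
#' The default half-life is that of 99mTc, 6.01 h = 360.6 min.
#'
#' @param half_life Tracer half-life (min, > 0).
#' @param reference_time Label for the common reference time all counts are
#'   corrected to (informational; `t_elapsed` of each sample is measured from
#'   it).
#' @return A `decay_settings` object.
#' @export
decay_settings <- function(half_life = 360.6, reference_time = 0) {
  if (half_life <= 0) stop("`half_life` must be positive (min)")
  structure(list(half_life = half_life, reference_time = reference_time),
            class = "decay_settings")
}

#' Correct counts for radioactive decay back to the reference time
#'
#' `corrected = counts * 2^(t_elapsed / half_life)`.
#'
#' @param sample A `count_sample`.
#' @param settings A `decay_settings`.
#' @return Decay-corrected counts.
#' @examples
#' s <- count_sample(100, t_elapsed = 360.6)
#' decay_correct(s, decay_settings())  # 200
#' @export
decay_correct <- function(sample, settings = decay_settings()) {
  stopifnot(inherits(sample, "count_sample"), inherits(settings, "decay_settings"))
  sample$counts * 2^(sample$t_elapsed / settings$half_life)
}

#' Dead-time screening of a gamma-counter sample
#'
#' Samples whose detector dead-time fraction exceeds the threshold must be
#' re-measured before entering any ECV computation.
#'
#' @param sample A `count_sample`.
#' @param threshold Dead-time fraction above which a rerun is required
#'   (strict inequality). Default 0.10.
#' @return `"pass"` or `"rerun"`.
#' @export
screen_dead_time <- function(sample, threshold = 0.10) {
  stopifnot(inherits(sample, "count_sample"))
  if (sample$dead_time_frac > threshold) "rerun" else "pass"
}

#' Weight-normalized, decay-corrected specific activity
#'
#' @param sample A `count_sample`.
#' @param settings A `decay_settings`.
#' @param min_weight Least measurable weight of the scale (g); samples below
#'   it are rejected as unquantifiable. Default 0.097 g.
#' @return Specific activity in counts/g at the reference time.
#' @export
specific_activity <- function(sample, settings = decay_settings(),
                              min_weight = 0.097) {
  stopifnot(inherits(sample, "count_sample"))
  if (sample$weight < min_weight) {
    stop(sprintf("sample weight %.3f g is below the least measurable weight (%.3f g)",
                 sample$weight, min_weight))
  }
  decay_correct(sample, settings) / sample$weight
}

#' Tracer-dilution ECV from biopsies against a plasma reference
#'
#' Plasma specific activity is the 100 % ECV calibration point; each biopsy's
#' ECV is its specific activity divided by the plasma specific activity, and
#' the biopsies (typically 16 per subject) are averaged.
#'
#' @param biopsies List of `count_sample`s of kind `"biopsy"`.
#' @param plasma A `count_sample` of kind `"plasma"` (or the fallback
#'   reference of [plasma_reference_from_whole_blood()], given as counts/g).
#' @param settings A `decay_settings`.
#' @param dead_time_threshold Passed to [screen_dead_time()]; any failing
#'   sample aborts with an error naming it.
#' @param min_weight Passed to [specific_activity()].
#' @return ECV fraction.
#' @export
isotope_ecv <- function(biopsies, plasma, settings = decay_settings(),
                        dead_time_threshold = 0.10, min_weight = 0.097) {
  if (inherits(biopsies, "count_sample")) biopsies <- list(biopsies)
  if (length(biopsies) < 1L) stop("at least one biopsy is required")
  screened <- vapply(biopsies, screen_dead_time, character(1),
                     threshold = dead_time_threshold)
  if (inherits(plasma, "count_sample")) {
    if (screen_dead_time(plasma, dead_time_threshold) == "rerun") {
      stop("plasma sample exceeds the dead-time threshold; rerun it before computing ECV")
    }
    plasma_sa <- specific_activity(plasma, settings, min_weight)
  } else {
    plasma_sa <- plasma  # pre-computed reference activity in counts/g
  }
  if (any(screened == "rerun")) {
    stop(sprintf("biopsies %s exceed the dead-time threshold; rerun them before computing ECV",
                 paste(which(screened == "rerun"), collapse = ", ")))
  }
  if (plasma_sa <= 0) stop("plasma specific activity must be positive to serve as reference")
  sa <- vapply(biopsies, specific_activity, numeric(1),
               settings = settings, min_weight = min_weight)
  mean(sa / plasma_sa)
}

#' Hematocrit from whole-blood and plasma activities
#'
#' The tracer distributes in plasma only, so the whole-blood specific
#' activity is `(1 - Hct)` times the plasma specific activity (equal mass
#' densities assumed): `Hct = 1 - SA_wb / SA_plasma`.
#'
#' @param whole_blood,plasma `count_sample`s.
#' @param settings A `decay_settings`.
#' @param min_weight Passed to [specific_activity()].
#' @return Hematocrit fraction; values below 0 (activity ratio above 1) are
#'   returned with a plausibility warning.
#' @export
hct_from_activity <- function(whole_blood, plasma, settings = decay_settings(),
                              min_weight = 0.097) {
  plasma_sa <- specific_activity(plasma, settings, min_weight)
  if (plasma_sa <= 0) stop("plasma specific activity must be positive")
  ratio <- specific_activity(whole_blood, settings, min_weight) / plasma_sa
  if (ratio > 1) {
    warning(sprintf("whole-blood activity exceeds plasma activity (ratio %.3f): negative hematocrit is not physiologically plausible", ratio))
  }
  1 - ratio
}

#' Plasma reference activity reconstructed from whole blood
#'
#' Fallback for a hemolysed plasma sample: the whole-blood specific activity
#' divided by `1 - Hct` (laboratory hematocrit) estimates the plasma
#' specific activity.
#'
#' @param whole_blood A `count_sample`.
#' @param hct_lab Laboratory hematocrit in [0, 1).
#' @param settings A `decay_settings`.
#' @param min_weight Passed to [specific_activity()].
#' @return Estimated plasma specific activity (counts/g).
#' @export
plasma_reference_from_whole_blood <- function(whole_blood, hct_lab,
                                              settings = decay_settings(),
                                              min_weight = 0.097) {
  if (!is.numeric(hct_lab) || hct_lab < 0 || hct_lab >= 1) {
    stop("`hct_lab` must be a fraction in [0, 1)")
  }
  specific_activity(whole_blood, settings, min_weight) / (1 - hct_lab)
}

#' Sample mass below which gamma self-absorption would matter
#'
#' Approximates the sample as a cube of the given density with side equal to
#' the tissue half-value layer; a biopsy far lighter than this mass is
#' insensitive to self-absorption.
#'
#' @param half_value_layer Half-value layer of tissue for the tracer's
#'   photons (cm).
#' @param density Tissue density (g/cm^3).
#' @return Mass in g: `density * half_value_layer^3`.
#' @examples
#' self_absorption_mass(4, 1)  # 64 g
#' @export
self_absorption_mass <- function(half_value_layer, density = 1) {
  if (half_value_layer <= 0 || density <= 0) {
    stop("`half_value_layer` and `density` must be positive")
  }
  density * half_value_layer^3
}

#' Synthetic gamma-counter fixture for one subject
#'
#' Emulates the tracer-dilution experiment: `n_biopsies` myocardial punch
#' biopsies, one plasma and one whole-blood sample, counted sequentially so
#' each sample carries a different decay (`t_elapsed`) and must be
#' decay-corrected. True per-gram activities follow the dilution model:
#' biopsy activity = `ecv_true` times plasma activity, whole-blood activity =
#' `(1 - hct_true)` times plasma activity. Counts are the per-window totals;
#' with `poisson = TRUE` they are Poisson-perturbed.
#'
#' @param ecv_true True ECV fraction.
#' @param hct_true True hematocrit fraction.
#' @param plasma_activity Plasma specific activity at the reference time
#'   (counts/g over the counting window).
#' @param n_biopsies Number of biopsies (>= 1). Default 16.
#' @param poisson Add Poisson counting noise?
#' @param seed Integer seed; required when `poisson = TRUE` (it also draws
#'   the biopsy weights). Without a seed, weights are fixed at 0.24 g.
#' @param weight_mean,weight_sd Biopsy weight distribution (g); draws are
#'   truncated at the 0.097 g scale minimum. Defaults 0.24 and 0.11.
#' @param duration Counting window (s). Default 300 (5 min).
#' @param settings A `decay_settings`.
#' @return List with `biopsies` (list of `count_sample`), `plasma`,
#'   `whole_blood`, and the generating truths.
#' @export
make_isotope_fixture <- function(ecv_true, hct_true, plasma_activity = 2e5,
                                 n_biopsies = 16, poisson = FALSE, seed = NULL,
                                 weight_mean = 0.24, weight_sd = 0.11,
                                 duration = 300,
                                 settings = decay_settings()) {
  if (ecv_true <= 0 || ecv_true > 1) stop("`ecv_true` must be in (0, 1]")
  if (hct_true <= 0 || hct_true >= 1) stop("`hct_true` must be in (0, 1)")
  if (n_biopsies < 1) stop("`n_biopsies` must be at least 1")
  if (poisson && is.null(seed)) stop("a `seed` is required when `poisson = TRUE`")

  slot_min <- duration / 60 + 1               # counting window plus handling
  t_elapsed <- (seq_len(n_biopsies + 2) - 1) * slot_min + duration / 120
  sa_true <- c(rep(ecv_true * plasma_activity, n_biopsies),  # biopsies
               plasma_activity,                              # plasma
               (1 - hct_true) * plasma_activity)             # whole blood
  draw <- function() {
    w <- stats::rnorm(n_biopsies, weight_mean, weight_sd)
    pmax(w, 0.097)
  }
  weights <- if (is.null(seed)) rep(weight_mean, n_biopsies) else withr::with_seed(seed, draw())
  weights <- c(weights, 0.24, 0.24)            # plasma / whole-blood aliquots
  expected <- sa_true * weights * 2^(-t_elapsed / settings$half_life)
  counts <- if (poisson) {
    withr::with_seed(seed + 1L, stats::rpois(length(expected), expected))
  } else {
    expected
  }
  kinds <- c(rep("biopsy", n_biopsies), "plasma", "whole_blood")
  samples <- lapply(seq_along(counts), function(i) {
    count_sample(counts[i], duration = duration, t_elapsed = t_elapsed[i],
                 weight = weights[i], dead_time_frac = 0.02, kind = kinds[i])
  })
  list(biopsies = samples[seq_len(n_biopsies)],
       plasma = samples[[n_biopsies + 1]],
       whole_blood = samples[[n_biopsies + 2]],
       ecv_true = ecv_true, hct_true = hct_true, seed = seed)
}
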