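#' Inputs of the two-point contrast ECV computation
#'
#' @param t1_myo_pre,t1_myo_post Myocardial T1 before / after contrast (ms).
#' @param t1_blood_pre,t1_blood_post Blood T1 before / after contrast (ms).
#' @param hct Hematocrit fraction in [0, 1); 0 is the plasma-equivalent
#'   limit.
#' @return An `ecv_inputs` object. Post-contrast T1 values that are not
#'   shorter than their pre-contrast counterparts trigger a warning (the
#'   input is physically implausible for contrast-enhanced data) but are not
#'   rejected.
#' @export
ecv_inputs <- function(t1_myo_pre, t1_myo_post, t1_blood_pre, t1_blood_post, hct) {
  vals <- c(t1_myo_pre, t1_myo_post, t1_blood_pre, t1_blood_post)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all T1 values must be positive and finite (ms)")
  }
  if (!is.finite(hct) || hct < 0 || hct >= 1) stop("`hct` must be a fraction below 1")
  if (t1_myo_post >= t1_myo_pre || t1_blood_post >= t1_blood_pre) {
    warning("post-contrast T1 not shorter than pre-contrast T1: input is implausible for contrast-enhanced data")
  }
  structure(list(t1_myo_pre = t1_myo_pre, t1_myo_post = t1_myo_post,
                 t1_blood_pre = t1_blood_pre, t1_blood_post = t1_blood_post,
                 hct = hct),
            class = "ecv_inputs")
}

#' Extracellular volume fraction from paired pre/post-contrast T1
#'
#' The two-point contrast formula
#' `ECV = (1 - Hct) * (1/T1_myo_post - 1/T1_myo_pre) /
#'        (1/T1_blood_post - 1/T1_blood_pre)`:
#' the contrast-induced relaxation-rate change of myocardium relative to
#' blood, scaled from whole blood to plasma by `1 - Hct`.
#'
#' @param inputs An [ecv_inputs()] object.
#' @return ECV as a dimensionless fraction. Values outside (0, 1) indicate an
#'   upstream problem and are returned with a warning, never clamped.
#' @examples
#' compute_ecv(ecv_inputs(1000, 500, 1600, 300, hct = 0.31))  # ~0.255
#' @export
compute_ecv <- function(inputs) {
  stopifnot(inherits(inputs, "ecv_inputs"))
  dr1_myo <- 1 / inputs$t1_myo_post - 1 / inputs$t1_myo_pre
  dr1_blood <- 1 / inputs$t1_blood_post - 1 / inputs$t1_blood_pre
  if (dr1_blood == 0) {
    stop("blood relaxation-rate change is zero: ECV is undefined")
  }
  ecv <- (1 - inputs$hct) * dr1_myo / dr1_blood
  if (ecv < 0 || ecv > 1) {
    warning(sprintf("ECV %.3f lies outside (0, 1): check the input T1 values", ecv))
  }
  ecv
}

#' ECV measurements over time after contrast injection
#'
#' @param t Minutes after contrast injection (>= 0, strictly increasing).
#' @param ecv ECV fractions, one per time point.
#' @param subject,sequence Optional identifiers.
#' @return An `ecv_time_series` object.
#' @export
ecv_time_series <- function(t, ecv, subject = NA_character_,
                            sequence = NA_character_) {
  if (length(t) != length(ecv)) stop("`t` and `ecv` must have equal length")
  if (any(t < 0)) stop("`t` must be non-negative (min)")
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing")
  structure(list(points = data.frame(t = t, ecv = ecv),
                 subject = subject, sequence = sequence),
            class = "ecv_time_series")
}

#' Linear regression of ECV on time after contrast
#'
#' Ordinary least squares of ECV on time, optionally excluding the early
#' points before contrast has equilibrated across compartments (commonly the
#' first 10 min). The p-value is the two-sided t-test on the slope.
#'
#' @param series An `ecv_time_series`.
#' @param exclude_first_min Drop points with `t < exclude_first_min`; `NULL`
#'   keeps all points.
#' @return List with `slope` (fraction/min), `intercept` (fraction), `r2`,
#'   `p`, `n` and `excluded` (number of points dropped).
#' @export
ecv_time_regression <- function(series, exclude_first_min = NULL) {
  stopifnot(inherits(series, "ecv_time_series"))
  pts <- series$points
  excluded <- 0L
  if (!is.null(exclude_first_min)) {
    keep <- pts$t >= exclude_first_min
    excluded <- sum(!keep)
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) < 3L) {
    stop("at least 3 points are required for the time regression (after exclusion)")
  }
  fit <- stats::lm(ecv ~ t, data = pts)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)["t"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r2 = sm$r.squared,
       p = unname(sm$coefficients["t", "Pr(>|t|)"]),
       n = nrow(pts), excluded = excluded)
}

#' Mean ECV within a post-contrast time window
#'
#' @param series An `ecv_time_series`.
#' @param window Length-2 minutes `(min, max)`; points with
#'   `min <= t < max` are averaged. Default `c(10, 20)`.
#' @return Mean ECV fraction over the window.
#' @export
window_mean_ecv <- function(series, window = c(10, 20)) {
  stopifnot(inherits(series, "ecv_time_series"), length(window) == 2L)
  sel <- series$points$t >= window[1] & series$points$t < window[2]
  if (!any(sel)) {
    stop(sprintf("no ECV measurements in the %g-%g min window", window[1], window[2]))
  }
  mean(series$points$ecv[sel])
}

#' Format an ECV fraction as percent for reporting
#'
#' @param ecv ECV fraction(s).
#' @param digits Decimals; default 1, the conventional reporting precision.
#' @return Character vector, e.g. `"25.5"`.
#' @export
format_ecv_percent <- function(ecv, digits = 1) {
  sprintf(paste0("%.", digits, "f"), 100 * ecv)
}
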