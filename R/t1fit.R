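#' Septal sector region of interest
#'
#' Angles are measured counter-clockwise from the phantom's septal reference
#' direction; the radial band is expressed as fractions of the transmural
#' wall thickness (0 = endocardium, 1 = epicardium). The conventional septal
#' ROI spans 60 degrees of the circumference and the middle 60 % of the wall.
#'
#' @param angular_center Sector centre (degrees; 0 = septal reference).
#' @param angular_width Sector width (degrees, in (0, 360]).
#' @param radial_band Length-2 fractions `(inner, outer)` of wall thickness
#'   with `0 <= inner < outer <= 1`. Default `c(0.2, 0.8)` (middle 60 %).
#' @return A `sector_roi` object.
#' @export
sector_roi <- function(angular_center = 0, angular_width = 60,
                       radial_band = c(0.2, 0.8)) {
  if (angular_width <= 0 || angular_width > 360) {
    stop("`angular_width` must be in (0, 360] degrees")
  }
  if (length(radial_band) != 2L || radial_band[1] < 0 ||
      radial_band[1] >= radial_band[2] || radial_band[2] > 1) {
    stop("`radial_band` must satisfy 0 <= inner < outer <= 1")
  }
  structure(list(angular_center = angular_center,
                 angular_width = angular_width,
                 radial_band = radial_band),
            class = "sector_roi")
}

#' Mean signal over a myocardial sector
#'
#' Averages the pixels of a [make_phantom()] image whose polar angle (at the
#' pixel centre, counter-clockwise from the septal reference) lies within the
#' sector and whose normalized transmural depth lies within the radial band.
#' The lower angular boundary is inclusive, the upper exclusive, so pixels on
#' an exact boundary belong to the lower angle bin; the radial band is
#' closed.
#'
#' @param image A `phantom_image`.
#' @param roi A `sector_roi`.
#' @return Mean signal (a.u.) over the selected pixels.
#' @export
extract_sector_mean <- function(image, roi) {
  stopifnot(inherits(image, "phantom_image"), inherits(roi, "sector_roi"))
  dx <- col(image$pixels) - image$center[1]
  dy <- image$center[2] - row(image$pixels)  # counter-clockwise positive with y increasing downward
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) * 180 / pi
  rel <- (ang - image$septal_angle - roi$angular_center) %% 360
  rel[rel > 180] <- rel[rel > 180] - 360
  in_sector <- rel >= -roi$angular_width / 2 & rel < roi$angular_width / 2
  depth <- (r - image$r_endo) / (image$r_epi - image$r_endo)
  in_band <- depth >= roi$radial_band[1] & depth <= roi$radial_band[2]
  sel <- image$myo_mask & in_sector & in_band
  if (!any(sel)) {
    stop(sprintf("sector (centre %.0f deg, width %.0f deg, band %.2f-%.2f) contains no myocardial pixels",
                 roi$angular_center, roi$angular_width,
                 roi$radial_band[1], roi$radial_band[2]))
  }
  mean(image$pixels[sel])
}

new_t1_fit <- function(a, b, t1_star, t1, rss, n_points, corrected,
                       converged = TRUE, model = "ir3", message = NA_character_,
                       polarity_flips = NA_integer_) {
  structure(list(a = a, b = b, t1_star = t1_star, t1 = t1, rss = rss,
                 n_points = n_points, corrected = corrected,
                 converged = converged, model = model, message = message,
                 polarity_flips = polarity_flips),
            class = "t1_fit")
}

#' @export
print.t1_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<t1_fit> %s: FIT FAILED (%s)\n", x$model, x$message))
  } else {
    cat(sprintf("<t1_fit> %s: T1 = %.1f ms (T1* = %.1f ms%s), A = %.4g, B = %.4g, RSS = %.3g, n = %d\n",
                x$model, x$t1, x$t1_star,
                if (x$corrected) ", Look-Locker corrected" else "",
                x$a, x$b, x$rss, x$n_points))
  }
  invisible(x)
}

# Levenberg-Marquardt fit of y = A - B exp(-t / T1s) with multi-start
# initialization; returns NULL when no start converges.
fit_exp3 <- function(t, y, t1_starts = NULL, a0 = NULL, b0 = NULL) {
  if (is.null(t1_starts)) {
    med <- stats::median(t[is.finite(t)])
    t1_starts <- med * c(0.5, 1, 2)
  }
  if (is.null(a0)) a0 <- y[which.max(t)]
  if (is.null(b0)) b0 <- a0 - y[which.min(t)]
  if (!is.finite(b0) || b0 == 0) b0 <- if (a0 != 0) 2 * a0 else 1
  best <- NULL
  for (ts0 in t1_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A - B * exp(-t / T1s),
        start = list(A = a0, B = b0, T1s = ts0),
        lower = c(-Inf, -Inf, 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                             ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      p <- stats::coef(fit)
      best <- list(a = unname(p["A"]), b = unname(p["B"]),
                   t1_star = unname(p["T1s"]), rss = rss)
    }
  }
  best
}

#' 3-parameter inversion-recovery T1 fit with Look-Locker correction
#'
#' Fits `A - B exp(-t/T1*)` to the pooled (inversion time, signal) samples of
#' a MOLLI-style series by Levenberg-Marquardt least squares with
#' multi-start initialization. For magnitude data, polarity is restored by
#' trying every sign assignment consistent with a single zero crossing
#' (ordered by inversion time) and keeping the lowest-RSS fit. The reported
#' T1 is `T1* (B/A - 1)` (Look-Locker correction) when `ll_correction` is
#' `TRUE`, otherwise the apparent `T1*` itself; the apparent value is always
#' kept in `t1_star`.
#'
#' @param series An `acq_series` whose samples are inversion-prepared, or a
#'   data frame with columns `t_prep` (ms) and `signal`.
#' @param ll_correction Apply the Look-Locker correction? Default `TRUE`.
#'   Whether blood should be corrected is debatable — inflow of unperturbed
#'   spins removes the apparent-T1 shortening — so the flag is exposed rather
#'   than hard-wired.
#' @param is_magnitude Override the series' magnitude flag.
#' @return A `t1_fit`; on non-convergence a `t1_fit` with
#'   `converged = FALSE` and a diagnostic message, never a silent number.
#' @examples
#' t <- c(100, 300, 600, 1200, 2500, 5000)
#' y <- 1 - 2 * exp(-t / 800)
#' fit_ir3(data.frame(t_prep = t, signal = y))
#' @export
fit_ir3 <- function(series, ll_correction = TRUE, is_magnitude = NULL) {
  if (inherits(series, "acq_series")) {
    if (is.null(is_magnitude)) is_magnitude <- series$is_magnitude
    samp <- series$samples[series$samples$prep == "inversion", , drop = FALSE]
  } else {
    samp <- as.data.frame(series)
    if (is.null(is_magnitude)) is_magnitude <- FALSE
  }
  samp <- samp[is.finite(samp$t_prep), , drop = FALSE]
  if (length(unique(samp$t_prep)) < 3L) {
    stop("inversion-recovery fitting needs at least 3 distinct inversion times")
  }
  ord <- order(samp$t_prep)
  t <- samp$t_prep[ord]
  y <- samp$signal[ord]
  n <- length(y)

  if (is_magnitude) {
    best <- NULL
    best_k <- NA_integer_
    for (k in 0:n) {  # first k samples (shortest inversion times) negative
      sgn <- c(rep(-1, k), rep(1, n - k))
      cand <- fit_exp3(t, sgn * y)
      if (!is.null(cand) && (is.null(best) || cand$rss < best$rss)) {
        best <- cand
        best_k <- k
      }
    }
  } else {
    best <- fit_exp3(t, y)
    best_k <- NA_integer_
  }
  if (is.null(best)) {
    return(new_t1_fit(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, n,
                      corrected = ll_correction, converged = FALSE,
                      model = "ir3",
                      message = "no start of the Levenberg-Marquardt fit converged"))
  }
  t1 <- if (ll_correction) best$t1_star * (best$b / best$a - 1) else best$t1_star
  new_t1_fit(best$a, best$b, best$t1_star, t1, best$rss, n,
             corrected = ll_correction, model = "ir3",
             polarity_flips = best_k)
}

#' 3-parameter saturation-recovery T1 fit (SASHA)
#'
#' Fits `A - B exp(-t/T1)` to saturation-prepared samples; a non-prepared
#' reference sample (full recovery) contributes the asymptote as a data point
#' with infinite recovery time. Saturation destroys magnetization history, so
#' no Look-Locker correction is applied: the reported T1 equals the fitted
#' relaxation time.
#'
#' @param series An `acq_series` containing saturation-prepared samples and
#'   optionally one reference (`prep = "none"`) sample, or a data frame with
#'   columns `t_prep` (ms; `NA` or `Inf` for the reference) and `signal`.
#' @return A `t1_fit` with `corrected = FALSE`.
#' @export
fit_sr3 <- function(series) {
  if (inherits(series, "acq_series")) {
    samp <- series$samples[series$samples$prep %in% c("saturation", "none"), ,
                           drop = FALSE]
    t <- ifelse(samp$prep == "none", Inf, samp$t_prep)
  } else {
    samp <- as.data.frame(series)
    t <- ifelse(is.na(samp$t_prep), Inf, samp$t_prep)
  }
  y <- samp$signal
  n_sat <- sum(is.finite(t))
  if (n_sat < 2L || length(y) < 3L) {
    stop("saturation-recovery fitting needs at least 2 saturation-prepared samples and 3 samples in total (insufficient recovery points)")
  }
  ord <- order(t)
  t <- t[ord]
  y <- y[ord]
  a0 <- if (any(!is.finite(t))) mean(y[!is.finite(t)]) else max(y)
  best <- fit_exp3(t, y, a0 = a0, b0 = a0)
  if (is.null(best)) {
    return(new_t1_fit(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
                      length(y), corrected = FALSE, converged = FALSE,
                      model = "sr3",
                      message = "no start of the Levenberg-Marquardt fit converged"))
  }
  new_t1_fit(best$a, best$b, best$t1_star, best$t1_star, best$rss, length(y),
             corrected = FALSE, model = "sr3")
}

#' Round a T1 value for reporting
#'
#' T1 values are reported to the nearest 10 ms (half away from zero),
#' reflecting the practical precision of in-vivo T1 mapping. Reporting only —
#' never used inside computations.
#'
#' @param t1 T1 in ms (finite); vectorized.
#' @return T1 rounded to the nearest 10 ms.
#' @examples
#' round_report_t1(c(1823, 1825))  # 1820 1830
#' @export
round_report_t1 <- function(t1) {
  if (any(!is.finite(t1))) stop("`t1` must be finite")
  sign(t1) * floor(abs(t1) / 10 + 0.5) * 10
}
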