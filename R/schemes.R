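#' Parse a MOLLI acquisition-and-pause scheme string
#'
#' Clinical Look-Locker style T1-mapping protocols are described by a compact
#' notation such as `"5(3b)3"`: numbers outside parentheses are acquisition
#' trains (a count of images, one per heartbeat, or — when suffixed with
#' `"s"` — a window in seconds during which one image is acquired on every
#' R-wave), and parenthesized numbers are recovery pauses between inversions,
#' in beats (`"b"`) or seconds (`"s"`).
#'
#' @param notation Scheme string, e.g. `"5(3b)3"`, `"4(1s)3(1s)2"`,
#'   `"5s(3s)3s"`.
#' @return A `sampling_scheme` object: a list with `segments` (data frame with
#'   columns `kind`, `length`, `unit`) and `label` (the original notation).
#' @examples
#' parse_scheme("5(3b)3")
#' parse_scheme("4(1s)3(1s)2")
#' @export
parse_scheme <- function(notation) {
  if (!is.character(notation) || length(notation) != 1L || is.na(notation)) {
    stop("`notation` must be a single scheme string")
  }
  s <- notation
  kind <- character()
  len <- numeric()
  unit <- character()
  expect_acquire <- TRUE
  while (nchar(s) > 0L) {
    if (expect_acquire) {
      m <- regmatches(s, regexec("^([0-9]+)(s?)", s))[[1]]
      if (length(m) == 0L || m[1] == "") {
        tok <- substr(s, 1L, attr(regexpr("^[^0-9]*", s), "match.length"))
        stop(sprintf("malformed scheme '%s': expected an acquisition count, found '%s'",
                     notation, tok))
      }
      kind <- c(kind, "acquire")
      len <- c(len, as.numeric(m[2]))
      unit <- c(unit, if (m[3] == "s") "seconds" else "beats")
      s <- substring(s, nchar(m[1]) + 1L)
      expect_acquire <- FALSE
    } else {
      m <- regmatches(s, regexec("^\\(([0-9]+)([bs])\\)", s))[[1]]
      if (length(m) == 0L || m[1] == "") {
        tok <- sub("^(\\([^)]*\\)?).*$", "\\1", s)
        stop(sprintf("malformed scheme '%s': invalid pause token '%s'", notation, tok))
      }
      kind <- c(kind, "pause")
      len <- c(len, as.numeric(m[2]))
      unit <- c(unit, if (m[3] == "s") "seconds" else "beats")
      s <- substring(s, nchar(m[1]) + 1L)
      expect_acquire <- TRUE
    }
  }
  if (expect_acquire) {
    stop(sprintf("malformed scheme '%s': scheme must end with an acquisition segment",
                 notation))
  }
  segments <- data.frame(kind = kind, length = len, unit = unit,
                         stringsAsFactors = FALSE)
  if (any(segments$length <= 0)) {
    stop(sprintf("malformed scheme '%s': zero-length segment", notation))
  }
  pu <- unique(segments$unit[segments$kind == "pause"])
  if (length(pu) > 1L) {
    stop(sprintf("malformed scheme '%s': pause units must be uniform", notation))
  }
  structure(list(segments = segments, label = notation),
            class = "sampling_scheme")
}

#' Format a sampling scheme back to its notation string
#'
#' Inverse of [parse_scheme()]; round-trips every supported scheme.
#'
#' @param scheme A `sampling_scheme`.
#' @return The notation string.
#' @export
format_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  seg <- scheme$segments
  out <- character(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    if (seg$kind[i] == "acquire") {
      out[i] <- paste0(seg$length[i], if (seg$unit[i] == "seconds") "s" else "")
    } else {
      out[i] <- paste0("(", seg$length[i],
                       if (seg$unit[i] == "seconds") "s" else "b", ")")
    }
  }
  paste(out, collapse = "")
}

#' @export
print.sampling_scheme <- function(x, ...) {
  n_tr <- sum(x$segments$kind == "acquire")
  cat(sprintf("<sampling_scheme> %s (%d acquisition train%s)\n",
              x$label, n_tr, if (n_tr == 1L) "" else "s"))
  invisible(x)
}

new_timing_plan <- function(prep_times, prep_type, readout_times, heart_rate,
                            label = NA_character_) {
  rr <- 60 / heart_rate
  plan <- structure(
    list(prep_times = prep_times, prep_type = prep_type,
         readout_times = readout_times, heart_rate = heart_rate,
         rr_interval = rr, label = label),
    class = "timing_plan")
  validate_timing_plan(plan)
  plan
}

validate_timing_plan <- function(plan) {
  n <- length(plan$readout_times)
  if (length(plan$prep_times) != n || length(plan$prep_type) != n) {
    stop("timing plan: one preparation entry required per train")
  }
  for (i in seq_len(n)) {
    ro <- plan$readout_times[[i]]
    if (length(ro) == 0L) stop("timing plan: train without readouts")
    if (any(diff(ro) <= 0)) stop("timing plan: readout times must increase within a train")
    if (!is.na(plan$prep_times[i]) && any(ro < plan$prep_times[i])) {
      stop("timing plan: readout precedes its preparation pulse")
    }
    if (i < n) {
      nxt <- if (is.na(plan$prep_times[i + 1])) min(plan$readout_times[[i + 1]]) else plan$prep_times[i + 1]
      if (max(ro) >= nxt) stop("timing plan: trains overlap")
    }
  }
  invisible(plan)
}

#' @export
print.timing_plan <- function(x, ...) {
  cat(sprintf("<timing_plan> %s at %.0f beats/min (RR %.3f s): %d trains, %d readouts\n",
              if (is.na(x$label)) "unlabelled" else x$label,
              x$heart_rate, x$rr_interval,
              length(x$readout_times), sum(lengths(x$readout_times))))
  invisible(x)
}

#' Expand a sampling scheme into absolute ECG-gated timing
#'
#' Places preparation pulses and image readouts on the R-wave grid of a
#' subject with the given heart rate. Acquire segments yield one image per
#' heartbeat; a second-defined acquire window of k seconds yields
#' `floor(k/RR) + 1` images starting at the first R-wave of the window.
#' Beat-defined pauses last exactly `length * RR` seconds; second-defined
#' pauses end at the first R-wave at or after the stated duration, because
#' acquisition is cardiac triggered. Each train begins with one inversion
#' pulse fired on its starting R-wave; images are read `start_offsets`
#' seconds after their R-wave.
#'
#' @param scheme A `sampling_scheme` from [parse_scheme()].
#' @param heart_rate Heart rate in beats/min (> 0).
#' @param start_offsets Trigger delay (s) from each train's R-waves to the
#'   readout centre; a scalar is recycled across trains. Default 0.3 s.
#' @return A `timing_plan` with `prep_times` (s), `prep_type`,
#'   `readout_times` (list of numeric vectors, s), `heart_rate` and
#'   `rr_interval`.
#' @examples
#' expand_timing(parse_scheme("5(3b)3"), heart_rate = 60)
#' @export
expand_timing <- function(scheme, heart_rate, start_offsets = 0.3) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  if (!is.numeric(heart_rate) || length(heart_rate) != 1L || heart_rate <= 0) {
    stop("`heart_rate` must be a single positive number (beats/min)")
  }
  rr <- 60 / heart_rate
  seg <- scheme$segments
  n_trains <- sum(seg$kind == "acquire")
  offsets <- rep_len(start_offsets, n_trains)
  if (any(offsets <= 0) || any(offsets >= rr)) {
    stop(sprintf("trigger delays must lie strictly within one RR interval (%.3f s)", rr))
  }
  beat <- 0L                      # index of the next free R-wave
  train <- 0L
  prep_times <- numeric(n_trains)
  readout_times <- vector("list", n_trains)
  for (i in seq_len(nrow(seg))) {
    if (seg$kind[i] == "acquire") {
      train <- train + 1L
      prep_times[train] <- beat * rr
      n_img <- if (seg$unit[i] == "beats") {
        as.integer(seg$length[i])
      } else {
        as.integer(floor(seg$length[i] / rr + 1e-9)) + 1L
      }
      readout_times[[train]] <- (beat + seq_len(n_img) - 1L) * rr + offsets[train]
      beat <- beat + n_img
    } else {
      if (seg$unit[i] == "beats") {
        beat <- beat + as.integer(seg$length[i])
      } else {
        beat <- beat + as.integer(ceiling(seg$length[i] / rr - 1e-9))
      }
    }
  }
  new_timing_plan(prep_times, rep("inversion", n_trains), readout_times,
                  heart_rate, label = scheme$label)
}

#' Build a SASHA saturation-recovery timing plan
#'
#' SASHA acquires one non-prepared reference image (full recovery) plus a set
#' of saturation-prepared images, each in its own heartbeat with a saturation
#' pulse on the R-wave and the readout a chosen saturation delay later.
#' Because saturation destroys the magnetization history, consecutive beats
#' are independent and no Look-Locker correction is needed downstream.
#'
#' @param n_sat Number of saturation-prepared images (>= 2).
#' @param heart_rate Heart rate in beats/min.
#' @param ts_grid Saturation delays (s), one per saturation image; each must
#'   fit within one RR interval. Default: `n_sat` delays evenly spaced from
#'   0.1 s to 0.9 RR, capped so that the half readout window after the
#'   k-space centre still fits inside the beat (`RR - readout_margin`).
#' @param readout_margin Seconds reserved after the latest readout centre for
#'   the second half of the readout window. Default 0.1 s.
#' @return A `timing_plan`; the reference readout is the first train with
#'   `prep_type = "none"` and `prep_times = NA`.
#' @examples
#' sasha_timing(n_sat = 10, heart_rate = 60)
#' @export
sasha_timing <- function(n_sat = 10, heart_rate = 60, ts_grid = NULL,
                         readout_margin = 0.1) {
  if (!is.numeric(heart_rate) || length(heart_rate) != 1L || heart_rate <= 0) {
    stop("`heart_rate` must be a single positive number (beats/min)")
  }
  if (n_sat < 2) stop("`n_sat` must be at least 2")
  rr <- 60 / heart_rate
  if (is.null(ts_grid)) {
    ts_max <- min(0.9 * rr, rr - readout_margin)
    if (ts_max <= 0.1) stop(sprintf("RR interval %.3f s is too short for the default saturation-delay grid", rr))
    ts_grid <- seq(0.1, ts_max, length.out = n_sat)
  }
  if (length(ts_grid) != n_sat) stop("`ts_grid` must supply one delay per saturation image")
  if (any(ts_grid <= 0) || any(ts_grid >= rr)) {
    stop(sprintf("saturation delays must lie strictly within one RR interval (%.3f s)", rr))
  }
  # reference image first, in its own beat, no preparation
  prep_times <- c(NA_real_, seq_len(n_sat) * rr)
  prep_type <- c("none", rep("saturation", n_sat))
  readout_times <- c(list(max(ts_grid)),
                     as.list(seq_len(n_sat) * rr + ts_grid))
  new_timing_plan(prep_times, prep_type, readout_times, heart_rate,
                  label = sprintf("SASHA %dxSAT+1xREF", as.integer(n_sat)))
}

#' Serialize a timing plan to JSON
#'
#' Times are written in seconds with 6-decimal fixed precision.
#'
#' @param plan A `timing_plan`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
timing_plan_json <- function(plan, path = NULL) {
  stopifnot(inherits(plan, "timing_plan"))
  obj <- list(
    label = plan$label,
    heart_rate = plan$heart_rate,
    rr_interval = round(plan$rr_interval, 6),
    prep_times = round(plan$prep_times, 6),
    prep_type = plan$prep_type,
    readout_times = lapply(plan$readout_times, function(v) round(v, 6))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 6, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
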