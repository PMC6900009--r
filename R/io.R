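ACQ_SERIES_SCHEMA <- "ecvmri/acq_series/1"
RUN_CONFIG_SCHEMA <- "ecvmri/run_config/1"

#' Write an acquisition series as a JSON sidecar plus flat signal array
#'
#' Metadata (scheme label, heart rate, preparation types, inversion times in
#' ms, seed, schema tag) goes to `<stem>.json`; the signals go to
#' `<stem>.signals.txt`, one value per line, full precision.
#'
#' @param series An `acq_series`.
#' @param stem Output path stem (without extension).
#' @return `stem`, invisibly.
#' @export
write_acq_series <- function(series, stem) {
  stopifnot(inherits(series, "acq_series"))
  meta <- list(schema = ACQ_SERIES_SCHEMA,
               scheme_label = series$scheme_label,
               heart_rate = series$heart_rate,
               is_magnitude = series$is_magnitude,
               seed = series$seed,
               prep = series$samples$prep,
               t_prep_ms = series$samples$t_prep,
               train = series$samples$train)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, na = "null"),
             paste0(stem, ".json"))
  writeLines(format(series$samples$signal, digits = 17, scientific = TRUE,
                    trim = TRUE),
             paste0(stem, ".signals.txt"))
  invisible(stem)
}

#' Read an acquisition series written by [write_acq_series()]
#'
#' @param stem Path stem used when writing.
#' @return An `acq_series`.
#' @export
read_acq_series <- function(stem) {
  meta <- jsonlite::fromJSON(paste0(stem, ".json"))
  if (!identical(meta$schema, ACQ_SERIES_SCHEMA)) {
    stop(sprintf("unknown acquisition-series schema '%s' (expected '%s')",
                 meta$schema, ACQ_SERIES_SCHEMA))
  }
  signal <- as.numeric(readLines(paste0(stem, ".signals.txt")))
  n <- length(signal)
  if (length(meta$prep) != n) stop("signal array and sidecar metadata disagree in length")
  samples <- data.frame(prep = meta$prep,
                        t_prep = if (is.null(meta$t_prep_ms)) rep(NA_real_, n) else as.numeric(meta$t_prep_ms),
                        train = as.integer(meta$train),
                        signal = signal, stringsAsFactors = FALSE)
  new_acq_series(samples, meta$scheme_label, meta$heart_rate,
                 isTRUE(meta$is_magnitude),
                 seed = if (is.null(meta$seed)) NULL else meta$seed)
}

#' Write a run configuration to JSON
#'
#' The file round-trips losslessly through [read_run_config()].
#'
#' @param config A `run_config` from [default_run_config()].
#' @param path Output `.json` file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- unclass(config)
  obj$schema <- RUN_CONFIG_SCHEMA
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"),
             path)
  invisible(path)
}

#' Read a run configuration written by [write_run_config()]
#'
#' @param path `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!identical(obj$schema, RUN_CONFIG_SCHEMA)) {
    stop(sprintf("unknown run-config schema '%s' (expected '%s')",
                 obj$schema, RUN_CONFIG_SCHEMA))
  }
  obj$schema <- NULL
  # JSON stores every number the same way; restore the in-memory types
  normalize <- function(x) {
    if (is.list(x)) {
      if (length(x) == 0L) return(NULL)
      return(lapply(x, normalize))
    }
    if (is.integer(x)) return(as.double(x))
    x
  }
  obj <- normalize(obj)
  obj$seed <- as.integer(obj$seed)
  obj$n_subjects <- as.integer(obj$n_subjects)
  structure(obj, class = "run_config")
}

#' Hash of a run configuration
#'
#' MD5 of the canonical JSON form; stamped on every pipeline output so
#' results can be traced back to the exact configuration that produced them.
#'
#' @param config A `run_config`.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}
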