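#' Bland-Altman agreement against a reference method
#'
#' Differences are `test - reference`; the bias is their mean and the limits
#' of agreement are `bias +/- 1.96 SD` (sample SD, n - 1). In the modified
#' formulation used with a gold-standard reference, differences are plotted
#' against the reference values rather than the pairwise means; the choice
#' only affects the x-axis, never the bias or limits.
#'
#' @param reference,test Numeric vectors of equal length (>= 2).
#' @param x_axis `"reference"` (modified form) or `"mean"` (classical form).
#' @param loa_multiplier Limits-of-agreement multiplier. Default 1.96.
#' @return An `agreement_result`: `bias`, `loa_low`, `loa_high`, `sd_diff`,
#'   `n`, `x_axis`, and a `points` data frame (`x`, `difference`) for
#'   plotting.
#' @examples
#' bland_altman(c(0.18, 0.20, 0.22), c(0.22, 0.25, 0.27))
#' @export
bland_altman <- function(reference, test, x_axis = c("reference", "mean"),
                         loa_multiplier = 1.96) {
  x_axis <- match.arg(x_axis)
  if (length(reference) != length(test)) {
    stop("`reference` and `test` must have equal length")
  }
  if (length(reference) < 2L) stop("at least 2 paired values are required")
  d <- test - reference
  bias <- mean(d)
  sd_d <- stats::sd(d)
  x <- if (x_axis == "reference") reference else (reference + test) / 2
  structure(list(bias = bias,
                 loa_low = bias - loa_multiplier * sd_d,
                 loa_high = bias + loa_multiplier * sd_d,
                 sd_diff = sd_d, n = length(d), x_axis = x_axis,
                 points = data.frame(x = x, difference = d)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> bias %.4f, limits of agreement [%.4f, %.4f], n = %d (x-axis: %s)\n",
              x$bias, x$loa_low, x$loa_high, x$n, x$x_axis))
  invisible(x)
}

#' Paired comparisons with Bonferroni correction
#'
#' Two-sided paired t-tests over a pre-declared family of method pairs, with
#' Bonferroni adjustment over the family (`p_adjusted = min(1, m * p_raw)`).
#' Subjects with a missing value in either method of a pair are excluded
#' listwise, and the exclusion count is reported. When the paired differences
#' have zero variance the t-statistic is undefined; such comparisons are
#' flagged as degenerate and the p-value reported as the machine floor (or 1
#' when the differences are identically zero).
#'
#' @param values_by_method Data frame with a `subject` column and one column
#'   of per-subject values per method.
#' @param comparisons List of length-2 character vectors naming the method
#'   pairs; defaults to all pairs of method columns.
#' @return Data frame with one row per comparison: `method_a`, `method_b`,
#'   `mean_difference` (a - b), `p_raw`, `p_adjusted`, `n`, `n_excluded`,
#'   `degenerate`.
#' @export
paired_bonferroni <- function(values_by_method, comparisons = NULL) {
  stopifnot(is.data.frame(values_by_method), "subject" %in% names(values_by_method))
  methods <- setdiff(names(values_by_method), "subject")
  if (length(methods) < 2L) stop("at least 2 method columns are required")
  if (is.null(comparisons)) {
    comparisons <- utils::combn(methods, 2, simplify = FALSE)
  }
  bad <- vapply(comparisons, function(p) !all(p %in% methods), logical(1))
  if (any(bad)) {
    stop(sprintf("unknown method(s) in comparisons: %s",
                 paste(unique(unlist(comparisons[bad])), collapse = ", ")))
  }
  m <- length(comparisons)
  rows <- lapply(comparisons, function(pair) {
    a <- values_by_method[[pair[1]]]
    b <- values_by_method[[pair[2]]]
    ok <- is.finite(a) & is.finite(b)
    n_excl <- sum(!ok)
    if (n_excl > 0) {
      message(sprintf("%s vs %s: %d subject(s) excluded listwise for missing values",
                      pair[1], pair[2], n_excl))
    }
    d <- a[ok] - b[ok]
    if (length(d) < 3L) stop("at least 3 complete pairs are required per comparison")
    degenerate <- stats::sd(d) == 0
    if (degenerate) {
      p_raw <- if (mean(d) == 0) 1 else .Machine$double.xmin
    } else {
      p_raw <- stats::t.test(a[ok], b[ok], paired = TRUE)$p.value
    }
    data.frame(method_a = pair[1], method_b = pair[2],
               mean_difference = mean(d), p_raw = p_raw,
               p_adjusted = min(1, m * p_raw),
               n = length(d), n_excluded = n_excl,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
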