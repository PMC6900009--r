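#' Assemble the study report bundle
#'
#' Collects the pipeline outputs into presentation-ready tables following the
#' field's reporting conventions — ECV as percent with one decimal, T1
#' rounded to the nearest 10 ms — plus Bland-Altman and ECV-versus-time
#' figures and a machine-readable JSON of every number printed. In the
#' time plot, the first measurement of each sequence is drawn at its actual
#' mean acquisition time while later measurements are binned at 10-min
#' intervals.
#'
#' @param ecv_table Data frame with columns `subject`, `sequence`, `ecv`
#'   (fraction); one row per subject/sequence.
#' @param t1_table Optional data frame with columns `subject`, `sequence`,
#'   `compartment`, `phase`, `t1_ms`.
#' @param agreement Optional named list of `agreement_result`s (one per
#'   sequence).
#' @param regressions Optional data frame of per-sequence regression
#'   summaries (`sequence`, `slope`, `intercept`, `r2`, `p`, `n`).
#' @param ecv_time Optional data frame with columns `subject`, `sequence`,
#'   `t`, `ecv` for the time plot.
#' @param comparisons Optional data frame from [paired_bonferroni()].
#' @param out_dir Optional directory: writes `summary.csv`, `t1_table.csv`,
#'   `agreement.csv`, `regressions.csv`, `report.json` and PNG figures.
#' @return A `report_bundle` list with elements `summary`, `t1`,
#'   `agreement`, `regressions`, `comparisons`, `plots` and `json` (the JSON
#'   string), invisibly when written to disk.
#' @export
make_report <- function(ecv_table, t1_table = NULL, agreement = NULL,
                        regressions = NULL, ecv_time = NULL,
                        comparisons = NULL, out_dir = NULL) {
  if (is.null(ecv_table) || nrow(ecv_table) == 0L) {
    stop("`ecv_table` is empty: nothing to report")
  }
  need <- c("subject", "sequence", "ecv")
  if (!all(need %in% names(ecv_table))) {
    stop(sprintf("`ecv_table` must have columns %s", paste(need, collapse = ", ")))
  }
  seqs <- unique(ecv_table$sequence)
  check_keys <- function(tab, what) {
    extra <- setdiff(unique(tab$sequence), seqs)
    if (length(extra)) {
      stop(sprintf("%s refers to sequence(s) absent from `ecv_table`: %s",
                   what, paste(extra, collapse = ", ")))
    }
  }

  agg <- stats::aggregate(ecv ~ sequence, data = ecv_table,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  summary_tab <- data.frame(
    sequence = agg$sequence,
    n = agg$ecv[, "n"],
    ecv_mean_percent = format_ecv_percent(agg$ecv[, "mean"]),
    ecv_sd_percent = format_ecv_percent(agg$ecv[, "sd"]),
    stringsAsFactors = FALSE)

  t1_report <- NULL
  if (!is.null(t1_table) && nrow(t1_table) > 0L) {
    check_keys(t1_table, "`t1_table`")
    t1_report <- t1_table
    t1_report$t1_report_ms <- round_report_t1(t1_report$t1_ms)
  }

  agreement_tab <- NULL
  if (!is.null(agreement) && length(agreement)) {
    if (is.null(names(agreement))) stop("`agreement` must be a named list (one entry per sequence)")
    extra <- setdiff(names(agreement), seqs)
    if (length(extra)) {
      stop(sprintf("`agreement` refers to sequence(s) absent from `ecv_table`: %s",
                   paste(extra, collapse = ", ")))
    }
    agreement_tab <- do.call(rbind, lapply(names(agreement), function(nm) {
      a <- agreement[[nm]]
      data.frame(sequence = nm, bias = a$bias, loa_low = a$loa_low,
                 loa_high = a$loa_high, n = a$n, x_axis = a$x_axis,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(regressions) && nrow(regressions)) check_keys(regressions, "`regressions`")

  plots <- list()
  if (!is.null(agreement) && length(agreement)) {
    ba <- do.call(rbind, lapply(names(agreement), function(nm) {
      cbind(sequence = nm, agreement[[nm]]$points)
    }))
    plots$bland_altman <-
      ggplot2::ggplot(ba, ggplot2::aes(x = .data$x, y = .data$difference)) +
      ggplot2::geom_point() +
      ggplot2::geom_hline(data = agreement_tab,
                          ggplot2::aes(yintercept = .data$bias)) +
      ggplot2::geom_hline(data = agreement_tab,
                          ggplot2::aes(yintercept = .data$loa_low), linetype = 2) +
      ggplot2::geom_hline(data = agreement_tab,
                          ggplot2::aes(yintercept = .data$loa_high), linetype = 2) +
      ggplot2::facet_wrap(~sequence) +
      ggplot2::labs(x = "reference ECV (fraction)",
                    y = "test - reference ECV (fraction)")
  }
  if (!is.null(ecv_time) && nrow(ecv_time)) {
    check_keys(ecv_time, "`ecv_time`")
    et <- ecv_time
    et$bin <- floor(et$t / 10)
    binned <- stats::aggregate(cbind(ecv, t) ~ sequence + bin, data = et, FUN = mean)
    first_bin <- stats::aggregate(bin ~ sequence, data = binned, FUN = min)
    binned <- merge(binned, first_bin, by = "sequence", suffixes = c("", "_first"))
    binned$t_plot <- ifelse(binned$bin == binned$bin_first, binned$t,
                            binned$bin * 10 + 5)
    plots$ecv_time <-
      ggplot2::ggplot(binned, ggplot2::aes(x = .data$t_plot, y = .data$ecv)) +
      ggplot2::geom_point() + ggplot2::geom_line() +
      ggplot2::facet_wrap(~sequence) +
      ggplot2::labs(x = "time after contrast (min)", y = "ECV (fraction)")
  }

  json <- jsonlite::toJSON(
    list(summary = summary_tab, t1 = t1_report, agreement = agreement_tab,
         regressions = regressions, comparisons = comparisons),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null", null = "null")

  bundle <- structure(list(summary = summary_tab, t1 = t1_report,
                           agreement = agreement_tab, regressions = regressions,
                           comparisons = comparisons, plots = plots,
                           json = as.character(json)),
                      class = "report_bundle")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary_tab, file.path(out_dir, "summary.csv"), row.names = FALSE)
    if (!is.null(t1_report)) {
      utils::write.csv(t1_report, file.path(out_dir, "t1_table.csv"), row.names = FALSE)
    }
    if (!is.null(agreement_tab)) {
      utils::write.csv(agreement_tab, file.path(out_dir, "agreement.csv"), row.names = FALSE)
    }
    if (!is.null(regressions)) {
      utils::write.csv(regressions, file.path(out_dir, "regressions.csv"), row.names = FALSE)
    }
    writeLines(bundle$json, file.path(out_dir, "report.json"))
    for (nm in names(plots)) {
      ggplot2::ggsave(file.path(out_dir, paste0(nm, ".png")), plots[[nm]],
                      width = 8, height = 5, dpi = 120)
    }
    return(invisible(bundle))
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  print(x$summary)
  invisible(x)
}
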