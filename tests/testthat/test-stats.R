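test_that("Bland-Altman bias and limits match direct arithmetic", {
  ref <- c(0.18, 0.20, 0.22)
  tst <- c(0.22, 0.25, 0.27)
  d <- tst - ref
  a <- bland_altman(ref, tst)
  expect_equal(a$bias, mean(d))
  expect_equal(a$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(a$loa_high, mean(d) + 1.96 * sd(d))
  expect_equal(a$n, 3L)
  expect_true(a$loa_low <= a$bias && a$bias <= a$loa_high)
})

test_that("degenerate Bland-Altman cases collapse correctly", {
  x <- c(0.2, 0.25, 0.3)
  same <- bland_altman(x, x)
  expect_equal(same$bias, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)
  off <- bland_altman(x, x + 0.05)
  expect_equal(off$bias, 0.05)
  expect_equal(off$loa_high - off$loa_low, 0)
  expect_error(bland_altman(x, x[1:2]), "equal length")
})

test_that("the x-axis choice moves the plot abscissa but never the bias", {
  ref <- c(0.18, 0.21, 0.24, 0.20)
  tst <- c(0.24, 0.23, 0.28, 0.25)
  m <- bland_altman(ref, tst, x_axis = "mean")
  r <- bland_altman(ref, tst, x_axis = "reference")
  expect_equal(m$bias, r$bias)
  expect_equal(m$loa_low, r$loa_low)
  expect_equal(m$points$x, (ref + tst) / 2)
  expect_equal(r$points$x, ref)
})

test_that("paired comparisons adjust p-values over the declared family", {
  df <- data.frame(subject = 1:6,
                   a = c(0.20, 0.22, 0.24, 0.21, 0.23, 0.25),
                   b = c(0.25, 0.26, 0.30, 0.27, 0.28, 0.31),
                   c = c(0.20, 0.22, 0.24, 0.21, 0.23, 0.25))
  res <- paired_bonferroni(df, list(c("a", "b"), c("a", "c"), c("b", "c")))
  expect_equal(nrow(res), 3L)
  # identical methods: zero difference, adjusted p of 1
  row_ac <- res[res$method_a == "a" & res$method_b == "c", ]
  expect_equal(row_ac$mean_difference, 0)
  expect_equal(row_ac$p_adjusted, 1)
  # raw t-test times the family size, capped at 1
  raw <- t.test(df$a, df$b, paired = TRUE)$p.value
  row_ab <- res[res$method_a == "a" & res$method_b == "b", ]
  expect_equal(row_ab$p_raw, raw)
  expect_equal(row_ab$p_adjusted, min(1, 3 * raw))
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-15))
  expect_true(all(res$p_adjusted <= 1))
})

test_that("zero-variance differences are flagged, not silently tested", {
  df <- data.frame(subject = 1:4, a = c(1, 2, 3, 4), b = c(1, 2, 3, 4) + 0.04)
  res <- paired_bonferroni(df, list(c("a", "b")))
  expect_true(res$degenerate)
  expect_equal(res$mean_difference, -0.04)
  expect_lte(res$p_raw, .Machine$double.xmin)
})

test_that("subjects with missing values are excluded listwise with a count", {
  df <- data.frame(subject = 1:5,
                   a = c(0.2, 0.22, NA, 0.21, 0.23),
                   b = c(0.24, 0.25, 0.28, 0.26, 0.27))
  expect_message(res <- paired_bonferroni(df, list(c("a", "b"))), "excluded")
  expect_equal(res$n, 4L)
  expect_equal(res$n_excluded, 1L)
})

test_that("a true method offset is detected with the expected power", {
  # 8 subjects, offset 0.04, SD 0.02: the noncentral-t oracle puts the
  # paired-test power near 0.998, so at least 95% of seeds must reject
  ncp <- 0.04 / (0.02 / sqrt(8))
  crit <- qt(0.975, df = 7)
  power_oracle <- 1 - pt(crit, 7, ncp) + pt(-crit, 7, ncp)
  expect_gt(power_oracle, 0.95)
  rejections <- vapply(1:500, function(s) {
    d <- withr::with_seed(s, rnorm(8, 0.04, 0.02))
    df <- data.frame(subject = 1:8, a = d, b = 0)
    paired_bonferroni(df, list(c("a", "b")))$p_adjusted < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
})

test_that("reports apply the field's formatting conventions and round-trip", {
  ecv_tab <- data.frame(subject = rep(c("S1", "S2"), each = 2),
                        sequence = rep(c("MOLLI 5(3b)3", "SASHA"), 2),
                        ecv = c(0.2547, 0.212, 0.2612, 0.2203))
  t1_tab <- data.frame(subject = "S1", sequence = "SASHA",
                       compartment = "blood", phase = "pre", t1_ms = 1823)
  bundle <- make_report(ecv_tab, t1_table = t1_tab)
  expect_equal(bundle$t1$t1_report_ms, 1820)
  molli_row <- bundle$summary[bundle$summary$sequence == "MOLLI 5(3b)3", ]
  expect_identical(molli_row$ecv_mean_percent,
                   format_ecv_percent(mean(c(0.2547, 0.2612))))
  # machine-readable JSON reproduces every printed cell
  parsed <- jsonlite::fromJSON(bundle$json)
  expect_identical(parsed$summary$ecv_mean_percent, bundle$summary$ecv_mean_percent)
  expect_equal(parsed$t1$t1_report_ms, 1820)
})

test_that("reports validate their inputs", {
  expect_error(make_report(data.frame()), "empty")
  ecv_tab <- data.frame(subject = "S1", sequence = "SASHA", ecv = 0.21)
  bad_t1 <- data.frame(subject = "S1", sequence = "MOLLI 5(3b)3",
                       compartment = "blood", phase = "pre", t1_ms = 1600)
  expect_error(make_report(ecv_tab, t1_table = bad_t1), "MOLLI 5\\(3b\\)3")
})
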