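# Shared fixtures and independent oracles, built in code at test time.

# Noise-free signed inversion-recovery samples y = a - b exp(-t / t1_star).
ideal_ir_df <- function(t, a = 1, b = 2, t1_star = 800) {
  data.frame(t_prep = t, signal = a - b * exp(-t / t1_star))
}

# Brute-force grid search over (A, B, T1*) minimising the residual sum of
# squares; independent of the Levenberg-Marquardt path it checks.
grid_search_ir <- function(t, y, a_range, b_range, t1_range, n = 41) {
  grid_a <- seq(a_range[1], a_range[2], length.out = n)
  grid_b <- seq(b_range[1], b_range[2], length.out = n)
  grid_t1 <- seq(t1_range[1], t1_range[2], length.out = n)
  best <- list(rss = Inf)
  for (a in grid_a) for (b in grid_b) for (t1 in grid_t1) {
    rss <- sum((y - (a - b * exp(-t / t1)))^2)
    if (rss < best$rss) best <- list(a = a, b = b, t1_star = t1, rss = rss)
  }
  best
}

table2_schemes <- c("5(3b)3", "5(3s)3", "5s(3s)3s",
                    "4(1b)3(1b)2", "4(1s)3(1s)2", "4s(1s)3s(1s)2s")

# Standard myocardium-like and blood-like tissue used across tests.
myo_1000 <- function() tissue_state(1000, 45, label = "myocardium")
blood_1800 <- function() tissue_state(1800, 250, label = "blood")

# Tiny pipeline configuration that keeps test runtime low.
small_config <- function(seed = 7, ...) {
  cfg <- default_run_config(seed = seed, n_subjects = 3,
                            post_times_min = c(12, 18, 27), ...)
  cfg$sequences <- cfg$sequences[c(1, 4)]   # one MOLLI variant + SASHA
  cfg
}
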