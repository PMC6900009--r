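test_that("free relaxation follows the closed-form Bloch recovery", {
  myo <- myo_1000()
  expect_equal(evolve_mz(-1, 1e9, myo), 1)
  expect_equal(evolve_mz(-1, 1000 * log(2), myo), 0)
  expect_equal(evolve_mz(0, 1000, myo), 1 - exp(-1))
  expect_error(evolve_mz(0.5, -1, myo), "non-negative")
})

test_that("tissue and sequence parameter invariants are enforced", {
  expect_error(tissue_state(1000, 1200), "t2")
  expect_error(tissue_state(-5, 45), "t1")
  expect_error(sequence_params(te = 3, tr = 2.6), "te")
  expect_error(sequence_params(inversion_efficiency = 0), "inversion_efficiency")
  expect_error(sequence_params(saturation_residual = 1), "saturation_residual")
})

test_that("apparent relaxation under the readout shortens T1 and collapses correctly", {
  myo <- myo_1000()
  # alpha = 0: transparent readout, free relaxation, signal tracks input
  sp0 <- sequence_params(flip_angle = 0)
  ro <- apply_readout(0.4, myo, sp0)
  expect_equal(ro$signal, 0.4)
  expect_equal(ro$mz_out, evolve_mz(0.4, sp0$readout_duration, myo))
  # T1 = T2: the apparent rate collapses to 1/T1 at any flip angle
  iso <- tissue_state(800, 800)
  expect_equal(readout_steady_state(iso, sequence_params(flip_angle = 35))$t1_star,
               800)
  # myocardium-like tissue at 35 degrees: strict shortening
  expect_lt(readout_steady_state(myo, sequence_params(flip_angle = 35))$t1_star,
            1000)
})

test_that("ideal single-train inversion recovery lies exactly on the closed form", {
  plan <- expand_timing(parse_scheme("5"), 60)
  myo <- myo_1000()
  sp <- sequence_params(flip_angle = 0, inversion_efficiency = 1)
  sim <- simulate_series(plan, myo, sp)
  expected <- myo$m0 * (1 - 2 * exp(-sim$samples$t_prep / 1000))
  expect_equal(sim$samples$signal, expected, tolerance = 1e-12)
})

test_that("simulation is deterministic under a fixed seed and demands one with noise", {
  plan <- expand_timing(parse_scheme("5(3b)3"), 75)
  myo <- myo_1000()
  spn <- sequence_params(flip_angle = 35, noise_sd = 0.01)
  a <- simulate_series(plan, myo, spn, seed = 42)
  b <- simulate_series(plan, myo, spn, seed = 42)
  expect_identical(a$samples$signal, b$samples$signal)
  c <- simulate_series(plan, myo, spn, seed = 43)
  expect_false(identical(a$samples$signal, c$samples$signal))
  expect_error(simulate_series(plan, myo, spn), "seed")
})

test_that("rician noise flags the series as magnitude data", {
  plan <- expand_timing(parse_scheme("5"), 60)
  spr <- sequence_params(flip_angle = 0, noise_sd = 0.01, noise_model = "rician")
  sim <- simulate_series(plan, myo_1000(), spr, seed = 1)
  expect_true(sim$is_magnitude)
  expect_true(all(sim$samples$signal >= 0))
})

test_that("later MOLLI trains start from incompletely recovered magnetization", {
  plan <- expand_timing(parse_scheme("5(3b)3"), 88)
  sim <- simulate_series(plan, myo_1000(), sequence_params(flip_angle = 35),
                         inflow = FALSE)
  expect_equal(sim$mz_pre_prep[1], 1)
  expect_lt(sim$mz_pre_prep[2], 0.99)
})

test_that("magnetization stays within physical bounds across the parameter grid", {
  for (hr in c(60, 88, 110)) for (t1 in c(400, 1000, 1800)) {
    tis <- tissue_state(t1, min(45, t1 / 3), label = "myocardium")
    plan <- expand_timing(parse_scheme("4(1b)3(1b)2"), hr)
    sim <- simulate_series(plan, tis, sequence_params(flip_angle = 35),
                           inflow = FALSE)
    expect_true(all(abs(sim$samples$signal) <= tis$m0 + 1e-9))
    expect_true(all(abs(sim$mz_pre_prep) <= 1 + 1e-9))
  }
})

test_that("contrast kinetics prolong T1 back to native as the agent clears", {
  kin <- gd_kinetics(ecv_true = 0.25, hct_true = 0.31)
  expect_equal(gd_t1_course(1e7, 1800, kin, "blood"), 1800, tolerance = 1e-6)
  kin0 <- gd_kinetics(k_clear = 0, ecv_true = 0.25, hct_true = 0.31)
  expect_equal(gd_t1_course(0, 1800, kin0, "blood"),
               gd_t1_course(50, 1800, kin0, "blood"))
  expect_error(gd_t1_course(-1, 1800, kin, "blood"), "non-negative")
  # T1 is monotonically prolonged over time
  tt <- gd_t1_course(seq(0, 60, by = 5), 1200, kin, "myocardium")
  expect_true(all(diff(tt) > 0))
})

test_that("the equilibrium contrast model is the algebraic inverse of the ECV formula", {
  for (ecv in c(0.1, 0.25, 0.4)) for (t in c(0, 12, 47)) {
    kin <- gd_kinetics(ecv_true = ecv, hct_true = 0.31)
    inp <- ecv_inputs(
      t1_myo_pre = 1200,
      t1_myo_post = gd_t1_course(t, 1200, kin, "myocardium"),
      t1_blood_pre = 1800,
      t1_blood_post = gd_t1_course(t, 1800, kin, "blood"),
      hct = 0.31)
    expect_equal(compute_ecv(inp), ecv, tolerance = 1e-13)
  }
})

test_that("full-loop ECV recovery is exact under complete-recovery acquisition", {
  # single-train IR sampling removes the between-inversion recovery residual:
  # simulate pre/post series for both compartments, fit, feed the ECV formula
  kin <- gd_kinetics(ecv_true = 0.27, hct_true = 0.33)
  plan <- expand_timing(parse_scheme("5"), 60)
  sp <- sequence_params(flip_angle = 0, noise_sd = 0)
  t1_of <- function(native, comp, t_post = NULL) {
    t1 <- if (is.null(t_post)) native else gd_t1_course(t_post, native, kin, comp)
    tis <- tissue_state(t1, 45, label = if (comp == "blood") "blood" else "myocardium")
    fit_ir3(simulate_series(plan, tis, sp))$t1
  }
  inp <- ecv_inputs(t1_of(1200, "myocardium"), t1_of(1200, "myocardium", 15),
                    t1_of(1800, "blood"), t1_of(1800, "blood", 15),
                    hct = 0.33)
  expect_equal(compute_ecv(inp), 0.27, tolerance = 1e-7)
})

test_that("pause-limited recovery biases MOLLI T1 down, worse at high heart rate", {
  # transparent readout isolates the incomplete-recovery mechanism of
  # beat-defined pauses: deficit grows with heart rate and with 1/pause
  fit_bias <- function(scheme, hr, t1) {
    plan <- expand_timing(parse_scheme(scheme), hr)
    tis <- tissue_state(t1, 45, label = "myocardium")
    sim <- simulate_series(plan, tis, sequence_params(flip_angle = 0))
    fit_ir3(sim)$t1 - t1
  }
  b60 <- fit_bias("5(3b)3", 60, 1000)
  b90 <- fit_bias("5(3b)3", 90, 1000)
  expect_lt(b60, 0)
  expect_lt(b90, b60)
  # the short-pause post-contrast scheme is hit harder than the long-pause one
  expect_lt(fit_bias("4(1b)3(1b)2", 90, 1000), b90)
})

test_that("isochromat MOLLI underestimates T1 while SASHA stays nearly unbiased", {
  tis <- tissue_state(1100, 45, label = "myocardium")
  plan <- expand_timing(parse_scheme("5(3b)3"), 70)
  molli <- fit_ir3(simulate_series(plan, tis, sequence_params(flip_angle = 35),
                                   inflow = FALSE))
  sasha <- fit_sr3(simulate_series(sasha_timing(10, 70), tis,
                                   sequence_params(flip_angle = 70),
                                   inflow = FALSE))
  expect_lt(molli$t1, 1100)
  expect_lt(abs(sasha$t1 - 1100), abs(molli$t1 - 1100))
})

test_that("phantom geometry, masks and noise behave as specified", {
  ph <- make_phantom(n = 64, r_endo = 12, r_epi = 20, myo_signal = 1,
                     blood_signal = 2)
  expect_true(all(ph$pixels[ph$myo_mask] == 1))
  expect_true(all(ph$pixels[ph$blood_mask] == 2))
  expect_false(any(ph$myo_mask & ph$blood_mask))
  # brute-force per-pixel radius oracle for the annulus count
  cnt <- 0L
  for (row in 1:64) for (col in 1:64) {
    r <- sqrt((col - ph$center[1])^2 + (row - ph$center[2])^2)
    if (r >= 12 && r < 20) cnt <- cnt + 1L
  }
  expect_equal(sum(ph$myo_mask), cnt)
  # determinism and the seed requirement
  p1 <- make_phantom(n = 32, r_endo = 6, r_epi = 10, noise_sd = 0.1, seed = 5)
  p2 <- make_phantom(n = 32, r_endo = 6, r_epi = 10, noise_sd = 0.1, seed = 5)
  expect_identical(p1$pixels, p2$pixels)
  expect_error(make_phantom(n = 32, r_endo = 6, r_epi = 10, noise_sd = 0.1),
               "seed")
  expect_error(make_phantom(n = 32, r_endo = 10, r_epi = 20), "grid")
})

test_that("noiseless isotope fixtures round-trip the generating truths exactly", {
  fx <- make_isotope_fixture(ecv_true = 0.19, hct_true = 0.31)
  st <- decay_settings()
  expect_equal(isotope_ecv(fx$biopsies, fx$plasma, st), 0.19, tolerance = 1e-12)
  expect_equal(hct_from_activity(fx$whole_blood, fx$plasma, st), 0.31,
               tolerance = 1e-12)
  # hemolysis fallback reproduces the plasma reference exactly
  expect_equal(plasma_reference_from_whole_blood(fx$whole_blood, 0.31, st),
               specific_activity(fx$plasma, st), tolerance = 1e-9)
  # ecv_true = 1: biopsies indistinguishable from plasma per gram
  fx1 <- make_isotope_fixture(ecv_true = 1, hct_true = 0.31)
  expect_equal(specific_activity(fx1$biopsies[[1]], st),
               specific_activity(fx1$plasma, st), tolerance = 1e-12)
})
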