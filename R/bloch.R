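#' Tissue relaxation state
#'
#' @param t1 Longitudinal relaxation time (ms).
#' @param t2 Transverse relaxation time (ms); must satisfy `0 < t2 <= t1`.
#' @param m0 Equilibrium magnetization (arbitrary units, > 0).
#' @param label `"myocardium"` or `"blood"`; steers the default inflow
#'   behaviour during simulated readouts (flowing blood is continuously
#'   replaced by spins unaffected by previous readouts).
#' @return A `tissue_state` object.
#' @examples
#' tissue_state(t1 = 1200, t2 = 45, label = "myocardium")
#' @export
tissue_state <- function(t1, t2, m0 = 1, label = c("myocardium", "blood")) {
  label <- match.arg(label)
  if (!is.numeric(t1) || t1 <= 0) stop("`t1` must be positive (ms)")
  if (!is.numeric(t2) || t2 <= 0 || t2 > t1) stop("`t2` must satisfy 0 < t2 <= t1")
  if (!is.numeric(m0) || m0 <= 0) stop("`m0` must be positive")
  structure(list(t1 = t1, t2 = t2, m0 = m0, label = label),
            class = "tissue_state")
}

#' Pulse-sequence parameters for the simulated bSSFP readout
#'
#' @param flip_angle Readout flip angle (degrees); 0 makes the readout
#'   transparent (no perturbation of the recovery curve).
#' @param tr Repetition time (ms).
#' @param te Echo time (ms); must be below `tr`.
#' @param readout_duration Length of the single-shot readout window (ms).
#' @param inversion_efficiency Fraction in (0, 1]: an inversion maps
#'   `mz -> -inversion_efficiency * mz`.
#' @param saturation_residual Fraction in [0, 1): longitudinal magnetization
#'   left immediately after a saturation pulse.
#' @param noise_sd Standard deviation of additive signal noise (same units as
#'   the signal; `m0` scales the signal).
#' @param noise_model `"gaussian"` (additive, signed signal) or `"rician"`
#'   (magnitude signal).
#' @return A `sequence_params` object.
#' @export
sequence_params <- function(flip_angle = 35, tr = 2.6, te = 1.1,
                            readout_duration = 161,
                            inversion_efficiency = 0.96,
                            saturation_residual = 0,
                            noise_sd = 0,
                            noise_model = c("gaussian", "rician")) {
  noise_model <- match.arg(noise_model)
  if (te >= tr) stop("`te` must be smaller than `tr`")
  if (readout_duration <= 0) stop("`readout_duration` must be positive (ms)")
  if (flip_angle < 0 || flip_angle > 180) stop("`flip_angle` must be in [0, 180] degrees")
  if (inversion_efficiency <= 0 || inversion_efficiency > 1) {
    stop("`inversion_efficiency` must be in (0, 1]")
  }
  if (saturation_residual < 0 || saturation_residual >= 1) {
    stop("`saturation_residual` must be in [0, 1)")
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(list(flip_angle = flip_angle, tr = tr, te = te,
                 readout_duration = readout_duration,
                 inversion_efficiency = inversion_efficiency,
                 saturation_residual = saturation_residual,
                 noise_sd = noise_sd, noise_model = noise_model),
            class = "sequence_params")
}

#' Free longitudinal relaxation
#'
#' Closed-form Bloch recovery of the longitudinal magnetization toward
#' equilibrium: `mz(dt) = 1 - (1 - mz0) * exp(-dt / t1)`, in units of `m0`.
#'
#' @param mz0 Starting magnetization, as a fraction of `m0`.
#' @param dt Elapsed time (ms, >= 0); vectorized.
#' @param tissue A `tissue_state`.
#' @return Magnetization after `dt`, fraction of `m0`.
#' @examples
#' evolve_mz(-1, 1000 * log(2), tissue_state(1000, 45))  # inversion null point
#' @export
evolve_mz <- function(mz0, dt, tissue) {
  stopifnot(inherits(tissue, "tissue_state"))
  if (any(dt < 0)) stop("`dt` must be non-negative (ms)")
  1 - (1 - mz0) * exp(-dt / tissue$t1)
}

#' Apparent relaxation rate and steady state under a bSSFP readout
#'
#' During a balanced SSFP readout the longitudinal magnetization is driven
#' toward a T1/T2-dependent steady state with an apparent rate
#' `1/T1* = cos^2(a/2)/T1 + sin^2(a/2)/T2` and steady-state level
#' `M_ss = M0 sin(a/2) / ((T1/T2 + 1) - cos(a) (T1/T2 - 1))`. This is the
#' mechanism that shortens the recovery curve of Look-Locker style sequences
#' and motivates the T1* correction.
#'
#' @param tissue A `tissue_state`.
#' @param seq A `sequence_params`.
#' @return List with `t1_star` (ms) and `m_ss` (fraction of `m0`).
#' @export
readout_steady_state <- function(tissue, seq) {
  stopifnot(inherits(tissue, "tissue_state"), inherits(seq, "sequence_params"))
  a <- seq$flip_angle * pi / 180
  r_star <- cos(a / 2)^2 / tissue$t1 + sin(a / 2)^2 / tissue$t2
  ratio <- tissue$t1 / tissue$t2
  m_ss <- sin(a / 2) / ((ratio + 1) - cos(a) * (ratio - 1))
  list(t1_star = 1 / r_star, m_ss = m_ss)
}

#' Apply one single-shot bSSFP readout to the longitudinal magnetization
#'
#' The magnetization relaxes toward the driven steady state of
#' [readout_steady_state()] over `readout_duration`; the signal is
#' proportional to the magnetization at the readout centre. With
#' `flip_angle = 0` the readout is transparent: the magnetization relaxes
#' freely and the signal is proportional to the input magnetization.
#'
#' @param mz_in Magnetization entering the readout (fraction of `m0`).
#' @param tissue A `tissue_state`.
#' @param seq A `sequence_params`.
#' @return List with `signal` (a.u., `m0`-scaled) and `mz_out` (fraction of
#'   `m0` after the full readout window).
#' @export
apply_readout <- function(mz_in, tissue, seq) {
  stopifnot(inherits(tissue, "tissue_state"), inherits(seq, "sequence_params"))
  rd <- seq$readout_duration
  if (seq$flip_angle == 0) {
    signal <- tissue$m0 * mz_in
    mz_out <- evolve_mz(mz_in, rd, tissue)
    return(list(signal = signal, mz_out = mz_out))
  }
  ss <- readout_steady_state(tissue, seq)
  drive <- function(mz, dt) ss$m_ss + (mz - ss$m_ss) * exp(-dt / ss$t1_star)
  mz_mid <- drive(mz_in, rd / 2)
  list(signal = tissue$m0 * mz_mid, mz_out = drive(mz_mid, rd / 2))
}

# One single-shot bSSFP readout simulated pulse by pulse (on-resonance
# isochromat): alpha/2 catalyzation, alternating +/-alpha excitations about x,
# T1/T2 relaxation between pulses. The signed signal is the transverse
# magnitude at the k-space-centre TR, signed by the longitudinal state;
# residual transverse magnetization after the shot is discarded (crushed),
# so mz_out is the longitudinal component only.
bssfp_shot <- function(mz_in, tissue, seq) {
  t1 <- tissue$t1
  t2 <- tissue$t2
  tr <- seq$tr
  n_tr <- max(2L, round(seq$readout_duration / tr))
  cen <- max(1L, round(n_tr / 2))
  a <- seq$flip_angle * pi / 180
  e1h <- exp(-tr / 2 / t1); e2h <- exp(-tr / 2 / t2)
  e1 <- e1h^2; e2 <- e2h^2
  rot <- function(M, th) c(M[1],
                           cos(th) * M[2] - sin(th) * M[3],
                           sin(th) * M[2] + cos(th) * M[3])
  M <- c(0, 0, mz_in)
  M <- rot(M, a / 2)
  M <- c(M[1] * e2h, M[2] * e2h, 1 - (1 - M[3]) * e1h)
  sgn <- -1
  sig <- NA_real_
  for (k in seq_len(n_tr)) {
    M <- rot(M, sgn * a)
    if (k == cen) {
      Me <- c(M[1] * e2h, M[2] * e2h)   # echo at TE = TR/2
      sig <- sign(M[3]) * sqrt(Me[1]^2 + Me[2]^2)
    }
    M <- c(M[1] * e2, M[2] * e2, 1 - (1 - M[3]) * e1)
    sgn <- -sgn
  }
  list(signal = tissue$m0 * sig, mz_out = M[3])
}

new_acq_series <- function(samples, scheme_label, heart_rate, is_magnitude,
                           seed = NULL, mz_pre_prep = NULL) {
  structure(list(samples = samples, scheme_label = scheme_label,
                 heart_rate = heart_rate, is_magnitude = is_magnitude,
                 seed = seed, mz_pre_prep = mz_pre_prep,
                 schema = "ecvmri/acq_series/1"),
            class = "acq_series")
}

#' @export
print.acq_series <- function(x, ...) {
  cat(sprintf("<acq_series> %s at %.0f beats/min: %d samples (%s)\n",
              x$scheme_label, x$heart_rate, nrow(x$samples),
              if (x$is_magnitude) "magnitude" else "signed"))
  invisible(x)
}

#' Simulate an acquisition series through a timing plan
#'
#' Chains preparation pulses (inversion: `mz -> -inversion_efficiency * mz`;
#' saturation: `mz -> saturation_residual`), free Bloch relaxation between
#' events and the bSSFP readout perturbation of [apply_readout()] for every
#' image of the plan, then adds noise. For flowing blood the default is
#' `inflow = TRUE`: imaged spins are continuously replaced, so the readout
#' leaves the recovery curve unperturbed (transparent readout) even at a
#' nonzero flip angle.
#'
#' @param plan A `timing_plan` (times in seconds).
#' @param tissue A `tissue_state`.
#' @param seq A `sequence_params`.
#' @param seed Integer seed; mandatory whenever `noise_sd > 0`.
#' @param inflow Logical; `NULL` (default) resolves to `TRUE` for blood and
#'   `FALSE` for myocardium.
#' @param readout_model `"isochromat"` (default): the readout block is
#'   simulated pulse by pulse, which reproduces the empirically observed
#'   direction and magnitude of the Look-Locker T1 underestimation;
#'   `"apparent"`: the closed-form driven-relaxation approximation of
#'   [apply_readout()], cheaper but cruder about the transient.
#' @return An `acq_series`: `samples` is a data frame with columns `prep`,
#'   `t_prep` (ms since the sample's preparation pulse; `NA` for the
#'   non-prepared reference image), `train` and `signal`. The magnetization
#'   entering each preparation pulse is kept in `mz_pre_prep` for
#'   diagnostics of incomplete recovery between trains.
#' @examples
#' plan <- expand_timing(parse_scheme("5(3b)3"), heart_rate = 60)
#' myo <- tissue_state(1000, 45)
#' sim <- simulate_series(plan, myo, sequence_params(flip_angle = 0))
#' @export
simulate_series <- function(plan, tissue, seq, seed = NULL, inflow = NULL,
                            readout_model = c("isochromat", "apparent")) {
  stopifnot(inherits(plan, "timing_plan"), inherits(tissue, "tissue_state"),
            inherits(seq, "sequence_params"))
  readout_model <- match.arg(readout_model)
  if (seq$noise_sd > 0 && is.null(seed)) {
    stop("a `seed` is required when `noise_sd` > 0")
  }
  if (is.null(inflow)) inflow <- identical(tissue$label, "blood")
  rd <- seq$readout_duration            # ms
  transparent <- inflow || seq$flip_angle == 0

  t_cur <- 0                            # ms on the absolute clock
  mz <- 1                               # fraction of m0; equilibrium at start
  prep <- character(); t_prep <- numeric(); train_idx <- integer()
  signal <- numeric(); mz_pre_prep <- numeric()

  n_trains <- length(plan$readout_times)
  for (i in seq_len(n_trains)) {
    ptype <- plan$prep_type[i]
    if (ptype != "none") {
      pt <- plan$prep_times[i] * 1000
      mz <- evolve_mz(mz, pt - t_cur, tissue)
      t_cur <- pt
      mz_pre_prep <- c(mz_pre_prep, mz)
      mz <- switch(ptype,
                   inversion = -seq$inversion_efficiency * mz,
                   saturation = seq$saturation_residual,
                   stop(sprintf("unknown preparation type '%s'", ptype)))
    } else {
      mz_pre_prep <- c(mz_pre_prep, NA_real_)
    }
    for (tc in plan$readout_times[[i]] * 1000) {
      w0 <- tc - rd / 2                 # readout window start
      if (w0 < t_cur) {
        stop(sprintf("readout window at %.1f ms starts before the previous event (%.1f ms); increase the trigger delay or shorten the readout", tc, t_cur))
      }
      mz <- evolve_mz(mz, w0 - t_cur, tissue)
      if (transparent) {
        mz_mid <- evolve_mz(mz, rd / 2, tissue)
        s <- tissue$m0 * mz_mid
        mz <- evolve_mz(mz_mid, rd / 2, tissue)
      } else if (readout_model == "isochromat") {
        ro <- bssfp_shot(mz, tissue, seq)
        s <- ro$signal
        mz <- ro$mz_out
      } else {
        ro <- apply_readout(mz, tissue, seq)
        s <- ro$signal
        mz <- ro$mz_out
      }
      t_cur <- tc + rd / 2
      prep <- c(prep, ptype)
      t_prep <- c(t_prep,
                  if (ptype == "none") NA_real_ else tc - plan$prep_times[i] * 1000)
      train_idx <- c(train_idx, i)
      signal <- c(signal, s)
    }
  }

  is_magnitude <- FALSE
  if (seq$noise_sd > 0) {
    signal <- withr::with_seed(seed, {
      if (seq$noise_model == "rician") {
        sqrt((signal + stats::rnorm(length(signal), 0, seq$noise_sd))^2 +
               stats::rnorm(length(signal), 0, seq$noise_sd)^2)
      } else {
        signal + stats::rnorm(length(signal), 0, seq$noise_sd)
      }
    })
    is_magnitude <- seq$noise_model == "rician"
  }
  samples <- data.frame(prep = prep, t_prep = t_prep, train = train_idx,
                        signal = signal, stringsAsFactors = FALSE)
  new_acq_series(samples, plan$label, plan$heart_rate, is_magnitude,
                 seed = seed, mz_pre_prep = mz_pre_prep)
}

#' Gadolinium contrast kinetics
#'
#' Mono-exponential renal clearance of an extracellular gadolinium agent from
#' plasma, with the myocardial concentration tied to the blood concentration
#' through the equilibrium two-compartment relation
#' `C_myo = C_blood * ecv_true / (1 - hct_true)` — the algebraic inverse of
#' the two-point ECV formula, which makes the generator/estimator pair
#' exactly self-consistent.
#'
#' @param r1 Relaxivity (1/ms per mM). Default 0.0035, typical of
#'   macrocyclic agents at 1.5 T.
#' @param c0_blood Blood concentration at t = 0 (mM).
#' @param k_clear Clearance rate (1/min).
#' @param ecv_true True extracellular volume fraction in (0, 1).
#' @param hct_true True hematocrit in (0, 1).
#' @return A `gd_kinetics` object.
#' @export
gd_kinetics <- function(r1 = 0.0035, c0_blood = 0.8, k_clear = 0.011,
                        ecv_true = 0.25, hct_true = 0.31) {
  if (any(c(r1, c0_blood) <= 0) || k_clear < 0) {
    stop("`r1` and `c0_blood` must be positive; `k_clear` non-negative")
  }
  if (ecv_true <= 0 || ecv_true >= 1) stop("`ecv_true` must be in (0, 1)")
  if (hct_true <= 0 || hct_true >= 1) stop("`hct_true` must be in (0, 1)")
  structure(list(r1 = r1, c0_blood = c0_blood, k_clear = k_clear,
                 ecv_true = ecv_true, hct_true = hct_true),
            class = "gd_kinetics")
}

#' T1 time course after contrast injection
#'
#' `R1(t) = 1/T1_native + r1 * C(t)` with `C_blood(t) = c0 exp(-k t)` and the
#' equilibrium myocardial concentration of [gd_kinetics()]; returns
#' `1 / R1(t)` in ms. As contrast clears, T1 is gradually prolonged back
#' toward its native value.
#'
#' @param t_after_contrast Minutes since injection (>= 0); vectorized.
#' @param tissue_native_t1 Native T1 of the compartment (ms).
#' @param kin A `gd_kinetics`.
#' @param compartment `"blood"` or `"myocardium"`.
#' @return T1 (ms) at each requested time.
#' @export
gd_t1_course <- function(t_after_contrast, tissue_native_t1, kin,
                         compartment = c("blood", "myocardium")) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(kin, "gd_kinetics"))
  if (any(t_after_contrast < 0)) stop("`t_after_contrast` must be non-negative (min)")
  if (tissue_native_t1 <= 0) stop("`tissue_native_t1` must be positive (ms)")
  conc <- kin$c0_blood * exp(-kin$k_clear * t_after_contrast)
  if (compartment == "myocardium") {
    conc <- conc * kin$ecv_true / (1 - kin$hct_true)
  }
  1 / (1 / tissue_native_t1 + kin$r1 * conc)
}
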