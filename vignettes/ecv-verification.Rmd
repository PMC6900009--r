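---
title: "Simulating and verifying the ECV measurement chain"
author: "ecvmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and verifying the ECV measurement chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecvmri)
```

## The measurement chain

Myocardial extracellular volume fraction (ECV) is estimated clinically from
paired T1 measurements before and after administration of an extracellular
gadolinium agent:

$$\mathrm{ECV} \;=\; (1-\mathrm{Hct})\,
\frac{1/T_{1,\mathrm{myo}}^{\mathrm{post}} - 1/T_{1,\mathrm{myo}}^{\mathrm{pre}}}
     {1/T_{1,\mathrm{blood}}^{\mathrm{post}} - 1/T_{1,\mathrm{blood}}^{\mathrm{pre}}}.$$

Every quantity entering this formula is itself the output of a pulse
sequence and a curve fit, so sequence-dependent T1 bias propagates into
sequence-dependent ECV. The package implements the whole chain so that this
propagation can be studied quantitatively without a scanner:

1. **schemes** — the acquisition-and-pause grammar of Look-Locker protocols
   (`"5(3b)3"`, `"4(1s)3(1s)2"`, ...) expanded onto the R-wave grid of a
   given heart rate (`parse_scheme()`, `expand_timing()`, `sasha_timing()`).
2. **simulation** — longitudinal Bloch dynamics through a timing plan:
   inversion and saturation preparations, free relaxation, and the
   perturbation of a balanced SSFP readout (`simulate_series()`), plus the
   contrast kinetics that generate paired pre/post tissue states
   (`gd_kinetics()`, `gd_t1_course()`) and a ring phantom for ROI analysis
   (`make_phantom()`, `extract_sector_mean()`).
3. **fitting** — 3-parameter recovery fits with polarity restoration and the
   Look-Locker correction $T_1 = T_1^*(B/A-1)$ for inversion recovery
   (`fit_ir3()`), and the uncorrected saturation-recovery fit (`fit_sr3()`).
4. **ECV** — the two-point formula (`compute_ecv()`), drift regression over
   time after contrast (`ecv_time_regression()`) and window means
   (`window_mean_ecv()`).
5. **isotope reference** — the tracer-dilution gold standard: decay
   correction, dead-time screening, weight normalisation, the
   plasma-referenced ECV, activity-derived hematocrit and the hemolysis
   fallback (`isotope_ecv()` and friends).
6. **agreement** — modified Bland-Altman against the reference and
   Bonferroni-corrected paired comparisons (`bland_altman()`,
   `paired_bonferroni()`), assembled by `make_report()` /
   `run_pipeline()`.

## The readout model

A single-shot bSSFP readout does not merely sample the recovering
magnetization, it drives it: during the shot the magnetization magnitude
relaxes toward the bSSFP steady state with an apparent time constant

$$\frac{1}{T_1^*} = \frac{\cos^2(\alpha/2)}{T_1} +
\frac{\sin^2(\alpha/2)}{T_2}, \qquad
M_{ss} = \frac{M_0\,\sin(\alpha/2)}{(T_1/T_2+1) - \cos\alpha\,(T_1/T_2-1)},$$

which is why Look-Locker sequences report an apparent $T_1^* < T_1$ and need
correction. `apply_readout()` exposes this closed-form approximation
directly (drive toward the steady state at rate $1/T_1^*$, signal taken at
the k-space centre of the window).

For the simulator default we went one level deeper. The closed-form drive
treats the whole shot as a single exponential; when its samples are fed to
the pooled 3-parameter fit plus Look-Locker correction, the correction
over-compensates and the fitted T1 comes out *above* truth — the opposite of
what is observed on real Look-Locker acquisitions. Simulating the shot pulse
by pulse (on-resonance isochromat: $\alpha/2$ catalyzation, alternating
$\pm\alpha$ excitations every TR, T1/T2 relaxation between pulses, signal at
the k-space-centre TR, residual transverse magnetization discarded)
reproduces the empirically established behaviour: with $\alpha = 35^\circ$,
TR 2.6 ms, a 161 ms shot and inversion efficiency 0.96, the corrected MOLLI
T1 of a 1000/45 ms tissue at 60 beats/min comes out near 950 ms, a ~5 %
underestimation of the right sign and magnitude. `simulate_series()`
therefore defaults to `readout_model = "isochromat"`; the cheaper
closed-form drive remains available as `readout_model = "apparent"`. The
shot costs 62 small vector operations per image, so the isochromat default
is still desk-scale.

Flowing blood is continuously replaced by spins that never experienced a
readout, so for blood the readout is transparent by default
(`inflow = TRUE`); this also removes the rationale for the Look-Locker
correction in blood, which is why `fit_ir3()` exposes `ll_correction` as a
switch (the pipeline applies it to blood by default, configurable via
`fit$ll_blood`).

## Which biases the simulator does and does not reproduce

Worth stating precisely, because it defines what a green test suite means:

* **MOLLI underestimates T1; SASHA is nearly unbiased.** Reproduced. The
  isochromat readout gives MOLLI deficits of roughly 30–80 ms at
  myocardium-like T1, while the saturation preparation erases magnetization
  history and leaves SASHA essentially exact. The native-T1 ordering
  (SASHA > all MOLLI variants, in both compartments) emerges from the
  simulation.
* **Short pauses hurt, and more so at high heart rate.** Reproduced where
  the mechanism applies: with beat-defined pauses that are short relative to
  T1 (the post-contrast `4(1b)3(1b)2` pattern, or any scheme once T1 is
  long), the fitted deficit grows with heart rate, and the simulated ECV
  drift over time after contrast is largest for `5(3b)3`, smaller for
  `5(3s)3`, smaller again for `5s(3s)3s` and absent for SASHA — the ordering
  expected from pause arithmetic. For the *native* long-pause `5(3b)3`
  acquisition itself the net heart-rate trend of the deficit is slightly
  positive in this model: the readout-drag term (which shrinks with beat
  spacing) outweighs the pause-recovery term there. The two mechanisms can
  be separated with `flip_angle = 0`, which isolates incomplete recovery and
  then shows the deficit growing with heart rate for every beat-defined
  scheme.
* **MOLLI overestimates ECV in vivo.** *Not* reproduced, deliberately. The
  in-vivo overestimation is driven by post-contrast myocardial T1 being
  underestimated *more* than pre-contrast T1, for which magnetization
  transfer is a leading explanation. Magnetization transfer, off-resonance,
  slice profile and through-plane motion are outside this package's scope; a
  scalar inversion efficiency is the only "hardware imperfection" retained.
  In the simulator the pre-contrast (long-T1) fits are the more biased ones,
  so simulated MOLLI ECV sits slightly *below* the reference instead. Tests
  therefore assert T1-level directions and exact algebraic round trips, not
  cohort-level ECV means.

## Synthetic study conditions

`default_run_config()` fixes the conditions of the synthetic verification
study; they are chosen once, as plausible 1.5 T large-animal values, and are
not tuned per run:

| parameter | default | rationale |
|---|---|---|
| subjects | 8 | paired-design size typical of verification experiments |
| heart rate | 88 ± 11 beats/min (truncated 50–120) | anesthetized-pig range |
| hematocrit | 0.31 ± 0.04 | porcine venous values |
| true ECV | 0.25 ± 0.02 | healthy-myocardium range |
| myocardium T1/T2 | 1200 / 45 ms | native 1.5 T values |
| blood T1/T2 | 1800 / 250 ms | native 1.5 T values |
| relaxivity $r_1$ | 0.0035 (ms·mM)$^{-1}$ | macrocyclic Gd agent at 1.5 T |
| $C_0$ blood | 0.8 mM | 0.2 mmol/kg dose after first-pass dilution |
| clearance $k$ | 0.011 min$^{-1}$ | renal elimination half-time ≈ 1 h |
| flip angle | 35° (MOLLI) / 70° (SASHA) | protocol values |
| TE/TR, shot | 1.1/2.6 ms, 161 ms | protocol values |
| inversion efficiency | 0.96 | adiabatic pulse, scalar stand-in for its T2 dependence |
| trigger delay | 0.3 s | mid-diastolic readout; no per-image TI increments are published for the protocols, so the delay is a configurable scalar |
| image noise | Gaussian, SD 0.005 · M0 | SNR ~ 200 ROI-mean regime; Rician available for magnitude pixels |
| post-contrast times | 5–55 min, every 10 min | hour-long decay experiment |
| isotope fixture | 16 biopsies, 0.24 ± 0.11 g (≥ 0.097 g), 5-min counts, half-life 360.6 min, plasma 2·10⁵ counts/g, Poisson | gamma-counting protocol of the reference method |

The myocardial concentration is tied to blood by the equilibrium relation
$C_{\mathrm{myo}} = C_{\mathrm{blood}}\,\mathrm{ECV}/(1-\mathrm{Hct})$ — the
algebraic inverse of the ECV formula. This makes the generator/estimator
pair exactly self-consistent: feeding the four noise-free
`gd_t1_course()` outputs into `compute_ecv()` returns the true ECV to
machine precision, which is the pipeline's core self-test. The isotope
fixture has the same property (exact ECV and hematocrit recovery without
Poisson noise; unbiased recovery within counting statistics with it).

## Numerical choices

* Fits use Levenberg–Marquardt (`minpack.lm::nlsLM`) with multi-start
  initialization ($T_1^*$ seeds at 0.5×, 1×, 2× the median recovery time),
  relative tolerance $10^{-10}$, at most 500 iterations. Non-convergence
  returns a flagged failure object, never a silent number.
* Magnitude inversion-recovery data are fitted by trying every polarity
  assignment consistent with one zero crossing in recovery-time order and
  keeping the lowest residual sum of squares.
* Multi-train MOLLI samples are pooled into a single (TI, signal) cloud
  before fitting. Because the later trains start from incompletely recovered
  magnetization, the pooled noiseless fit is not bit-exact against truth —
  roughly 0.3–1 % for native T1 values — which is physics, not a numerical
  artifact; the exactness tests therefore use single-train or
  saturation-recovery acquisitions.
* Second-defined pauses end at the first R-wave at or after the stated
  duration (acquisition is ECG-triggered, and sub-beat timing is not
  defined); at exactly 60 beats/min, beat- and second-defined variants of
  the same scheme produce identical plans. A second-defined acquire window
  of $k$ seconds yields $\lfloor k/RR\rfloor + 1$ images starting on its
  first R-wave.
* The default SASHA saturation grid spans 0.1 s to 0.9 RR (capped so the
  readout window still fits inside the beat at high heart rate), plus one
  non-prepared reference image treated as infinite recovery in the fit.
* Sector ROIs decide membership at pixel centres; pixels on an exact
  angular boundary belong to the lower angle bin, and the radial band is
  closed. Angles are counter-clockwise from the phantom's septal reference.
* Decay correction uses the midpoint of the counting interval; with 5-min
  windows the midpoint-versus-endpoint difference is below 0.5 %.
* T1 values are rounded to the nearest 10 ms (half away from zero) and ECV
  formatted as percent with one decimal *only at the reporting layer*.
* Every stochastic stage receives a seed derived deterministically from the
  root seed; reports embed the MD5 hash of the generating configuration.

## Problem sizes

The test suite exercises the chain at desk scale: single acquisitions for
the fit oracles, 5×5×5 parameter grids for the algebraic round trip, 200
Monte-Carlo seeds for the Poisson counting calibration, 500 seeds for the
paired-test power check, and a 3-subject × 2-sequence pipeline for the
orchestration tests. The shipped demo (`run_pipeline(default_run_config())`)
runs 8 subjects × 4 sequences × 7 time points in a few seconds.

## Known limitations

* No magnetization transfer, off-resonance, slice-profile or inflow physics
  beyond the scalar efficiency and the transparent-blood option — hence no
  reproduction of in-vivo cohort means, and no MOLLI ECV overestimation (see
  above).
* Mono-exponential contrast clearance with a single compartment pair; no
  transient water-exchange effects early after injection.
* Fixed RR interval (no arrhythmia or gating variability).
* The isotope module models counting statistics and decay, not
  gamma-spectrum energy windows or geometry-dependent detector efficiency.
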