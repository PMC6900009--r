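# ecvmri

Quantifying myocardial extracellular volume fraction (ECV) by cardiac MRI
depends on T1-mapping sequences that are known to be biased: MOLLI-type
Look-Locker acquisitions underestimate T1 in a sequence-, tissue- and
timing-dependent way, while saturation-recovery SASHA is nearly unbiased.
Because ECV is computed from four fitted T1 values and the hematocrit,

    ECV = (1 - Hct) * (1/T1_myo_post - 1/T1_myo_pre) / (1/T1_blood_post - 1/T1_blood_pre)

those biases propagate into the reported ECV. `ecvmri` implements the full
measurement chain needed to study this propagation without a scanner, for
researchers developing or validating T1-mapping protocols:

* **Scheme grammar and timing** — parse protocol notation such as
  `"5(3b)3"` or `"4(1s)3(1s)2"` (acquisitions outside parentheses, pauses
  inside, in beats or seconds) and expand it onto the R-wave grid of any
  heart rate; SASHA saturation grids with a reference image.
* **Bloch-level simulation** — inversion/saturation preparations, free
  relaxation and a pulse-by-pulse balanced-SSFP readout that reproduces the
  apparent-T1 shortening and the resulting Look-Locker bias; gadolinium
  clearance kinetics that generate self-consistent pre/post tissue states;
  short-axis ring phantoms with septal sector ROIs; Gaussian or Rician
  noise, fully seeded.
* **T1 fitting** — 3-parameter inversion-recovery fits with polarity
  restoration and the Look-Locker correction `T1 = T1* (B/A - 1)`, and
  3-parameter saturation-recovery fits with an infinite-recovery reference
  point.
* **ECV analysis** — the two-point formula, ECV drift regression over time
  after contrast (with and without the first 10 minutes), window means.
* **Radioisotope reference** — the tracer-dilution gold standard:
  half-life decay correction, the 10 % dead-time rerun rule, weight
  normalisation, plasma-referenced ECV over 16 biopsies, activity-derived
  hematocrit and the hemolysis fallback.
* **Agreement statistics** — modified Bland-Altman against the reference
  and Bonferroni-corrected paired comparisons, with reporting in the
  field's conventions (T1 to the nearest 10 ms, ECV in percent with one
  decimal).

## Worked example

The sensitivity of ECV to the blood pre-contrast T1 — the quantity that
differs most visibly between MOLLI and SASHA native maps — is small:

```r
library(ecvmri)

molli <- compute_ecv(ecv_inputs(t1_myo_pre = 1000, t1_myo_post = 500,
                                t1_blood_pre = 1600, t1_blood_post = 300,
                                hct = 0.31))
sasha <- compute_ecv(ecv_inputs(t1_myo_pre = 1000, t1_myo_post = 500,
                                t1_blood_pre = 1820, t1_blood_post = 300,
                                hct = 0.31))
format_ecv_percent(c(molli, sasha))
#> [1] "25.5" "24.8"
```

Changing only the blood pre-contrast T1 from 1600 ms to 1820 ms moves ECV
by 0.7 percentage points — far less than the 4–5 point MOLLI–SASHA gaps
seen in vivo, which must therefore be driven by the myocardial post-contrast
T1 instead.

The full synthetic verification study — 8 subjects, four sequences
(MOLLI 5(3b)3, 5(3s)3, 5s(3s)3s, SASHA), repeated imaging over an hour
after contrast, and a 16-biopsy isotope reference per subject — runs in a
few seconds:

```r
res <- run_pipeline(default_run_config(seed = 1))
res$report$summary
#>         sequence n ecv_mean_percent ecv_sd_percent
#> 1        isotope 8             25.4            2.7
#> 2   MOLLI 5(3b)3 8             24.6            3.3
#> 3   MOLLI 5(3s)3 8             23.9            2.6
#> 4 MOLLI 5s(3s)3s 8             24.4            2.7
#> 5          SASHA 8             25.8            4.9
```

Native T1 in the same run reproduces the characteristic sequence ordering
(means over subjects, reported to the nearest 10 ms): myocardium 1140–1170
ms by the MOLLI variants against 1180 ms by SASHA (true 1200 ms), blood
1660–1710 ms against 1820 ms (true 1800 ms) — MOLLI low, SASHA nearly
unbiased. The simulated ECV drift after contrast is steepest for
MOLLI 5(3b)3 (0.05 %/min in this run), smaller for 5(3s)3 and 5s(3s)3s, and
absent for SASHA, the ordering expected from pause-recovery arithmetic.
`res$agreement` holds the Bland-Altman comparison of every sequence against
the isotope reference, and `res$report$json` the machine-readable report.
See the vignette (`vignettes/ecv-verification.Rmd`) for the model, its
assumptions, and which in-vivo effects it deliberately does not include.

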