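# uteT2star

Quantitative T2\* relaxometry of multi-echo ultrashort-echo-time (UTE)
MRI of the patellar tendon, with the longitudinal statistics needed to
track degeneration under exercise therapy.

Tendon collagen binds water so tightly that its transverse magnetization
decays with T2\* ≈ 1 msec — gone before a conventional gradient echo is
acquired.  UTE sequences (first echo 0.032 msec here) capture it, and a
16-echo decay supports a two-pool model at every voxel:

    A(t) = S0 * [ f_s * exp(-t / T2*_short) + (1 - f_s) * exp(-t / T2*_long) ]

where `f_s` is the short-T2\* (collagen-bound) fraction.  Degenerated,
water-rich tissue has a *low* short fraction and a long mono-exponential
T2\*.  Because magnitude MRI noise is Rician and biases low-SNR signals
upward, all fitting maximizes the Rician log-likelihood

    l(m | A, sigma) = log(m/sigma^2) - (m^2 + A^2)/(2 sigma^2) + log I0(m A / sigma^2)

rather than least squares.  The package provides, for whom this matters —
quantitative-MRI methodologists and musculoskeletal imaging researchers:

* **Phantom & cohort simulation** — `generate_phantom()` (three-zone
  digital tendon with known parameter maps, Rician noise, longitudinal
  change) and `generate_cohort()` (two-arm 0/12/24-week cohorts with the
  published effect sizes as generating truths).
* **Relaxometry** — `fit_mono_voxel()`, `fit_bi_voxel()`,
  `fit_volume()`: Rician maximum-likelihood mono-/bi-exponential fits
  with analytic gradients, variable-projection multi-start, background
  noise estimation (`estimate_sigma()`).
* **Compartments** — `average_short_fraction()`,
  `classify_compartments()` (degenerative 0–30%, interface 30–60%,
  aligned collagen 60–100% short-T2\* components; labels constant over
  visits), `compartment_mean_t2()`.
* **Statistics** — `fit_gee_longitudinal()` (exchangeable GEE with
  robust errors and Bonferroni-corrected visit contrasts, implemented
  in-package), `fit_cross_sectional()`, `fit_baseline_prediction()`,
  `fit_change_association()` (random-intercept model), `apply_locf()`.
* **I/O & pipeline** — NIfTI-1 volumes/maps/masks (echo along dim 4,
  YAML echo-time sidecar), CSV cohort tables, `run_pipeline()` plus a
  CLI at `inst/cli/ute-pipeline.R`.

## Worked example

```r
library(uteT2star)

# simulate a small two-visit phantom and fit it
ph <- generate_phantom(phantom_spec(grid_shape = c(16L, 16L, 2L), n_visits = 2L,
                                    visit_effects = c(0, -1.3), seed = 1))
fm <- fit_volume(ph$volumes[[1]], ph$truth$tendon_mask, !ph$truth$tendon_mask)
#> fit_volume: sigma_hat = 5.058; 216/216 mono and 216/216 bi fits converged

# simulate a 76-athlete cohort at the published effect sizes and analyze it
co  <- generate_cohort(cohort_spec(seed = 1))
gee <- fit_gee_longitudinal(co, "degenerative")
gee$contrasts
#>   contrast estimate ci_low  ci_high        p p_bonferroni significant
#> 1  0_vs_12   -0.818 -1.152 -0.48370 1.59e-06     4.78e-06        TRUE
#> 2 12_vs_24   -0.426 -0.854  0.00191 5.10e-02     1.53e-01       FALSE
#> 3  0_vs_24   -1.243 -1.610 -0.87671 3.02e-11     9.05e-11        TRUE
```

The estimated noise level (5.06) recovers the phantom's generating
sigma of 5.  The 0-vs-24-week contrast (−1.24 msec, CI −1.61 to −0.88)
recovers the generating 24-week degenerative-compartment change of
−1.3 msec and stays significant after Bonferroni correction over the
three planned visit comparisons; the 12-vs-24-week change does not reach
the corrected threshold.  The pooled VISA-P slope for the same cohort
(`fit_cross_sectional(co, "degenerative", robust = TRUE)`) estimates
−0.056 msec per VISA-P point (CI −0.085 to −0.028) against a generating
value of −0.046.

## Documentation

The methods vignette (`vignettes/ute-t2star-methods.Rmd`) documents the
signal and noise models, fitting bounds and initialization, what the
generators do and do not emulate, the GEE implementation, and known
limitations.
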