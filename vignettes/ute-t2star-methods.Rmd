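---
title: "Methods: Rician maximum-likelihood T2* relaxometry and longitudinal analysis of tendon UTE-MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Rician maximum-likelihood T2* relaxometry and longitudinal analysis of tendon UTE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Healthy tendon is dominated by water bound to highly ordered collagen,
whose transverse magnetization decays with a T2\* well below 2 msec —
invisible to conventional gradient-echo MRI.  Ultrashort-echo-time (UTE)
sequences with a first echo tens of microseconds after excitation capture
this signal, and a multi-echo UTE acquisition samples the full decay.  In
tendinopathy, degraded matrix and free water lengthen T2\*, so voxel-wise
T2\* maps are a candidate biomarker of degeneration and of response to
exercise therapy.

`uteT2star` implements the complete quantitative chain for a three-visit
(0/12/24-week) study of the proximal patellar tendon: signal modelling and
voxel-wise maximum-likelihood fitting, tissue-compartment segmentation,
longitudinal compartment summaries, and the adjusted statistical layer
linking T2\* to the VISA-P symptom score.  Because the underlying clinical
images are not public, every stage is validated on synthetic phantoms and
cohorts with known ground truth.

## Signal model and noise model

At echo time $t$ the noiseless magnitude of a two-pool voxel is

$$ A(t) = S_0\left[f_s\,e^{-t/T_{2s}^*} + (1-f_s)\,e^{-t/T_{2l}^*}\right], $$

with $f_s$ the short-pool (collagen-bound water) amplitude fraction at
$t = 0$; $100 f_s$ is the percentage of short-T2\* components.  The
mono-exponential model is the $f_s \in \{0, 1\}$ boundary.  The default
protocol is the 16-echo UTE schedule (0.032–26.32 msec, TR 83.4 msec,
flip angle 17°) exposed by `ute_echo_times()`.

Single-coil magnitude images carry Rician noise: the observed magnitude is
$m = \sqrt{(A + g_1\sigma)^2 + (g_2\sigma)^2}$ with independent standard
normal $g_1, g_2$.  At low SNR this biases magnitudes upward (the "noise
floor"), so least squares systematically overestimates T2\* in the late
echoes of short-T2\* tissue.  The fitters therefore maximize the Rician
log-likelihood

$$ \ell(m \mid A, \sigma) = \log\frac{m}{\sigma^2}
   - \frac{m^2 + A^2}{2\sigma^2} + \log I_0\!\left(\frac{mA}{\sigma^2}\right), $$

summed over echoes.  `log I0` is evaluated with the exponentially scaled
Bessel function up to $z = 700$ and with the standard large-argument
expansion beyond, keeping the likelihood finite at Bessel arguments of
$10^6$ and above (base R's `besselI` underflows near $10^5$ even when
scaled).  A magnitude of exactly zero has zero density for every
parameter value; such echoes are excluded from the fit and `m = 0`
returns `-Inf` by convention.

The noise scale is a single global $\sigma$ per acquisition, estimated
from signal-free background voxels pooled across echoes via the Rayleigh
second moment $\hat\sigma = \sqrt{\overline{m^2}/2}$.  A per-voxel
$\sigma$ is not identifiable from 16 echoes; a spatially uniform noise
floor is the appropriate single-coil assumption.

## Fitting: bounds, initialization, convergence

Both fitters use box-bounded quasi-Newton optimization (L-BFGS-B) with
analytic gradients; the gradient of $\ell$ with respect to $A$ involves
the ratio $I_1/I_0$, evaluated with the same large-argument switch.  The
relative function tolerance is $10^{-9}$ (`factr = 4.5e6`), tight enough
that dense-grid oracle comparisons in the tests are meaningful.

**T2\* bounds.**  The mono fit allows $T_2^* \in [0.05, 60]$ msec — with
echoes ending at 26.32 msec, longer values are not measurable.  The bi
fit uses $T_{2s}^* \in [0.05, 3]$ and $T_{2l}^* \in [8, 60]$ msec.  The
gap between the boxes is deliberate: piloting with adjacent boxes (short
pool up to 5 msec, long pool from 5 msec) showed a degenerate ridge on
which a "short" component near the shared boundary absorbs part of the
long-pool decay; the two pools are then indistinguishable from 16 echoes,
and the short fraction is inflated at low $f_s$.  Requiring a minimum
separation ($T_{2l}^*/T_{2s}^* \gtrsim 2.7$) removes the ridge while
comfortably containing the physiological pools (bound water
$\sim$0.5–1.5 msec, free water $\gtrsim$10 msec).

**Initialization.**  The mono fit starts from log-linear least squares on
echoes above $3\sigma$, where the Rician bias is negligible.  The bi fit
is multi-start: a log-spaced 10×10 grid of $(T_{2s}^*, T_{2l}^*)$ pairs
is screened by variable projection — for fixed time constants the two
pool amplitudes have a closed-form least-squares solution, clamped
non-negative — and the best start is polished by the bounded optimizer.
In piloting, polishing one, two, or three top starts produced identical
estimate distributions, so one polish is the default (`n_polish`).  The
mono solution lies on the $f_s \in \{0,1\}$ boundary of the bi model and
is always offered as a fallback, which enforces the nested-model
inequality $\ell_{bi} \ge \ell_{mono}$ exactly — on mono-exponential
input the bi fit returns the boundary solution rather than a spurious
second pool.

**Convergence and flags.**  Voxels whose every echo lies below $2\sigma$
are flagged `low_snr` and excluded from compartment averages, as are fits
that end on a T2\* bound (`bound`) or fail to converge.  At very high SNR
the line search can terminate abnormally on the optimum itself; a fit
whose restart cannot improve the objective by more than a relative
$10^{-9}$ is classified as converged.  All fits are deterministic given
their inputs.

## Compartments

Voxel labels derive from the short fraction averaged over all visits at
which the voxel's bi fit converged: below 30% short-T2\* components the
voxel is *degenerative* (mostly long T2\*), from 30% to 60% *interface*,
and at or above 60% *aligned collagen*.  Intervals are half-open and
lower-inclusive (0.30 is interface, 0.60 aligned collagen); any
consistent convention moves only voxels sitting exactly on a threshold.
The label map is computed once and applied unchanged to every visit, so
longitudinal summaries always average the same voxel group; per-visit
summaries are the unweighted mean and SD of the mono-exponential T2\*
over converged labeled voxels.

## The phantom generator

`generate_phantom()` is the forward model of the fitted bi-exponential:
a 32×32×10 grid (10 slices, mirroring the analyzed slab) whose
rectangular tendon cross-section contains three concentric zones —
an outer aligned-collagen ring, an interface ring, and a focal
degenerative core, matching tendinopathic anatomy where degeneration is
focal and ordered collagen dominates.  Ring thickness is three voxels at
the default grid so that every compartment retains voxels farther than
one voxel from a zone boundary; a label-recovery property can then be
evaluated in all three compartments, not just the core.

Per-voxel parameters are drawn uniformly: $S_0 \in [80, 120]$,
$T_{2s}^* \in [0.6, 1.4]$ msec, $T_{2l}^* \in [12, 16]$ msec.  Zone short
fractions target 0.15 / 0.45 / 0.80 — the centres of the three
classification bands — with a small within-zone jitter (±0.04) so the
fraction field is not piecewise constant.  Longitudinal change enters
only through per-visit additive shifts of the long-component T2\* in
designated zones; the default (0, −0.7, −1.3 msec in the degenerative
zone) mirrors the adjusted 12- and 24-week changes observed in
degenerative tendon tissue.  Default noise is $\sigma = 5$, putting the
first-echo tendon SNR near 20; this is a convention (tissue SNR is not
reported for the protocol), chosen once and used everywhere.  Background
voxels carry pure Rayleigh noise and drive $\hat\sigma$.

At this SNR the Cramér–Rao bound for a single-visit short-fraction
estimate is $\mathrm{sd}(\hat f_s) \approx 0.07$–0.08, and the
variable-projection fitter attains it; visit-averaging over three visits
brings the off-boundary mean absolute error of the averaged fraction
below 0.05.  What the phantom does *not* emulate: registration error and
motion (volumes are generated pre-aligned), partial-volume mixing at the
tendon margin, fat signal, B1/flip-angle inhomogeneity, multi-coil
(noncentral-$\chi$) noise, and spatially correlated noise.  Passing
recovery tests therefore validates the estimation chain, not robustness
to those acquisition effects.

## The cohort generator

`generate_cohort()` draws a two-arm cohort (progressive tendon-loading,
PTLE, versus eccentric exercise, EET; 1:1) of default size 76 with visits
at 0, 12, 24 weeks.  The degenerative compartment mean for subject $i$ at
visit $j$ is

$$ T^*_{ij} = b_i + \delta_j + \beta\,(V_{ij} - \bar V_j) + \varepsilon_{ij}, $$

with subject intercept $b_i \sim N(14.2, 3.0^2)$ msec, visit effects
$\delta = (0, -0.7, -1.3)$ msec, VISA-P slope $\beta = -0.046$ msec per
point, residual SD 1.0 msec.  The VISA-P term is centred at the
*per-visit expected score* $\bar V_j$, so per-visit population means are
exactly $14.2 + \delta_j$ and both the GEE visit contrast and the pooled
slope are identifiable at their generating values.  VISA-P trajectories
improve from 57 to 72 to 80 points on average (PTLE gaining more at 24
weeks), are integer-valued and truncated to [0, 100].  The interface and
aligned compartments get their own intercepts (7.5, 3.1 msec), visit
effects ((0, −0.3, −0.6) and (0, 0.1, 0.0)) and slopes (−0.019, −0.003).
Covariates (age, sex, BMI, CSAS, symptom duration) are subject-constant
draws from plausible athlete distributions and are null with respect to
T2\* — they exist to exercise the adjustment machinery.  By default 11%
of scans are missing completely at random (matching 21 of 195 scheduled
acquisitions), never removing every visit of a subject; the paper's
arm-unbalanced dropout is available by setting `missing_rate` per arm
externally but is not the default.

One structural note: with both the visit effects and the
visit-to-visit VISA-P gains active, a *single* cross-sectional slope is
over-determined — the longitudinal T2\* change (−1.3 msec) is not equal
to the slope times the VISA-P change (−0.046 × 23 ≈ −1.06 msec), so
pooled regression across visits absorbs the ~8% discrepancy as bias.
Recovery checks of the slope therefore disable the visit-level trends so
that the regression estimates exactly the parameter under test.

## The statistical layer

All models adjust for the predefined confounders age, sex, BMI, CSAS and
symptom duration; confidence intervals are Wald with normal quantiles
(no small-sample df correction), matching the population-averaged
reporting style.

* **Pooled cross-sectional model** (`fit_cross_sectional`): OLS of
  compartment T2\* on VISA-P plus confounders, observations pooled across
  visits.  The default covariance is the plain OLS one (faithful to the
  original pooled analysis); `robust = TRUE` switches to subject-clustered
  sandwich errors, which are the statistically correct choice for pooled
  repeated measures and are used by the recovery checks.
* **Baseline prediction** (`fit_baseline_prediction`): OLS of final-visit
  VISA-P on baseline T2\* plus confounders; reports model $R^2$ and the
  T2\* p-value.
* **GEE** (`fit_gee_longitudinal`): Gaussian identity-link generalized
  estimating equations with an exchangeable working correlation and the
  Liang–Zeger robust covariance, implemented in the package (no GEE
  library is a dependency).  Scalar moment estimators update the
  dispersion and the within-subject correlation between generalized
  least-squares steps.  Visit enters as a categorical factor; the three
  planned contrasts (0 vs 12, 12 vs 24, 0 vs 24 weeks) are flagged
  significant when the unadjusted p-value is below 0.05/3 (Bonferroni
  over the three comparisons).  With balanced complete data and no
  covariates the estimator reduces exactly to differences of per-visit
  means — the closed-form oracle used in the tests; under the
  independence working correlation it reduces to OLS with cluster-robust
  errors, cross-checked against `sandwich::vcovCL`.  The arm-by-visit
  interaction is a joint robust Wald test of the two interaction terms.
* **Change association** (`fit_change_association`): random-intercept
  linear model (`lme4::lmer`) of VISA-P on compartment T2\* and
  confounders across visits.
* **LOCF** (`apply_locf`): the sensitivity analysis carries each missing
  T2\*/VISA-P value forward from the subject's most recent preceding
  observation (a missing baseline stays missing); it is idempotent and
  the identity on complete data.  `locf_trigger` fires when missingness
  exceeds 5% of scheduled observations.  The primary analysis is always
  complete-case; LOCF is sensitivity only.

The GEE working correlation structure and CI method of the original
analysis are not stated; exchangeable working correlation with robust
errors is the default here and is recorded in each result object, and
point estimates are consistent regardless of that choice.

## Problem sizes and runtimes

Validation uses desk-scale problems chosen once: the full 32×32×10
phantom (3520 tendon voxels, three visits) for label recovery; 500
simulated voxels for the noise-model bias comparison at first-echo
SNR 5; 100 replicate cohorts of 60 subjects for contrast coverage; 200
replicates of 76 subjects for test size under the null; 25 replicates of
500 subjects for slope recovery.  Single-seed confidence-interval checks
fail for ~5% of seeds by construction, so recovery criteria are asserted
as coverage over replicates plus unbiasedness of the mean estimate.

## Known limitations

* No T1/flip-angle correction, no stretched-exponential or
  three-component models, no noncentral-$\chi$ multi-coil noise model, no
  complex-valued fitting pathway.
* Image registration and manual segmentation are out of scope; volumes
  are assumed pre-aligned and masks supplied.
* The compartment thresholds (30% / 60%) are fixed, not data-driven.
* The GEE implementation supports Gaussian outcomes with identity link
  only — sufficient for T2\* and VISA-P summaries, not a general GEE.
* The phantom's noise convention (first-echo SNR ≈ 20) is a choice, not a
  measured property of the protocol; estimator variance scales with it.
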