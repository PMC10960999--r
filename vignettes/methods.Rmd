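---
title: "Models and methods: leaf water content from canopy spectra and multi-source covariates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricelwc)
```

## The problem

Leaf water content (LWC, the mass fraction of water in fresh leaves,
`(FW - DW)/FW`) is the quantity irrigation decisions in rice hinge on.
Canopy hyperspectral reflectance offers a non-destructive proxy: water
absorbs strongly in the near infrared, so reflectance contrasts between
water-sensitive and water-insensitive bands track LWC. A single
two-band index, however, ignores the canopy micro-environment and the
plant's physiological state, both of which shift the index-LWC relation
across growth stages. `ricelwc` implements the full workflow for
building and evaluating LWC models that couple a spectral index with
such covariates: the crop water stress index (CWSI), dark-adapted
chlorophyll fluorescence (Fv/Fm), and SPAD chlorophyll readings.

## The model chain

**Physiology.** Fv/Fm = (Fm − Fo)/Fm and Y(II) = (Fm′ − Fs)/Fm′ from
pulse-modulated fluorometry; LWC = (FW − DW)/FW from gravimetric
sampling; LAI = D·ρ/10000 from per-hill leaf area (cm²) and planting
density (hills m⁻²). All are plain ratios; the package guards the
degenerate denominators with typed errors rather than propagating
non-finite values, because a zero Fm or FW is a data error, not a
measurement.

**CWSI.** For each hourly record, saturation vapor pressure follows the
Tetens form es(Ta) = 0.61·exp(17.27·Ta/(Ta + 237.3)) (kPa), VPD =
es(Ta)·(1 − RH/100), and the index is

CWSI = ((Tc − Ta) − Tmin) / (Tmax − Tmin),  Tmin = A + B·VPD,
Tmax = A + B·VPG,

where the non-water-stressed baseline (A, B) is an ordinary
least-squares fit of Tc − Ta on VPD over well-watered (CK) records in
the 10:00-14:00 window, matching the spectral measurement window so the
stress state is consistent across co-measured variables. The baseline
is fitted once per campaign from CK plots across stages, since a single
(A, B) pair describes a site-year. VPG is taken in the Idso upper-limit
convention es(Ta) − es(Ta + A); the textual definitions of VPG in the
applied literature are often ambiguous, so the opposite sign is
available through `vpg(..., sign = -1)` without being endorsed. CWSI is
deliberately **not clamped** to [0, 1]: out-of-envelope values flag
baseline misfit, and clamping would hide it from the downstream
regressions, which accept raw values.

**Two-band index screening.** For every unordered pair (λ1, λ2) on the
1-nm 350-2500 nm grid, ND = (R_λ1 − R_λ2)/(R_λ1 + R_λ2) is regressed
against LWC per stage. For a single-predictor OLS fit R² equals the
squared Pearson correlation and RMSE = √(SStot·(1 − R²)/n), so the scan
runs as column-wise correlations against a fixed response: only the
upper triangle is computed (swapping bands negates ND, leaving R² and
RMSE unchanged) and the lower triangle is mirrored. The full 2151-band
scan on ~120 samples takes well under ten minutes on one CPU; `step`
decimates the grid for quick runs (step 3 takes a few seconds and
shifts the located optimum by at most the step width). The best pair
maximizes R², with ties broken by smaller RMSE and then the
lexicographically smaller pair — the tie rule is arbitrary but
deterministic. Per-stage optima are reported as such; the cross-stage
recommendation (the per-stage optimum with the highest mean R² over all
stages) is this package's own aggregation, labelled accordingly.

**Coupled models.** Stage-wise lines LWC = a·ND + b are extended to
two-predictor multiple linear regressions LWC = b0 + b1·ND +
b2·covariate, fitted on a training year and validated on a held-out
year (`year_split()`), with R² on validation defined as 1 − SSres/SStot
against the observed values (the 1:1-line convention) and RMSE in LWC
units. A widely printed form of the R² formula gives SSres/SStot — the
unexplained fraction — which contradicts its use as a goodness-of-fit
score; this package uses the standard complement everywhere, for fits
and predictions alike. Collinearity (tolerance and VIF via `car::vif`)
and the Durbin-Watson statistic of the training residuals are attached
to every coupled fit; rows are ordered by (year, site, plot) before
computing DW because observation order is not otherwise recorded, and
the significance stars on correlation matrices are uncorrected
two-sided t tests, flagged as such.

**Slope/intercept analysis.** The per-stage slope a and intercept b are
regressed on stage-mean covariates with quadratics. With four stages
the quadratic has one residual degree of freedom and with three it is
saturated (R² = 1 by construction), so these relations are reported
descriptively, without significance claims — p-values at df ≤ 1 would
be decoration, not inference.

**Machine-learning benchmark.** Decision tree (rpart, depth 10, grown
with `cp = 0, minsplit = 2` so depth is the binding constraint), random
forest (ranger, 100 trees, all features per split), k-nearest
neighbours (k = 3, Euclidean distance on features standardized with
training-set statistics — KNN is the only distance-based learner, so it
is the only one standardized), gradient boosting (xgboost, 100 trees,
depth 3, learning rate 0.1, squared-error objective, single thread) and
OLS, all on the same seeded 70/30 split (`ceiling(0.7·n)` training
rows). Every stochastic step takes the seed explicitly, so results
reproduce bit-identically. One property worth stating plainly: an
unconstrained depth-10 tree *memorizes* any training set with unique
feature rows (training R² = 1 exactly), and bagged or shrunk ensembles
then cannot match its training fit — training-set comparisons between
exact trees and ensembles are therefore uninformative, and the
benchmark's substance lives in the validation columns.

## The synthetic campaign generator

No field data ship with the package, so `simulate_campaign()` generates
complete campaigns — wide spectra, hourly microclimate, a raw
physiology table — with a `truth` record of everything planted.
Defaults encode the study conditions the analysis targets:

* **Design**: 2 years × 4 cultivars × 3 irrigation treatments × 5
  replicate plots (120 plots), 4 growth stages, 5 midday hours of
  microclimate per plot-stage.
* **LWC populations**: treatment-graded means, CK > MADW > SADW,
  spanning ≈ 0.61-0.79 with within-cell SD 0.02 — the range a
  field campaign with alternate-wetting-and-drying treatments produces.
* **Stress model**: Tc − Ta = A + B·VPD + s·(1 − LWC_norm + η) + ε with
  planted baseline A = 2 °C, B = −2 °C kPa⁻¹ (values in the physically
  plausible range for lower-baseline regressions; recovery testing
  needs a known truth). LWC_norm maps the CK stage mean to 1 and the
  SADW mean to 0, so well-watered plots sit on the baseline in
  expectation. The stage gain s is scaled in closed form so the
  stage-mean CWSI hits its planted target; the plot-level heterogeneity
  η (SD 0.4) keeps the CWSI-LWC correlation in the reported −0.60 to
  −0.85 band rather than at an unrealistic −0.98.
* **Spectra**: a smooth dry-canopy base curve minus water-absorption
  troughs near 1450 and 1940 nm, plus a narrow bump/trough pair at the
  planted bands (1287, 1673) nm constructed so the noise-free ND at
  that pair equals (LWC_w − b_s)/a_s exactly, where LWC_w is a latent
  water signal (LWC plus plot-level jitter) shared by *every*
  water-driven feature. Sharing the jitter is what makes the planted
  pair the least-noisy channel on the grid — any rival pair sees the
  same latent signal through extra feature noise — and the bump gain
  splits the signal roughly evenly between the two bands so neither
  band alone rivals the pair. Per-band i.i.d. noise (SD 0.008) puts the
  stage-line R² in the 0.5-0.7 range typical of field campaigns.
* **Stage structure**: the planted per-stage slope a_s and intercept
  b_s are quadratic in the planted stage-mean CWSI and Fv/Fm
  respectively, with curvature chosen strong enough (|c2| of 25 and 45)
  that the 4-point quadratic analysis recovers the curvature *sign*
  above stage-line estimation noise.
* **Covariates**: SPAD, Fv/Fm, Y(II), LAI, biomass and yield are linear
  in LWC with noise set in closed form from the realized within-stage
  LWC spread to hit target correlations (SPAD 0.60, Fv/Fm 0.63, ...,
  inside the reported field ranges), then materialised as raw
  measurables (FW/DW, Fo/Fm, Fs/Fm′, leaf area and density) so the
  physiology module genuinely recomputes them.

What the generator does **not** emulate: radiative-transfer leaf optics
(no PROSPECT-class structure), weather realism beyond a deterministic
midday profile with noise, spatial autocorrelation between plots,
instrument drift, or non-Gaussian measurement error. Passing recovery
tests therefore demonstrates that the pipeline's estimators are correct
and well-calibrated under the assumed statistical structure — not that
the specific bands or coefficients would transfer to any real paddy.

Two deliberate consequences of the latent-signal construction are worth
knowing. First, the OLS slope of LWC on the noisy ND is attenuated
relative to the planted a_s by the reliability factor 1/(1 + f²) (f the
jitter fraction) — classic errors-in-variables behaviour — so the truth
record's stage lines are recovered up to that factor, and the recovery
tests assert structure (curvature signs, ordering, band locations)
rather than raw slope equality. Second, because ND and CWSI are both
noisy proxies of the same latent LWC, coupling them *must* improve
validation R² over ND alone on average; the tests verify the machinery
delivers that improvement, and its size (≈ 0.08-0.12 here) is a
property of the chosen noise scales, not an estimate of any field
improvement.

## Numerical choices and edge cases

* Wavelengths are exact 1-nm grid lookups; no interpolation, smoothing
  or resampling anywhere (inputs on other grids are rejected).
* Reflectance in fractions; percent-scale files are detected by the
  95th percentile of values exceeding 1.5 and converted with a warning.
  A robust quantile, not the maximum, drives the detection so that a
  single out-of-range cell is reported as the data error it is instead
  of silently rescaling the whole file.
* Constant-ND scan cells are masked (`NA`), counted and reported, as
  are zero-variance variables in correlation matrices.
* Outlier rule: mean ± 3 SD per variable by default, 1.5·IQR as an
  alternative; flags are reported and never silently removed.
  Shapiro-Wilk normality is likewise reported, never enforced.
* Generated reflectance is floored at 0.001 — real canopies never
  reflect exactly zero, and an exact zero at two bands would make ND
  0/0.
* All stage-level seeds derive deterministically from one global seed;
  reruns are bit-identical.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run on the default 120-plot
campaign with the band scan at step 3 (full range, 717 bands), 20-seed
suites for recovery rates, and 100-seed suites for the baseline and
coupled-coefficient calibration checks; the oracle-equivalence check
uses a 20-band, 30-sample fixture where the naive double-loop fit is
affordable. These sizes were chosen so each property is tested at the
scale where its statistics are stable.
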