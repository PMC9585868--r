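---
title: "Tumour-stroma ratio quantification and its prognostic analysis: methods"
author: "tsrquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumour-stroma ratio quantification and its prognostic analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The tumour–stroma ratio (TSR) is the percentage of tumour-epithelium area
among the total tumour-plus-stroma area of a tissue section,

$$\mathrm{TSR} = 100 \cdot
  \frac{A_\mathrm{tumor}}{A_\mathrm{tumor} + A_\mathrm{stroma}},$$

and stroma-rich ("stroma-high", *low* TSR — note the inverted naming that
is conventional in this literature) breast tumours tend to recur earlier.
`tsrquant` implements the complete analysis chain for studying this on
cytokeratin (CK) immunohistochemistry tissue-microarray (TMA) cores:

1. **Segmentation** of each core image into tumour and stroma and
   computation of TSR (`segment_core()`).
2. **Cutpoint selection** by maximally selected rank statistics
   (`max_selected_rank()`), dividing patients into stroma-low
   (TSR > cutoff) and stroma-high (TSR ≤ cutoff; the boundary goes to
   stroma-high).
3. **Association** of the TSR group with clinicopathological parameters by
   uncorrected Pearson $\chi^2$ (`build_table1()`).
4. **Survival analysis**: Kaplan–Meier curves and log-rank tests, and Cox
   proportional-hazards models with TSR entered both as the binary group
   and as a continuous covariate in units of 10 percentage points of
   stroma (`cox_fit()`, `continuous_tsr_covariate()`).

Because patient-level data of this kind are generally not deposited, the
package ships a first-class synthetic-data module — an image renderer with
known ground-truth tumour fraction and a cohort simulator with planted
hazard structure — so that every stage is testable against known truth.

## Segmentation model

CK IHC with a DAB chromogen stains tumour epithelium brown and leaves the
counterstained stroma off-white, so tumour and stroma separate on the
*hue* circle. The pipeline is deliberately classical:

* **Gaussian smoothing.** Each RGB channel is convolved with a discrete
  Gaussian kernel, default $5\times 5$ with
  $\sigma = 0.3\,((k-1)/2 - 1) + 0.8 = 1.1$ px (the usual
  kernel-size-derived sigma). Smoothing suppresses pixel noise before the
  hue transform, which is noise-sensitive at low saturation.
* **Tissue contour.** Edges are detected on the smoothed luminance with a
  Sobel gradient magnitude thresholded at
  $\max(10,\ 1.33\cdot\mathrm{median})$; the edge band is bridged with a
  box dilation (5 px), the enclosed region filled, eroded back, and the
  largest connected component kept. Everything outside is background and
  excluded. A final 7-px-disc erosion (`contour_trim`) removes the blur
  skirt the smoothing spreads beyond the physical contour; with it the
  recovered disc area of synthetic cores is within 2% of $\pi r^2$. We
  use a plain gradient threshold rather than the full Canny machinery
  (non-maximum suppression, hysteresis) because core-on-white TMA images
  are high-contrast and the filled-largest-contour step discards stray
  edge responses anyway.
* **Hue channel.** RGB is converted to HSV; hue in degrees $[0, 360)$ is
  quantized to the integer scale $0..255$ by
  $\mathrm{round}(\deg \cdot 255/360)$ (the documented scale constant;
  thresholds are reported on both scales). Achromatic pixels get hue 0 by
  convention.
* **Otsu threshold.** The split level maximizing the between-class
  variance of the hue histogram, computed **on tissue-masked pixels
  only** — including the white background would place a large spurious
  mode in the histogram and bias the threshold. Ties break toward the
  lowest maximizing level; a single-valued histogram is flagged
  degenerate.
* **Class orientation.** The class whose mean RGB is closer to a
  configured DAB-brown reference (150, 90, 40) is tumour; the other is
  stroma. Orientation is by colour rather than "above threshold = tumour"
  because hue wraps and the numeric position of brown depends on the hue
  origin convention. If *both* classes are nearer the same reference —
  an entirely-stroma or entirely-tumour core, where Otsu merely splits
  noise — the whole tissue takes that single label.
* **Morphological repair.** Closing then opening with a $3\times3$ square
  element (1 iteration each) fills small holes and removes speckles.
* **Two-core aggregation.** With two cores per patient the stroma-richest
  core — the minimum TSR — is recorded as the patient value
  (`aggregate_patient()`).

### Known accuracy limits

On synthetic cores at the default geometry (256 px frame, radius-100
core, noise SD 8) the pipeline recovers ground-truth tumour fractions
with a mean absolute error of about 1.5 percentage points and Spearman
rank correlation above 0.99 (the test suite and `scripts/acceptance.R`
recompute both). The residual error is a systematic tumour-ward bias of
roughly +1 pp: pixels on a smoothed tumour–stroma boundary are colour
*blends*, and because DAB brown is far more saturated than the pale
stroma, even a 50/50 blend is still warm-hued and classifies as tumour.
The bias grows as core radius shrinks (boundary ring scales as $1/r$).
This is a property of hue-threshold segmentation generally, not of the
implementation.

## The synthetic image generator

`render_core()` draws a filled disc (the core) on a white background and
places tumour regions as the upper level set of a sum of Gaussian bumps
("metaballs") at random positions inside the disc; the level is the
empirical quantile of the field matching the target fraction, so realized
truth hits the target up to pixel quantization and the ground-truth mask
is exact by construction. Per-channel Gaussian noise (SD 8 by default) is
added and clipped to 8-bit.

Default colours: tumour RGB(150, 90, 40), a mid-tone DAB brown; stroma
RGB(225, 228, 238), an off-white with a faint hematoxylin (cool) tint;
background white. The cool tint matters: a *warm* off-white such as
RGB(235, 230, 225) sits at hue ≈ 30°, essentially the same hue as DAB
brown (≈ 27°), because hue disregards saturation — hue-channel Otsu
cannot separate such a pair at all. Counterstained stroma in real CK-DAB
sections is blued by hematoxylin, and the chosen default reproduces the
brown-vs-off-white hue separation the method relies on (tumour ≈ 27°,
stroma ≈ 226°).

What the generator does **not** emulate: nuclei and texture, staining
gradients and artefacts, scanner colour profiles, partially torn or
folded cores. Passing tests therefore demonstrate the correctness of the
algorithmic chain on images satisfying the method's own colour
assumptions, not clinical-grade robustness.

## The cohort simulator

`simulate_cohort()` draws, per patient: covariates from configurable
marginal frequencies (defaults match a 240-patient breast-cancer TMA
cohort: 149/91 age ≤50/>50, grade 40/141/59, nodal 131/109, ER 106/134,
PR 107/133, HER2 61/179, menopausal 134/106, size 35/162/43); a TSR from
Beta(2, 2.67) scaled to percent, which places 36.25% of patients at or
below the 33.5% cutoff; and an event time from a proportional-hazards
model with linear predictor

$$\eta_i = \beta_\mathrm{SH}\,\mathbf{1}(\mathrm{TSR}_i \le c)
         + \beta_{10}\,\tfrac{100-\mathrm{TSR}_i}{10}
         + \textstyle\sum_j \beta_j x_{ij},$$

latent time $T_i$ with survival $\exp(-\lambda_0 e^{\eta_i} t^k)$
(default $k=1$: exponential, for closed-form checkability; Weibull via
`weibull_shape`), an independent exponential loss-to-follow-up time, and
administrative censoring at 60 months. Defaults: planted stroma-high
log-hazard $\log 2.82$ at cutoff 33.5% (the demo effect), baseline hazard
0.00515 events/month — chosen so the mixed-group five-year disease-free
survival is about 62% — and loss rate 0.005/month, giving a median
follow-up in the mid-40-month range. Covariates are drawn independently
of each other and of TSR (the simulator plants *marginal* frequencies,
not the correlation structure of a real cohort), and molecular subtype is
derived from the ER/PR/HER2 draws, so its counts are close to but not
exactly the marginal ones.

Each artifact (every image, every cohort) consumes its own seed, so
regenerating one never perturbs another, and identical spec + seed is
bit-identical output.

## Cutpoint selection

Candidates are midpoints between consecutive distinct TSR values whose
split leaves at least `min_group_fraction` (default 0.10, the
conventional maxstat constraint) of patients on each side. At each
candidate $c$ the standardized log-rank statistic
$z(c) = (O - E)/\sqrt{V}$ is computed for (TSR ≤ c) vs (TSR > c) from the
life table over distinct event times with hypergeometric variance; the
selected cutoff maximizes $|z|$, ties breaking toward the smaller
cutoff. The scan is exhaustive and deterministic, and shuffling patient
order never changes the result.

The *naive* p-value attached to the maximum is anti-conservative by
construction — the maximum of many correlated tests is compared against a
single-test reference — and the package reports it as such (the test
suite demonstrates the type-I inflation on null cohorts). No closed-form
corrected p-value is applied by default, matching how such cutoffs are
commonly reported; `maxstat_permutation_p()` provides a selection-aware
permutation p-value behind an explicit flag for users who want one.

## Survival and association analyses

Kaplan–Meier estimation, the k-sample log-rank test and Cox
partial-likelihood maximization are delegated to the `survival` package
(`survfit`, `survdiff`, `coxph`) behind the module's interface; the
package's own life-table log-rank (`logrank_z()`) is retained as the
building block of the cutpoint scan, which keeps an independent
cross-check available: the test suite verifies `logrank_z()` against the
`coxph` score test (Breslow ties) to within $10^{-8}$, and against
hand-computed life tables.

Conventions, all following standard reporting practice for such cohorts:

* **Efron tie handling** in Cox models. Follow-up recorded in months
  guarantees heavily tied event times, and Efron's approximation is the
  less biased default.
* **Wald 95% CIs**, $\exp(\hat\beta \pm 1.96\,\mathrm{SE})$, and Wald
  p-values per covariate.
* **Reference levels**: Negative (ER/PR/HER2/nodal), grade I, T1,
  premenopausal, stroma-low.
* **Age** enters the multivariate model as the binary ≤50 / >50 split by
  default; continuous years is available via `age_encoding`
  (published univariable age hazard ratios near 0.99 suggest some
  reports use continuous age, so both encodings are exposed).
* **Continuous TSR** enters as stroma content per 10 percentage points,
  $(100 - \mathrm{TSR})/10$, so a hazard ratio above 1 reads "more
  stroma, shorter disease-free survival"; the tumour-ward orientation is
  available via `orientation = "tumor"`.
* **p-value formatting**: never "0.000"; values below 0.001 print as
  "<0.001".
* **Association tests**: uncorrected Pearson $\chi^2$ without continuity
  correction — this convention exactly reproduces, to the printed three
  decimals, all nine statistics of the published baseline table shipped
  in `inst/extdata/reference_table1_counts.csv`. A Yates-corrected
  statistic would not. Expected counts below 5 trigger a warning, not a
  Fisher fallback.
* **Molecular subtype**: ER−/PR−/HER2− → TNBC; HER2+ (any ER/PR) →
  HER2-positive; (ER+ or PR+) and HER2− → luminal–HER2-negative. The
  subtype labels partition the cohort; hormone-receptor-positive tumours
  are not subdivided into luminal A/B.

Subgroup Cox models drop covariates that are constant within the
subgroup (e.g. HER2 status inside the HER2-positive subgroup) and log the
drop; models are skipped, with a logged reason, when a subgroup has fewer
than 10 patients, fewer than 5 events, or a single TSR group.

## Degenerate inputs and numerical choices

* Empty tissue mask → the core errors with a condition class
  (`tsr_empty_tissue`); the pipeline logs and excludes it, and the
  patient survives on the other core if one exists.
* Single-valued hue histogram → degenerate flag; whole tissue assigned
  to the colour-nearest class.
* All TSR equal, or no admissible candidate → explicit validation error.
* Zero events → log-rank and Cox stages error cleanly rather than
  emitting NaNs.
* Cox non-convergence or monotone likelihood (|β| > 10) → flagged, never
  silent output.
* Exact zero-variance life tables are refused rather than returning 0/0.

## Problem sizes

The test suite and acceptance script run on deliberately modest sizes
chosen to exercise each statistical property with comfortable Monte-Carlo
margins: 36–54 rendered cores on a fraction grid for segmentation
recovery, 60–100 cohorts of n = 500 for cutpoint recovery, 200–500
replicates of n = 1000 for hazard-ratio recovery and CI coverage, and
1000 null cohorts of n = 240 for calibration and the anti-conservativeness
demonstration.

## Limitations

* The segmentation chain assumes the method's own colour model
  (brown vs cool off-white); H&E sections, weak staining or heavy
  background DAB would need different references.
* TSR values are analysed as fixed covariates; measurement error from
  segmentation is not propagated into the survival models.
* Proportional-hazards diagnostics (e.g. Schoenfeld residuals),
  time-varying covariates and stratified models are out of scope.
* The simulator's covariates are mutually independent; it cannot
  reproduce confounding structure, so multivariate and univariate
  estimates of the planted effect coincide in expectation — unlike in
  real cohorts.
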