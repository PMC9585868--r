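# tsrquant

Quantifies the tumour–stroma ratio (TSR) from cytokeratin-IHC tissue
microarray (TMA) core images and evaluates its prognostic value for
5-year disease-free survival in breast cancer, end to end.

The TSR of a tissue core is

    TSR = 100 · area_tumor / (area_tumor + area_stroma)   [percent],

measured by a classical segmentation chain on DAB-stained images:
Gaussian smoothing → edge-detected tissue contour (background excluded)
→ RGB-to-HSV hue channel → Otsu thresholding of the tissue-masked hue
histogram → colour-referenced tumour/stroma orientation → morphological
repair → pixel counting. Per patient, the stroma-richest of the two TMA
cores (minimum TSR) is kept.

Downstream, the package

* selects the optimal prognostic cutoff `c*` by **maximally selected
  rank statistics** — the admissible split (TSR ≤ c vs > c) maximizing
  the absolute standardized log-rank statistic `z(c) = (O − E)/√V` —
  and dichotomizes patients into *stroma-low* (TSR > c*) and
  *stroma-high* (TSR ≤ c*);
* tests association of the TSR group with clinicopathological
  parameters by uncorrected Pearson χ²;
* fits Kaplan–Meier curves with log-rank tests, and Cox
  proportional-hazards models (Efron ties, Wald 95% CIs) with TSR as
  the binary group and as a continuous covariate in units of 10
  percentage points of stroma, `(100 − TSR)/10`, for the total cohort
  and the three molecular subtypes (TNBC, HER2-positive,
  luminal–HER2-negative).

Because cohorts of this kind are not publicly deposited, a synthetic-data
module generates TMA-like core images with exact ground-truth tumour
fractions and 240-patient-like cohorts with planted hazard structure, so
the whole pipeline is testable offline. See the methods vignette
(`vignettes/tsr-methods.Rmd`) for the models, defaults and design
decisions.

## Worked example

```r
library(tsrquant)

# render a synthetic core with 40% tumour and segment it
rc  <- render_core(image_spec(tumor_fraction_target = 0.4, seed = 7))
seg <- segment_core(rc$image)
seg
#> TSR 41.94% (tumor 13047 / tissue 31112 px; hue threshold 72)
100 * rc$truth          # ground truth of this render
#> [1] 40
```

The estimated TSR (41.94%) is within 2 percentage points of the known
truth; the hue threshold 72 (on the 0..255 hue scale, about 102°) falls
between the DAB-brown tumour mode (~27°) and the counterstained stroma
mode (~226°).

```r
# a cohort with a planted stroma-high hazard (HR 2.82 at TSR <= 33.5%)
co <- simulate_cohort(cohort_spec(seed = 2026))
cp <- max_selected_rank(co$tsr, co$time_months, co$event)
cp
#> Maximally selected log-rank statistic
#>   cutoff: 31.612%  |z| = 7.537  (193 candidates, n = 240, events = 80)
#>   naive p (uncorrected for selection): <0.001

fit <- cox_fit(transform(co, tsr_group = dichotomize(co$tsr, cp$selected_cutoff)),
               covariates = c("tsr_group", "grade", "nodal", "er"))
fit
#> Cox PH fit: n = 240, events = 80
#>                        HR    95% CI      P
#> tsr_groupstroma-high 5.13 3.26-8.07 <0.001
#> gradeII              1.25 0.68-2.30  0.470
#> gradeIII             0.57 0.27-1.20  0.136
#> nodalPositive        0.98 0.63-1.53  0.925
#> erPositive           0.93 0.60-1.45  0.763
```

The scan recovers a cutoff near the planted 33.5%, and the stroma-high
group carries a strongly elevated recurrence hazard (the point estimate
exceeds the planted 2.82 because the cutoff was *selected* to maximize
the group contrast — the selection bias the naive p-value warning is
about), while the unplanted covariates stay near HR 1.

## Analysis workflow

Numbered drivers under `analysis/` reproduce the full study flow on
synthetic data and write their tables under `results/`:

| script | does |
|---|---|
| `01_simulate.R` | renders 24 cores (12 patients × 2) + a 240-patient cohort |
| `02_segment.R` | segments all cores, aggregates per patient, checks against truth |
| `03_cutpoint.R` | maximally selected cutoff, candidate profile, permutation p |
| `04_association.R` | reference-table χ² reproduction + synthetic baseline table |
| `05_survival.R` | KM / log-rank / Cox reports, total cohort + subtypes |

Run them in order with `Rscript analysis/01_simulate.R` etc.

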