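# codaspectrum

Compositional data analysis of the physical activity **intensity spectrum**
in youth cohorts.

Wrist-accelerometer studies usually collapse movement intensity into a few
cut-point categories (sedentary, light, MVPA). The intensity-spectrum
approach instead partitions epoch-level acceleration (ENMO, mg) into nine
bands — 0–50, 50–100, …, 300–350, 350–700, ≥700 mg — and treats the nine
daily durations, closed to the 960-min waking day (07:00–23:00), as a
composition in the Aitchison geometry. `codaspectrum` is for
epidemiologists and movement scientists who want to run that workflow end
to end:

* **Banding**: `enmo()`, `band_minutes()`, wear-validity screening
  (`screen_wear()`: ≥600 min/day, ≥3 valid days, calibration error
  ≤10 mg), day averaging and closure.
* **Cohort preparation**: the sequential exclusion cascade
  (`exclusion_cascade()`), school-mean age centering, descriptive tables.
* **Compositional regression**: `coda_lm()` fits OLS of BMI z-score on the
  eight pivot isometric log-ratio (ILR) coordinates plus covariates;
  `pivot_scan()` rotates the basis through all nine bands and extracts
  each band-vs-remaining coefficient
  `z_1 = sqrt((D-1)/D) log(x_lead / gm(rest))`, with omnibus F test,
  sex-moderated stratification, VIF and school ICC diagnostics.
* **Isotemporal substitution**: `substitution_curve()` predicts the BMI
  z-score difference when t minutes move between one band and all
  remaining bands equally, `Δ(t) = β_z'(ilr(x_t) − ilr(x_0))`, with
  delta-method 95% CIs and the maximum-reallocation rule (leave ≥1 min in
  the band).
* **Synthetic cohorts**: `generate_cohort()` draws seeded cohorts with
  realistic compositions, covariates, outcome model and exact missingness
  counts, so everything above is testable without any data download.

## Worked example

```r
library(codaspectrum)
run <- run_pipeline(cohort_config(), seed = 1)
print(run)
```

```
Exclusion cascade: 1803 records in
  - missing_outcome  67 removed
  - wear_failure     233 removed
  - missing_ses      50 removed
  = 1453 retained

Pivot scan: band-vs-remaining associations
Omnibus ILR test: F(8, 1438) = 52.96, p = 1.74e-75
    band estimate    se  ci_lo  ci_hi        p
    0-50   0.0365 0.423 -0.794  0.867 9.31e-01
  50-100   1.8000 0.283  1.240  2.360 2.81e-10
 100-150  -2.9900 0.251 -3.480 -2.500 2.40e-31
 ...
    700+  -0.5940 0.102 -0.794 -0.393 8.02e-09

Sex term: F = 4.58, p = 0.0325 -> stratified analyses performed
```

Of 1803 synthetic roster records, 1453 survive the missing-outcome →
wear → missing-SES cascade. The omnibus test says the eight ILR
coordinates jointly predict BMI z-score; each row of the scan is the same
model refit with that band leading the pivot basis, so the estimate is
that band's association *relative to all remaining bands* (the nine
estimates sum to zero by construction). Sex is significant, so the scan
reruns within each sex. The ≥700 mg band is significantly and inversely
associated with BMI z-score in both sexes.

Substitution around the boys' baseline composition (geometric mean,
11.3 min in the ≥700 mg band, so at most 10 min can be removed):

```r
cv <- run$curves[["boy:700+"]]
cv[cv$minutes %in% c(-10, -5, 5, 10), ]
```

```
 band minutes  delta  ci_lo  ci_hi significant
 700+     -10  1.762  1.093  2.430        TRUE
 700+      -5  0.485  0.298  0.673        TRUE
 700+       5 -0.314 -0.442 -0.186        TRUE
 700+      10 -0.551 -0.785 -0.317        TRUE
```

Removing 10 min of ≥700 mg activity predicts a +1.76 BMI z-score
difference, over three times the −0.55 predicted when the same 10 min are
added — the characteristic asymmetry of log-ratio reallocations involving
a band that holds ~1% of the day. `plot(cv)` draws the curve with its CI
bounds; `run_pipeline(..., out_dir = "out")` writes all stage CSV/JSON
outputs, a checksummed manifest and a Markdown report.

See `vignettes/intensity-spectrum-coda.Rmd` for the model, the generator's
calibration and the package's numerical conventions.

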