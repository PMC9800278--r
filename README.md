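# cd8pet

Quantitative analysis of whole-body CD8 immuno-PET trials in R.

In trials of zirconium-89-labeled anti-CD8 antibody tracers, every tumor
lesion in the body is quantified by its standardized uptake value
(SUVmax = activity concentration / injected dose per body weight) before
and during immune-checkpoint-inhibitor therapy. Analyzing such data raises
a specific set of statistical problems that this package solves end to end:

* **Hierarchical uptake models** — log SUVmax with random intercepts per
  patient and per lesion nested within patient
  (`fit_lmm()`, `percent_effect()`, `lrt()`, `compute_icc()`), reported as
  geometric means and percent differences;
* **Empirical partial-volume adjustment** — small lesions read low on PET;
  a 5-knot restricted cubic spline of pretreatment log uptake on log
  CT volume (`fit_volume_uptake_spline()`) re-expresses every observation
  relative to a 5 cm³ reference lesion (`adjust_uptake()`), with CT volumes
  from oblate-spheroid diameters (`oblate_volume()`) interpolated to the
  PET date (`interpolate_volume()`); `treatment_change_model()` then
  estimates percent uptake change per treatment week, raw and adjusted;
* **Time–uptake curves and pharmacokinetics** — AIC selection among
  linear / log-linear / quadratic postinjection curves
  (`fit_time_uptake_curve()`) and noncompartmental terminal serum
  half-life (`estimate_terminal_half_life()`);
* **Survival on uptake strata** — Kaplan–Meier and log-rank
  (`km_estimate()`, `logrank_test()`) plus Firth-penalized Cox regression
  (`firth_cox()`), finite even under complete separation;
* **Autoradiography–IHC spatial correlation** — landmark affine
  registration (`estimate_affine()`, `warp_image()`), overlapping-tile
  summaries with the ≥25% ROI-overlap and ≥6-tile rules
  (`compute_tiles()`, `measure_tiles()`, `summarize_slide()`), and
  Kendall tau-b correlation within and across slides
  (`kendall_tau()`, `correlate_slides()`);
* **A synthetic-trial generator** — the clinical data behind such trials
  are access-restricted, so `generator_params()` / `generate_cohort()` /
  `generate_pk_series()` / `generate_slide_pair()` emulate the trial's
  statistical structure (hierarchical log-normal uptake, response-dependent
  slopes and shrinkage, partial-volume attenuation below 2 cm³,
  monoexponential serum decay, uptake-linked exponential survival, paired
  slides with known misalignment) with full ground truth for recovery
  testing.

Everything is tibble-in / tibble-out and pipe-friendly; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods. `run_pipeline()` chains the
stages (simulate → quantify → adjust → model → survival → coregister) with
seeded, manifest-checksummed outputs.

## Worked example

```r
library(cd8pet)

params <- generator_params(seed = 7)
cohort <- generate_cohort(params)
cohort
#> Synthetic cohort: 38 patients, 288 lesions, 576 lesion-scan rows
#>
#> PD SD PR CR
#> 23  7  4  4

baseline <- dplyr::filter(cohort$lesions, timepoint == 0, !irradiated)
summarize_uptake(baseline$suv_max)
#> # A tibble: 1 × 5
#>   geometric_mean   gcv ci_low ci_high     n
#>            <dbl> <dbl>  <dbl>   <dbl> <int>
#> 1           5.53 0.681   5.13    5.96   259
```

The baseline geometric mean SUVmax is 5.53 with a geometric coefficient of
variation of 0.68: tumor uptake is right-skewed and spans roughly an order
of magnitude across lesions. Fitting the volume–uptake spline and the
longitudinal model shows why the partial-volume adjustment matters:

```r
adj <- prepare_volume_adjusted(cohort$lesions)
raw <- treatment_change_model(adj$lesions, adjusted = FALSE)
corr <- treatment_change_model(adj$lesions, adjusted = TRUE)
raw$overall$percent; raw$interaction$p_value
#> [1] -5.09      # %/week, exaggerated by shrinkage-induced attenuation
#> [1] 5.5e-06    # spurious response-group interaction
corr$overall$percent; corr$interaction$p_value
#> [1] -4.59      # close to the generator truth of -4.6 %/week
#> [1] 0.91
```

Here every response group was generated with the same −4.6 %/week uptake
slope, but responder lesions shrink below the scanner's partial-volume
knee, so unadjusted uptake appears to fall faster in responders; the
spline adjustment removes most of that artifact.

```r
expo <- patient_uptake_exposure(cohort$lesions)
surv <- dplyr::inner_join(cohort$patients, expo, by = "patient_id")
firth_cox(
  tibble::tibble(time = surv$os_months, event = surv$os_event,
                 geomean = surv$geomean_suv),
  "geomean", standardize = TRUE, direction = "decrease")
#> Firth-penalized Cox: HR 1.940 (95% CI 1.277-3.065), p = 0.0014
#>   per SD of geomean (decrease); 38 subjects, 31 events
```

Patients whose baseline geometric-mean uptake is one population SD lower
face a ~1.9-fold higher death hazard in this synthetic cohort, mirroring
how low CD8 tracer uptake portends poor survival.

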