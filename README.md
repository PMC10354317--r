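# ramantriage

Simulation, preprocessing and diagnostic-accuracy evaluation for serum
Raman spectroscopy triage tests for colorectal cancer (CRC).

## Why

Most colorectal cancers present symptomatically in primary care, where
referral criteria convert to a cancer diagnosis only a few percent of
the time, and colonoscopy capacity cannot keep pace. A serum Raman test
is a candidate triage tool: the Raman spectrum of serum in the
600–1800 cm⁻¹ fingerprint region carries a biochemical signature of
proteins, nucleic acids, lipids and carotenoids, and cancer perturbs
the relative band intensities. Coupled to a classifier, a single blood
draw yields a per-patient cancer probability that can prioritise
referrals before invasive testing.

Clinical serum spectra from such studies are not public. This package
therefore implements the *entire computational pipeline* of a triage
study — and validates it end to end on synthetic cohorts with known
ground truth:

- **`simulate_cohort()`** — synthetic symptomatic cohorts: Gaussian
  band model of serum spectra, per-patient biological variability,
  case/control effect maps with stage-dependent attenuation,
  fluorescence background, noise, cosmic-ray spikes, axis
  miscalibration, reference-standard allocation.
- **`run_preprocessing()`** — the standard chain: despiking,
  wavenumber calibration (weighted affine fit to reference bands),
  binning, Savitzky–Golay smoothing, baseline subtraction (asymmetric
  least squares or iterative polynomial), vector-L2 or area
  normalisation.
- **`propensity_match()`** — age/sex propensity-score matching
  (1:1 without replacement, 0.2 SD logit caliper, exact on sex,
  best-pair-first, deterministic) for the case–control training set.
- **`train_forest()` / `cross_validate()` / `predict_patients()`** —
  probability random forest with *patient-grouped* repeated k-fold
  cross-validation; per-patient probability is the arithmetic mean
  over that patient's spectra, classified CRC when ≥ 0.5 (boundary
  inclusive). Prediction takes no diagnosis input — blinding is
  structural.
- **`build_report()` and friends** — sensitivity/specificity with
  exact Clopper–Pearson intervals, midrank (Mann–Whitney) AUC,
  stage-stratified sensitivity pooled from counts, patient-flow
  accounting, and Buderer's prevalence-adjusted sample size:

  n = z²₁₋α/₂ · p(1−p) / d² / prevalence

  for target performance p, absolute precision d.

## Worked example

```r
library(ramantriage)

# exact binomial interval for 22 detections in 23 cancers
clopper_pearson(22, 23)
#>       low      high
#> 0.7805134 0.9988998     # i.e. 95.7% sensitivity, 95% CI 78.1% to 99.9%

# recruits needed to pin 90% specificity to ±0.1 at 5% prevalence
buderer_sample_size(0.90, 0.10, prevalence = 0.05)
#> [1] 691

# a small end-to-end study: simulate a retrospective pool, match cases
# to controls on age and sex, train, then blindly evaluate a separate
# prospective cohort after the exclusion rules
cfg <- study_config(
  train_sim      = sim_config(n_patients = 120, prevalence = 0.25, seed = 101),
  validation_sim = sim_config(n_patients = 80,  prevalence = 0.15, seed = 202),
  cv_repeats = 2, seed = 1)
res <- run_study(cfg, output_dir = file.path(tempdir(), "demo"))
res
#> 2 x 5-fold patient-grouped cross-validation
#>   sensitivity 0.713 +/- 0.174
#>   specificity 0.757 +/- 0.123
#>   auc         0.824 +/- 0.100
#>   typical fold AUC 0.806 (repeat 1, fold 3)
#>
#> diagnostic accuracy report (95% exact CIs)
#>
#> colonoscopy_only (n = 37):
#>   sensitivity 62.5% (24.5% to 91.5%)
#>   specificity 72.4% (52.8% to 87.3%)
#>   AUC 0.677
#> colonoscopy_plus_ctc (n = 61):
#>   sensitivity 75.0% (42.8% to 94.5%)
#>   specificity 79.6% (65.7% to 89.8%)
#>   AUC 0.790
#> ...
```

The cross-validation block is the internal (training-set) estimate; the
report below it is the blinded evaluation of the prospective cohort,
split into the colonoscopy-only stratum and the combined
colonoscopy-plus-CT-colonography stratum, with exact 95% intervals.
At this toy scale the intervals are wide; the package's reference
conditions (300 training patients, 532-patient prospective cohort) are
what the tests and the acceptance script use.

Each run directory contains the resolved configuration (including all
seeds), per-patient predictions, the report as JSON and markdown, and a
line-delimited JSON log of per-stage patient/spectrum counts — enough
to reproduce the run bit for bit.

## Package layout

- `R/synthetic_data.R` — cohort generator and artifact injection
- `R/spectra_io.R` — CSV fixtures, validation, report serialisation
- `R/preprocess.R` — the five-step preprocessing chain
- `R/cohort.R` — matching, exclusions, stratification
- `R/model.R` — forest, grouped CV, per-patient aggregation
- `R/dxstats.R` — intervals, AUC, stage pooling, sample size, reports
- `R/pipeline.R` — `study_config()` / `run_study()` orchestration
- `vignettes/spectral-triage-methods.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical decisions, limitations
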