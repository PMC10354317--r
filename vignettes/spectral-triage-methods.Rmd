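---
title: "Methods: simulating and evaluating a serum Raman triage test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating a serum Raman triage test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package models

Symptomatic patients referred from primary care on an urgent
suspected-cancer pathway have a low colorectal cancer (CRC) conversion
rate, so colonoscopy capacity is spent mostly on patients without
cancer. A serum Raman spectroscopy test offers a triage signal: the
inelastic light-scattering spectrum of serum carries a biochemical
fingerprint of proteins, nucleic acids, lipids and carotenoids, and
cancer shifts the relative intensities of some of those bands. A
classifier over preprocessed spectra can then rank patients by cancer
probability before invasive testing.

`ramantriage` implements the full computational path of such a study:

1. a synthetic cohort generator with known ground truth,
2. the standard spectral preprocessing chain,
3. a propensity-matched case-control training cohort,
4. a random-forest classifier with patient-grouped cross-validation and
   per-patient probability aggregation, and
5. diagnostic-accuracy reporting with exact binomial confidence
   intervals, stage-stratified sensitivity and prevalence-adjusted
   sample-size planning.

Clinical serum spectra are not publicly available, so the package's
empirical claims are about the *pipeline*, validated end to end on
simulated cohorts whose generating truth is known.

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` emulate a symptomatic referral
cohort. The defaults describe the reference conditions used throughout
the package's tests:

* **Cohort shape.** 532 patients at a fixed CRC prevalence of 29/532,
  three replicate spectra per patient. Stage mix over UICC I-IV is
  (4, 10, 12, 3)/29. Reference-standard tests are allocated exactly
  (largest-remainder rounding) as 248 colonoscopy, 157 CT colonography,
  87 flexible sigmoidoscopy and 40 with no reference test, so that the
  documented exclusion rules retain 405 patients, 248 of them in the
  colonoscopy stratum. How the excluded fractions decompose is a free
  parameter of the generator, not an assertion about any particular
  study.
* **Spectral model.** Each spectrum is a sum of Gaussian bands at
  serum-typical Raman shifts in the 600-1800 cm^-1 fingerprint region
  (`serum_peak_library()`: phenylalanine 621/1003/1032, tyrosine
  643/852, tryptophan 757, carotenoids 1157/1518, CH/nucleic-acid bands
  1340, CH2 1450, amide I 1655), on a broad smooth fluorescence
  background with additive Gaussian detector noise (optionally Poisson
  shot noise), a per-spectrum acquisition-scale drift, and optional
  cosmic-ray spikes and affine axis miscalibration. No public numerical
  description of serum spectra exists for the emulated assay, so the
  band library and all intensity scales are documented stand-ins
  chosen to look like biofluid Raman data, not measured references.
* **Biological variability.** Every patient owns a log-normal per-band
  amplitude fingerprint (`bio_sd = 0.25`), with small additional
  replicate-level variation (`rep_sd = 0.05`). Patient-level
  variability dominating replicate variability is what makes
  patient-grouped cross-validation matter.
* **Disease effect.** Cases multiply each band amplitude by
  `effect_map`; the default direction (aromatic and nucleic-acid bands
  up, carotenoids down) follows the direction reported for serum in
  the CRC spectroscopy literature. The default magnitude is a
  *calibration choice*: the log-effect scale 0.40 was set once, from a
  strength-versus-AUC sweep, so that the default end-to-end pipeline
  reaches a held-out patient-level AUC of roughly 0.8-0.85 — the
  operating regime reported for serum Raman CRC classifiers — and was
  not revisited afterwards. Early-stage cases express an attenuated
  effect (stage exponents I 0.6, II 0.8, III 1.1, IV 1.3), so stage-
  stratified sensitivity has a gradient by construction.

What the generator does *not* model: instrument response functions,
quartz substrate signal, water/hemolysis artifacts, batch effects
between acquisition days, or any correlation between spectra and
demographics. Passing tests therefore demonstrate correctness of the
computational pipeline under a plausible data model; they are not
evidence about real serum performance.

## Preprocessing

`run_preprocessing()` applies, in a fixed order: optional despiking,
wavenumber calibration, binning to a common grid, Savitzky-Golay
smoothing, baseline subtraction, and normalisation. Every parameter is
carried in `preprocess_config()`; the chain contains no randomness and
records its provenance.

* **Despiking** (median filter, threshold 8 robust SDs) runs first:
  a cosmic-ray spike inside a calibration search window would corrupt
  peak detection. A point is a spike only if it is far above the
  running median, jumps sharply over both neighbours, and its
  neighbours sit near the median — the last condition keeps smooth
  peak apexes untouched.
* **Wavenumber calibration** estimates an affine axis correction from
  known reference bands. Implementation detail that matters: each band
  centre is located by a local Gaussian-plus-linear least-squares fit
  (after a coarse anchor shift at the dominant 1003 cm^-1 band), and
  the affine map is fitted by least squares weighted by the inverse
  variance of each fitted centre. A simpler 3-point parabolic apex
  estimate was tried first and discarded: with reference bands
  clustered at 850-1650 cm^-1, the extrapolation of the intercept to
  0 cm^-1 amplifies per-band position error about threefold, and the
  parabolic estimator's ~1 cm^-1 per-band error produced offset errors
  of several cm^-1. The model-based fit achieves a mean absolute
  offset-recovery error of ~0.25 cm^-1 over injected offsets in
  [-3, +3] cm^-1 (tested invariant: < 0.3 cm^-1); single-spectrum
  estimates scatter more, so offset examples are asserted on the mean
  over a patient's replicates.
* **Binning** takes arithmetic means over half-open bins of the target
  grid (default 600-1800 cm^-1, step 2); empty bins are linearly
  interpolated and flagged.
* **Smoothing** is Savitzky-Golay (window 11, order 3): the field
  default, with an exact test surface — any polynomial of degree at
  most the order is reproduced to machine precision, including at the
  endpoints, where the boundary window is evaluated off-centre.
* **Baseline subtraction** offers asymmetric least squares (Whittaker
  smoothing with asymmetry `p = 0.01`, stiffness `lambda = 1e5`,
  iterated until the weight pattern stabilises; exceeding the
  iteration cap is an error) and iterative modified polynomial
  fitting (default order 5; a pure polynomial input of that order is
  reproduced exactly). Known behaviour worth stating: at the default
  stiffness, ALS carries a bias of up to ~6% in recovered peak height
  where the background curvature is strongest, while the polynomial
  estimator recovers heights of peaks over polynomial backgrounds to
  about 1%. Negative residual values are *not* clipped: clipping would
  destroy the linearity that the recovery tests rely on, and
  L2 normalisation downstream is indifferent to sign.
* **Normalisation** is vector-L2 by default (total-area as option);
  the invariant (unit norm to 1e-12) is asserted for every processed
  spectrum in every run.

## Training cohort construction

`propensity_match()` builds the case-control training set: a logistic
model of case membership on age and sex, then 1:1 matching without
replacement inside a caliper of 0.2 SD of the propensity logit.
Two refinements depart from the textbook greedy sweep, both forced by
measured balance failures: (1) categorical covariates are matched
exactly — inside a logit caliper, a cross-sex pair must carry an
exactly compensating, and therefore one-signed, age difference; and
(2) pairs form best-first (globally smallest standardised covariate
distance first) rather than in descending-score order — a fixed sweep
direction produces a systematic quantile-mismatch drift whenever the
per-stratum group sizes differ. With these rules the post-match age
SMD on exchangeable groups is ~0.005 where the plain sweep gave
0.2-0.3. The cost is coverage: exact sex matching caps the pair count
at the per-sex minimum counts, so "almost all" rather than all cases
match when the groups have random sex imbalance. Matching is
deterministic without a seed (ties break on patient id).

`apply_exclusions()` implements the prospective study's rules —
flexible-sigmoidoscopy-only patients, missing reference test, missing
diagnosis — with exact partition accounting, and
`stratify_by_reference()` produces the nested colonoscopy-only and
colonoscopy-plus-CT strata.

## Classifier and evaluation

The classifier is a probability random forest (`ranger`; 500 trees,
sqrt(p) features per split, single-threaded for determinism, seeded).
Hyperparameters are deliberately untuned defaults.

Cross-validation (`cross_validate()`) is stratified by class and
grouped by patient: folds partition *patients*, never spectra, because
replicate spectra of one patient are strongly correlated and splitting
them across folds would leak identity. All metrics are computed after
per-patient aggregation. The "typical fold" is the fold whose AUC is
the median across all folds and repeats.

Per-patient aggregation (`predict_patients()` /
`aggregate_patient()`) is the arithmetic mean of a patient's
per-spectrum cancer probabilities, thresholded at 0.5 with the
boundary classified as cancer. The prediction surface takes no
diagnosis input, so blinding is structural, not procedural.

## Diagnostic statistics

* `clopper_pearson()` computes the exact binomial interval from beta
  quantiles; the tests verify it against an independent bisection on
  the binomial tail sums for every `x <= n <= 30` (1e-6 agreement) and
  check conservative coverage by Monte-Carlo.
* `roc_auc()` uses midranks, so the trapezoidal ROC area equals
  the Mann-Whitney pairwise-concordance probability exactly; the
  tests verify this against exhaustive pair counting.
* `stage_sensitivity()` pools early (I-II) and late (III-IV) stages
  from summed counts — never by averaging percentages — so strata of
  different sizes weight correctly: detections of 2/4 and 9/10 pool to
  11/14 = 78.6%, not (50% + 90%)/2 = 70%.
* `buderer_sample_size()` inflates the single-proportion sample size
  `z^2 p (1-p) / d^2` by the prevalence of the subgroup that
  contributes to the metric, truncating towards zero (the convention
  under which 90% specificity, 0.1 precision and 5% prevalence give
  691 recruits, from 691.46).
* Percentages in reports are rendered at 1 decimal with half-up
  rounding. One numerical caveat is documented rather than hidden:
  exact CP bounds for 26 of 29 give a lower limit of 72.648%, which
  prints as 72.6% in this package, while double rounding
  (72.648 → 72.65 → 72.7) would print 72.7%.

## Reference problem sizes

The package's own test suite and the acceptance script run at the
following sizes, chosen as the package's documented reference
conditions: null and effect calibration on 300 patients (50:50, three
replicates, 900 spectra) with 5x5 patient-grouped cross-validation;
effect-sweep points at 2 repeats; calibration recovery on 63 spectra
across offsets in [-3, +3]; the end-to-end study on a 450-patient
retrospective pool (150 cases, matched 1:1) and a 532-patient
prospective cohort. A complete acceptance run takes a few minutes on
one CPU.

## Known limitations

* All spectral realism limits listed for the generator; in particular
  there are no batch effects, so the calibration operator is tested
  only against the artifact model it was designed for.
* The matched training cohort and the prospective cohort are drawn
  from the same generative distribution; domain shift between
  retrospective and prospective sampling is not modelled.
* Under a pure-noise propensity (already exchangeable groups) matching
  discards some cases through the exact-sex rule and the caliper;
  with a real confounded pool the coverage is higher.
* The 0.5 decision threshold is fixed a priori, not tuned; no
  threshold-free calibration measure beyond AUC is reported.
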