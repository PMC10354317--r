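#' Default serum peak library
#'
#' A library of Gaussian bands at serum-typical Raman shifts in the
#' 600-1800 cm^-1 fingerprint region, covering the aromatic amino acids
#' (phenylalanine 621/1003/1032, tyrosine 643/852, tryptophan 757),
#' carotenoids (1157, 1518), nucleic-acid/CH deformation bands (1340),
#' the CH2 bending band (1450) and amide I (1655). Amplitudes are in
#' arbitrary counts relative to the phenylalanine 1003 band at 1.
#'
#' Real serum spectra are not described numerically anywhere in the
#' triage literature this package emulates; this library is a documented,
#' configurable stand-in, not a measured reference.
#'
#' @return Tibble with columns `center`, `width` (FWHM, cm^-1),
#'   `amplitude`, `shape`.
#' @export
serum_peak_library <- function() {
  tibble::tibble(
    center    = c(621, 643, 757, 852, 1003, 1032, 1157, 1208, 1340, 1450, 1518, 1655),
    width     = c(10,  10,  10,  12,  8,    10,   12,   14,   20,   18,   12,   22),
    amplitude = c(0.15, 0.12, 0.18, 0.25, 1.00, 0.35, 0.40, 0.20, 0.25, 0.70, 0.45, 0.80),
    shape     = "gaussian"
  )
}

#' Default case/control spectral effect map
#'
#' Multiplicative amplitude factors applied to each peak of the library
#' for cancer cases: nucleic-acid and aromatic bands rise, carotenoid
#' bands fall, mirroring the direction of serum spectral changes reported
#' for colorectal cancer. `strength` scales the log-effects; the default
#' is calibrated so the default end-to-end pipeline operates in the
#' AUC 0.8-0.85 regime on held-out synthetic patients.
#'
#' @param strength Non-negative scalar; `0` gives an all-ones map (no
#'   case/control difference).
#' @return Named numeric vector of factors, names = peak centers.
#' @export
default_effect_map <- function(strength = 1) {
  # log-scale direction of change per band; scaled by `strength`
  direction <- c("621" = 0.3, "643" = 0.2, "757" = 0.5, "852" = -0.2,
                 "1003" = 0.25, "1032" = 0.2, "1157" = -0.6, "1208" = 0.15,
                 "1340" = 0.5, "1450" = 0.1, "1518" = -0.6, "1655" = 0.3)
  base_scale <- 0.40   # calibration constant for the default operating regime
  exp(strength * base_scale * direction)
}

#' Simulation configuration for synthetic serum Raman cohorts
#'
#' Defines the study conditions a simulated cohort emulates: a
#' symptomatic referral population of `n_patients` at the stated CRC
#' `prevalence`, several replicate spectra per patient, case/control
#' spectral effects, per-patient biological variability, broad
#' fluorescence background, detector noise, and optional cosmic-ray
#' spikes and axis miscalibration.
#'
#' @param n_patients Number of patients. Default `532`, the size of the
#'   eligible symptomatic cohort the defaults emulate.
#' @param prevalence CRC prevalence in (0, 1). Default `29 / 532`.
#' @param fixed_prevalence If `TRUE` (default) exactly
#'   `round(n_patients * prevalence)` cases are drawn; otherwise the case
#'   count is Binomial(`n_patients`, `prevalence`).
#' @param replicates_per_patient Spectra acquired per patient, default `3`.
#' @param axis_range Simulated wavenumber range (cm^-1), default
#'   `c(580, 1820)` so the 600-1800 analysis grid stays covered under
#'   small miscalibrations.
#' @param points_per_spectrum Points on the raw axis, default `640`.
#' @param peaks Peak library tibble, default [serum_peak_library()].
#' @param effect_map Named per-peak multiplicative amplitude factors for
#'   cases, default [default_effect_map()].
#' @param stage_effect_exponents Named exponents applied to the log-effect
#'   by UICC stage, so early-stage cases carry a weaker spectral signal.
#' @param bio_sd SD of per-patient log-normal peak amplitude variation.
#' @param rep_sd SD of per-replicate log-normal peak amplitude variation.
#' @param baseline_params `list(order, scale)` of the broad fluorescence
#'   background polynomial.
#' @param noise_sd Additive Gaussian noise SD (intensity counts).
#' @param shot_noise If `TRUE`, replace additive noise with Poisson
#'   counting noise on the photon scale.
#' @param spike_rate Expected cosmic-ray spikes per spectrum (Poisson).
#' @param miscalibration `c(offset_cm1, gain)` affine axis perturbation.
#' @param stage_distribution Probabilities over stages I-IV for cases,
#'   default `c(4, 10, 12, 3) / 29` (the stage mix of the emulated cohort).
#' @param reference_probs Probabilities over reference-standard tests
#'   `colonoscopy`, `ct_colonography`, `flexible_sigmoidoscopy`, `none`,
#'   allocated exactly (largest remainder). The default reproduces a
#'   532-patient flow that retains 405 patients after exclusions, 248 of
#'   them colonoscopy-investigated. Cases are only ever assigned
#'   colonoscopy or CT colonography (their diagnosis is histologically
#'   confirmed).
#' @param seed Integer RNG seed; identical configs give bit-identical
#'   cohorts.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 532,
                       prevalence = 29 / 532,
                       fixed_prevalence = TRUE,
                       replicates_per_patient = 3,
                       axis_range = c(580, 1820),
                       points_per_spectrum = 640,
                       peaks = serum_peak_library(),
                       effect_map = default_effect_map(),
                       stage_effect_exponents = c(I = 0.6, II = 0.8, III = 1.1, IV = 1.3),
                       bio_sd = 0.25,
                       rep_sd = 0.05,
                       baseline_params = list(order = 3, scale = 2),
                       noise_sd = 0.02,
                       shot_noise = FALSE,
                       spike_rate = 0,
                       miscalibration = c(0, 1),
                       stage_distribution = c(I = 4, II = 10, III = 12, IV = 3) / 29,
                       reference_probs = c(colonoscopy = 248, ct_colonography = 157,
                                           flexible_sigmoidoscopy = 87, none = 40) / 532,
                       seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1) {
    stop("`prevalence` must be in (0, 1)", call. = FALSE)
  }
  if (replicates_per_patient < 1) {
    stop("`replicates_per_patient` must be >= 1", call. = FALSE)
  }
  if (abs(sum(stage_distribution) - 1) > 1e-6) {
    stop("`stage_distribution` must sum to 1", call. = FALSE)
  }
  if (abs(sum(reference_probs) - 1) > 1e-6) {
    stop("`reference_probs` must sum to 1", call. = FALSE)
  }
  stopifnot(axis_range[1] < axis_range[2], points_per_spectrum > 10)
  if (!all(peaks$center > axis_range[1] & peaks$center < axis_range[2])) {
    stop("all peak centers must lie inside `axis_range`", call. = FALSE)
  }
  stopifnot(all(peaks$width > 0), all(peaks$amplitude >= 0),
            all(peaks$shape %in% c("gaussian", "lorentzian")))
  if (is.null(names(effect_map)) ||
      !all(as.character(peaks$center) %in% names(effect_map))) {
    stop("`effect_map` must be named by peak center and cover every peak",
         call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients), prevalence = prevalence,
    fixed_prevalence = fixed_prevalence,
    replicates_per_patient = as.integer(replicates_per_patient),
    axis_range = axis_range, points_per_spectrum = as.integer(points_per_spectrum),
    peaks = peaks, effect_map = effect_map,
    stage_effect_exponents = stage_effect_exponents,
    bio_sd = bio_sd, rep_sd = rep_sd, baseline_params = baseline_params,
    noise_sd = noise_sd, shot_noise = shot_noise, spike_rate = spike_rate,
    miscalibration = miscalibration,
    stage_distribution = stage_distribution, reference_probs = reference_probs,
    seed = as.integer(seed)
  ), class = "sim_config")
}

peak_profile <- function(axis, center, width, amplitude, shape) {
  if (shape == "gaussian") {
    sigma <- width / (2 * sqrt(2 * log(2)))
    amplitude * exp(-0.5 * ((axis - center) / sigma)^2)
  } else {
    hwhm <- width / 2
    amplitude / (1 + ((axis - center) / hwhm)^2)
  }
}

# exact integer allocation of n units to probabilities (largest remainder)
allocate_counts <- function(n, probs) {
  raw <- n * probs
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

simulate_baseline <- function(axis, params) {
  t <- (axis - min(axis)) / diff(range(axis))
  ord <- params$order
  coefs <- stats::runif(ord + 1, 0, 1) * c(1, rep(0.8, ord))
  # decaying fluorescence shape: strongest at the low-wavenumber end
  shape <- coefs[1] + drop(outer(1 - t, seq_len(ord), `^`) %*% coefs[-1])
  params$scale * shape
}

#' Simulate a cohort of serum-like Raman spectra with ground truth
#'
#' Draws a patient cohort at the configured prevalence, assigns UICC
#' stages and reference-standard tests, gives every patient a biological
#' spectral fingerprint (log-normal per-peak variation around the
#' library), multiplies case amplitudes by the effect map (attenuated or
#' amplified by stage), and acquires `replicates_per_patient` spectra per
#' patient with fluorescence background and noise. Spikes and axis
#' miscalibration are injected via [inject_artifacts()] when configured.
#'
#' @param config A [sim_config()].
#' @return Object of class `raman_cohort`: `spectra` (list of
#'   `raw_spectrum`), `patients` (patient table), `truth` (ground-truth
#'   tibble with `patient_id`, `is_crc`, `stage`, `reference_test`) and
#'   the generating `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  n_cases <- if (config$fixed_prevalence) {
    as.integer(round(n * config$prevalence))
  } else {
    stats::rbinom(1, n, config$prevalence)
  }
  is_crc <- rep(FALSE, n)
  is_crc[sample.int(n, n_cases)] <- TRUE

  stages <- rep("none", n)
  if (n_cases > 0) {
    stages[is_crc] <- sample(names(config$stage_distribution), n_cases,
                             replace = TRUE, prob = config$stage_distribution)
  }

  # exact reference-test allocation; cases only get confirmatory tests
  ref_names <- names(config$reference_probs)
  counts <- allocate_counts(n, config$reference_probs)
  pool <- rep(ref_names, counts)
  conf_tests <- intersect(c("colonoscopy", "ct_colonography"), ref_names)
  conf_pool_idx <- which(pool %in% conf_tests)
  if (n_cases > length(conf_pool_idx)) {
    stop("not enough colonoscopy/CT colonography slots for the case count",
         call. = FALSE)
  }
  reference <- character(n)
  case_slots <- conf_pool_idx[sample.int(length(conf_pool_idx), n_cases)]
  reference[is_crc] <- pool[case_slots]
  rest <- if (n_cases > 0) pool[-case_slots] else pool
  reference[!is_crc] <- sample(rest)

  age <- pmin(pmax(round(stats::rnorm(n, mean = ifelse(is_crc, 72, 68), sd = 9)), 50), 95)
  sex <- ifelse(stats::runif(n) < ifelse(is_crc, 0.6, 0.5), "M", "F")

  patients <- tibble::tibble(
    patient_id = ids, age = as.numeric(age), sex = sex,
    reference_test = reference,
    diagnosis = ifelse(is_crc, "crc", "non_crc"),
    uicc_stage = stages
  )
  truth <- tibble::tibble(patient_id = ids, is_crc = is_crc, stage = stages,
                          reference_test = reference)

  axis <- seq(config$axis_range[1], config$axis_range[2],
              length.out = config$points_per_spectrum)
  pk <- config$peaks
  eff <- config$effect_map[as.character(pk$center)]
  log_eff <- log(eff)

  spectra <- vector("list", n * config$replicates_per_patient)
  k <- 0
  for (i in seq_len(n)) {
    # patient-level biological fingerprint
    pat_amp <- pk$amplitude * exp(stats::rnorm(nrow(pk), 0, config$bio_sd))
    if (is_crc[i]) {
      expo <- config$stage_effect_exponents[[stages[i]]]
      pat_amp <- pat_amp * exp(expo * log_eff)
    }
    for (r in seq_len(config$replicates_per_patient)) {
      rep_amp <- pat_amp * exp(stats::rnorm(nrow(pk), 0, config$rep_sd))
      sig <- rowSums(mapply(function(c, w, a, sh) peak_profile(axis, c, w, a, sh),
                            pk$center, pk$width, rep_amp, pk$shape))
      y <- sig + simulate_baseline(axis, config$baseline_params)
      y <- y * exp(stats::rnorm(1, 0, 0.1))   # overall acquisition scale drift
      if (config$shot_noise) {
        photon_scale <- 1 / max(config$noise_sd^2, 1e-12)
        y <- stats::rpois(length(y), pmax(y, 0) * photon_scale) / photon_scale
      } else {
        y <- y + stats::rnorm(length(y), 0, config$noise_sd)
      }
      k <- k + 1
      s <- raw_spectrum(patient_id = ids[i], replicate_id = sprintf("R%02d", r),
                        wavenumber = axis, intensity = y)
      if (config$spike_rate > 0 || any(config$miscalibration != c(0, 1))) {
        s <- inject_artifacts(s, config)
      }
      spectra[[k]] <- s
    }
  }
  structure(list(spectra = spectra, patients = patients, truth = truth,
                 config = config),
            class = "raman_cohort")
}

#' @export
print.raman_cohort <- function(x, ...) {
  cat("synthetic Raman cohort:", nrow(x$patients), "patients,",
      length(x$spectra), "spectra,", sum(x$truth$is_crc), "CRC cases\n")
  invisible(x)
}

#' Inject acquisition artifacts into a spectrum
#'
#' Adds `Poisson(spike_rate)` isolated single-point positive excursions
#' (cosmic-ray spikes) and perturbs the wavenumber axis by the affine map
#' `offset + gain * axis` given in `config$miscalibration`. With
#' `spike_rate = 0` and `miscalibration = c(0, 1)` the spectrum is
#' returned unchanged.
#'
#' @param spectrum A `raw_spectrum`.
#' @param config A [sim_config()] (only `spike_rate` and `miscalibration`
#'   are used).
#' @return The perturbed spectrum.
#' @export
inject_artifacts <- function(spectrum, config) {
  stopifnot(inherits(spectrum, "raw_spectrum"), inherits(config, "sim_config"))
  out <- spectrum
  if (config$spike_rate > 0) {
    n_spikes <- stats::rpois(1, config$spike_rate)
    if (n_spikes > 0) {
      pos <- sample.int(length(out$intensity), min(n_spikes, length(out$intensity)))
      mag <- stats::runif(length(pos), 5, 20) * max(abs(out$intensity))
      out$intensity[pos] <- out$intensity[pos] + mag
    }
  }
  mc <- config$miscalibration
  if (any(mc != c(0, 1))) {
    out$wavenumber <- mc[1] + mc[2] * out$wavenumber
  }
  out
}

#' Write a simulated cohort to a plain-text fixture directory
#'
#' Writes `spectra.csv` (long format: `wavenumber_cm1`, `intensity`,
#' `patient_id`, `replicate_id`), `cohort.csv` (patient table),
#' `truth.csv` (ground truth) and `config.json` (the generating
#' configuration, including the seed) into `directory`. The files
#' round-trip bit-exactly through [read_cohort()].
#'
#' @param cohort A `raman_cohort` from [simulate_cohort()].
#' @param directory Output directory, created if needed.
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(cohort, directory) {
  stopifnot(inherits(cohort, "raman_cohort"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(directory, 2) != 0) {
    stop("cannot write fixture directory: ", directory, call. = FALSE)
  }
  spectra_long <- dplyr::bind_rows(lapply(cohort$spectra, function(s) {
    tibble::tibble(wavenumber_cm1 = s$wavenumber, intensity = s$intensity,
                   patient_id = s$patient_id, replicate_id = s$replicate_id)
  }))
  readr::write_csv(spectra_long, file.path(directory, "spectra.csv"))
  readr::write_csv(cohort$patients, file.path(directory, "cohort.csv"))
  readr::write_csv(cohort$truth, file.path(directory, "truth.csv"))
  cfg <- cohort$config
  cfg$peaks <- as.data.frame(cfg$peaks)
  jsonlite::write_json(unclass(cfg), file.path(directory, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory)
}
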