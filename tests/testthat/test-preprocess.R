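make_spec <- function(wn, y, pid = "P1", rid = "R1") {
  raw_spectrum(pid, rid, wn, y)
}

test_that("binning takes half-open bin means and honours the grid", {
  s <- make_spec(c(100, 101, 102, 103), c(1, 2, 3, 4))
  out <- bin_to_grid(s, c(100, 104, 2))
  expect_equal(out$intensity, c(1.5, 3.5))
  expect_equal(out$wavenumber, c(101, 103))

  # constant spectra stay constant on any grid
  s2 <- make_spec(seq(600, 700, by = 1), rep(5, 101))
  out2 <- bin_to_grid(s2, c(600, 700, 7))
  expect_true(all(out2$intensity == 5))

  expect_error(bin_to_grid(s, c(500, 520, 2)), "outside")
})

test_that("width-1 bins aligned to the input axis reproduce the input", {
  withr::with_seed(5, {
    for (i in 1:5) {
      wn <- seq(100, 149, by = 1)
      y <- stats::runif(50)
      s <- make_spec(wn, y)
      out <- bin_to_grid(s, c(100, 150, 1))
      expect_equal(out$intensity, y)
    }
  })
})

test_that("empty bins are interpolated and flagged", {
  wn <- c(100, 101, 108, 109)
  s <- make_spec(wn, c(1, 1, 5, 5))
  out <- bin_to_grid(s, c(100, 110, 2))
  expect_equal(attr(out, "empty_bins"), c(2, 3, 4))
  expect_false(anyNA(out$intensity))
  # interpolated values lie between the neighbouring bin means
  expect_true(all(out$intensity[2:4] >= 1 & out$intensity[2:4] <= 5))
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials exactly", {
  wn <- seq(600, 800, length.out = 201)
  for (deg in 0:3) {
    y <- (wn / 700)^deg * 2 + deg
    s <- make_spec(wn, y)
    out <- smooth_spectrum(s, window = 11, polyorder = 3)
    expect_equal(out$intensity, y, tolerance = 1e-9)
  }
  expect_error(smooth_spectrum(make_spec(wn[1:5], 1:5), window = 7, polyorder = 3),
               "shorter")
  expect_error(smooth_spectrum(make_spec(wn, wn), window = 10, polyorder = 3),
               "odd")
})

test_that("smoothing strictly reduces white-noise variance", {
  withr::with_seed(8, {
    reductions <- replicate(100, {
      y <- stats::rnorm(300)
      s <- make_spec(seq_len(300) + 500, y)
      stats::var(smooth_spectrum(s, 11, 3)$intensity) < stats::var(y)
    })
  })
  expect_true(all(reductions))
})

test_that("polynomial baseline reproduces a pure polynomial input", {
  wn <- seq(600, 1800, by = 2)
  x <- (wn - 1200) / 400
  y <- 5 + 0.3 * x - 0.8 * x^2 + 0.05 * x^3 + 0.2 * x^4 - 0.04 * x^5
  s <- make_spec(wn, y)
  out <- subtract_background(s, "polynomial", list(order = 5))
  expect_lt(max(abs(out$intensity)), 1e-6 * max(abs(y)))
})

test_that("baseline subtraction recovers known peak heights over a polynomial", {
  wn <- seq(600, 1800, by = 2)
  x <- (wn - 1200) / 600
  baseline <- 10 + 2 * x - 3 * x^2 + x^3
  centers <- c(800, 1003, 1340, 1655)
  heights <- c(1, 2, 1.5, 1.2)
  peaks <- rowSums(sapply(seq_along(centers), function(j) {
    heights[j] * exp(-0.5 * ((wn - centers[j]) / 6)^2)
  }))
  s <- make_spec(wn, baseline + peaks)
  # the polynomial estimator models this baseline class exactly
  out <- subtract_background(s, "polynomial")
  got <- sapply(centers, function(ct) out$intensity[which.min(abs(wn - ct))])
  expect_lt(max(abs(got - heights) / heights), 0.05)
  # ALS carries a small stiffness bias where the background curvature peaks;
  # bound its mean recovery error and a looser worst case
  out_als <- subtract_background(s, "asymmetric_least_squares")
  got_als <- sapply(centers, function(ct) out_als$intensity[which.min(abs(wn - ct))])
  expect_lt(mean(abs(got_als - heights) / heights), 0.05)
  expect_lt(max(abs(got_als - heights) / heights), 0.10)
})

test_that("baseline of a flat zero spectrum is zero", {
  wn <- seq(600, 1800, by = 4)
  s <- make_spec(wn, rep(0, length(wn)))
  out <- subtract_background(s, "asymmetric_least_squares")
  expect_equal(out$intensity, rep(0, length(wn)), tolerance = 1e-10)
})

test_that("normalisation invariants: 3-4-5, scale invariance, unit area", {
  s <- make_spec(c(1000, 1001), c(3, 4))
  expect_equal(normalise_spectrum(s, "vector_l2")$intensity, c(0.6, 0.8))

  withr::with_seed(2, y <- stats::runif(80) + 0.1)
  wn <- seq(700, 1490, by = 10)
  s1 <- normalise_spectrum(make_spec(wn, y), "vector_l2")
  s2 <- normalise_spectrum(make_spec(wn, 7.3 * y), "vector_l2")
  expect_equal(s1$intensity, s2$intensity, tolerance = 1e-12)

  sa <- normalise_spectrum(make_spec(wn, y), "total_area")
  integral <- sum(diff(wn) * (sa$intensity[-1] + sa$intensity[-80]) / 2)
  expect_equal(integral, 1, tolerance = 1e-12)

  expect_error(normalise_spectrum(make_spec(wn, rep(0, 80)), "vector_l2"),
               "all-zero")
})

test_that("despiking removes isolated spikes and nothing else", {
  wn <- seq(600, 1800, by = 2)
  y <- exp(-0.5 * ((wn - 1000) / 20)^2) + 0.01 * sin(wn / 30)
  y_spiked <- y
  y_spiked[c(100, 400)] <- y_spiked[c(100, 400)] + 10
  out <- despike_spectrum(make_spec(wn, y_spiked))
  expect_setequal(attr(out, "spikes_removed"), c(100, 400))
  expect_lt(max(abs(out$intensity - y)), 0.1)
  # a clean spectrum is untouched
  clean <- despike_spectrum(make_spec(wn, y))
  expect_length(attr(clean, "spikes_removed"), 0)
})

test_that("injected axis offsets are recovered by calibration", {
  # replicate-mean offset estimate within 0.2 cm^-1 of the injected value
  refs <- serum_peak_library()[, c("center", "width")]
  names(refs) <- c("center", "fwhm")
  for (off in c(2, -1.5)) {
    cfg <- sim_config(n_patients = 2, seed = 19, miscalibration = c(off, 1))
    co <- simulate_cohort(cfg)
    ests <- sapply(co$spectra, function(s) {
      attr(calibrate_wavenumber(s, refs), "calibration")$offset
    })
    expect_lt(abs(mean(ests) - (-off)), 0.2)
  }
})

test_that("calibration recovers an affine gain perturbation", {
  refs <- serum_peak_library()[, c("center", "width")]
  names(refs) <- c("center", "fwhm")
  cfg <- sim_config(n_patients = 5, seed = 23, miscalibration = c(-1.5, 1.01))
  co <- simulate_cohort(cfg)
  cals <- lapply(co$spectra, function(s) {
    attr(calibrate_wavenumber(s, refs), "calibration")
  })
  offs <- sapply(cals, `[[`, "offset")
  gains <- sapply(cals, `[[`, "gain")
  # true inverse map: offset 1.5/1.01, gain 1/1.01
  expect_lt(abs(mean(offs) - 1.5 / 1.01) / (1.5 / 1.01), 0.10)
  expect_lt(abs(mean(gains) - 1 / 1.01) / (1 / 1.01), 0.10)
})

test_that("an unperturbed spectrum calibrates to near-identity", {
  refs <- serum_peak_library()[, c("center", "width")]
  names(refs) <- c("center", "fwhm")
  co <- simulate_cohort(sim_config(n_patients = 2, seed = 29))
  cals <- lapply(co$spectra, function(s) {
    attr(calibrate_wavenumber(s, refs), "calibration")
  })
  expect_lt(abs(mean(sapply(cals, `[[`, "offset"))), 0.2)
  expect_lt(abs(mean(sapply(cals, `[[`, "gain")) - 1), 0.002)
})

test_that("calibration with too few detectable peaks errors", {
  wn <- seq(600, 1800, by = 2)
  flat <- make_spec(wn, rep(1, length(wn)) + stats::rnorm(length(wn), 0, 1e-4))
  expect_error(calibrate_wavenumber(flat, c(1003)), "underdetermined")
})

test_that("the pipeline equals the manual composition of its five steps", {
  cfg <- preprocess_config(despike = FALSE)
  co <- simulate_cohort(sim_config(n_patients = 3, seed = 31))
  proc <- run_preprocessing(as_cohort_bundle(co), cfg)
  manual <- lapply(co$spectra, function(s) {
    s <- calibrate_wavenumber(s, cfg$reference_peaks, window = cfg$calibration_window)
    s <- bin_to_grid(s, cfg$grid)
    s <- smooth_spectrum(s, cfg$smooth_window, cfg$smooth_polyorder)
    s <- subtract_background(s, cfg$baseline_method, cfg$baseline_params)
    normalise_spectrum(s, cfg$normalisation)
  })
  expect_equal(proc$values, do.call(rbind, lapply(manual, `[[`, "intensity")))
  expect_equal(proc$grid, manual[[1]]$wavenumber)
})

test_that("preprocessing is deterministic and enforces its invariants", {
  co <- simulate_cohort(sim_config(n_patients = 4, seed = 37, spike_rate = 1,
                                   miscalibration = c(1, 1)))
  p1 <- run_preprocessing(as_cohort_bundle(co))
  p2 <- run_preprocessing(as_cohort_bundle(co))
  expect_identical(p1$values, p2$values)
  # normalisation invariant holds for every spectrum
  expect_true(all(abs(sqrt(rowSums(p1$values^2)) - 1) < 1e-12))
  # the provenance lists the steps in pipeline order
  expect_equal(p1$provenance$steps,
               c("despike", "wavenumber_calibration", "binning", "smoothing",
                 "background_subtraction", "normalisation"))
})

test_that("preprocess_config rejects invalid parameter combinations", {
  expect_error(preprocess_config(smooth_window = 10), "odd")
  expect_error(preprocess_config(smooth_window = 3, smooth_polyorder = 3), "odd")
  expect_error(preprocess_config(reference_peaks = c(100, 1003)), "grid")
  expect_error(preprocess_config(reference_peaks = 1003), "two reference")
})
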