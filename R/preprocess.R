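#' Preprocessing configuration
#'
#' Bundles the parameters of the five-step spectral preprocessing chain:
#' wavenumber calibration, binning to a common grid, Savitzky-Golay
#' smoothing, baseline (fluorescence background) subtraction and
#' normalisation. Every choice the chain makes is explicit here; nothing
#' is hard-coded downstream.
#'
#' @param reference_peaks Calibration reference bands: numeric centres
#'   (cm^-1) or a data frame with `center` and `fwhm` columns; at least
#'   two, all inside the grid. Defaults to the serum band library.
#' @param grid Target axis as `c(start, stop, step)` in cm^-1; features
#'   are bin means on half-open bins of width `step`.
#' @param smooth_window Odd number of points in the smoothing window.
#' @param smooth_polyorder Polynomial order of the smoother, less than
#'   `smooth_window`.
#' @param baseline_method `"asymmetric_least_squares"` (default) or
#'   `"polynomial"`.
#' @param baseline_params Method-specific parameters: for ALS `lambda`
#'   (smoothness, default `1e5`) and `p` (asymmetry, default `0.01`); for
#'   the polynomial method `order` (default `5`).
#' @param normalisation `"vector_l2"` (default) or `"total_area"`.
#' @param despike Logical; run the median-filter cosmic-ray despiker
#'   before calibration. Default `TRUE`.
#' @param calibration_window Half-width (cm^-1) of the search window
#'   around each reference peak. Default `10`.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(reference_peaks = NULL,
                              grid = c(600, 1800, 2),
                              smooth_window = 11,
                              smooth_polyorder = 3,
                              baseline_method = c("asymmetric_least_squares", "polynomial"),
                              baseline_params = NULL,
                              normalisation = c("vector_l2", "total_area"),
                              despike = TRUE,
                              calibration_window = 10) {
  baseline_method <- match.arg(baseline_method)
  normalisation <- match.arg(normalisation)
  if (is.null(reference_peaks)) {
    pk <- serum_peak_library()
    reference_peaks <- data.frame(center = pk$center, fwhm = pk$width)
  }
  reference_peaks <- as_reference_peaks(reference_peaks)
  if (is.null(baseline_params)) {
    baseline_params <- switch(baseline_method,
      asymmetric_least_squares = list(lambda = 1e5, p = 0.01),
      polynomial = list(order = 5))
  }
  stopifnot(length(grid) == 3, grid[3] > 0, grid[1] < grid[2])
  if (smooth_window %% 2 != 1 || smooth_window <= smooth_polyorder) {
    stop("`smooth_window` must be odd and greater than `smooth_polyorder`",
         call. = FALSE)
  }
  if (nrow(reference_peaks) < 2) {
    stop("at least two reference peaks are required for affine calibration",
         call. = FALSE)
  }
  if (any(reference_peaks$center < grid[1] | reference_peaks$center > grid[2])) {
    stop("all reference peaks must lie within the grid", call. = FALSE)
  }
  structure(list(reference_peaks = reference_peaks, grid = grid,
                 smooth_window = smooth_window, smooth_polyorder = smooth_polyorder,
                 baseline_method = baseline_method, baseline_params = baseline_params,
                 normalisation = normalisation, despike = despike,
                 calibration_window = calibration_window),
            class = "preprocess_config")
}

grid_centres <- function(grid) {
  edges <- seq(grid[1], grid[2], by = grid[3])
  (edges[-length(edges)] + edges[-1]) / 2
}

as_reference_peaks <- function(reference_peaks) {
  if (is.data.frame(reference_peaks)) {
    stopifnot(all(c("center", "fwhm") %in% names(reference_peaks)))
    return(reference_peaks[, c("center", "fwhm")])
  }
  data.frame(center = as.numeric(reference_peaks),
             fwhm = rep(12, length(reference_peaks)))
}

# localise one band: local linear detrend, then Gaussian + linear fit
fit_reference_band <- function(wn, y, target, fwhm, min_window) {
  window <- max(min_window, 1.3 * fwhm)
  sel <- which(wn >= target - window & wn <= target + window)
  if (length(sel) < 7) return(c(NA_real_, NA_real_))
  xs <- wn[sel]
  ys <- y[sel]
  k <- max(2, floor(length(sel) * 0.15))
  edge <- c(seq_len(k), seq(length(sel) - k + 1, length(sel)))
  co <- stats::lm.fit(cbind(1, xs[edge]), ys[edge])$coefficients
  yd <- ys - (co[1] + co[2] * xs)
  i <- which.max(yd)
  xs0 <- xs - xs[i]
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      yd ~ a * exp(-((xs0 - c)^2) / (2 * s^2)) + b0 + b1 * xs0,
      start = list(a = max(yd[i], 1e-6), c = 0, s = fwhm / 2.355, b0 = 0, b1 = 0),
      control = minpack.lm::nls.lm.control(maxiter = 60))),
    error = function(e) NULL)
  if (is.null(fit)) return(c(xs[i], NA_real_))
  cf <- stats::coef(fit)
  if (abs(cf["c"]) > window / 2 || cf["a"] <= 0 || cf["s"] > 2 * fwhm) {
    return(c(NA_real_, NA_real_))          # fit wandered off the band
  }
  se <- tryCatch(summary(fit)$coefficients["c", "Std. Error"],
                 error = function(e) NA_real_)
  c(xs[i] + unname(cf["c"]), se)
}

#' Wavenumber calibration against reference bands
#'
#' Estimates the affine axis correction (offset, gain) of a spectrum from
#' the observed positions of known reference bands. Each band is located
#' as the local maximum inside a search window (on a lightly smoothed
#' copy of the spectrum, after a coarse shift estimated at the anchor
#' band) and refined by a local Gaussian-plus-linear-baseline least
#' squares fit; the affine map is then fitted by weighted least squares
#' between detected and expected positions, weighting each band by the
#' inverse variance of its fitted centre. The corrected axis is
#' `offset + gain * axis`.
#'
#' @param s A `raw_spectrum`.
#' @param reference_peaks Expected band positions: numeric vector of
#'   centres (cm^-1), or a data frame with columns `center` and `fwhm`
#'   so each band's fit window matches its width.
#' @param window Minimum fit half-width in cm^-1 around each expected
#'   position; widened to 1.3 x the band's FWHM when that is larger.
#' @param anchor Centre (cm^-1) of the band used for the coarse shift
#'   estimate; must be the dominant band of its +/- 25 cm^-1
#'   neighbourhood. Defaults to the phenylalanine band at 1003 when
#'   present, otherwise the strongest detected reference.
#' @param residual_threshold Mean absolute post-fit residual (cm^-1) above
#'   which the spectrum is flagged (attribute `calibration_warning`).
#' @return The spectrum with corrected axis; attribute `calibration`
#'   carries `offset`, `gain`, detected positions and residuals.
#' @export
calibrate_wavenumber <- function(s, reference_peaks, window = 10,
                                 anchor = NULL, residual_threshold = 1.5) {
  stopifnot(inherits(s, "raw_spectrum"))
  refs <- as_reference_peaks(reference_peaks)
  if (nrow(refs) < 2) {
    stop("at least 2 reference peaks are needed; affine calibration is ",
         "underdetermined", call. = FALSE)
  }
  wn <- s$wavenumber
  n <- length(wn)
  y <- if (n > 11) as.numeric(signal::sgolayfilt(s$intensity, p = 3, n = 9)) else
    s$intensity

  if (is.null(anchor)) {
    anchor <- if (any(abs(refs$center - 1003) < 1e-6)) 1003 else
      refs$center[which.max(vapply(refs$center, function(ct) {
        sel <- which(wn >= ct - 25 & wn <= ct + 25)
        if (length(sel) == 0) -Inf else max(y[sel])
      }, numeric(1)))]
  }
  sel <- which(wn >= anchor - 25 & wn <= anchor + 25)
  shift <- if (length(sel) > 0) wn[sel][which.max(y[sel])] - anchor else 0

  det <- t(vapply(seq_len(nrow(refs)), function(j) {
    fit_reference_band(wn, y, refs$center[j] + shift, refs$fwhm[j], window)
  }, numeric(2)))
  ok <- !is.na(det[, 1])
  if (sum(ok) < 2) {
    stop("fewer than 2 reference peaks detected; affine calibration is ",
         "underdetermined", call. = FALSE)
  }
  # inverse-variance weights with a floor so no single band dominates
  w <- 1 / pmax(det[, 2], 0.05)^2
  w[is.na(w)] <- stats::median(w, na.rm = TRUE) / 4
  fit <- stats::lm.wfit(cbind(1, det[ok, 1]), refs$center[ok], w[ok])
  offset <- unname(fit$coefficients[1])
  gain <- unname(fit$coefficients[2])
  resid <- refs$center[ok] - (offset + gain * det[ok, 1])
  out <- s
  out$wavenumber <- offset + gain * wn
  attr(out, "calibration") <- list(offset = offset, gain = gain,
                                   detected = det[, 1], center_se = det[, 2],
                                   residuals = resid)
  attr(out, "calibration_warning") <- mean(abs(resid)) > residual_threshold
  out
}

#' Bin a spectrum onto a common wavenumber grid
#'
#' Each output value is the arithmetic mean of the input intensities whose
#' wavenumber falls in the half-open bin `[edge_i, edge_{i+1})`. Empty
#' bins are filled by linear interpolation from neighbouring bins and
#' flagged in the `empty_bins` attribute.
#'
#' @param s A `raw_spectrum`.
#' @param grid `c(start, stop, step)` in cm^-1.
#' @return A `raw_spectrum` on the bin-centre axis.
#' @export
bin_to_grid <- function(s, grid) {
  stopifnot(inherits(s, "raw_spectrum"), length(grid) == 3)
  edges <- seq(grid[1], grid[2], by = grid[3])
  nb <- length(edges) - 1
  if (max(s$wavenumber) < edges[1] || min(s$wavenumber) >= edges[nb + 1]) {
    stop("grid lies entirely outside the spectrum's wavenumber range",
         call. = FALSE)
  }
  idx <- findInterval(s$wavenumber, edges, left.open = FALSE)
  inside <- idx >= 1 & idx <= nb & s$wavenumber < edges[nb + 1]
  vals <- rep(NA_real_, nb)
  agg <- vapply(split(s$intensity[inside], idx[inside]), mean, numeric(1))
  vals[as.integer(names(agg))] <- agg
  empty <- which(is.na(vals))
  centres <- (edges[-(nb + 1)] + edges[-1]) / 2
  if (length(empty) > 0) {
    filled <- stats::approx(centres[-empty], vals[-empty], xout = centres[empty],
                            rule = 2)$y
    vals[empty] <- filled
  }
  out <- s
  out$wavenumber <- centres
  out$intensity <- vals
  attr(out, "empty_bins") <- empty
  out
}

#' Savitzky-Golay smoothing
#'
#' Local polynomial least-squares smoothing with the stated window and
#' order; reproduces any polynomial of degree at most `polyorder`
#' exactly, including at the endpoints, where the fit is evaluated
#' off-centre on the boundary window.
#'
#' @param s A `raw_spectrum`.
#' @param window Odd window length (points).
#' @param polyorder Polynomial order, less than `window`.
#' @return The smoothed spectrum.
#' @export
smooth_spectrum <- function(s, window = 11, polyorder = 3) {
  stopifnot(inherits(s, "raw_spectrum"))
  if (window %% 2 != 1 || window <= polyorder) {
    stop("`window` must be odd and greater than `polyorder`", call. = FALSE)
  }
  if (window >= length(s$intensity)) {
    stop("smoothing window must be shorter than the spectrum", call. = FALSE)
  }
  out <- s
  out$intensity <- as.numeric(signal::sgolayfilt(s$intensity, p = polyorder, n = window))
  out
}

#' Median-filter cosmic-ray despiking
#'
#' Replaces isolated single-point positive excursions (cosmic-ray spikes)
#' with the local running median. A point is a spike when it exceeds the
#' running median by more than `threshold` robust standard deviations of
#' the residual (median absolute deviation scaled to the normal).
#'
#' @param s A `raw_spectrum`.
#' @param window Odd median window, default `7`.
#' @param threshold Detection threshold in robust SD units, default `8`.
#' @return Despiked spectrum; attribute `spikes_removed` gives indices.
#' @export
despike_spectrum <- function(s, window = 7, threshold = 8) {
  stopifnot(inherits(s, "raw_spectrum"))
  y <- s$intensity
  med <- stats::runmed(y, k = window, endrule = "median")
  resid <- y - med
  sigma <- stats::mad(resid)
  if (sigma == 0) sigma <- stats::sd(resid)
  out <- s
  if (is.na(sigma) || sigma == 0) {
    attr(out, "spikes_removed") <- integer(0)
    return(out)
  }
  # a spike is an isolated single-point positive excursion: far above the
  # running median, a sharp jump over both neighbours, and the neighbours
  # themselves close to the running median (smooth peaks fail the last test)
  n <- length(y)
  lo <- c(y[1], y[-n])
  hi <- c(y[-1], y[n])
  jump <- y - pmax(lo, hi)
  nb_resid <- pmax(c(resid[1], resid[-n]), c(resid[-1], resid[n]))
  spikes <- which(resid > threshold * sigma &
                    jump > threshold * sigma / 2 &
                    nb_resid < 0.5 * resid)
  y[spikes] <- med[spikes]
  out$intensity <- y
  attr(out, "spikes_removed") <- spikes
  out
}

# second-difference penalty matrix for Whittaker/ALS smoothing
als_penalty <- function(n, lambda) {
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  lambda * Matrix::crossprod(D)
}

#' Baseline (fluorescence background) subtraction
#'
#' Estimates the broad smooth background under the spectrum and removes
#' it. Two estimators are provided:
#'
#' * `asymmetric_least_squares`: Whittaker smoothing with asymmetric
#'   weights (Eilers-Boelens): points above the running baseline get
#'   weight `p`, points below weight `1 - p`; `lambda` controls baseline
#'   stiffness. Iterated until the weight pattern is stable.
#' * `polynomial`: iterative modified polynomial fitting: fit a
#'   polynomial of the stated order, clip the working signal to the fit,
#'   repeat until the fit stops changing. A pure polynomial input of the
#'   stated order or lower is reproduced exactly.
#'
#' Small negative values may remain in the output; no clipping is applied
#' so the operator stays linear in regions away from peaks.
#'
#' @param s A `raw_spectrum`.
#' @param method `"asymmetric_least_squares"` or `"polynomial"`.
#' @param params Method parameters, see [preprocess_config()].
#' @param max_iter Iteration cap; exceeding it is an error carrying the
#'   iteration count.
#' @return Baseline-subtracted spectrum; attribute `baseline` carries the
#'   estimate.
#' @export
subtract_background <- function(s,
                                method = c("asymmetric_least_squares", "polynomial"),
                                params = NULL,
                                max_iter = if (match.arg(method) == "polynomial") 500 else 50) {
  stopifnot(inherits(s, "raw_spectrum"))
  method <- match.arg(method)
  y <- s$intensity
  n <- length(y)
  if (method == "asymmetric_least_squares") {
    if (is.null(params)) params <- list(lambda = 1e5, p = 0.01)
    lambda <- params$lambda
    p <- params$p
    P <- als_penalty(n, lambda)
    w <- rep(1, n)
    z <- y
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      W <- Matrix::Diagonal(n, w)
      z <- as.numeric(Matrix::solve(W + P, w * y))
      w_new <- ifelse(y > z, p, 1 - p)
      if (all(w_new == w)) { converged <- TRUE; break }
      w <- w_new
    }
    if (!converged) {
      stop(sprintf("ALS baseline did not converge within %d iterations", max_iter),
           call. = FALSE)
    }
    baseline <- z
  } else {
    if (is.null(params)) params <- list(order = 5)
    order <- params$order
    x <- (s$wavenumber - mean(s$wavenumber)) / stats::sd(s$wavenumber)
    X <- stats::poly(x, degree = order, raw = FALSE)
    X <- cbind(1, X)
    y_work <- y
    fit_prev <- NULL
    converged <- FALSE
    scale_y <- max(abs(y), 1e-12)
    for (it in seq_len(max_iter)) {
      fit <- X %*% qr.solve(X, y_work)
      if (!is.null(fit_prev) && max(abs(fit - fit_prev)) < 1e-8 * scale_y) {
        converged <- TRUE; break
      }
      fit_prev <- fit
      y_work <- pmin(y_work, as.numeric(fit))
    }
    if (!converged) {
      stop(sprintf("polynomial baseline did not converge within %d iterations",
                   max_iter), call. = FALSE)
    }
    baseline <- as.numeric(fit)
  }
  out <- s
  out$intensity <- y - baseline
  attr(out, "baseline") <- baseline
  out
}

#' Spectrum normalisation
#'
#' `vector_l2` scales the intensity vector to unit Euclidean norm;
#' `total_area` scales it so the trapezoidal integral over the axis
#' equals 1. Both are invariant to the overall intensity scale.
#'
#' @param s A `raw_spectrum`.
#' @param method `"vector_l2"` or `"total_area"`.
#' @return Normalised spectrum.
#' @export
normalise_spectrum <- function(s, method = c("vector_l2", "total_area")) {
  stopifnot(inherits(s, "raw_spectrum"))
  method <- match.arg(method)
  y <- s$intensity
  denom <- switch(method,
    vector_l2 = sqrt(sum(y^2)),
    total_area = trapz(s$wavenumber, y))
  if (!is.finite(denom) || denom == 0) {
    stop("normalisation undefined for an all-zero spectrum", call. = FALSE)
  }
  out <- s
  out$intensity <- y / denom
  out
}

trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Run the full preprocessing chain over a cohort
#'
#' Applies, in order: optional despiking, wavenumber calibration, binning
#' to the common grid, Savitzky-Golay smoothing, baseline subtraction and
#' normalisation. Every output spectrum lives on the identical bin-centre
#' grid; the chain is fully deterministic.
#'
#' @param bundle A `cohort_bundle` (or a plain list of `raw_spectrum`).
#' @param cfg A [preprocess_config()].
#' @return Object of class `processed_set`: `grid` (bin centres), `values`
#'   (spectra x wavenumber matrix), `meta` (tibble of `patient_id`,
#'   `replicate_id`), `provenance` (ordered step list with parameters) and
#'   `failures` (per-spectrum errors, if any).
#' @export
run_preprocessing <- function(bundle, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  spectra <- if (inherits(bundle, "cohort_bundle")) bundle$spectra else bundle
  stopifnot(length(spectra) > 0)

  steps <- c(if (cfg$despike) "despike",
             "wavenumber_calibration", "binning", "smoothing",
             "background_subtraction", "normalisation")
  process_one <- function(s) {
    if (cfg$despike) s <- despike_spectrum(s)
    s <- calibrate_wavenumber(s, cfg$reference_peaks, window = cfg$calibration_window)
    s <- bin_to_grid(s, cfg$grid)
    s <- smooth_spectrum(s, cfg$smooth_window, cfg$smooth_polyorder)
    s <- subtract_background(s, cfg$baseline_method, cfg$baseline_params)
    normalise_spectrum(s, cfg$normalisation)
  }

  results <- lapply(spectra, function(s) tryCatch(process_one(s),
                                                  error = function(e) e))
  failed <- vapply(results, inherits, logical(1), what = "error")
  if (any(failed)) {
    ids <- vapply(spectra[failed], function(s) paste0(s$patient_id, "/", s$replicate_id),
                  character(1))
    msgs <- vapply(results[failed], conditionMessage, character(1))
    stop("preprocessing failed for ", sum(failed), " spectra: ",
         paste0(ids, " (", msgs, ")", collapse = "; "), call. = FALSE)
  }
  grid <- grid_centres(cfg$grid)
  values <- do.call(rbind, lapply(results, function(s) s$intensity))
  meta <- tibble::tibble(
    patient_id = vapply(spectra, function(s) s$patient_id, character(1)),
    replicate_id = vapply(spectra, function(s) s$replicate_id, character(1))
  )
  structure(list(grid = grid, values = values, meta = meta,
                 provenance = list(steps = steps, config = unclass(cfg))),
            class = "processed_set")
}

#' @export
print.processed_set <- function(x, ...) {
  cat("processed spectra:", nrow(x$values), "spectra x", length(x$grid),
      "grid points (", min(x$grid), "-", max(x$grid), "cm^-1 )\n")
  cat("steps:", paste(x$provenance$steps, collapse = " -> "), "\n")
  invisible(x)
}
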