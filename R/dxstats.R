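#' Exact Clopper-Pearson binomial confidence interval
#'
#' Computes the exact two-sided confidence interval for a binomial
#' proportion from the beta-quantile representation. The interval inverts
#' the binomial tail probabilities, so it is conservative by construction:
#' coverage is at least the nominal level for every true proportion.
#'
#' @param x Number of successes (non-negative integer, `x <= n`).
#' @param n Number of trials (positive integer).
#' @param level Confidence level, default `0.95`.
#'
#' @return Named numeric vector `c(low, high)` of interval bounds on the
#'   proportion scale. `x = 0` gives `low = 0`; `x = n` gives `high = 1`.
#'
#' @examples
#' clopper_pearson(22, 23)
#' clopper_pearson(26, 29)
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  stopifnot(length(x) == 1, length(n) == 1, length(level) == 1)
  if (!is.finite(n) || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (!is.finite(x) || x < 0 || x > n || x != round(x)) {
    stop("`x` must be an integer with 0 <= x <= n", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  alpha <- 1 - level
  low <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(low = low, high = high)
}

#' Confusion counts for a binary diagnostic test
#'
#' @param tp,fp,tn,fn Non-negative integer counts of true positives, false
#'   positives, true negatives and false negatives against the reference
#'   standard.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion counts: tp =", x$tp, " fp =", x$fp,
      " tn =", x$tn, " fn =", x$fn, "\n")
  invisible(x)
}

metric_with_ci <- function(x, n, level) {
  if (n == 0) {
    return(list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                x = x, n = n, level = level, method = "clopper_pearson",
                defined = FALSE))
  }
  ci <- clopper_pearson(x, n, level)
  list(estimate = x / n, ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
       x = x, n = n, level = level, method = "clopper_pearson", defined = TRUE)
}

#' Sensitivity and specificity with exact confidence intervals
#'
#' Sensitivity is `tp / (tp + fn)` and specificity `tn / (tn + fp)`, each
#' with an exact Clopper-Pearson interval at `level`. A metric whose
#' denominator is zero is returned with `defined = FALSE` and `NA`
#' estimates rather than a silent zero.
#'
#' @param conf A [confusion_counts()] object.
#' @param level Confidence level, default `0.95`.
#' @return List with elements `sensitivity` and `specificity`, each a list
#'   carrying `estimate`, `ci_low`, `ci_high`, the counts, and the method
#'   tag `"clopper_pearson"`.
#' @export
sens_spec <- function(conf, level = 0.95) {
  stopifnot(inherits(conf, "confusion_counts"))
  list(
    sensitivity = metric_with_ci(conf$tp, conf$tp + conf$fn, level),
    specificity = metric_with_ci(conf$tn, conf$tn + conf$fp, level)
  )
}

#' Area under the empirical ROC curve
#'
#' Trapezoidal area under the empirical ROC curve with tied scores handled
#' by the midrank convention, so the result equals the pairwise
#' concordance probability (the Mann-Whitney statistic scaled to
#' `[0, 1]`): the probability that a randomly chosen diseased patient
#' scores above a randomly chosen non-diseased one, counting ties as 1/2.
#'
#' @param scores Numeric vector of predicted probabilities or scores.
#' @param labels Logical (or 0/1) vector, `TRUE` for diseased.
#' @return AUC as a single number in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  # midranks make the trapezoidal ROC area identical to pairwise concordance
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve coordinates
#'
#' @param scores,labels As in [roc_auc()].
#' @return Tibble with columns `threshold`, `fpr`, `tpr`, ordered from the
#'   (0, 0) to the (1, 1) corner. Tied scores contribute a single vertex,
#'   so the trapezoidal area of this curve equals [roc_auc()].
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  keep <- !duplicated(s)         # one vertex per distinct threshold
  tp <- cumsum(l)
  fp <- cumsum(!l)
  idx <- c(which(keep)[-1] - 1L, length(s))
  tibble::tibble(
    threshold = c(Inf, s[keep]),
    fpr = c(0, fp[idx] / sum(!labels)),
    tpr = c(0, tp[idx] / sum(labels))
  )
}

#' Stage-stratified sensitivity with early/late pooling
#'
#' Computes per-stage detection counts and sensitivities for diseased
#' patients, plus pooled early (I-II) and late (III-IV) sensitivities.
#' Pooled values are computed from summed counts (detected sum over n
#' sum), never by averaging percentages, so strata of different sizes are
#' weighted correctly.
#'
#' @param predictions Tibble with columns `patient_id` and `label`
#'   (`"crc"` / `"non_cancer"`), as from [predict_patients()], or any data
#'   frame with those columns.
#' @param truth Data frame with `patient_id`, `is_crc`, `stage`
#'   (`"I"`..`"IV"`, `"none"`); every diseased patient must carry a stage.
#' @return Object of class `stage_breakdown`: tibble `per_stage` with
#'   `stage`, `detected`, `n`, `sensitivity`, plus `pooled_early` and
#'   `pooled_late` lists with `detected`, `n`, `sensitivity`.
#' @export
stage_sensitivity <- function(predictions, truth) {
  stopifnot(all(c("patient_id", "label") %in% names(predictions)),
            all(c("patient_id", "is_crc", "stage") %in% names(truth)))
  diseased <- truth[truth$is_crc, , drop = FALSE]
  if (any(!diseased$stage %in% c("I", "II", "III", "IV"))) {
    stop("every diseased patient must have a UICC stage I-IV", call. = FALSE)
  }
  m <- match(diseased$patient_id, predictions$patient_id)
  if (anyNA(m)) {
    stop("missing predictions for diseased patients: ",
         paste(diseased$patient_id[is.na(m)], collapse = ", "), call. = FALSE)
  }
  detected_flag <- predictions$label[m] == "crc"
  per_stage <- tibble::tibble(stage = factor(diseased$stage, levels = c("I", "II", "III", "IV")),
                              detected = detected_flag)
  per_stage <- dplyr::summarise(
    dplyr::group_by(per_stage, stage, .drop = FALSE),
    detected = sum(detected), n = dplyr::n(), .groups = "drop"
  )
  per_stage$sensitivity <- ifelse(per_stage$n > 0, per_stage$detected / per_stage$n, NA_real_)

  pool <- function(stages) {
    sel <- per_stage$stage %in% stages
    d <- sum(per_stage$detected[sel])
    n <- sum(per_stage$n[sel])
    list(detected = d, n = n, sensitivity = if (n > 0) d / n else NA_real_)
  }
  structure(list(per_stage = per_stage,
                 pooled_early = pool(c("I", "II")),
                 pooled_late = pool(c("III", "IV"))),
            class = "stage_breakdown")
}

#' @export
print.stage_breakdown <- function(x, ...) {
  cat("stage-stratified sensitivity\n")
  print(as.data.frame(x$per_stage))
  cat(sprintf("pooled I-II:  %d/%d = %s\n", x$pooled_early$detected, x$pooled_early$n,
              format_pct(x$pooled_early$sensitivity)))
  cat(sprintf("pooled III-IV: %d/%d = %s\n", x$pooled_late$detected, x$pooled_late$n,
              format_pct(x$pooled_late$sensitivity)))
  invisible(x)
}

#' Prevalence-adjusted sample size for a diagnostic accuracy study
#'
#' Buderer's method: the single-proportion sample size
#' `z^2 p (1 - p) / d^2` needed to estimate a test characteristic `p`
#' with absolute precision `d` is inflated by the disease prevalence (for
#' sensitivity) or by `1 - prevalence` taken as the relevant fraction (the
#' caller passes the fraction of recruits contributing to the metric as
#' `prevalence`). The result is truncated towards zero, matching the
#' convention that 691.46 recruits are reported as 691.
#'
#' @param target_proportion Expected test performance (sensitivity or
#'   specificity), in (0, 1).
#' @param precision Absolute half-width of the confidence interval, in (0, 1).
#' @param prevalence Fraction of recruited participants contributing to the
#'   metric, in (0, 1].
#' @param alpha Significance level, default `0.05` (95% interval).
#' @return Required number of recruited participants (integer).
#' @examples
#' buderer_sample_size(0.90, 0.10, prevalence = 0.05)  # 691
#' @export
buderer_sample_size <- function(target_proportion, precision, prevalence,
                                alpha = 0.05) {
  p <- target_proportion
  d <- precision
  if (!is.finite(prevalence) || prevalence <= 0 || prevalence > 1) {
    stop("`prevalence` must be in (0, 1]", call. = FALSE)
  }
  stopifnot(p > 0, p < 1, d > 0, d < 1, alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  as.integer(floor(z^2 * p * (1 - p) / d^2 / prevalence))
}

#' Assemble a diagnostic accuracy report
#'
#' Joins per-patient predictions to the cohort's final diagnoses and
#' produces, for each reference-standard stratum, confusion counts,
#' sensitivity and specificity with exact Clopper-Pearson intervals and
#' the patient-level AUC, together with a stage-stratified sensitivity
#' breakdown and the patient-flow (exclusion) accounting.
#'
#' @param predictions Tibble from [predict_patients()] (columns
#'   `patient_id`, `probability`, `label`).
#' @param patients Patient table with `patient_id`, `diagnosis`,
#'   `uicc_stage` (exclusions already applied).
#' @param strata Named list of patient-id vectors, as from
#'   [stratify_by_reference()]; default one stratum `all` containing every
#'   patient.
#' @param level Confidence level for the intervals, default `0.95`.
#' @param exclusions Optional `exclusion_report` to embed for patient-flow
#'   accounting.
#' @return Object of class `dx_report`.
#' @export
build_report <- function(predictions, patients, strata = NULL, level = 0.95,
                         exclusions = NULL) {
  stopifnot(all(c("patient_id", "probability", "label") %in% names(predictions)))
  missing_ids <- setdiff(predictions$patient_id, patients$patient_id)
  if (length(missing_ids) > 0) {
    stop("predictions refer to patients absent from the cohort: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(strata)) strata <- list(all = patients$patient_id)

  joined <- dplyr::inner_join(predictions, patients, by = "patient_id")
  joined$truth_crc <- joined$diagnosis == "crc"

  eval_stratum <- function(ids) {
    d <- joined[joined$patient_id %in% ids, , drop = FALSE]
    conf <- confusion_counts(
      tp = sum(d$truth_crc & d$label == "crc"),
      fp = sum(!d$truth_crc & d$label == "crc"),
      tn = sum(!d$truth_crc & d$label != "crc"),
      fn = sum(d$truth_crc & d$label != "crc")
    )
    metrics <- sens_spec(conf, level)
    auc <- if (sum(d$truth_crc) > 0 && sum(!d$truth_crc) > 0) {
      roc_auc(d$probability, d$truth_crc)
    } else NA_real_
    list(n = nrow(d), confusion = conf, sensitivity = metrics$sensitivity,
         specificity = metrics$specificity, auc = auc)
  }

  truth <- tibble::tibble(patient_id = joined$patient_id,
                          is_crc = joined$truth_crc,
                          stage = joined$uicc_stage)
  structure(list(
    strata = lapply(strata, eval_stratum),
    stage_breakdown = if (any(truth$is_crc)) stage_sensitivity(predictions, truth) else NULL,
    level = level,
    exclusions = exclusions,
    n_patients = nrow(patients)
  ), class = "dx_report")
}

format_pct <- function(p, digits = 1) {
  if (is.null(p) || !length(p) || is.na(p)) return("NA")
  sprintf(paste0("%.", digits, "f%%"), round_half_up(100 * p, digits))
}

# half-up decimal rounding (base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5 + 1e-9 * sign(x)) / scale
}

#' @export
print.dx_report <- function(x, ...) {
  cat("diagnostic accuracy report (", round(100 * x$level), "% exact CIs)\n\n", sep = "")
  for (nm in names(x$strata)) {
    s <- x$strata[[nm]]
    cat(sprintf("%s (n = %d):\n", nm, s$n))
    cat(sprintf("  sensitivity %s (%s to %s)\n",
                format_pct(s$sensitivity$estimate),
                format_pct(s$sensitivity$ci_low), format_pct(s$sensitivity$ci_high)))
    cat(sprintf("  specificity %s (%s to %s)\n",
                format_pct(s$specificity$estimate),
                format_pct(s$specificity$ci_low), format_pct(s$specificity$ci_high)))
    cat(sprintf("  AUC %.3f\n", s$auc))
  }
  if (!is.null(x$stage_breakdown)) {
    cat("\n")
    print(x$stage_breakdown)
  }
  invisible(x)
}
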