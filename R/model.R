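#' Build a feature matrix from processed spectra
#'
#' One row per spectrum, one column per grid wavenumber; the outcome is
#' the per-patient CRC ground truth. Rows stay linked to patients so
#' cross-validation can split by patient, never by spectrum.
#'
#' @param processed A `processed_set` from [run_preprocessing()].
#' @param truth Tibble with `patient_id` and `is_crc` covering every
#'   patient in the set.
#' @return Object of class `feature_matrix`: `x` (matrix), `y` (logical
#'   per spectrum), `patient_id` (per spectrum), `grid`.
#' @export
feature_matrix <- function(processed, truth) {
  stopifnot(inherits(processed, "processed_set"))
  m <- match(processed$meta$patient_id, truth$patient_id)
  if (anyNA(m)) {
    stop("ground truth missing for patients: ",
         paste(unique(processed$meta$patient_id[is.na(m)]), collapse = ", "),
         call. = FALSE)
  }
  x <- processed$values
  colnames(x) <- paste0("wn_", format(processed$grid, trim = TRUE))
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  structure(list(x = x, y = truth$is_crc[m],
                 patient_id = processed$meta$patient_id,
                 grid = processed$grid),
            class = "feature_matrix")
}

default_hyperparams <- function(p) {
  list(num_trees = 500, mtry = max(1L, floor(sqrt(p))), min_node_size = 1L)
}

#' Train a random-forest spectral classifier
#'
#' Fits a probability random forest (500 trees, sqrt(p) candidate
#' features per split, unlimited depth by default) on per-spectrum
#' features. The artifact records the hyperparameters, the seed and the
#' training grid, so predictions can refuse mismatched grids.
#'
#' @param features A [feature_matrix()]; both classes must be present.
#' @param hyperparams Optional list overriding `num_trees`, `mtry`,
#'   `min_node_size`.
#' @param seed Integer seed; the same data and seed give identical
#'   per-spectrum probabilities.
#' @return Object of class `rf_artifact`.
#' @export
train_forest <- function(features, hyperparams = NULL, seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"))
  if (length(unique(features$y)) < 2) {
    stop("training set contains a single class", call. = FALSE)
  }
  hp <- utils::modifyList(default_hyperparams(ncol(features$x)),
                          hyperparams %||% list())
  df <- as.data.frame(features$x)
  names(df) <- paste0("wn_", format(features$grid, trim = TRUE))
  df$.class <- factor(ifelse(features$y, "crc", "non_cancer"),
                      levels = c("non_cancer", "crc"))
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = hp$num_trees, mtry = hp$mtry, min.node.size = hp$min_node_size,
    probability = TRUE, seed = seed, num.threads = 1,
    verbose = FALSE
  )
  structure(list(model = fit, hyperparams = hp, seed = as.integer(seed),
                 grid = features$grid),
            class = "rf_artifact")
}

#' @export
print.rf_artifact <- function(x, ...) {
  cat("random-forest artifact:", x$hyperparams$num_trees, "trees, mtry",
      x$hyperparams$mtry, ",", length(x$grid), "grid features, seed", x$seed, "\n")
  invisible(x)
}

predict_spectrum_probs <- function(artifact, processed) {
  if (length(artifact$grid) != length(processed$grid) ||
      any(abs(artifact$grid - processed$grid) > 1e-9)) {
    stop(sprintf(
      "grid mismatch: model trained on %d points (%.1f-%.1f cm^-1), input has %d (%.1f-%.1f)",
      length(artifact$grid), min(artifact$grid), max(artifact$grid),
      length(processed$grid), min(processed$grid), max(processed$grid)),
      call. = FALSE)
  }
  df <- as.data.frame(processed$values)
  names(df) <- paste0("wn_", format(processed$grid, trim = TRUE))
  pred <- stats::predict(artifact$model, data = df, num.threads = 1)
  as.numeric(pred$predictions[, "crc"])
}

#' Per-patient cancer probability and classification
#'
#' Predicts a cancer probability for every spectrum, averages the
#' probabilities of all spectra belonging to each patient (arithmetic
#' mean), and classifies the patient as `"crc"` when the aggregated
#' probability is at least 0.5, `"non_cancer"` otherwise. The boundary
#' value 0.5 classifies as `"crc"`. The function takes no diagnosis
#' input: evaluation against the reference standard happens only
#' downstream, so prediction is structurally blinded.
#'
#' @param artifact An `rf_artifact` from [train_forest()].
#' @param processed A `processed_set` on the model's grid.
#' @return Tibble with one row per distinct patient: `patient_id`,
#'   `probability`, `n_spectra`, `label`.
#' @export
predict_patients <- function(artifact, processed) {
  stopifnot(inherits(artifact, "rf_artifact"), inherits(processed, "processed_set"))
  probs <- predict_spectrum_probs(artifact, processed)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(patient_id = processed$meta$patient_id,
                                   prob = probs), patient_id),
    probability = mean(prob), n_spectra = dplyr::n(), .groups = "drop"
  )
  agg$label <- ifelse(agg$probability >= 0.5, "crc", "non_cancer")
  agg
}

#' Aggregate per-spectrum probabilities to patient level
#'
#' The probability-aggregation rule on its own: arithmetic mean of a
#' patient's per-spectrum probabilities, threshold at 0.5 with the
#' boundary classified as `"crc"`.
#'
#' @param probabilities Numeric vector of per-spectrum cancer
#'   probabilities for one patient.
#' @return List with `probability` and `label`.
#' @export
aggregate_patient <- function(probabilities) {
  stopifnot(length(probabilities) >= 1, all(is.finite(probabilities)),
            all(probabilities >= 0), all(probabilities <= 1))
  p <- mean(probabilities)
  list(probability = p, label = if (p >= 0.5) "crc" else "non_cancer")
}

# patients dealt round-robin into k folds, stratified by class
make_patient_folds <- function(patient_ids, is_crc, k) {
  folds <- integer(length(patient_ids))
  for (cls in c(TRUE, FALSE)) {
    sel <- which(is_crc == cls)
    if (length(sel) > 0) {
      sel <- sel[sample.int(length(sel))]
      folds[sel] <- rep_len(seq_len(k), length(sel))
    }
  }
  folds
}

#' Repeated patient-grouped k-fold cross-validation
#'
#' Splits *patients* (never spectra) into k folds, stratified by class,
#' so all replicate spectra of a patient share a fold and no replicate
#' correlation leaks between training and test. Each fold's model is
#' evaluated after per-patient aggregation: sensitivity and specificity
#' at the 0.5 rule and the patient-level AUC. The "typical fold" is the
#' fold whose AUC is the median across all folds and repeats.
#'
#' @param features A [feature_matrix()].
#' @param k Number of folds, default `5`; at least `k` patients per class
#'   are required.
#' @param repeats Number of repetitions, default `5`.
#' @param hyperparams Passed to [train_forest()].
#' @param seed Integer seed controlling fold assignment and forests.
#' @return Object of class `cv_result`: `folds` tibble (repeat, fold,
#'   sensitivity, specificity, auc, n_test_patients), `summary` (mean and
#'   SD per metric), `typical_fold` (row of `folds` with the median AUC),
#'   and `patient_scores` (held-out per-patient probabilities, averaged
#'   over repeats).
#' @export
cross_validate <- function(features, k = 5, repeats = 5, hyperparams = NULL,
                           seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"))
  pt <- tibble::tibble(patient_id = features$patient_id, y = features$y)
  pt <- dplyr::distinct(pt)
  if (anyDuplicated(pt$patient_id)) {
    stop("inconsistent class labels within a patient", call. = FALSE)
  }
  n_case <- sum(pt$y)
  n_ctrl <- sum(!pt$y)
  if (min(n_case, n_ctrl) < k) {
    stop(sprintf("need at least k = %d patients per class (have %d cases, %d controls)",
                 k, n_case, n_ctrl), call. = FALSE)
  }
  pt <- pt[order(pt$patient_id), , drop = FALSE]   # seed-stable ordering

  rows <- list()
  score_sum <- stats::setNames(numeric(nrow(pt)), pt$patient_id)
  score_n <- stats::setNames(integer(nrow(pt)), pt$patient_id)
  withr::with_seed(seed, {
    for (r in seq_len(repeats)) {
      folds <- make_patient_folds(pt$patient_id, pt$y, k)
      for (f in seq_len(k)) {
        test_pat <- pt$patient_id[folds == f]
        tr <- !(features$patient_id %in% test_pat)
        fit <- train_forest(
          structure(list(x = features$x[tr, , drop = FALSE], y = features$y[tr],
                         patient_id = features$patient_id[tr], grid = features$grid),
                    class = "feature_matrix"),
          hyperparams = hyperparams,
          seed = sample.int(.Machine$integer.max, 1)
        )
        te_set <- structure(list(grid = features$grid,
                                 values = features$x[!tr, , drop = FALSE],
                                 meta = tibble::tibble(
                                   patient_id = features$patient_id[!tr],
                                   replicate_id = NA_character_)),
                            class = "processed_set")
        preds <- predict_patients(fit, te_set)
        truth <- pt$y[match(preds$patient_id, pt$patient_id)]
        conf <- confusion_counts(
          tp = sum(truth & preds$label == "crc"),
          fp = sum(!truth & preds$label == "crc"),
          tn = sum(!truth & preds$label != "crc"),
          fn = sum(truth & preds$label != "crc"))
        rows[[length(rows) + 1]] <- tibble::tibble(
          repeat_idx = r, fold = f,
          sensitivity = conf$tp / (conf$tp + conf$fn),
          specificity = conf$tn / (conf$tn + conf$fp),
          auc = roc_auc(preds$probability, truth),
          n_test_patients = nrow(preds))
        score_sum[preds$patient_id] <- score_sum[preds$patient_id] + preds$probability
        score_n[preds$patient_id] <- score_n[preds$patient_id] + 1L
      }
    }
  })
  folds_tbl <- dplyr::bind_rows(rows)
  summ <- tibble::tibble(
    metric = c("sensitivity", "specificity", "auc"),
    mean = c(mean(folds_tbl$sensitivity), mean(folds_tbl$specificity),
             mean(folds_tbl$auc)),
    sd = c(stats::sd(folds_tbl$sensitivity), stats::sd(folds_tbl$specificity),
           stats::sd(folds_tbl$auc))
  )
  typical <- folds_tbl[which.min(abs(folds_tbl$auc - stats::median(folds_tbl$auc))), ]
  structure(list(folds = folds_tbl, summary = summ, typical_fold = typical,
                 patient_scores = tibble::tibble(
                   patient_id = pt$patient_id, is_crc = pt$y,
                   probability = score_sum / pmax(score_n, 1L)),
                 k = k, repeats = repeats, seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d x %d-fold patient-grouped cross-validation\n", x$repeats, x$k))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-11s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  cat(sprintf("  typical fold AUC %.3f (repeat %d, fold %d)\n",
              x$typical_fold$auc, x$typical_fold$repeat_idx, x$typical_fold$fold))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
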