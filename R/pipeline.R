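#' Study configuration for an end-to-end run
#'
#' Describes a complete two-cohort study: a retrospective source cohort
#' from which an age/sex propensity-matched case-control training set is
#' built, and a prospective symptomatic cohort on which the trained
#' model is blindly evaluated after the exclusion rules. Each cohort
#' comes either from a fixture directory on disk or from a simulation
#' config — exactly one of the two.
#'
#' @param train_sim,validation_sim [sim_config()]s for the two cohorts
#'   (ignored when the corresponding `*_path` is given). The defaults
#'   emulate the study conditions: a retrospective pool yielding a
#'   150:150 matched training set, and a 532-patient prospective cohort
#'   at 29/532 prevalence.
#' @param train_path,validation_path Optional fixture directories readable
#'   by [read_cohort()]. Ground truth for training is taken from the
#'   cohort table's `diagnosis` column.
#' @param preprocess A [preprocess_config()].
#' @param hyperparams Forest hyperparameters, see [train_forest()].
#' @param cv_k,cv_repeats Cross-validation shape on the training set;
#'   `cv_repeats = 0` skips CV.
#' @param level Confidence level for the report intervals.
#' @param seed Single top-level seed; fanned out deterministically to the
#'   simulation, CV and training stages.
#' @return Object of class `study_config`.
#' @export
study_config <- function(train_sim = sim_config(n_patients = 600, prevalence = 0.25,
                                                seed = 101L),
                         validation_sim = sim_config(seed = 202L),
                         train_path = NULL, validation_path = NULL,
                         preprocess = preprocess_config(),
                         hyperparams = NULL,
                         cv_k = 5, cv_repeats = 5,
                         level = 0.95, seed = 1L) {
  if (!is.null(train_path) && !is.null(train_sim) && !missing(train_sim)) {
    stop("give either `train_path` or `train_sim`, not both", call. = FALSE)
  }
  if (!is.null(validation_path) && !is.null(validation_sim) && !missing(validation_sim)) {
    stop("give either `validation_path` or `validation_sim`, not both", call. = FALSE)
  }
  structure(list(train_sim = train_sim, validation_sim = validation_sim,
                 train_path = train_path, validation_path = validation_path,
                 preprocess = preprocess, hyperparams = hyperparams,
                 cv_k = cv_k, cv_repeats = cv_repeats, level = level,
                 seed = as.integer(seed)),
            class = "study_config")
}

# deterministic fan-out of the top-level seed to stage seeds
stage_seeds <- function(seed) {
  base <- (as.integer(seed) %% 1000003L)
  list(train_sim = base * 7L + 1L, validation_sim = base * 7L + 2L,
       cv = base * 7L + 3L, final_fit = base * 7L + 4L)
}

load_stage_cohort <- function(path, sim, seed_override) {
  if (!is.null(path)) {
    bundle <- read_cohort(path)
    truth <- tibble::tibble(patient_id = bundle$patients$patient_id,
                            is_crc = bundle$patients$diagnosis == "crc",
                            stage = bundle$patients$uicc_stage,
                            reference_test = bundle$patients$reference_test)
    list(bundle = bundle, truth = truth)
  } else {
    sim$seed <- as.integer(seed_override)
    cohort <- simulate_cohort(sim)
    list(bundle = as_cohort_bundle(cohort), truth = cohort$truth)
  }
}

#' Run a complete simulated (or file-based) triage study
#'
#' Stages, in order: build the training cohort (propensity match cases
#' to controls 1:1 on age and sex), preprocess its spectra, optionally
#' cross-validate, train the final forest; then load the prospective
#' cohort, apply the exclusion rules, preprocess, predict per patient
#' blinded to diagnosis, and evaluate per reference-standard stratum
#' with exact intervals. All artifacts (resolved config, predictions,
#' report in JSON and markdown, line-delimited JSON log) are written to
#' `output_dir`.
#'
#' @param config A [study_config()].
#' @param output_dir Directory for run artifacts; created if needed.
#' @return Object of class `study_result`: `report` (a `dx_report`),
#'   `cv` (a `cv_result` or `NULL`), `match` (the `match_result`),
#'   `predictions`, `exclusions`, `log` (list of stage records).
#' @export
run_study <- function(config, output_dir = tempfile("ramantriage_run_")) {
  stopifnot(inherits(config, "study_config"))
  seeds <- stage_seeds(config$seed)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  note <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    log[[length(log) + 1]] <<- rec
    rec
  }

  # -- training cohort: match, preprocess, fit -------------------------
  tr <- load_stage_cohort(config$train_path, config$train_sim, seeds$train_sim)
  cases <- tr$bundle$patients[tr$bundle$patients$diagnosis == "crc", ]
  controls <- tr$bundle$patients[tr$bundle$patients$diagnosis == "non_crc", ]
  match <- propensity_match(cases, controls)
  matched_ids <- c(match$pairs$case_id, match$pairs$control_id)
  note("match", cases = nrow(cases), controls = nrow(controls),
       pairs = nrow(match$pairs))

  train_spectra <- Filter(function(s) s$patient_id %in% matched_ids,
                          tr$bundle$spectra)
  train_proc <- run_preprocessing(train_spectra, config$preprocess)
  note("preprocess_train", spectra = nrow(train_proc$values))
  train_feat <- feature_matrix(train_proc, tr$truth)

  cv <- NULL
  if (config$cv_repeats > 0) {
    cv <- cross_validate(train_feat, k = config$cv_k, repeats = config$cv_repeats,
                         hyperparams = config$hyperparams, seed = seeds$cv)
    note("cross_validate", mean_auc = cv$summary$mean[cv$summary$metric == "auc"],
         typical_fold_auc = cv$typical_fold$auc)
  }
  artifact <- train_forest(train_feat, hyperparams = config$hyperparams,
                           seed = seeds$final_fit)
  note("train", patients = length(unique(train_feat$patient_id)),
       spectra = nrow(train_feat$x))

  # -- prospective cohort: exclude, preprocess, blind predict ----------
  va <- load_stage_cohort(config$validation_path, config$validation_sim,
                          seeds$validation_sim)
  excl <- apply_exclusions(va$bundle$patients)
  note("exclusions", input = excl$report$input, retained = excl$report$retained)
  keep_ids <- excl$retained$patient_id
  va_spectra <- Filter(function(s) s$patient_id %in% keep_ids, va$bundle$spectra)
  va_proc <- run_preprocessing(va_spectra, config$preprocess)
  note("preprocess_validation", spectra = nrow(va_proc$values))

  predictions <- predict_patients(artifact, va_proc)   # no diagnosis in scope
  note("predict", patients = nrow(predictions))

  strata <- stratify_by_reference(excl$retained)
  report <- build_report(predictions, excl$retained, strata = strata,
                         level = config$level, exclusions = excl$report)
  note("evaluate", strata = length(strata),
       n = vapply(report$strata, function(s) s$n, numeric(1)))

  # -- artifacts -------------------------------------------------------
  resolved <- unclass(config)
  resolved$stage_seeds <- seeds
  resolved$train_sim <- if (is.null(config$train_sim)) NULL else unclass(config$train_sim)
  resolved$validation_sim <- if (is.null(config$validation_sim)) NULL else
    unclass(config$validation_sim)
  resolved$train_sim$peaks <- as.data.frame(resolved$train_sim$peaks)
  resolved$validation_sim$peaks <- as.data.frame(resolved$validation_sim$peaks)
  resolved$preprocess <- unclass(config$preprocess)
  jsonlite::write_json(resolved, file.path(output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  readr::write_csv(predictions, file.path(output_dir, "predictions.csv"))
  write_report(report, file.path(output_dir, "report.json"), "json")
  write_report(report, file.path(output_dir, "report.md"), "markdown")
  writeLines(vapply(log, function(rec) jsonlite::toJSON(rec, auto_unbox = TRUE,
                                                        digits = NA),
                    character(1)),
             file.path(output_dir, "log.jsonl"))

  structure(list(report = report, cv = cv, match = match,
                 predictions = predictions, exclusions = excl$report,
                 log = log, output_dir = output_dir),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("study run complete; artifacts in", x$output_dir, "\n\n")
  if (!is.null(x$cv)) { print(x$cv); cat("\n") }
  print(x$report)
  invisible(x)
}
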