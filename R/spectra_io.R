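#' Construct a raw spectrum
#'
#' @param patient_id,replicate_id Identifiers (coerced to character).
#' @param wavenumber Strictly increasing numeric axis in cm^-1.
#' @param intensity Finite numeric intensities, same length as the axis.
#' @return Object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(patient_id, replicate_id, wavenumber, intensity) {
  patient_id <- as.character(patient_id)
  replicate_id <- as.character(replicate_id)
  if (length(wavenumber) != length(intensity)) {
    stop("`wavenumber` and `intensity` must have equal length", call. = FALSE)
  }
  if (any(diff(wavenumber) <= 0)) {
    stop("`wavenumber` must be strictly increasing (spectrum ",
         patient_id, "/", replicate_id, ")", call. = FALSE)
  }
  if (any(!is.finite(intensity))) {
    stop("`intensity` must be finite (spectrum ",
         patient_id, "/", replicate_id, ")", call. = FALSE)
  }
  structure(list(patient_id = patient_id, replicate_id = replicate_id,
                 wavenumber = as.numeric(wavenumber),
                 intensity = as.numeric(intensity)),
            class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("raw spectrum %s/%s: %d points, %.1f-%.1f cm^-1\n",
              x$patient_id, x$replicate_id, length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

patient_enum_levels <- list(
  sex = c("M", "F"),
  reference_test = c("colonoscopy", "ct_colonography", "flexible_sigmoidoscopy", "none"),
  diagnosis = c("crc", "non_crc", "other_cancer", "unknown"),
  uicc_stage = c("I", "II", "III", "IV", "none")
)

validate_patients <- function(patients) {
  required <- c("patient_id", "age", "sex", "reference_test", "diagnosis", "uicc_stage")
  missing_cols <- setdiff(required, names(patients))
  if (length(missing_cols) > 0) {
    stop("cohort table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in cohort table: ",
         paste(unique(patients$patient_id[duplicated(patients$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  for (col in names(patient_enum_levels)) {
    bad <- which(!patients[[col]] %in% patient_enum_levels[[col]])
    if (length(bad) > 0) {
      stop(sprintf("unknown %s value '%s' in cohort row %d", col,
                   patients[[col]][bad[1]], bad[1]), call. = FALSE)
    }
  }
  staged_non_crc <- patients$uicc_stage != "none" & patients$diagnosis != "crc"
  if (any(staged_non_crc)) {
    stop("uicc_stage must be 'none' unless diagnosis is 'crc' (patients: ",
         paste(patients$patient_id[staged_non_crc], collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(patients)
}

#' Read a cohort fixture directory (or explicit files) into a bundle
#'
#' Reads the long-format spectra CSV (`wavenumber_cm1`, `intensity`,
#' `patient_id`, `replicate_id`) and the cohort CSV, validates both
#' (strictly increasing axes, known enum values, no duplicate
#' patient/replicate pairs, no orphan spectra) and returns the linked
#' bundle. A load report (counts plus validation warnings) is attached.
#'
#' @param path Directory containing `spectra.csv` and `cohort.csv`, or a
#'   named list `list(spectra = ..., cohort = ...)` of file paths. The
#'   spectra entry may be a vector of per-patient files; all are read.
#' @return Object of class `cohort_bundle`: `patients`, `spectra`,
#'   `load_report`.
#' @export
read_cohort <- function(path) {
  if (is.character(path) && length(path) == 1 && dir.exists(path)) {
    files <- list(spectra = file.path(path, "spectra.csv"),
                  cohort = file.path(path, "cohort.csv"))
  } else if (is.list(path) && all(c("spectra", "cohort") %in% names(path))) {
    files <- path
  } else {
    stop("`path` must be a fixture directory or list(spectra=, cohort=)",
         call. = FALSE)
  }
  if (!file.exists(files$cohort)) {
    stop("cohort file not found: ", files$cohort, call. = FALSE)
  }
  patients <- readr::read_csv(files$cohort, show_col_types = FALSE,
                              progress = FALSE)
  patients <- tibble::as_tibble(patients)
  patients$patient_id <- as.character(patients$patient_id)
  validate_patients(patients)

  warnings <- character(0)
  spectra_files <- files$spectra[file.exists(files$spectra)]
  if (length(spectra_files) < length(files$spectra)) {
    warnings <- c(warnings, paste("missing spectra files:",
                                  paste(setdiff(files$spectra, spectra_files),
                                        collapse = ", ")))
  }
  spectra <- list()
  if (length(spectra_files) > 0) {
    long <- dplyr::bind_rows(lapply(spectra_files, readr::read_csv,
                                    show_col_types = FALSE, progress = FALSE))
    req <- c("wavenumber_cm1", "intensity", "patient_id", "replicate_id")
    if (!all(req %in% names(long))) {
      stop("spectra file must have columns ", paste(req, collapse = ", "),
           call. = FALSE)
    }
    long$patient_id <- as.character(long$patient_id)
    long$replicate_id <- as.character(long$replicate_id)
    orphans <- setdiff(unique(long$patient_id), patients$patient_id)
    if (length(orphans) > 0) {
      stop("spectra reference patient ids absent from the cohort table: ",
           paste(orphans, collapse = ", "), call. = FALSE)
    }
    key <- paste(long$patient_id, long$replicate_id, sep = "\r")
    groups <- split(seq_len(nrow(long)), factor(key, levels = unique(key)))
    spectra <- lapply(groups, function(ix) {
      raw_spectrum(long$patient_id[ix[1]], long$replicate_id[ix[1]],
                   long$wavenumber_cm1[ix], long$intensity[ix])
    })
    names(spectra) <- NULL
  } else {
    warnings <- c(warnings, "no spectra read; bundle contains zero spectra")
  }
  if (length(spectra) == 0 && nrow(patients) > 0 &&
      !("no spectra read; bundle contains zero spectra" %in% warnings)) {
    warnings <- c(warnings, "no spectra read; bundle contains zero spectra")
  }
  report <- list(patients_read = nrow(patients), spectra_read = length(spectra),
                 warnings = warnings)
  if (length(warnings) > 0) {
    warning(paste(warnings, collapse = "; "), call. = FALSE)
  }
  structure(list(patients = patients, spectra = spectra, load_report = report),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort bundle:", nrow(x$patients), "patients,",
      length(x$spectra), "spectra\n")
  if (length(x$load_report$warnings) > 0) {
    cat("warnings:", paste(x$load_report$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Convert a simulated cohort into a bundle
#'
#' @param cohort A `raman_cohort`.
#' @return A `cohort_bundle` sharing the cohort's patients and spectra.
#' @export
as_cohort_bundle <- function(cohort) {
  stopifnot(inherits(cohort, "raman_cohort"))
  structure(list(patients = cohort$patients, spectra = cohort$spectra,
                 load_report = list(patients_read = nrow(cohort$patients),
                                    spectra_read = length(cohort$spectra),
                                    warnings = character(0))),
            class = "cohort_bundle")
}

report_to_list <- function(report) {
  strata <- lapply(report$strata, function(s) {
    list(n = s$n, confusion = unclass(s$confusion),
         sensitivity = s$sensitivity, specificity = s$specificity, auc = s$auc)
  })
  sb <- report$stage_breakdown
  list(level = report$level, n_patients = report$n_patients,
       strata = strata,
       stage_breakdown = if (is.null(sb)) NULL else list(
         per_stage = as.data.frame(sb$per_stage),
         pooled_early = sb$pooled_early, pooled_late = sb$pooled_late),
       exclusions = if (is.null(report$exclusions)) NULL else unclass(report$exclusions))
}

list_to_report <- function(x) {
  strata <- lapply(x$strata, function(s) {
    conf <- do.call(confusion_counts, as.list(unlist(s$confusion)))
    list(n = s$n, confusion = conf, sensitivity = s$sensitivity,
         specificity = s$specificity, auc = s$auc)
  })
  sb <- NULL
  if (!is.null(x$stage_breakdown)) {
    per_stage <- tibble::as_tibble(x$stage_breakdown$per_stage)
    per_stage$stage <- factor(per_stage$stage, levels = c("I", "II", "III", "IV"))
    sb <- structure(list(per_stage = per_stage,
                         pooled_early = x$stage_breakdown$pooled_early,
                         pooled_late = x$stage_breakdown$pooled_late),
                    class = "stage_breakdown")
  }
  excl <- NULL
  if (!is.null(x$exclusions)) {
    excl <- structure(x$exclusions, class = "exclusion_report")
  }
  structure(list(strata = strata, stage_breakdown = sb, level = x$level,
                 exclusions = excl, n_patients = x$n_patients),
            class = "dx_report")
}

#' Write a diagnostic report to disk
#'
#' JSON output is lossless and round-trips through [read_report()]; CSV
#' holds one row per reference-standard stratum; markdown renders the
#' stratified sensitivity/specificity table and the stage table in the
#' layout of a diagnostic accuracy study table.
#'
#' @param report A `dx_report` from [build_report()].
#' @param path Output file path.
#' @param format `"json"`, `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv", "markdown")) {
  stopifnot(inherits(report, "dx_report"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  } else if (format == "csv") {
    rows <- dplyr::bind_rows(lapply(names(report$strata), function(nm) {
      s <- report$strata[[nm]]
      tibble::tibble(stratum = nm, n = s$n,
                     tp = s$confusion$tp, fp = s$confusion$fp,
                     tn = s$confusion$tn, fn = s$confusion$fn,
                     sensitivity = s$sensitivity$estimate,
                     sens_ci_low = s$sensitivity$ci_low,
                     sens_ci_high = s$sensitivity$ci_high,
                     specificity = s$specificity$estimate,
                     spec_ci_low = s$specificity$ci_low,
                     spec_ci_high = s$specificity$ci_high,
                     auc = s$auc)
    }))
    readr::write_csv(rows, path)
  } else {
    lines <- c("| Stratum | n | Sensitivity (95% CI) | Specificity (95% CI) | AUC |",
               "|---|---|---|---|---|")
    for (nm in names(report$strata)) {
      s <- report$strata[[nm]]
      lines <- c(lines, sprintf(
        "| %s | %d | %s (%s to %s) | %s (%s to %s) | %.2f |",
        nm, s$n,
        format_pct(s$sensitivity$estimate), format_pct(s$sensitivity$ci_low),
        format_pct(s$sensitivity$ci_high),
        format_pct(s$specificity$estimate), format_pct(s$specificity$ci_low),
        format_pct(s$specificity$ci_high), s$auc))
    }
    if (!is.null(report$stage_breakdown)) {
      ps <- report$stage_breakdown$per_stage
      lines <- c(lines, "", "| Stage | Detected | n | Sensitivity |", "|---|---|---|---|")
      for (i in seq_len(nrow(ps))) {
        lines <- c(lines, sprintf("| %s | %d | %d | %s |", ps$stage[i],
                                  ps$detected[i], ps$n[i], format_pct(ps$sensitivity[i])))
      }
      pe <- report$stage_breakdown$pooled_early
      pl <- report$stage_breakdown$pooled_late
      lines <- c(lines,
                 sprintf("| I-II (pooled) | %d | %d | %s |", pe$detected, pe$n,
                         format_pct(pe$sensitivity)),
                 sprintf("| III-IV (pooled) | %d | %d | %s |", pl$detected, pl$n,
                         format_pct(pl$sensitivity)))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a JSON diagnostic report back into a `dx_report`
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return A `dx_report`.
#' @export
read_report <- function(path) {
  list_to_report(jsonlite::read_json(path, simplifyVector = TRUE,
                                     simplifyDataFrame = TRUE))
}
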