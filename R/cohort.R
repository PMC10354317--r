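#' Propensity-score match cases to controls on age and sex
#'
#' Fits a logistic regression of case membership on the covariates,
#' then greedily pairs cases 1:1 without replacement with controls drawn
#' from those within a caliper of `caliper_sd` standard deviations of
#' the pooled propensity logit. Categorical covariates (such as sex) are
#' matched exactly, and pairs are formed best-first: at every step the
#' eligible case-control pair with the smallest standardised covariate
#' (Mahalanobis) distance is matched, with ties broken by patient id, so
#' the procedure is deterministic without a seed. Best-first order
#' avoids the one-directional drift a fixed case sweep produces when
#' stratum sizes differ, and the exact-category rule excludes
#' cross-category pairs whose score agreement would force a compensating
#' one-signed age difference; together they keep balance tight even when
#' the groups are already exchangeable and the fitted score is mostly
#' noise.
#'
#' @param cases,controls Patient tibbles (as in a `cohort_bundle`) with
#'   the covariate columns present; both non-empty.
#' @param covariates Character vector of covariate columns, default
#'   `c("age", "sex")`.
#' @param caliper_sd Caliper width in SDs of the logit score, default
#'   `0.2`; `Inf` disables the caliper.
#' @return Object of class `match_result`: `pairs` (tibble `case_id`,
#'   `control_id`, `distance`), `propensity` (per-patient scores),
#'   `balance` (per-covariate standardised mean differences before and
#'   after matching), `matched` (the matched patient table with a `group`
#'   column).
#' @export
propensity_match <- function(cases, controls, covariates = c("age", "sex"),
                             caliper_sd = 0.2) {
  if (nrow(cases) == 0 || nrow(controls) == 0) {
    stop("both `cases` and `controls` must be non-empty", call. = FALSE)
  }
  for (cv in covariates) {
    if (anyNA(cases[[cv]]) || anyNA(controls[[cv]])) {
      stop("covariate '", cv, "' has missing values", call. = FALSE)
    }
  }
  pool <- dplyr::bind_rows(
    dplyr::mutate(cases, .case = 1L),
    dplyr::mutate(controls, .case = 0L)
  )
  fml <- stats::as.formula(paste(".case ~", paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, data = pool, family = stats::binomial()))
  ps <- stats::fitted(fit)
  if (any(ps > 1 - 1e-10) || any(ps < 1e-10)) {
    stop("complete covariate separation: propensity scores at the boundary; ",
         "consider matching with `caliper_sd = Inf` on a reduced model",
         call. = FALSE)
  }
  logit <- stats::qlogis(ps)
  pool$.ps <- ps
  pool$.logit <- logit
  caliper <- caliper_sd * stats::sd(logit)

  # standardised covariate coordinates for the within-caliper refinement,
  # plus an exact-match key over the categorical covariates
  z <- sapply(covariates, function(cv) {
    x <- pool[[cv]]
    if (!is.numeric(x)) x <- as.numeric(factor(x, levels = sort(unique(x))))
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  z <- matrix(z, nrow = nrow(pool))
  cat_cov <- covariates[!vapply(covariates, function(cv) is.numeric(pool[[cv]]),
                                logical(1))]
  exact_key <- if (length(cat_cov) > 0) {
    do.call(paste, c(pool[cat_cov], sep = "\r"))
  } else rep("", nrow(pool))

  case_rows <- which(pool$.case == 1L)
  ctrl_rows <- which(pool$.case == 0L)
  # eligible pair distances: caliper on the logit + exact categorical match
  d_logit <- abs(outer(pool$.logit[case_rows], pool$.logit[ctrl_rows], `-`))
  eligible <- d_logit <= caliper &
    outer(exact_key[case_rows], exact_key[ctrl_rows], `==`)
  zc <- z[case_rows, , drop = FALSE]
  zk <- z[ctrl_rows, , drop = FALSE]
  d_cov <- outer(rowSums(zc^2), rowSums(zk^2), `+`) - 2 * tcrossprod(zc, zk)
  d_cov[!eligible] <- Inf
  # deterministic tie-break: covariate distance, then case id, then control id
  case_o <- order(pool$patient_id[case_rows])
  ctrl_o <- order(pool$patient_id[ctrl_rows])
  d_cov <- d_cov[case_o, ctrl_o, drop = FALSE]
  d_logit <- d_logit[case_o, ctrl_o, drop = FALSE]
  case_ids <- pool$patient_id[case_rows][case_o]
  ctrl_ids <- pool$patient_id[ctrl_rows][ctrl_o]

  pairs <- vector("list", length(case_ids))
  np <- 0
  while (any(is.finite(d_cov))) {
    j <- which(d_cov == min(d_cov))[1]          # column-major: earliest ids win
    ci <- (j - 1) %% nrow(d_cov) + 1
    ki <- (j - 1) %/% nrow(d_cov) + 1
    np <- np + 1
    pairs[[np]] <- tibble::tibble(case_id = case_ids[ci],
                                  control_id = ctrl_ids[ki],
                                  distance = d_logit[ci, ki])
    d_cov[ci, ] <- Inf
    d_cov[, ki] <- Inf
  }
  pairs <- if (np > 0) dplyr::bind_rows(pairs[seq_len(np)]) else
    tibble::tibble(case_id = character(0), control_id = character(0),
                   distance = numeric(0))
  pairs <- pairs[order(pairs$case_id), , drop = FALSE]

  smd <- function(data, sel1, sel0, cv) {
    x <- data[[cv]]
    if (!is.numeric(x)) x <- as.numeric(factor(x, levels = sort(unique(x)))) - 1
    m1 <- mean(x[sel1]); m0 <- mean(x[sel0])
    s <- sqrt((stats::var(x[sel1]) + stats::var(x[sel0])) / 2)
    if (s == 0) return(0)
    (m1 - m0) / s
  }
  matched_ids <- c(pairs$case_id, pairs$control_id)
  matched <- pool[pool$patient_id %in% matched_ids, , drop = FALSE]
  balance <- tibble::tibble(
    covariate = covariates,
    smd_before = vapply(covariates, function(cv)
      smd(pool, pool$.case == 1L, pool$.case == 0L, cv), numeric(1)),
    smd_after = vapply(covariates, function(cv) {
      if (np == 0) return(NA_real_)
      smd(matched, matched$.case == 1L, matched$.case == 0L, cv)
    }, numeric(1))
  )
  matched$group <- ifelse(matched$.case == 1L, "case", "control")
  matched <- matched[, setdiff(names(matched), c(".case", ".ps", ".logit")), drop = FALSE]
  structure(list(pairs = pairs,
                 propensity = tibble::tibble(patient_id = pool$patient_id,
                                             score = ps, logit = logit),
                 balance = balance, matched = tibble::as_tibble(matched),
                 caliper = caliper),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("propensity match:", nrow(x$pairs), "pairs (caliper",
      format(x$caliper, digits = 3), "on the logit)\n")
  print(as.data.frame(x$balance))
  invisible(x)
}

#' Apply the prospective study's exclusion rules
#'
#' Removes, in order of precedence: patients investigated only by
#' flexible sigmoidoscopy; patients with no reference-standard test
#' (`reference_test == "none"`); patients with missing diagnosis
#' (`diagnosis == "unknown"`). The report partitions the input exactly.
#'
#' @param patients Patient tibble.
#' @return List with `retained` (tibble) and `report`
#'   (class `exclusion_report` with counts per reason).
#' @export
apply_exclusions <- function(patients) {
  reason <- rep("retained", nrow(patients))
  reason[patients$diagnosis == "unknown"] <- "missing_diagnosis"
  reason[patients$reference_test == "none"] <- "missing_reference"
  reason[patients$reference_test == "flexible_sigmoidoscopy"] <- "flexible_sigmoidoscopy"
  retained <- patients[reason == "retained", , drop = FALSE]
  report <- structure(list(
    flexible_sigmoidoscopy = sum(reason == "flexible_sigmoidoscopy"),
    missing_reference = sum(reason == "missing_reference"),
    missing_diagnosis = sum(reason == "missing_diagnosis"),
    retained = nrow(retained),
    input = nrow(patients)
  ), class = "exclusion_report")
  list(retained = tibble::as_tibble(retained), report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("patient flow:", x$input, "in ->", x$retained, "retained\n")
  cat("  excluded: flexible sigmoidoscopy", x$flexible_sigmoidoscopy,
      "| missing reference", x$missing_reference,
      "| missing diagnosis", x$missing_diagnosis, "\n")
  invisible(x)
}

#' Stratify retained patients by reference-standard investigation
#'
#' Returns the nested strata reported in diagnostic accuracy studies
#' where colonoscopy is the gold standard: the colonoscopy-only stratum
#' and the combined colonoscopy-plus-CT-colonography stratum (a superset
#' of the first).
#'
#' @param patients Retained patient tibble (exclusions already applied).
#' @return Named list of patient-id vectors `colonoscopy_only`,
#'   `colonoscopy_plus_ctc`.
#' @export
stratify_by_reference <- function(patients) {
  known <- c("colonoscopy", "ct_colonography")
  bad <- setdiff(unique(patients$reference_test), known)
  if (length(bad) > 0) {
    stop("unexpected reference test after exclusions: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(
    colonoscopy_only = patients$patient_id[patients$reference_test == "colonoscopy"],
    colonoscopy_plus_ctc = patients$patient_id[patients$reference_test %in% known]
  )
}
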