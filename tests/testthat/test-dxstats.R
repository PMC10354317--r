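test_that("Clopper-Pearson bounds match the binomial-tail bisection oracle", {
  for (n in c(1, 2, 5, 10, 23, 29, 30)) {
    for (x in unique(round(seq(0, n, length.out = 6)))) {
      got <- clopper_pearson(x, n)
      want <- cp_oracle_bisect(x, n)
      expect_equal(got[["low"]], want[["low"]], tolerance = 1e-6)
      expect_equal(got[["high"]], want[["high"]], tolerance = 1e-6)
    }
  }
})

test_that("Clopper-Pearson boundary and error behaviour", {
  expect_identical(clopper_pearson(0, 10)[["low"]], 0)
  expect_identical(clopper_pearson(10, 10)[["high"]], 1)
  expect_error(clopper_pearson(11, 10), "x")
  expect_error(clopper_pearson(1, 0), "n")
  expect_error(clopper_pearson(2, 5, level = 1.2), "level")
})

test_that("exact intervals are conservative: empirical coverage >= nominal", {
  # Monte-Carlo at n = 23, p = 0.9, 10,000 replicates, computed by weighting
  # the 24 possible outcomes by their empirical frequencies
  bounds <- t(vapply(0:23, function(x) clopper_pearson(x, 23), numeric(2)))
  withr::with_seed(42, {
    draws <- stats::rbinom(10000, 23, 0.9)
  })
  covered <- bounds[draws + 1, 1] <= 0.9 & 0.9 <= bounds[draws + 1, 2]
  expect_gte(mean(covered), 0.95)
})

test_that("sensitivity/specificity with CIs reproduce published-style counts", {
  conf <- confusion_counts(tp = 22, fp = 69, tn = 156, fn = 1)
  m <- sens_spec(conf)
  expect_equal(round(100 * m$sensitivity$estimate, 1), 95.7)
  expect_equal(round(100 * m$specificity$estimate, 1), 69.3)
  expect_equal(round(100 * m$sensitivity$ci_low, 1), 78.1)
  expect_equal(round(100 * m$sensitivity$ci_high, 1), 99.9)
  # sensitivity + false-negative rate is 1 by construction
  fnr <- conf$fn / (conf$tp + conf$fn)
  expect_equal(m$sensitivity$estimate + fnr, 1)
})

test_that("zero-denominator metrics are flagged undefined, not silently 0", {
  m <- sens_spec(confusion_counts(tp = 0, fp = 3, tn = 7, fn = 0))
  expect_false(m$sensitivity$defined)
  expect_true(is.na(m$sensitivity$estimate))
  expect_true(m$specificity$defined)

  m2 <- sens_spec(confusion_counts(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_equal(m2$sensitivity$estimate, 0)
  expect_equal(m2$specificity$estimate, 1)
})

test_that("trapezoidal/midrank AUC equals exhaustive pairwise concordance", {
  withr::with_seed(7, {
    for (i in 1:50) {
      n <- sample(4:12, 1)
      labels <- c(TRUE, FALSE, stats::runif(n - 2) > 0.5)
      scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # many ties
      expect_identical(roc_auc(scores, labels), auc_bruteforce(scores, labels))
    }
  })
})

test_that("AUC handles separation, null and degenerate inputs", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  withr::with_seed(3, {
    scores <- stats::runif(200)
    labels <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  })
  a <- roc_auc(scores, labels)
  expect_gt(a, 0.4)
  expect_lt(a, 0.6)
  expect_error(roc_auc(c(0.1, 0.2), c(TRUE, TRUE)), "both classes")
})

test_that("ROC curve trapezoid area equals the midrank AUC", {
  withr::with_seed(11, {
    scores <- round(stats::runif(40), 1)
    labels <- stats::runif(40) > 0.6
  })
  rc <- roc_curve(scores, labels)
  area <- sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
  expect_equal(area, roc_auc(scores, labels), tolerance = 1e-12)
})

test_that("stage sensitivities pool by summed counts, not averaged percentages", {
  truth <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:14),
    is_crc = TRUE,
    stage = c(rep("I", 4), rep("II", 10))
  )
  # detected: 2/4 stage I, 9/10 stage II
  detected <- c(TRUE, TRUE, FALSE, FALSE, rep(TRUE, 9), FALSE)
  preds <- tibble::tibble(patient_id = truth$patient_id,
                          label = ifelse(detected, "crc", "non_cancer"))
  sb <- stage_sensitivity(preds, truth)
  expect_equal(sb$pooled_early$detected, 11)
  expect_equal(sb$pooled_early$n, 14)
  expect_equal(round(100 * sb$pooled_early$sensitivity, 1), 78.6)
  # a percentage average would give (50 + 90) / 2 = 70, not 78.6
  expect_false(isTRUE(all.equal(sb$pooled_early$sensitivity, 0.7)))
})

test_that("late-stage pooling and degenerate stage breakdowns", {
  truth <- tibble::tibble(patient_id = sprintf("L%02d", 1:15), is_crc = TRUE,
                          stage = c(rep("III", 12), rep("IV", 3)))
  preds <- tibble::tibble(patient_id = truth$patient_id, label = "crc")
  sb <- stage_sensitivity(preds, truth)
  expect_equal(sb$pooled_late$sensitivity, 1)
  expect_equal(sb$pooled_late$n, 15)

  none <- tibble::tibble(patient_id = truth$patient_id, label = "non_cancer")
  sb0 <- stage_sensitivity(none, truth)
  expect_true(all(sb0$per_stage$sensitivity[sb0$per_stage$n > 0] == 0))

  bad <- truth
  bad$stage[1] <- "none"
  expect_error(stage_sensitivity(preds, bad), "stage")
})

test_that("prevalence-adjusted sample size reproduces the planning numbers", {
  expect_identical(buderer_sample_size(0.90, 0.10, prevalence = 0.05), 691L)
  expect_identical(buderer_sample_size(0.50, 0.50, prevalence = 1.0), 3L)
  # prevalence 1 reduces to the unadjusted single-proportion formula
  z <- qnorm(0.975)
  expect_identical(buderer_sample_size(0.8, 0.05, prevalence = 1),
                   as.integer(floor(z^2 * 0.8 * 0.2 / 0.05^2)))
  expect_error(buderer_sample_size(0.9, 0.1, prevalence = 0), "prevalence")
})

test_that("build_report assembles strata, rejects unknown patients", {
  patients <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:8),
    reference_test = rep(c("colonoscopy", "ct_colonography"), each = 4),
    diagnosis = c("crc", "crc", "non_crc", "non_crc",
                  "crc", "non_crc", "non_crc", "non_crc"),
    uicc_stage = c("II", "III", "none", "none", "I", "none", "none", "none")
  )
  preds <- tibble::tibble(patient_id = patients$patient_id,
                          probability = c(0.9, 0.8, 0.2, 0.6, 0.3, 0.1, 0.2, 0.4),
                          label = ifelse(c(0.9, 0.8, 0.2, 0.6, 0.3, 0.1, 0.2, 0.4) >= 0.5,
                                         "crc", "non_cancer"))
  rep_ <- build_report(preds, patients, strata = stratify_by_reference(patients))
  expect_named(rep_$strata, c("colonoscopy_only", "colonoscopy_plus_ctc"))
  expect_equal(rep_$strata$colonoscopy_only$n, 4)
  expect_equal(rep_$strata$colonoscopy_plus_ctc$n, 8)
  col <- rep_$strata$colonoscopy_only$confusion
  expect_equal(c(col$tp, col$fp, col$tn, col$fn), c(2, 1, 1, 0))

  bad <- preds
  bad$patient_id[1] <- "GHOST"
  expect_error(build_report(bad, patients), "absent")
})

test_that("all-correct predictions give unit sensitivity and specificity", {
  patients <- tibble::tibble(
    patient_id = sprintf("Q%02d", 1:6),
    reference_test = "colonoscopy",
    diagnosis = c("crc", "crc", rep("non_crc", 4)),
    uicc_stage = c("I", "IV", rep("none", 4))
  )
  preds <- tibble::tibble(patient_id = patients$patient_id,
                          probability = c(0.99, 0.8, 0.1, 0.2, 0.05, 0.3),
                          label = c("crc", "crc", rep("non_cancer", 4)))
  rep_ <- build_report(preds, patients)
  expect_equal(rep_$strata$all$sensitivity$estimate, 1)
  expect_equal(rep_$strata$all$specificity$estimate, 1)
  expect_equal(rep_$strata$all$auc, 1)
})

test_that("midrank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(13, {
    scores <- round(stats::runif(60), 2)
    labels <- stats::runif(60) > 0.5
  })
  independent <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                direction = "<")))
  expect_equal(roc_auc(scores, labels), independent, tolerance = 1e-12)
})
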