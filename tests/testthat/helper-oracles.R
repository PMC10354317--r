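# Independent oracles used to verify the analytic implementations.

# Exact binomial interval by bisection on the binomial tail sums:
# lower bound solves P(X >= x | p) = alpha/2, upper solves P(X <= x | p) = alpha/2.
cp_oracle_bisect <- function(x, n, level = 0.95, tol = 1e-9) {
  alpha <- 1 - level
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  low <- if (x == 0) 0 else
    bisect(function(p) (1 - stats::pbinom(x - 1, n, p)) - alpha / 2, 0, 1)
  high <- if (x == n) 1 else
    bisect(function(p) alpha / 2 - stats::pbinom(x, n, p), 0, 1)
  c(low = low, high = high)
}

# AUC as exhaustive pairwise concordance: P(score_case > score_control) + 1/2 ties.
auc_bruteforce <- function(scores, labels) {
  labels <- as.logical(labels)
  s1 <- scores[labels]
  s0 <- scores[!labels]
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(s1) * length(s0))
}

# small, fast simulated cohort for structural tests
tiny_sim_config <- function(seed = 1, n_patients = 6, ...) {
  sim_config(n_patients = n_patients, prevalence = 0.34, seed = seed, ...)
}

# minimal two-band configuration for patient-count-heavy tests where the
# spectral content is irrelevant
flat_sim_config <- function(seed = 1, n_patients = 100,
                            axis_range = c(600, 1400),
                            points_per_spectrum = 64,
                            peaks = tibble::tibble(
                              center = c(700, 1100), width = c(10, 10),
                              amplitude = c(1, 0.5), shape = "gaussian"),
                            effect_map = c("700" = 1.3, "1100" = 0.8),
                            replicates_per_patient = 1, ...) {
  sim_config(n_patients = n_patients, seed = seed, axis_range = axis_range,
             points_per_spectrum = points_per_spectrum, peaks = peaks,
             effect_map = effect_map,
             replicates_per_patient = replicates_per_patient, ...)
}
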