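# Shared fixture builders and independent oracles, all generated in code.

# Minimal hand-written cohort: 10 patients, 2 baseline variables.
make_tiny_cohort <- function() {
  df <- data.frame(
    patient_id = sprintf("T%02d", 1:10),
    arm = rep(c("active", "placebo"), 5),
    covid_confirmed = c(TRUE, TRUE, rep(FALSE, 8)),
    prior_rrt = c(FALSE, FALSE, TRUE, rep(FALSE, 7)),
    pre_aki_egfr = c(80, 75, 90, 60, 70, 85, 65, 95, 72, 88),
    death_day = c(NA, 12, NA, NA, 45, NA, NA, NA, NA, NA),
    rrt_through_day28 = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                          FALSE, FALSE, FALSE),
    rrt_at_day90 = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                     FALSE, FALSE),
    egfr_day90 = c(70, NA, 80, NA, NA, 30, 58, 90, 55, 85),
    lactate = c(1.1, 2.3, 4.5, 3.3, 2.2, 5.1, 1.9, 0.8, 2.7, 3.8),
    bicarbonate = c(22, 18, 15, 24, 20, 14, 25, 23, 19, 17),
    stringsAsFactors = FALSE
  )
  cohort_table(df)
}

# Gaussian blob matrix with known labels.
make_blobs <- function(n_per, centers, sd = 1, d = 2, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(n_per), function(i) {
    matrix(rnorm(n_per[i] * d, mean = centers[i], sd = sd), ncol = d)
  }))
  rownames(x) <- sprintf("B%03d", seq_len(nrow(x)))
  list(x = x, labels = rep(seq_along(n_per), n_per))
}

# Synthetic config matching the recovery world: 4 informative variables
# separated by `sep` SDs, plus noise variables, planted published incidences.
recovery_config <- function(seed, n = 570, sep = 1.75, n_noise = 2,
                            missing_rate = 0) {
  specs <- c(
    lapply(1:4, function(i) {
      list(name = sprintf("info_%d", i), mean = c(0, sep), sd = c(1, 1))
    }),
    lapply(seq_len(n_noise), function(i) {
      list(name = sprintf("noise_%d", i), mean = c(0, 0), sd = c(1, 1))
    })
  )
  synthetic_config(n_patients = n, variable_specs = specs,
                   missing_rate = missing_rate, seed = seed)
}

# Exact permutation log-rank p: enumerate all assignments of the pooled
# subjects to a group of size n_a, P(statistic >= observed).
perm_logrank_p <- function(outcomes_a, outcomes_b) {
  pooled <- rbind(outcomes_a, outcomes_b)
  n <- nrow(pooled)
  n_a <- nrow(outcomes_a)
  obs <- logrank_test(outcomes_a, outcomes_b)$statistic
  splits <- combn(n, n_a, simplify = FALSE)
  stats <- vapply(splits, function(ix) {
    tryCatch(
      logrank_test(pooled[ix, , drop = FALSE],
                   pooled[-ix, , drop = FALSE])$statistic,
      error = function(e) 0
    )
  }, numeric(1))
  mean(stats >= obs - 1e-9)
}

# Brute-force exhaustive k-medoid search: minimal total dissimilarity over
# all medoid subsets.
exhaustive_medoid_cost <- function(x, k) {
  D <- as.matrix(dist(x))
  n <- nrow(D)
  best <- Inf
  for (med in combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(D[, med, drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

make_outcomes <- function(time, event) {
  data.frame(patient_id = sprintf("O%03d", seq_along(time)), event = event,
             event_day = time, stringsAsFactors = FALSE)
}
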