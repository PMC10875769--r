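test_that("model enumeration covers the size/algorithm/k cross", {
  specs <- enumerate_models(c("a", "b", "c", "d"), size_range = c(2, 4))
  expect_length(specs, (6 + 4 + 1) * 2)

  one_alg <- enumerate_models(sprintf("v%02d", 1:15), size_range = c(2, 4),
                              algorithms = "kmeans")
  expect_length(one_alg, choose(15, 2) + choose(15, 3) + choose(15, 4))

  expect_error(enumerate_models(c("a", "b"), size_range = c(1, 1)),
               "size_range")
  expect_length(enumerate_models(c("a", "b"), size_range = c(1, 1),
                                 allow_single = TRUE), 2 * 2)
  expect_error(enumerate_models(character()), "empty")

  # deterministic order and the shrinking property
  s1 <- vapply(enumerate_models(c("b", "a", "c"), c(2, 3)), format, "")
  s2 <- vapply(enumerate_models(c("c", "a", "b"), c(2, 3)), format, "")
  expect_identical(s1, s2)
  small <- vapply(enumerate_models(letters[1:5], c(2, 3)), format, "")
  large <- vapply(enumerate_models(letters[1:5], c(2, 4)), format, "")
  expect_true(all(small %in% large))
})

make_eval_stub <- function(p, gap, nvars, gate_consensus = TRUE,
                           gate_efficacy = TRUE) {
  structure(list(spec = model_spec(sprintf("v%02d", seq_len(nvars)),
                                   "kmeans", 2),
                 gate_consensus = gate_consensus,
                 gate_efficacy = gate_efficacy,
                 p_best = p, incidence_gap = gap),
            class = "model_evaluation")
}

test_that("select_best applies the ranking and tie rules", {
  a <- make_eval_stub(0.01, 0.10, 3)
  b <- make_eval_stub(0.03, 0.20, 2)
  expect_identical(select_best(list(b, a)), a)

  # equal p: larger absolute incidence difference wins
  c1 <- make_eval_stub(0.02, 0.05, 2)
  c2 <- make_eval_stub(0.02, 0.14, 4)
  expect_identical(select_best(list(c1, c2)), c2)

  # equal p and gap: fewer variables wins
  d1 <- make_eval_stub(0.02, 0.10, 4)
  d2 <- make_eval_stub(0.02, 0.10, 2)
  expect_identical(select_best(list(d1, d2)), d2)

  # failing either gate disqualifies
  e1 <- make_eval_stub(0.001, 0.3, 2, gate_consensus = FALSE)
  e2 <- make_eval_stub(0.001, 0.3, 2, gate_efficacy = FALSE)
  expect_error(select_best(list(e1, e2)), "no model passes")
})

strong_world_config <- function(seed, harm = FALSE) {
  # large planted effect so the end-to-end gate example is near-certain
  risk <- matrix(c(0.45, 0.45,
                   if (harm) c(0.75, 0.30) else c(0.30, 0.75)),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(phenotype = c("1", "2"),
                                 arm = c("active", "placebo")))
  specs <- lapply(1:3, function(i) {
    list(name = sprintf("v%d", i), mean = c(0, 2.5), sd = c(1, 1))
  })
  synthetic_config(n_patients = 300, variable_specs = specs,
                   event_risk = risk, missing_rate = 0, seed = seed)
}

test_that("evaluate_model passes both gates on a strongly planted cohort", {
  sim <- simulate_cohort(strong_world_config(19))
  oc <- derive_make90(sim$cohort)
  ev <- evaluate_model(sim$cohort, oc, model_spec(c("v1", "v2", "v3"),
                                                  "kmeans", 2),
                       search_params(reps = 60), seed = 7)
  expect_true(ev$gate_consensus)
  expect_true(ev$gate_efficacy)
  # the benefiting phenotype is the planted one
  truth <- sim$truth$phenotype[match(names(ev$labels),
                                     sim$truth$patient_id)]
  tab <- table(ev$labels, truth)
  planted_label <- which.max(tab[, "2"])
  expect_equal(ev$best_phenotype, as.integer(planted_label))
  expect_gt(adjusted_rand_index(ev$labels, truth), 0.9)

  # determinism
  ev2 <- evaluate_model(sim$cohort, oc, ev$spec, search_params(reps = 60),
                        seed = 7)
  expect_identical(ev$per_phenotype, ev2$per_phenotype)
  expect_identical(ev$labels, ev2$labels)
})

test_that("harm in the significant phenotype does not pass the gate", {
  sim <- simulate_cohort(strong_world_config(23, harm = TRUE))
  oc <- derive_make90(sim$cohort)
  ev <- evaluate_model(sim$cohort, oc, model_spec(c("v1", "v2", "v3"),
                                                  "kmeans", 2),
                       search_params(reps = 60), seed = 3)
  expect_true(ev$gate_consensus)
  expect_false(ev$gate_efficacy)
  expect_true(is.na(ev$p_best))
})

test_that("a phenotype with fewer than 2 patients per arm is noted", {
  # two tight clouds; the 4-patient cloud is all active-arm
  set.seed(42)
  df <- data.frame(
    patient_id = sprintf("M%02d", 1:24),
    arm = c(rep(c("active", "placebo"), 10), rep("active", 4)),
    covid_confirmed = FALSE, prior_rrt = FALSE, pre_aki_egfr = 80,
    death_day = c(rep(c(10, NA), 10), 20, NA, 30, NA),
    rrt_through_day28 = FALSE, rrt_at_day90 = FALSE, egfr_day90 = NA,
    v1 = c(rnorm(20, 0, 0.05), rnorm(4, 8, 0.05)),
    v2 = c(rnorm(20, 0, 0.05), rnorm(4, 8, 0.05)),
    stringsAsFactors = FALSE
  )
  cohort <- cohort_table(df)
  oc <- derive_make90(cohort)
  ev <- evaluate_model(cohort, oc, model_spec(c("v1", "v2"), "pam", 2),
                       search_params(reps = 30, max_rounds = 0), seed = 2)
  expect_false(ev$gate_efficacy)
  expect_true(any(grepl("fewer than 2", ev$per_phenotype$note)))
})

test_that("search over a pool returns a reproducible table and winner", {
  sim <- simulate_cohort(strong_world_config(31))
  oc <- derive_make90(sim$cohort)
  res <- search_models(sim$cohort, oc, c("v1", "v2", "v3"),
                       size_range = c(2, 3),
                       params = search_params(reps = 40), seed = 5)
  expect_equal(nrow(res$table), (3 + 1) * 2)
  expect_false(is.null(res$best))
  res2 <- search_models(sim$cohort, oc, c("v1", "v2", "v3"),
                        size_range = c(2, 3),
                        params = search_params(reps = 40), seed = 5)
  expect_identical(res$table, res2$table)
  expect_identical(format(res$best$spec), format(res2$best$spec))
})
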