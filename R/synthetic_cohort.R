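# Synthetic trial-cohort generator. Emulates the statistical structure the
# pipeline assumes — two (or more) latent phenotypes with distinct baseline
# distributions and a phenotype-specific treatment effect on the MAKE90
# composite — because the motivating trial's data are proprietary.

#' Default per-phenotype baseline-variable specifications
#'
#' Eight named clinical variables whose per-phenotype means are seeded from
#' the published phenotype characteristic medians (severity scores, blood
#' gas / chemistry, renal and respiratory function), plus optional
#' uninformative filler variables to exercise the wide-table contract (the
#' trial screened 44 numeric baseline variables).
#'
#' @param n_filler number of additional filler variables (same distribution
#'   in every phenotype).
#' @return list of per-variable specs: `name`, `mean` (one per phenotype),
#'   `sd` (one per phenotype).
#' @export
default_variable_specs <- function(n_filler = 0) {
  tab <- data.frame(
    name = c("apache_ii", "msofa", "bicarbonate", "hematocrit", "lactate",
             "egfr", "pao2_fio2", "creatinine"),
    mean1 = c(20.5, 8.0, 22.0, 32.8, 1.8, 55, 250, 1.8),
    mean2 = c(26.5, 9.5, 17.5, 35.1, 4.1, 35, 200, 2.8),
    sd1 = c(6.0, 2.2, 3.7, 7.2, 1.0, 25, 90, 0.8),
    sd2 = c(7.0, 2.2, 3.0, 7.4, 2.6, 20, 85, 1.2)
  )
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    list(name = tab$name[i], mean = c(tab$mean1[i], tab$mean2[i]),
         sd = c(tab$sd1[i], tab$sd2[i]))
  })
  if (n_filler > 0) {
    fillers <- lapply(seq_len(n_filler), function(i) {
      list(name = sprintf("filler_%02d", i), mean = c(10, 10), sd = c(3, 3))
    })
    specs <- c(specs, fillers)
  }
  specs
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the analyzed trial population: 570 patients, phenotype
#' weights 58%/42%, 1:1 randomization, and per-(phenotype, arm) 90-day
#' composite event probabilities from the published outcome table
#' (phenotype 1: 49.4% active / 45.8% placebo; phenotype 2: 54.1% active /
#' 67.8% placebo).
#'
#' @param n_patients number of patients to generate.
#' @param phenotype_weights probability vector (length >= 2, sums to 1).
#' @param arm_ratio probability of assignment to the active arm.
#' @param variable_specs list of per-variable specs as produced by
#'   [default_variable_specs()]; `mean`/`sd` must have one entry per
#'   phenotype.
#' @param event_risk matrix of composite event probabilities, phenotypes in
#'   rows, columns named `active`/`placebo`.
#' @param component_split probabilities dividing events among the
#'   `death` / `rrt` / `egfr_drop` components.
#' @param missing_rate MCAR missingness fraction applied to baseline cells.
#' @param outlier_rate fraction of patients given one shifted baseline value.
#' @param outlier_magnitude shift size in SD multiples (>= 3).
#' @param excluded_rate fraction of rows flagged COVID-19 / prior-RRT
#'   (flag split 33:23 as in the source trial).
#' @param correlation optional list of blocks, each
#'   `list(vars = <names>, rho = <value>)`, inducing equicorrelation within
#'   a phenotype.
#' @param seed integer RNG seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 570,
                             phenotype_weights = c(0.58, 0.42),
                             arm_ratio = 0.5,
                             variable_specs = default_variable_specs(),
                             event_risk = default_event_risk(),
                             component_split = c(death = 0.55, rrt = 0.35,
                                                 egfr_drop = 0.10),
                             missing_rate = 0.05,
                             outlier_rate = 0,
                             outlier_magnitude = 6,
                             excluded_rate = 0,
                             correlation = NULL,
                             seed = 1) {
  cfg <- list(n_patients = n_patients, phenotype_weights = phenotype_weights,
              arm_ratio = arm_ratio, variable_specs = variable_specs,
              event_risk = event_risk, component_split = component_split,
              missing_rate = missing_rate, outlier_rate = outlier_rate,
              outlier_magnitude = outlier_magnitude,
              excluded_rate = excluded_rate, correlation = correlation,
              seed = seed)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

#' Default per-(phenotype, arm) composite event probabilities
#'
#' Published MAKE90 incidences by phenotype and arm.
#' @return 2x2 matrix, rows phenotypes, columns `active`/`placebo`.
#' @export
default_event_risk <- function() {
  matrix(c(0.494, 0.458,
           0.541, 0.678),
         nrow = 2, byrow = TRUE,
         dimnames = list(phenotype = c("1", "2"),
                         arm = c("active", "placebo")))
}

# Normalize generator arguments that arrived through a JSON config file:
# jsonlite renders the variable-spec list as a data.frame with list columns
# and the event-risk matrix as a plain unnamed matrix.
normalize_synthetic_args <- function(args) {
  vs <- args$variable_specs
  if (is.data.frame(vs)) {
    args$variable_specs <- lapply(seq_len(nrow(vs)), function(i) {
      list(name = vs$name[i], mean = as.numeric(vs$mean[[i]]),
           sd = as.numeric(vs$sd[[i]]))
    })
  }
  if (!is.null(args$event_risk) && !is.matrix(args$event_risk))
    args$event_risk <- do.call(rbind, lapply(args$event_risk, as.numeric))
  if (!is.null(args$component_split))
    args$component_split <- unlist(args$component_split)
  args
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (!is.numeric(n_patients) || length(n_patients) != 1 ||
        n_patients < 1 || n_patients != floor(n_patients))
      stop("n_patients must be a positive integer", call. = FALSE)
    if (length(phenotype_weights) < 2)
      stop("need at least two phenotypes", call. = FALSE)
    if (any(phenotype_weights < 0) ||
        abs(sum(phenotype_weights) - 1) > 1e-9)
      stop("phenotype_weights must be non-negative and sum to 1",
           call. = FALSE)
    if (arm_ratio < 0 || arm_ratio > 1)
      stop("arm_ratio out of [0,1]", call. = FALSE)
    if (length(variable_specs) == 0)
      stop("variable_specs must be non-empty", call. = FALSE)
    k <- length(phenotype_weights)
    for (vs in variable_specs) {
      if (length(vs$mean) != k || length(vs$sd) != k)
        stop("variable spec '", vs$name, "' needs ", k,
             " means and SDs", call. = FALSE)
      if (any(vs$sd <= 0))
        stop("variable spec '", vs$name, "' has non-positive SD",
             call. = FALSE)
    }
    if (nrow(event_risk) != k)
      stop("event_risk needs one row per phenotype", call. = FALSE)
    if (any(event_risk < 0 | event_risk > 1))
      stop("event_risk probabilities out of [0,1]", call. = FALSE)
    if (any(component_split < 0) || abs(sum(component_split) - 1) > 1e-9)
      stop("component_split must be a probability vector", call. = FALSE)
    if (!setequal(names(component_split), c("death", "rrt", "egfr_drop")))
      stop("component_split must be named death/rrt/egfr_drop", call. = FALSE)
    for (r in c(missing_rate, outlier_rate, excluded_rate)) {
      if (r < 0 || r >= 1) stop("rates must lie in [0, 1)", call. = FALSE)
    }
    if (outlier_rate > 0 && outlier_magnitude < 3)
      stop("outlier_magnitude must be >= 3", call. = FALSE)
  })
  invisible(cfg)
}

#' Simulate a trial cohort with planted phenotype structure
#'
#' Draws a latent phenotype per patient, an arm assignment, per-phenotype
#' Gaussian baseline variables (optionally block-equicorrelated), and MAKE90
#' component outcomes such that the composite event probability equals the
#' configured `event_risk[phenotype, arm]`. Death days are uniform on 1..90;
#' eGFR-drop-only events are observed at day 90 (the component is assessed
#' only then). Same config + seed gives byte-identical output.
#'
#' @param config a [synthetic_config()].
#' @return list with `cohort` (a [cohort_table()]) and `truth`
#'   (data.frame `patient_id`, `phenotype`; the planted event-risk matrix
#'   and seed as attributes).
#' @export
simulate_cohort <- function(config) {
  validate_synthetic_config(config)
  n <- as.integer(config$n_patients)
  k <- length(config$phenotype_weights)
  vars <- vapply(config$variable_specs, `[[`, "", "name")

  with_seed(config$seed, {
    phenotype <- sample.int(k, n, replace = TRUE,
                            prob = config$phenotype_weights)
    arm <- ifelse(runif(n) < config$arm_ratio, "active", "placebo")

    z <- matrix(rnorm(n * length(vars)), nrow = n,
                dimnames = list(NULL, vars))
    if (!is.null(config$correlation)) {
      for (blk in config$correlation) {
        bv <- blk$vars
        stopifnot(all(bv %in% vars), length(bv) >= 2,
                  blk$rho > -1, blk$rho < 1)
        m <- length(bv)
        sigma <- matrix(blk$rho, m, m); diag(sigma) <- 1
        ch <- chol(sigma)
        z[, bv] <- z[, bv] %*% ch
      }
    }
    baseline <- matrix(NA_real_, n, length(vars),
                       dimnames = list(NULL, vars))
    for (j in seq_along(config$variable_specs)) {
      vs <- config$variable_specs[[j]]
      baseline[, j] <- vs$mean[phenotype] + vs$sd[phenotype] * z[, j]
    }

    pre_aki_egfr <- pmax(rnorm(n, 75, 20), 15)

    p_event <- config$event_risk[cbind(phenotype,
                                       ifelse(arm == "active", 1L, 2L))]
    event <- runif(n) < p_event
    component <- rep(NA_character_, n)
    component[event] <- sample(names(config$component_split),
                               sum(event), replace = TRUE,
                               prob = config$component_split)

    death_day <- rep(NA_real_, n)
    rrt28 <- rep(FALSE, n)
    rrt90 <- rep(FALSE, n)
    egfr_day90 <- rep(NA_real_, n)

    is_death <- component %in% "death"
    death_day[is_death] <- sample.int(90, sum(is_death), replace = TRUE)

    is_rrt <- component %in% "rrt"
    rrt_day <- sample.int(90, sum(is_rrt), replace = TRUE)
    rrt28[is_rrt] <- rrt_day <= 28
    rrt90[is_rrt] <- rrt_day > 28
    # survivors on RRT have a day-90 eGFR measurement; keep it above the
    # >25%-drop trigger so the planted composite probability stays exact
    egfr_day90[is_rrt] <- pre_aki_egfr[is_rrt] * runif(sum(is_rrt), 0.76, 1.1)

    is_drop <- component %in% "egfr_drop"
    egfr_day90[is_drop] <- pre_aki_egfr[is_drop] * runif(sum(is_drop), 0.3, 0.7)

    none <- !event
    egfr_day90[none] <- pre_aki_egfr[none] * runif(sum(none), 0.76, 1.15)

    covid <- rep(FALSE, n)
    prior_rrt <- rep(FALSE, n)
    if (config$excluded_rate > 0) {
      flagged <- runif(n) < config$excluded_rate
      # split flagged rows 33:23 between the two exclusion reasons
      reason <- runif(n) < 33 / 56
      covid <- flagged & reason
      prior_rrt <- flagged & !reason
    }

    df <- data.frame(
      patient_id = sprintf("P%05d", seq_len(n)),
      arm = arm,
      covid_confirmed = covid,
      prior_rrt = prior_rrt,
      pre_aki_egfr = pre_aki_egfr,
      death_day = death_day,
      rrt_through_day28 = rrt28,
      rrt_at_day90 = rrt90,
      egfr_day90 = egfr_day90,
      stringsAsFactors = FALSE
    )
    df <- cbind(df, as.data.frame(baseline))
    cohort <- cohort_table(df, baseline_vars = vars)

    if (config$missing_rate > 0)
      cohort <- inject_missingness(cohort, config$missing_rate, seed = NULL)
    outlier_ids <- character()
    if (config$outlier_rate > 0) {
      inj <- inject_outliers(cohort, config$outlier_rate,
                             config$outlier_magnitude, seed = NULL)
      cohort <- inj$cohort
      outlier_ids <- inj$outlier_ids
    }

    truth <- data.frame(patient_id = df$patient_id, phenotype = phenotype,
                        stringsAsFactors = FALSE)
    attr(truth, "event_risk") <- config$event_risk
    attr(truth, "seed") <- config$seed
    attr(truth, "outlier_ids") <- outlier_ids
    list(cohort = cohort, truth = truth)
  })
}

#' Set baseline cells missing completely at random
#'
#' Only baseline-variable cells are eligible; arm, flags and outcome fields
#' are never touched.
#'
#' @param cohort a [cohort_table()].
#' @param rate missingness fraction in \[0, 1).
#' @param seed RNG seed; `NULL` continues the ambient stream.
#' @return the modified cohort table.
#' @export
inject_missingness <- function(cohort, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)", call. = FALSE)
  if (rate == 0) return(cohort)
  vars <- baseline_vars(cohort)
  with_seed(seed, {
    for (v in vars) {
      hit <- runif(nrow(cohort)) < rate
      cohort[[v]][hit] <- NA_real_
    }
  })
  cohort
}

#' Plant gross outliers in baseline variables
#'
#' Each selected patient gets one baseline variable shifted by
#' +/- `magnitude` column SDs, emulating entry errors the Bonferroni outlier
#' test is meant to catch.
#'
#' @param cohort a [cohort_table()].
#' @param rate fraction of patients to perturb, in \[0, 1).
#' @param magnitude shift in SD multiples; must be >= 3.
#' @param seed RNG seed; `NULL` continues the ambient stream.
#' @return list with `cohort` and `outlier_ids`.
#' @export
inject_outliers <- function(cohort, rate, magnitude, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)", call. = FALSE)
  if (magnitude < 3) stop("magnitude must be >= 3", call. = FALSE)
  if (rate == 0) return(list(cohort = cohort, outlier_ids = character()))
  vars <- baseline_vars(cohort)
  with_seed(seed, {
    hit <- which(runif(nrow(cohort)) < rate)
    vpick <- sample(vars, length(hit), replace = TRUE)
    sgn <- sample(c(-1, 1), length(hit), replace = TRUE)
    for (i in seq_along(hit)) {
      v <- vpick[i]
      s <- sd(cohort[[v]], na.rm = TRUE)
      old <- cohort[[v]][hit[i]]
      if (is.na(old)) old <- mean(cohort[[v]], na.rm = TRUE)
      cohort[[v]][hit[i]] <- old + sgn[i] * magnitude * s
    }
    list(cohort = cohort, outlier_ids = cohort$patient_id[hit])
  })
}
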