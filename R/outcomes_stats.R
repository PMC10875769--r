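# MAKE90 composite derivation and the survival / comparison statistics used
# throughout the pipeline: Kaplan-Meier cumulative incidence, two-group
# log-rank, Mann-Whitney U, 2x2 chi-square, risk ratio, SMD profiles.
# Log-rank and the product-limit estimator are authored here (they drive the
# efficacy gate); rank/chi-square tests delegate to base stats.

#' Derive the MAKE90 composite outcome
#'
#' A MAKE90 event is death through day 90, OR a >25% (strict) drop in day-90
#' eGFR versus the pre-AKI reference, OR any renal replacement therapy
#' through day 28 or RRT status at day 90. Death is the only time-resolved
#' component in the patient table, so the event day is the death day
#' (capped at 90) when present and day 90 otherwise; non-events are censored
#' at day 90.
#'
#' @param cohort a [cohort_table()] (or data.frame with the outcome fields).
#' @return data.frame with `patient_id`, `event`, `event_day`, and the
#'   component indicators `death`, `egfr_drop`, `rrt`.
#' @export
derive_make90 <- function(cohort) {
  death <- !is.na(cohort$death_day)
  has_egfr <- !is.na(cohort$egfr_day90)
  bad_ref <- has_egfr & (is.na(cohort$pre_aki_egfr) | cohort$pre_aki_egfr <= 0)
  if (any(bad_ref))
    stop("pre_aki_egfr must be positive when egfr_day90 is present (",
         paste(cohort$patient_id[bad_ref], collapse = ", "), ")",
         call. = FALSE)
  egfr_drop <- has_egfr & cohort$egfr_day90 < 0.75 * cohort$pre_aki_egfr
  rrt <- (cohort$rrt_through_day28 %in% TRUE) | (cohort$rrt_at_day90 %in% TRUE)
  event <- death | egfr_drop | rrt
  event_day <- ifelse(death, pmin(cohort$death_day, 90), 90)
  data.frame(patient_id = as.character(cohort$patient_id), event = event,
             event_day = as.numeric(event_day), death = death,
             egfr_drop = egfr_drop, rrt = rrt, stringsAsFactors = FALSE)
}

# Product-limit (Kaplan-Meier) survival; events precede censorings at ties.
km_survival <- function(time, status, at = max(time)) {
  ut <- sort(unique(time[status]))
  surv <- 1
  for (t in ut[ut <= at]) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & status)
    surv <- surv * (1 - d / at_risk)
  }
  surv
}

#' Cumulative incidence at a day
#'
#' One minus the Kaplan-Meier survival estimate at `day`. When censoring
#' occurs only at day 90 this equals the plain event fraction.
#'
#' @param outcomes data.frame from [derive_make90()] (needs `event`,
#'   `event_day`).
#' @param day day in 1..90.
#' @return fraction in \[0, 1\].
#' @export
cumulative_incidence <- function(outcomes, day = 90) {
  if (nrow(outcomes) == 0) stop("empty outcomes", call. = FALSE)
  if (day < 1 || day > 90) stop("day must lie in 1..90", call. = FALSE)
  1 - km_survival(outcomes$event_day, outcomes$event, at = day)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank: at each distinct event time the observed
#' minus expected events in group A, variance from the hypergeometric
#' distribution (ties handled by the standard tied-event variance); the
#' squared standardized sum is referred to chi-square with 1 df.
#'
#' @param outcomes_a,outcomes_b data.frames with `event`, `event_day`.
#' @return a `logrank_result` list: `statistic`, `df`, `p_value`,
#'   `observed`, `expected`, `variance`, and the per-event-time table.
#' @export
logrank_test <- function(outcomes_a, outcomes_b) {
  if (nrow(outcomes_a) == 0 || nrow(outcomes_b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  time <- c(outcomes_a$event_day, outcomes_b$event_day)
  status <- c(outcomes_a$event, outcomes_b$event)
  group <- rep(1:2, c(nrow(outcomes_a), nrow(outcomes_b)))
  if (!any(status)) stop("no events in either group", call. = FALSE)

  ut <- sort(unique(time[status]))
  o <- e <- v <- numeric(length(ut))
  tab <- data.frame(time = ut, n_risk = NA_real_, n_risk_a = NA_real_,
                    events = NA_real_, events_a = NA_real_)
  for (i in seq_along(ut)) {
    t <- ut[i]
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & status)
    d1 <- sum(time == t & status & group == 1)
    o[i] <- d1
    e[i] <- d * n1 / n
    v[i] <- if (n > 1) d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1) else 0
    tab[i, -1] <- c(n, n1, d, d1)
  }
  O <- sum(o); E <- sum(e); V <- sum(v)
  stat <- if (V > 0) (O - E)^2 / V else 0
  structure(list(statistic = stat, df = 1L,
                 p_value = if (V > 0) pchisq(stat, 1, lower.tail = FALSE) else 1,
                 observed = O, expected = E, variance = V, table = tab),
            class = "logrank_result")
}

#' Mann-Whitney U test p-value
#'
#' Two-sided rank-sum comparison (normal approximation with continuity
#' correction, as in `stats::wilcox.test` for tied/medium samples).
#'
#' @param x,y numeric vectors (NAs dropped).
#' @return p-value.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
}

#' Chi-square test for a 2x2 table
#'
#' Pearson chi-square, without Yates continuity correction by default (the
#' correction is available via `correct = TRUE`).
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param correct apply the continuity correction?
#' @return p-value.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("negative counts", call. = FALSE)
  stopifnot(all(dim(table) == c(2, 2)))
  suppressWarnings(chisq.test(table, correct = correct)$p.value)
}

#' Risk ratio of two cumulative incidences
#'
#' `(events_e/n_e) / (events_u/n_u)` — exposed (treated) incidence over
#' unexposed (placebo) incidence. Undefined (flagged, estimate `NA`) when
#' the unexposed incidence is zero; the optional Haldane-Anscombe +0.5
#' correction is available for that case.
#'
#' @param events_e,n_e events and size of the exposed group.
#' @param events_u,n_u events and size of the unexposed group.
#' @param haldane apply a +0.5 continuity correction to all four counts when
#'   `events_u` is 0?
#' @return list `estimate`, `defined`, `ci_e`, `ci_u`.
#' @export
risk_ratio <- function(events_e, n_e, events_u, n_u, haldane = FALSE) {
  if (n_e <= 0 || n_u <= 0) stop("group sizes must be positive", call. = FALSE)
  if (events_e < 0 || events_u < 0) stop("negative counts", call. = FALSE)
  ci_e <- events_e / n_e
  ci_u <- events_u / n_u
  if (ci_u == 0) {
    if (haldane) {
      est <- ((events_e + 0.5) / (n_e + 0.5)) / ((events_u + 0.5) / (n_u + 0.5))
      return(list(estimate = est, defined = TRUE, ci_e = ci_e, ci_u = ci_u))
    }
    return(list(estimate = NA_real_, defined = FALSE, ci_e = ci_e, ci_u = ci_u))
  }
  list(estimate = ci_e / ci_u, defined = TRUE, ci_e = ci_e, ci_u = ci_u)
}

#' Standardized mean difference profile
#'
#' For each variable and group: (group mean - cohort mean) / cohort SD, a
#' dimensionless measure of how far a phenotype sits from the whole-cohort
#' center (the Fig 1B-style characterization).
#'
#' @param matrix numeric matrix, variables in columns.
#' @param labels group label per row.
#' @return matrix of SMDs, groups in rows, variables in columns.
#' @export
smd_profile <- function(matrix, labels) {
  stopifnot(nrow(matrix) == length(labels))
  mu <- colMeans(matrix, na.rm = TRUE)
  sigma <- apply(matrix, 2, sd, na.rm = TRUE)
  if (any(sigma == 0 | is.na(sigma)))
    stop("zero cohort SD for: ",
         paste(colnames(matrix)[sigma == 0 | is.na(sigma)], collapse = ", "),
         call. = FALSE)
  groups <- sort(unique(labels))
  out <- base::matrix(NA_real_, nrow = length(groups), ncol = ncol(matrix),
                      dimnames = list(as.character(groups),
                                      colnames(matrix)))
  for (i in seq_along(groups)) {
    g <- labels == groups[i]
    out[i, ] <- (colMeans(matrix[g, , drop = FALSE], na.rm = TRUE) - mu) / sigma
  }
  out
}
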