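# The screening algorithm: quartile categorization, per-quartile treated vs
# placebo risk ratios, the >=3-consecutive-quartile monotone-run screen, and
# OLS slope ranking with a top-15 cut.

#' Assign quartile indices by rank
#'
#' Ranks the non-missing values and maps them to quartiles 1..4; tied values
#' all take the quartile of their lowest rank. Missing values stay
#' unassigned (`NA`).
#'
#' @param values numeric vector.
#' @return integer vector of quartile indices (NA where `values` is NA).
#' @export
assign_quartiles <- function(values) {
  obs <- !is.na(values)
  x <- values[obs]
  if (length(x) < 8)
    stop("need at least 8 non-missing values", call. = FALSE)
  if (length(unique(x)) < 4)
    stop("non-informative variable: fewer than 4 distinct values",
         call. = FALSE)
  r <- rank(x, ties.method = "min")
  q <- floor(4 * (r - 1) / length(x)) + 1L
  out <- rep(NA_integer_, length(values))
  out[obs] <- as.integer(q)
  out
}

#' Per-quartile treated-vs-placebo risk ratios for one variable
#'
#' Quartiles are computed on the pooled cohort (both arms); within each
#' quartile the cumulative incidence of the composite event is computed per
#' arm and their ratio CIe/CIu taken. Patients missing the variable are
#' excluded from its quartiles only (per-variable complete case).
#'
#' @param values baseline values (one per patient, NAs allowed).
#' @param arm `"active"`/`"placebo"` per patient.
#' @param event logical composite-event indicator per patient.
#' @param variable variable name carried into the result.
#' @return a `quartile_risk_profile`: list with `variable`, `boundaries`
#'   (3 quartile cut values) and `table` (per-quartile n/events/CI per arm,
#'   `rr`, `rr_defined`).
#' @export
quartile_risk_ratios <- function(values, arm, event,
                                 variable = "variable") {
  stopifnot(length(values) == length(arm), length(arm) == length(event))
  if (!all(arm %in% c("active", "placebo")))
    stop("arm must be 'active' or 'placebo'", call. = FALSE)
  if (length(unique(arm[!is.na(values)])) < 2)
    stop("both arms must be represented", call. = FALSE)
  q <- assign_quartiles(values)
  tab <- data.frame(quartile = 1:4, n_e = 0L, events_e = 0L, ci_e = NA_real_,
                    n_u = 0L, events_u = 0L, ci_u = NA_real_, rr = NA_real_,
                    rr_defined = FALSE)
  for (qq in 1:4) {
    in_q <- !is.na(q) & q == qq
    e <- in_q & arm == "active"
    u <- in_q & arm == "placebo"
    tab$n_e[qq] <- sum(e)
    tab$events_e[qq] <- sum(event[e])
    tab$n_u[qq] <- sum(u)
    tab$events_u[qq] <- sum(event[u])
    if (tab$n_e[qq] > 0) tab$ci_e[qq] <- tab$events_e[qq] / tab$n_e[qq]
    if (tab$n_u[qq] > 0) tab$ci_u[qq] <- tab$events_u[qq] / tab$n_u[qq]
    if (tab$n_e[qq] > 0 && tab$n_u[qq] > 0 && tab$ci_u[qq] > 0) {
      tab$rr[qq] <- tab$ci_e[qq] / tab$ci_u[qq]
      tab$rr_defined[qq] <- TRUE
    }
  }
  obs <- values[!is.na(values)]
  structure(list(variable = variable,
                 boundaries = unname(quantile(obs, c(0.25, 0.5, 0.75))),
                 table = tab),
            class = "quartile_risk_profile")
}

#' Screen a risk-ratio profile for monotone runs
#'
#' Passes when some run of at least three consecutive quartiles has strictly
#' monotone, fully defined risk ratios. An undefined RR (placebo incidence
#' zero) breaks a run. Returns every maximal qualifying run.
#'
#' @param profile a [quartile_risk_ratios()] result, or a length-4 numeric
#'   RR vector (NA = undefined).
#' @param strict require strict monotonicity (default); `FALSE` allows
#'   plateaus inside a run.
#' @param direction `"both"` (default), `"increasing"` or `"decreasing"`:
#'   which run directions qualify.
#' @return list `pass` (logical) and `runs`
#'   (data.frame `start_q`, `end_q`, `direction`).
#' @export
screen_monotone <- function(profile, strict = TRUE,
                            direction = c("both", "increasing",
                                          "decreasing")) {
  direction <- match.arg(direction)
  rr <- if (inherits(profile, "quartile_risk_profile")) {
    ifelse(profile$table$rr_defined, profile$table$rr, NA_real_)
  } else {
    as.numeric(profile)
  }
  stopifnot(length(rr) == 4)
  cmp_up <- if (strict) `>` else `>=`
  cmp_dn <- if (strict) `<` else `<=`

  runs <- data.frame(start_q = integer(), end_q = integer(),
                     direction = character(), stringsAsFactors = FALSE)
  for (dir in c("increasing", "decreasing")) {
    if (direction != "both" && direction != dir) next
    cmp <- if (dir == "increasing") cmp_up else cmp_dn
    step_ok <- vapply(1:3, function(i) {
      !is.na(rr[i]) && !is.na(rr[i + 1]) && cmp(rr[i + 1], rr[i])
    }, logical(1))
    i <- 1
    while (i <= 3) {
      if (step_ok[i]) {
        j <- i
        while (j < 3 && step_ok[j + 1]) j <- j + 1
        if (j - i + 2 >= 3)  # run spans >= 3 quartiles
          runs <- rbind(runs, data.frame(start_q = i, end_q = j + 1,
                                         direction = dir,
                                         stringsAsFactors = FALSE))
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
  }
  list(pass = nrow(runs) > 0, runs = runs)
}

# Closed-form OLS slope of y on x.
ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

#' Rank screened variables by risk-ratio slope steepness
#'
#' For each qualifying run the OLS slope of RR on quartile index is
#' computed: one slope for a three-quartile run; for a full four-quartile
#' run two separate slopes (first-to-third and second-to-fourth quartile).
#' A variable's rank key is its maximum absolute slope (steepness); the
#' `top_k` steepest variables are selected.
#'
#' @param profiles list of [quartile_risk_ratios()] results (typically those
#'   that passed [screen_monotone()]).
#' @param top_k number of variables to keep (default 15). If fewer pass, all
#'   are returned with a warning.
#' @param strict,direction passed to [screen_monotone()].
#' @return list with `slopes` (data.frame: variable, start_q, end_q, slope,
#'   steepness), `ranking` (one row per variable, ordered by steepness) and
#'   `selected` (character vector, the top-k variables).
#' @export
slope_rank <- function(profiles, top_k = 15, strict = TRUE,
                       direction = "both") {
  if (length(profiles) == 0) stop("no profiles supplied", call. = FALSE)
  records <- list()
  for (pf in profiles) {
    scr <- screen_monotone(pf, strict = strict, direction = direction)
    if (!scr$pass) next
    rr <- ifelse(pf$table$rr_defined, pf$table$rr, NA_real_)
    for (i in seq_len(nrow(scr$runs))) {
      s <- scr$runs$start_q[i]; e <- scr$runs$end_q[i]
      windows <- if (e - s + 1 == 4) list(c(1, 3), c(2, 4)) else list(c(s, e))
      for (w in windows) {
        qs <- w[1]:w[2]
        slope <- ols_slope(qs, rr[qs])
        records[[length(records) + 1]] <-
          data.frame(variable = pf$variable, start_q = w[1], end_q = w[2],
                     slope = slope, steepness = abs(slope),
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(records) == 0)
    return(list(slopes = data.frame(), ranking = data.frame(),
                selected = character()))
  slopes <- do.call(rbind, records)
  ranking <- do.call(rbind, lapply(split(slopes, slopes$variable), function(d) {
    d[which.max(d$steepness), , drop = FALSE]
  }))
  ranking <- ranking[order(-ranking$steepness, ranking$variable), ,
                     drop = FALSE]
  rownames(ranking) <- NULL
  if (nrow(ranking) < top_k)
    warning("only ", nrow(ranking), " variables passed the screen (top_k = ",
            top_k, ")", call. = FALSE)
  selected <- head(ranking$variable, top_k)
  list(slopes = slopes, ranking = ranking, selected = selected)
}

#' Run the full variable-selection screen on a cohort
#'
#' Computes quartile risk-ratio profiles for every baseline variable,
#' applies the monotone-run screen and slope ranking, and returns the top-k
#' variables. Variables with fewer than 4 distinct (or 8 non-missing) values
#' are skipped with a note.
#'
#' @param cohort a [cohort_table()].
#' @param outcomes result of [derive_make90()] aligned with `cohort`.
#' @param variables candidate variables (default: all baseline variables).
#' @param top_k,strict,direction passed to [slope_rank()].
#' @return the [slope_rank()] result plus `profiles` and `skipped`.
#' @export
select_variables <- function(cohort, outcomes,
                             variables = baseline_vars(cohort),
                             top_k = 15, strict = TRUE, direction = "both") {
  stopifnot(identical(cohort$patient_id, outcomes$patient_id))
  profiles <- list()
  skipped <- character()
  for (v in variables) {
    pf <- tryCatch(
      quartile_risk_ratios(cohort[[v]], cohort$arm, outcomes$event,
                           variable = v),
      error = function(e) NULL
    )
    if (is.null(pf)) skipped <- c(skipped, v)
    else profiles[[v]] <- pf
  }
  if (length(profiles) == 0)
    stop("no screenable variables", call. = FALSE)
  res <- slope_rank(profiles, top_k = top_k, strict = strict,
                    direction = direction)
  res$profiles <- profiles
  res$skipped <- skipped
  res
}
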