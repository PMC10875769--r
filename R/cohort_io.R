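# Patient-table I/O, validation, pre-specified exclusions and the variable
# dictionary. The cohort table is a plain data.frame subclass so base verbs
# keep working; the set of baseline-variable columns travels in an attribute.

COHORT_FIXED_COLS <- c(
  "patient_id", "arm", "covid_confirmed", "prior_rrt", "pre_aki_egfr",
  "death_day", "rrt_through_day28", "rrt_at_day90", "egfr_day90"
)

#' Construct a cohort table
#'
#' One row per patient: identifier, treatment arm, exclusion flags, numeric
#' baseline variables (possibly missing), pre-AKI eGFR reference, and the
#' MAKE90 component outcome fields (death day up to 90, RRT through day 28,
#' RRT status at day 90, day-90 eGFR).
#'
#' @param df data.frame containing the fixed columns (see Details) and the
#'   baseline-variable columns.
#' @param baseline_vars character vector naming the baseline columns; by
#'   default every non-fixed column.
#' @return a `cohort_table` (data.frame subclass with a `baseline_vars`
#'   attribute).
#' @details Fixed columns: `patient_id` (unique string), `arm`
#'   ("active"/"placebo"), `covid_confirmed`, `prior_rrt` (logical),
#'   `pre_aki_egfr` (mL/min/1.73m2), `death_day` (1..90 or NA),
#'   `rrt_through_day28`, `rrt_at_day90` (logical), `egfr_day90`
#'   (numeric or NA).
#' @export
cohort_table <- function(df, baseline_vars = NULL) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(COHORT_FIXED_COLS, names(df))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (is.null(baseline_vars))
    baseline_vars <- setdiff(names(df), COHORT_FIXED_COLS)
  stopifnot(all(baseline_vars %in% names(df)))

  df$patient_id <- as.character(df$patient_id)
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup) > 0)
    stop("duplicate patient_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (any(is.na(df$arm)))
    stop("arm must be non-missing for every patient", call. = FALSE)
  df$arm <- as.character(df$arm)
  if (!all(df$arm %in% c("active", "placebo")))
    stop("arm must be 'active' or 'placebo'", call. = FALSE)
  bad_day <- !is.na(df$death_day) & (df$death_day < 1 | df$death_day > 90)
  if (any(bad_day))
    stop("death_day outside 1..90 for: ",
         paste(df$patient_id[bad_day], collapse = ", "), call. = FALSE)
  for (v in baseline_vars) {
    if (!is.numeric(df[[v]]))
      stop("baseline variable '", v, "' is not numeric", call. = FALSE)
  }
  structure(df, baseline_vars = baseline_vars,
            class = c("cohort_table", "data.frame"))
}

#' Baseline-variable names of a cohort table
#' @param cohort a `cohort_table`.
#' @return character vector.
#' @export
baseline_vars <- function(cohort) attr(cohort, "baseline_vars")

#' Default variable dictionary
#'
#' Names, units, plausible ranges and log-transform eligibility for the
#' default baseline variables emitted by the synthetic generator. Used by
#' [read_cohort()] for range warnings.
#'
#' @param extra_names further variable names to register (unit-free, no
#'   range check).
#' @return data.frame with columns name, units, min, max, log_ok.
#' @export
default_dictionary <- function(extra_names = character()) {
  base <- data.frame(
    name = c("apache_ii", "msofa", "bicarbonate", "hematocrit", "lactate",
             "egfr", "pao2_fio2", "creatinine", "pre_aki_egfr"),
    units = c("points", "points", "mmol/L", "%", "mmol/L",
              "mL/min/1.73m2", "mmHg", "mg/dL", "mL/min/1.73m2"),
    min = c(0, 0, 2, 5, 0, 0, 20, 0.1, 1),
    max = c(71, 24, 60, 70, 40, 250, 700, 30, 250),
    log_ok = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  if (length(extra_names) > 0) {
    extra <- data.frame(name = extra_names, units = "", min = NA_real_,
                        max = NA_real_, log_ok = TRUE,
                        stringsAsFactors = FALSE)
    base <- rbind(base, extra)
  }
  if (anyDuplicated(base$name)) stop("dictionary names must be unique")
  base
}

#' Read a cohort table from CSV
#'
#' CSV dialect: comma-separated, UTF-8, '.' decimal, empty cell = missing.
#' Values outside the dictionary's declared range are reported as warnings
#' but kept.
#'
#' @param path CSV file path.
#' @param dictionary optional variable dictionary (see
#'   [default_dictionary()]); baseline columns not in it are accepted
#'   unchecked.
#' @return a [cohort_table()].
#' @export
read_cohort <- function(path, dictionary = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                 check.names = FALSE)
  missing_cols <- setdiff(COHORT_FIXED_COLS, names(df))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (v in c("covid_confirmed", "prior_rrt", "rrt_through_day28",
              "rrt_at_day90")) {
    df[[v]] <- as.logical(df[[v]])
  }
  numeric_cols <- setdiff(names(df), c("patient_id", "arm", "covid_confirmed",
                                       "prior_rrt", "rrt_through_day28",
                                       "rrt_at_day90"))
  for (v in numeric_cols) {
    raw <- df[[v]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & is.na(num)
    if (any(bad))
      stop("unparseable numeric in column '", v, "': ",
           paste(unique(raw[bad]), collapse = ", "), call. = FALSE)
    df[[v]] <- num
  }
  cohort <- cohort_table(df)
  if (!is.null(dictionary)) {
    for (v in intersect(c(baseline_vars(cohort), "pre_aki_egfr"),
                        dictionary$name)) {
      row <- dictionary[dictionary$name == v, ]
      x <- cohort[[v]]
      out <- !is.na(x) &
        ((!is.na(row$min) & x < row$min) | (!is.na(row$max) & x > row$max))
      if (any(out))
        warning(sum(out), " value(s) of '", v, "' outside [",
                row$min, ", ", row$max, "]", call. = FALSE)
    }
  }
  cohort
}

#' Write a cohort table to CSV
#'
#' Missing cells are written as empty strings; doubles are written with 17
#' significant digits so that [read_cohort()] round-trips exactly.
#'
#' @param cohort a `cohort_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  for (v in names(df)) {
    if (is.double(df[[v]])) {
      out <- ifelse(is.na(df[[v]]), NA_character_,
                    sprintf("%.17g", df[[v]]))
      df[[v]] <- out
    }
  }
  write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Apply the trial's pre-specified exclusions
#'
#' Removes patients with confirmed COVID-19 or renal replacement therapy
#' prior to study-drug administration. A patient with both flags is counted
#' once, attributed to COVID (flag listed first); the surviving rows are
#' returned unmodified.
#'
#' @param cohort a `cohort_table`.
#' @return list with `cohort` (rows kept), `log` (named counts per reason)
#'   and `excluded_ids`.
#' @export
apply_exclusions <- function(cohort) {
  covid <- cohort$covid_confirmed %in% TRUE
  rrt <- cohort$prior_rrt %in% TRUE
  log <- c(covid = sum(covid), prior_rrt = sum(rrt & !covid))
  keep <- !(covid | rrt)
  kept <- cohort[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(
    cohort = cohort_table(as.data.frame(kept), baseline_vars(cohort)),
    log = log,
    excluded_ids = cohort$patient_id[!keep]
  )
}
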