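# Per-model preprocessing, in the fixed order the pipeline prescribes:
# missingness filter -> chained random-forest imputation -> log/scale/center
# -> Bonferroni outlier removal.

#' Drop patients with excessive missingness in the model variables
#'
#' Removes patients whose fraction of missing cells among `model_vars`
#' strictly exceeds `threshold` (a patient missing exactly 50% of 4
#' variables is retained at the default).
#'
#' @param cohort a [cohort_table()] (or data.frame with the columns).
#' @param model_vars variables of the candidate model.
#' @param threshold maximum tolerated missing fraction (default 0.5).
#' @return list `retained` (cohort rows kept), `removed`
#'   (data.frame `patient_id`, `frac_missing`).
#' @export
filter_missingness <- function(cohort, model_vars, threshold = 0.5) {
  stopifnot(length(model_vars) > 0, all(model_vars %in% names(cohort)))
  x <- as.matrix(as.data.frame(cohort)[, model_vars, drop = FALSE])
  frac <- rowMeans(is.na(x))
  drop <- frac > threshold
  retained <- cohort[!drop, , drop = FALSE]
  rownames(retained) <- NULL
  list(
    retained = retained,
    removed = data.frame(patient_id = cohort$patient_id[drop],
                         frac_missing = frac[drop],
                         stringsAsFactors = FALSE)
  )
}

#' Chained random-forest imputation
#'
#' Missing cells are initialized with column medians, then each
#' incomplete column is repeatedly re-imputed by a regression random forest
#' trained on the other columns (columns visited in order of increasing
#' missingness), until the summed out-of-bag error stops improving or
#' `max_iter` chained passes are done. Observed cells are never altered.
#'
#' @param x numeric matrix (>= 2 columns; every column needs at least one
#'   observed value).
#' @param seed RNG seed (the imputation is deterministic per seed).
#' @param max_iter maximum chained passes (default 10).
#' @param num_trees trees per forest (default 100).
#' @param mtry candidate features per split (default: floor(sqrt(p)), at
#'   least 1).
#' @param min_node minimum node size (default 5).
#' @param tol relative out-of-bag improvement below which iteration stops
#'   (default 1e-4).
#' @return the completed matrix, with attributes `iterations` and
#'   `oob_trace`.
#' @export
impute_chained_forest <- function(x, seed = 1, max_iter = 10,
                                  num_trees = 100, mtry = NULL,
                                  min_node = 5, tol = 1e-4) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 columns", call. = FALSE)
  n_miss <- colSums(is.na(x))
  if (any(n_miss == nrow(x)))
    stop("fully missing column: ",
         paste(colnames(x)[n_miss == nrow(x)], collapse = ", "),
         call. = FALSE)
  if (all(n_miss == 0)) {
    attr(x, "iterations") <- 0L
    attr(x, "oob_trace") <- numeric()
    return(x)
  }
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x) - 1)))

  miss <- is.na(x)
  filled <- x
  for (j in seq_len(ncol(x))) {
    if (n_miss[j] > 0)
      filled[miss[, j], j] <- median(x[, j], na.rm = TRUE)
  }
  visit <- order(n_miss)
  visit <- visit[n_miss[visit] > 0]

  with_seed(seed, {
    prev_oob <- Inf
    trace <- numeric()
    best <- filled
    for (iter in seq_len(max_iter)) {
      total_oob <- 0
      for (j in visit) {
        obs <- !miss[, j]
        fit <- cpp_forest_fit_predict(
          filled[obs, -j, drop = FALSE], filled[obs, j],
          filled[miss[, j], -j, drop = FALSE],
          as.integer(num_trees), as.integer(mtry), as.integer(min_node),
          draw_seed()
        )
        filled[miss[, j], j] <- fit$pred
        # scale OOB error by the column variance so columns are comparable
        total_oob <- total_oob + fit$oob_mse / max(var(x[obs, j]), 1e-12)
      }
      trace <- c(trace, total_oob)
      if (total_oob < prev_oob) best <- filled
      if (prev_oob - total_oob < tol * max(prev_oob, 1e-12)) break
      prev_oob <- total_oob
    }
    attr(best, "iterations") <- length(trace)
    attr(best, "oob_trace") <- trace
    best
  })
}

#' Log-transform, scale and center a matrix
#'
#' Per column: natural log when all values are positive, otherwise a shifted
#' log `log(x - min(x) + 1)` (clinical variables such as base excess can be
#' <= 0); then centered to mean 0 and scaled to SD 1.
#'
#' @param x numeric matrix with no missing cells.
#' @param log_transform apply the log step (default TRUE).
#' @return transformed matrix (each column mean 0, SD 1).
#' @export
transform_log_scale_center <- function(x, log_transform = TRUE) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("matrix contains missing cells", call. = FALSE)
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    if (log_transform) {
      col <- if (min(col) > 0) log(col) else log(col - min(col) + 1)
    }
    s <- sd(col)
    if (!is.finite(s) || s == 0)
      stop("degenerate variable (zero variance after log): column ",
           colnames(x)[j] %||% j, call. = FALSE)
    out[, j] <- (col - mean(col)) / s
  }
  out
}

# Externally studentized residuals of a least-squares fit of y on X
# (intercept added), plus the residual df used for their t reference.
studentized_residuals <- function(X, y) {
  X1 <- cbind(1, X)
  qr_x <- qr(X1)
  res <- qr.resid(qr_x, y)
  h <- rowSums(qr.Q(qr_x)^2)
  p <- qr_x$rank
  n <- length(y)
  s2 <- sum(res^2) / (n - p)
  ti <- res / sqrt(s2 * pmax(1 - h, 1e-12))
  # external (leave-one-out) studentization
  t_ext <- ti * sqrt((n - p - 1) / pmax(n - p - ti^2, 1e-12))
  list(t = t_ext, df = n - p - 1)
}

#' Bonferroni outlier removal
#'
#' For each model variable a linear model of that variable on the remaining
#' ones is fitted; patients whose externally studentized residual has a
#' Bonferroni-adjusted two-sided p-value below `alpha` (adjustment by the
#' number of rows) are flagged. The union of flags over variables is removed
#' and the test repeated up to `max_rounds` times.
#'
#' @param x numeric matrix, rows named by patient id (>= ncol + 2 rows).
#' @param alpha significance level after Bonferroni adjustment
#'   (default 0.05).
#' @param max_rounds maximal removal rounds (default 1).
#' @return list `matrix` (rows kept) and `removed_ids`.
#' @export
bonferroni_outlier_removal <- function(x, alpha = 0.05, max_rounds = 1) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  removed <- character()
  for (round in seq_len(max_rounds)) {
    n <- nrow(x)
    if (n < ncol(x) + 2)
      stop("too few rows for the outlier test (need >= ncol + 2)",
           call. = FALSE)
    flag <- rep(FALSE, n)
    for (j in seq_len(ncol(x))) {
      st <- studentized_residuals(x[, -j, drop = FALSE], x[, j])
      p_adj <- pmin(1, n * 2 * pt(-abs(st$t), df = st$df))
      flag <- flag | (p_adj < alpha)
    }
    if (!any(flag)) break
    removed <- c(removed, rownames(x)[flag])
    x <- x[!flag, , drop = FALSE]
  }
  list(matrix = x, removed_ids = removed)
}

#' Prepare a model matrix for clustering
#'
#' Runs the fixed preprocessing pipeline for one candidate model:
#' missingness filter (> `threshold` missing among the model variables),
#' chained random-forest imputation, log/scale/center transform, and
#' Bonferroni outlier removal.
#'
#' @param cohort a [cohort_table()].
#' @param model_vars the model's variables.
#' @param threshold missingness threshold (default 0.5).
#' @param seed imputation seed.
#' @param alpha,max_rounds outlier-test parameters.
#' @param num_trees,max_iter forest-imputation parameters.
#' @return a `prepared_matrix` list: `ids`, `x` (z-scored matrix, rows named
#'   by patient id), `removed` (data.frame `patient_id`, `reason`).
#' @export
prepare_matrix <- function(cohort, model_vars, threshold = 0.5, seed = 1,
                           alpha = 0.05, max_rounds = 1, num_trees = 100,
                           max_iter = 10) {
  fm <- filter_missingness(cohort, model_vars, threshold)
  removed <- data.frame(patient_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  if (nrow(fm$removed) > 0)
    removed <- rbind(removed,
                     data.frame(patient_id = fm$removed$patient_id,
                                reason = "missingness",
                                stringsAsFactors = FALSE))
  x <- as.matrix(as.data.frame(fm$retained)[, model_vars, drop = FALSE])
  rownames(x) <- fm$retained$patient_id
  x <- impute_chained_forest(x, seed = seed, num_trees = num_trees,
                             max_iter = max_iter)
  x <- transform_log_scale_center(x)
  outl <- bonferroni_outlier_removal(x, alpha = alpha,
                                     max_rounds = max_rounds)
  if (length(outl$removed_ids) > 0) {
    removed <- rbind(removed,
                     data.frame(patient_id = outl$removed_ids,
                                reason = "outlier", stringsAsFactors = FALSE))
    # re-standardize after removal so the matrix contract (mean 0, SD 1)
    # holds on the rows actually clustered
    outl$matrix <- scale(outl$matrix)
    attr(outl$matrix, "scaled:center") <- NULL
    attr(outl$matrix, "scaled:scale") <- NULL
  }
  structure(list(ids = rownames(outl$matrix), x = outl$matrix,
                 removed = removed),
            class = "prepared_matrix")
}
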