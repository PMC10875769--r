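`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Rounding used for all Table 1-style percentage rendering: ties go away
#' from zero (so 54.05 -> 54.1), unlike base [round()] which rounds half to
#' even.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(54.05, 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count, rounded to one decimal
#'
#' `format_percent(66, 122)` returns `54.1`, reproducing the rendering used
#' in trial characteristic tables (count/denominator, half-away-from-zero to
#' one decimal).
#'
#' @param count event count.
#' @param n denominator, must be positive.
#' @param digits decimal places (default 1).
#' @return numeric percentage.
#' @export
format_percent <- function(count, n, digits = 1) {
  stopifnot(all(n > 0), all(count >= 0))
  round_half_up(100 * count / n, digits)
}

#' Render a "count (percent%)" table cell
#'
#' @param count event count.
#' @param n denominator.
#' @return character, e.g. `"66 (54.1%)"`.
#' @export
format_count_percent <- function(count, n) {
  sprintf("%d (%s%%)", count,
          formatC(format_percent(count, n), format = "f", digits = 1))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards. seed = NULL uses the ambient
# stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Draw an integer seed for a downstream deterministic routine from the
# current RNG stream (keeps everything reproducible from one top seed).
draw_seed <- function() sample.int(.Machine$integer.max, 1L)

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to relabeling), ~0 for independent ones. Used as
#' the phenotype-recovery metric on synthetic cohorts.
#'
#' @param a,b integer/factor label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

stop_stage <- function(stage, msg, call. = FALSE) {
  stop(sprintf("[%s] %s", stage, msg), call. = call.)
}
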