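test_that("quartile assignment follows ranks with ties to the lower quartile", {
  expect_identical(assign_quartiles(1:8), rep(1:4, each = 2))
  expect_error(assign_quartiles(rep(5, 20)), "distinct")
  expect_error(assign_quartiles(c(1, 2, 3)), "8 non-missing")

  # missing values stay unassigned
  q <- assign_quartiles(c(1:8, NA))
  expect_true(is.na(q[9]))

  # oracle: brute-force rank computation on tied data
  set.seed(7)
  for (i in 1:50) {
    x <- sample(1:6, 40, replace = TRUE)  # heavy ties
    q <- assign_quartiles(x)
    r <- rank(x, ties.method = "min")
    oracle <- floor(4 * (r - 1) / length(x)) + 1
    expect_identical(q, as.integer(oracle))
    # all tied values share one quartile
    for (v in unique(x)) expect_length(unique(q[x == v]), 1)
  }
})

test_that("quartile risk ratios match a hand-counted 16-patient fixture", {
  # 16 patients, variable = 1..16 -> quartiles of 4; alternate arms
  values <- 1:16
  arm <- rep(c("active", "placebo"), 8)
  # events chosen so Q1: CIe 1/2, CIu 1/2; Q2: CIe 1/2, CIu 1 (RR 0.5);
  # Q3: CIe 0/2, CIu 1/2 (RR 0); Q4: CIe 1/2, CIu 0 (undefined)
  event <- c(TRUE, FALSE, FALSE, TRUE,   # Q1: a,p,a,p
             TRUE, TRUE, FALSE, TRUE,    # Q2
             FALSE, TRUE, FALSE, FALSE,  # Q3
             TRUE, FALSE, FALSE, FALSE)  # Q4
  pf <- quartile_risk_ratios(values, arm, event, variable = "toy")
  tab <- pf$table
  expect_equal(tab$n_e, rep(2L, 4))
  expect_equal(tab$n_u, rep(2L, 4))
  expect_equal(tab$ci_e, c(0.5, 0.5, 0, 0.5))
  expect_equal(tab$ci_u, c(0.5, 1, 0.5, 0))
  expect_equal(tab$rr, c(1, 0.5, 0, NA))
  expect_identical(tab$rr_defined, c(TRUE, TRUE, TRUE, FALSE))
  expect_length(pf$boundaries, 3)

  # single-quartile arithmetic example: 4/10 vs 5/10 -> RR 0.8
  v2 <- c(rep(1, 20), rep(2, 20), rep(3, 20), rep(4, 20))
  arm2 <- rep(c("active", "placebo"), 40)
  ev2 <- rep(FALSE, 80)
  ev2[which(v2 == 1 & arm2 == "active")[1:4]] <- TRUE
  ev2[which(v2 == 1 & arm2 == "placebo")[1:5]] <- TRUE
  pf2 <- quartile_risk_ratios(v2, arm2, ev2)
  expect_equal(pf2$table$rr[1], 0.8)

  expect_error(quartile_risk_ratios(values, rep("active", 16), event),
               "both arms")
})

test_that("monotone screen agrees with the stated examples", {
  r1 <- screen_monotone(c(1.2, 1.0, 0.8, 0.9))
  expect_true(r1$pass)
  expect_equal(r1$runs$start_q, 1)
  expect_equal(r1$runs$end_q, 3)
  expect_equal(r1$runs$direction, "decreasing")

  expect_false(screen_monotone(c(0.9, 1.1, 0.8, 1.2))$pass)

  r3 <- screen_monotone(c(2.0, 1.5, 1.0, 0.5))
  expect_true(r3$pass)
  expect_equal(r3$runs$start_q, 1)
  expect_equal(r3$runs$end_q, 4)

  # undefined RR breaks the run
  expect_false(screen_monotone(c(2.0, NA, 1.0, 0.5))$pass)

  # plateau: fails strict, passes non-strict
  flat <- c(1.2, 1.0, 1.0, 0.8)
  expect_false(screen_monotone(flat, strict = TRUE)$pass)
  expect_true(screen_monotone(flat, strict = FALSE)$pass)

  # direction filter
  up <- c(0.5, 1.0, 1.5, 2.0)
  expect_true(screen_monotone(up, direction = "increasing")$pass)
  expect_false(screen_monotone(up, direction = "decreasing")$pass)
})

test_that("monotone screen matches window enumeration on random quadruples", {
  # independent oracle: explicitly check every 3- and 4-quartile window
  oracle <- function(rr) {
    ok <- function(w) {
      if (any(is.na(w))) return(FALSE)
      all(diff(w) > 0) || all(diff(w) < 0)
    }
    ok(rr[1:3]) || ok(rr[2:4]) || ok(rr[1:4])
  }
  set.seed(123)
  quads <- matrix(round(runif(40000, 0.4, 1.6), 2), ncol = 4)
  na_rows <- which(runif(10000) < 0.1)
  quads[cbind(na_rows, sample(4, length(na_rows), TRUE))] <- NA
  got <- apply(quads, 1, function(rr) screen_monotone(rr)$pass)
  want <- apply(quads, 1, oracle)
  mism <- which(got != want)
  expect_identical(mism, integer(0),
                   label = paste("mismatching quadruples at rows",
                                 paste(head(mism), collapse = ",")))
})

test_that("slopes are closed-form OLS and ranked by max steepness", {
  pf <- structure(list(variable = "v",
                       table = data.frame(rr = c(1.5, 1.0, 0.5, NA),
                                          rr_defined = c(TRUE, TRUE, TRUE,
                                                         FALSE))),
                  class = "quartile_risk_profile")
  expect_warning(slope_rank(list(pf), top_k = 15), "top_k")
  suppressWarnings(res <- slope_rank(list(pf), top_k = 15))
  expect_equal(res$slopes$slope, -0.5)

  # full 4-quartile run: two slopes (Q1-Q3 and Q2-Q4)
  pf4 <- structure(list(variable = "v4",
                        table = data.frame(rr = c(2.0, 1.5, 1.0, 0.5),
                                           rr_defined = rep(TRUE, 4))),
                   class = "quartile_risk_profile")
  suppressWarnings(res4 <- slope_rank(list(pf4)))
  expect_equal(nrow(res4$slopes), 2)
  expect_equal(res4$slopes$slope, c(-0.5, -0.5))
  expect_equal(res4$ranking$steepness, 0.5)

  # slope of 3 equally spaced points = (RR3 - RR1) / 2
  set.seed(5)
  for (i in 1:25) {
    rr <- sort(runif(3), decreasing = sample(c(TRUE, FALSE), 1))
    pfr <- structure(list(variable = "r",
                          table = data.frame(rr = c(rr, NA),
                                             rr_defined = c(TRUE, TRUE, TRUE,
                                                            FALSE))),
                     class = "quartile_risk_profile")
    suppressWarnings(out <- slope_rank(list(pfr)))
    if (nrow(out$slopes) > 0)
      expect_equal(out$slopes$slope[1], (rr[3] - rr[1]) / 2)
  }

  expect_error(slope_rank(list()), "no profiles")
})

test_that("32 passing profiles are cut to the top 15", {
  set.seed(11)
  profiles <- lapply(1:32, function(i) {
    base <- runif(1, 0.8, 1.2)
    step <- runif(1, 0.05, 0.3) * sample(c(-1, 1), 1)
    structure(list(variable = sprintf("v%02d", i),
                   table = data.frame(rr = base + step * (0:3),
                                      rr_defined = rep(TRUE, 4))),
              class = "quartile_risk_profile")
  })
  res <- slope_rank(profiles, top_k = 15)
  expect_length(res$selected, 15)
  expect_equal(nrow(res$ranking), 32)
  # ranking really is by descending steepness
  expect_true(all(diff(res$ranking$steepness) <= 0))
})

test_that("negating a variable flips run direction, preserves steepness", {
  sim <- simulate_cohort(synthetic_config(n_patients = 300, missing_rate = 0,
                                          seed = 13))
  oc <- derive_make90(sim$cohort)
  v <- sim$cohort$lactate
  pf <- quartile_risk_ratios(v, sim$cohort$arm, oc$event, "lactate")
  pf_neg <- quartile_risk_ratios(-v, sim$cohort$arm, oc$event, "lactate_neg")
  s <- screen_monotone(pf); s_neg <- screen_monotone(pf_neg)
  expect_identical(s$pass, s_neg$pass)
  if (s$pass) {
    suppressWarnings({
      a <- slope_rank(list(pf)); b <- slope_rank(list(pf_neg))
    })
    expect_equal(a$ranking$steepness, b$ranking$steepness, tolerance = 1e-12)
    expect_equal(a$ranking$slope, -b$ranking$slope, tolerance = 1e-12)
  }
})
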