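test_that("model_spec validates its fields", {
  sp <- model_spec(c("a", "b"), "pam", 2)
  expect_s3_class(sp, "model_spec")
  expect_error(model_spec(character(), "kmeans"), "non-empty")
  expect_error(model_spec(c("a", "a"), "kmeans"), "unique")
  expect_error(model_spec("a", "kmeans", k = 1), ">= 2")
  expect_error(model_spec("a", "ward"), "arg")
})

test_that("k-means recovers separated blobs and minimizes WSS", {
  two <- matrix(c(0, 0, 10, 10), 2, byrow = TRUE)
  lab2 <- kmeans_fit(two, 2, seed = 1)
  expect_setequal(as.integer(lab2), 1:2)

  blobs <- make_blobs(c(20, 20), centers = c(0, 10), seed = 4)
  lab <- kmeans_fit(blobs$x, 2, seed = 2)
  expect_equal(adjusted_rand_index(lab, blobs$labels), 1)

  # converged objective never exceeds the single-iteration objective
  w1 <- attr(kmeans_fit(blobs$x, 2, seed = 9, n_init = 1, max_iter = 1),
             "wss")
  wc <- attr(kmeans_fit(blobs$x, 2, seed = 9, n_init = 1, max_iter = 100),
             "wss")
  expect_lte(wc, w1 + 1e-9)

  # same objective as stats::kmeans on easy data with many restarts
  set.seed(31)
  y <- make_blobs(c(15, 15, 15), centers = c(0, 5, 10), seed = 31)$x
  ours <- attr(kmeans_fit(y, 3, seed = 1, n_init = 25), "wss")
  ref <- stats::kmeans(y, 3, nstart = 25)$tot.withinss
  expect_equal(ours, ref, tolerance = 1e-6)

  expect_error(kmeans_fit(two, 3), "k exceeds")
})

test_that("PAM satisfies its algorithmic contracts", {
  blobs <- make_blobs(c(6, 6), centers = c(0, 10), seed = 12)
  # k = n: every point its own medoid, cost 0
  full <- pam_fit(blobs$x, k = nrow(blobs$x))
  expect_equal(full$cost, 0)
  expect_setequal(full$medoids, seq_len(nrow(blobs$x)))

  # two separated blobs: one medoid per blob
  fit <- pam_fit(blobs$x, k = 2)
  expect_setequal(c(fit$medoids[1] <= 6, fit$medoids[2] <= 6),
                  c(TRUE, FALSE))
  expect_equal(adjusted_rand_index(fit$labels, blobs$labels), 1)

  # SWAP cost is non-increasing step by step
  set.seed(55)
  z <- matrix(rnorm(240), ncol = 2)
  tr <- pam_fit(z, k = 4, trace_cost = TRUE)$cost_trace
  expect_true(all(diff(tr) <= 1e-9))
})

test_that("PAM matches exhaustive medoid search on small instances", {
  # separated instances: BUILD+SWAP attains the global optimum
  set.seed(77)
  for (i in 1:12) {
    k <- sample(2:3, 1)
    n_per <- sample(3:4, k, replace = TRUE)
    x <- do.call(rbind, lapply(seq_len(k), function(c) {
      matrix(rnorm(n_per[c] * 2, mean = 6 * c, sd = 0.8), ncol = 2)
    }))
    fit <- pam_fit(x, k = k)
    expect_equal(fit$cost, exhaustive_medoid_cost(x, k), tolerance = 1e-9,
                 label = sprintf("separated instance %d (n=%d, k=%d)",
                                 i, nrow(x), k))
  }

  # arbitrary instances: PAM is a local search, so the honest oracle is the
  # canonical implementation (cluster::pam stops at the same optima; see
  # decisions notes for the one shared local optimum among these draws)
  skip_if_not_installed("cluster")
  set.seed(77)
  for (i in 1:20) {
    n <- sample(8:12, 1)
    k <- sample(2:3, 1)
    x <- matrix(rnorm(n * 2), ncol = 2)
    fit <- pam_fit(x, k = k)
    D <- as.matrix(dist(x))
    ref <- cluster::pam(dist(x), k)
    ref_cost <- sum(apply(D[, ref$id.med, drop = FALSE], 1, min))
    expect_equal(fit$cost, ref_cost, tolerance = 1e-9,
                 label = sprintf("random instance %d (n=%d, k=%d)", i, n, k))
  }
})

test_that("consensus clustering hits the perfect-separation limit", {
  # two exact point clouds of duplicated rows
  x <- rbind(matrix(rep(c(0, 0), each = 12), ncol = 2),
             matrix(rep(c(8, 8), each = 10), ncol = 2))
  x <- x + 0  # plain doubles
  rownames(x) <- sprintf("P%02d", seq_len(nrow(x)))
  truth <- rep(1:2, c(12, 10))
  for (alg in c("kmeans", "pam")) {
    cr <- consensus_cluster(x, model_spec(c("a", "b"), alg, 2), reps = 60,
                            p_item = 0.8, seed = 10, n_init = 2)
    expect_equal(unname(cr$cluster_consensus), c(1, 1))
    expect_equal(adjusted_rand_index(cr$labels, truth), 1)
    cm <- cr$consensus_matrix
    expect_true(all(cm[1:12, 13:22] == 0))
    within <- cm[1:12, 1:12]
    expect_true(all(within[upper.tri(within)] == 1))
  }
})

test_that("consensus matrix is symmetric, deterministic, and in [0,1]", {
  blobs <- make_blobs(c(15, 15), centers = c(0, 1.2), seed = 9)
  sp <- model_spec(c("a", "b"), "kmeans", 2)
  a <- consensus_cluster(blobs$x, sp, reps = 40, seed = 3, n_init = 2)
  b <- consensus_cluster(blobs$x, sp, reps = 40, seed = 3, n_init = 2)
  expect_identical(a$consensus_matrix, b$consensus_matrix)
  expect_identical(a$labels, b$labels)
  expect_true(isSymmetric(a$consensus_matrix))
  expect_true(all(a$consensus_matrix >= 0 & a$consensus_matrix <= 1))
  expect_true(all(diag(a$consensus_matrix) == 1))

  c2 <- consensus_cluster(blobs$x, sp, reps = 40, seed = 4, n_init = 2)
  expect_false(identical(a$consensus_matrix, c2$consensus_matrix))
})

test_that("p_item = 1 with a deterministic clusterer gives a 0/1 matrix", {
  blobs <- make_blobs(c(10, 10), centers = c(0, 6), seed = 2)
  cr <- consensus_cluster(blobs$x, model_spec(c("a", "b"), "pam", 2),
                          reps = 10, p_item = 1, seed = 1)
  expect_true(all(cr$consensus_matrix %in% c(0, 1)))
})

test_that("row permutation permutes the consensus matrix conjugately", {
  # deterministic case (PAM, no subsampling) so the check is exact
  blobs <- make_blobs(c(8, 8), centers = c(0, 5), seed = 6)
  sp <- model_spec(c("a", "b"), "pam", 2)
  cr <- consensus_cluster(blobs$x, sp, reps = 5, p_item = 1, seed = 1)
  perm <- sample(nrow(blobs$x))
  crp <- consensus_cluster(blobs$x[perm, ], sp, reps = 5, p_item = 1,
                           seed = 1)
  expect_equal(unname(crp$consensus_matrix),
               unname(cr$consensus_matrix[perm, perm]))
})

test_that("singletons and insufficient sampling are handled explicitly", {
  # an isolated far point becomes a singleton cluster with consensus 1
  x <- rbind(matrix(rnorm(40, sd = 0.1), ncol = 2), c(50, 50))
  rownames(x) <- sprintf("S%02d", 1:21)
  cr <- consensus_cluster(x, model_spec(c("a", "b"), "pam", 2), reps = 30,
                          p_item = 1, seed = 8)
  sizes <- table(cr$labels)
  expect_true(any(sizes == 1))
  expect_equal(unname(cr$cluster_consensus[which(sizes == 1)]), 1)
  expect_true(any(grepl("singleton", cr$notes)))

  expect_error(
    consensus_cluster(matrix(rnorm(80), ncol = 2),
                      model_spec(c("a", "b"), "kmeans", 2),
                      reps = 2, p_item = 0.5, seed = 1, n_init = 1),
    "insufficient reps"
  )
})

test_that("consensus results round-trip to CSV", {
  blobs <- make_blobs(c(8, 8), centers = c(0, 6), seed = 3)
  cr <- consensus_cluster(blobs$x, model_spec(c("a", "b"), "pam", 2),
                          reps = 10, p_item = 1, seed = 1)
  stem <- file.path(withr::local_tempdir(), "cc")
  write_consensus(cr, stem)
  mat <- as.matrix(read.csv(paste0(stem, "_consensus.csv"), row.names = 1))
  expect_equal(unname(mat), unname(cr$consensus_matrix))
  lab <- read.csv(paste0(stem, "_labels.csv"))
  expect_equal(lab$phenotype, unname(cr$labels))
})

test_that("CDF-based k selection applies the threshold rule", {
  # plain area sequences exercise the rule directly
  expect_warning(
    res <- cdf_k_selection(list(0.50, 0.52, 0.53, 0.54), threshold = 0.1),
    "falling back"
  )
  expect_equal(res$k, 2L)

  res3 <- cdf_k_selection(list(0.30, 0.45, 0.46, 0.47), threshold = 0.1)
  expect_equal(res3$k, 3L)  # only k=3 exceeds a 10% relative increase

  res5 <- cdf_k_selection(list(0.30, 0.40, 0.50, 0.60), threshold = 0.1)
  expect_equal(res5$k, 5L)  # largest k above threshold wins

  expect_error(cdf_k_selection(list(0.5)), "at least 2")
})

test_that("CDF k-selection on data: correct at k=3, over-selects otherwise", {
  # The consensus-CDF area grows mechanically with k (area = 1 - expected
  # co-clustering mass), so the literal largest-k-above-threshold rule picks
  # the true k only when the k-1 -> k jump dominates; on clean 2-cluster and
  # noise data it over-selects (see the package vignette). These pins record
  # the honestly computed behaviour.
  scan <- function(x, ks = 2:5) {
    lapply(ks, function(k) {
      consensus_cluster(x, model_spec(letters[1:ncol(x)], "kmeans", k),
                        reps = 60, seed = 100 + k, n_init = 3)
    })
  }
  set.seed(1)
  three <- rbind(matrix(rnorm(80, 0), ncol = 2),
                 matrix(rnorm(80, 5), ncol = 2),
                 matrix(rnorm(80, 10), ncol = 2))
  expect_equal(cdf_k_selection(scan(three))$k, 3L)

  two <- rbind(matrix(rnorm(120, 0), ncol = 2),
               matrix(rnorm(80, 5), ncol = 2))
  sel2 <- cdf_k_selection(scan(two))
  expect_gte(sel2$k, 2L)          # known limitation: not pinned to 2
  expect_gt(sel2$deltas[["3"]], 0.1)  # the mechanism behind over-selection
})
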