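# From-scratch consensus clustering: Lloyd k-means and PAM (BUILD + SWAP)
# cluster subsamples; consensus(i,j) = co-clustered / co-sampled; final
# labels from average-linkage hierarchical clustering of 1 - consensus;
# per-cluster consensus scores and CDF areas for k selection.

#' Specify a candidate clustering model
#'
#' @param variables ordered, unique variable names.
#' @param algorithm `"kmeans"` or `"pam"`.
#' @param k number of clusters (>= 2).
#' @return a `model_spec`.
#' @export
model_spec <- function(variables, algorithm = c("kmeans", "pam"), k = 2) {
  algorithm <- match.arg(algorithm)
  if (length(variables) == 0) stop("variables must be non-empty", call. = FALSE)
  if (anyDuplicated(variables)) stop("variables must be unique", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  structure(list(variables = as.character(variables), algorithm = algorithm,
                 k = as.integer(k)),
            class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  sprintf("%s/k=%d[%s]", x$algorithm, x$k, paste(x$variables, collapse = ","))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' k-means clustering (Lloyd's algorithm with random restarts)
#'
#' Runs Lloyd's algorithm from `n_init` random initial center sets (k
#' distinct data rows each) and returns the best-objective solution. The
#' within-cluster sum of squares is non-increasing over iterations;
#' deterministic per seed.
#'
#' @param x numeric matrix (rows = items).
#' @param k number of clusters (<= nrow(x)).
#' @param seed RNG seed; `NULL` continues the ambient stream.
#' @param n_init random restarts (default 10).
#' @param max_iter Lloyd iterations per restart (default 100).
#' @return integer label vector with attributes `wss` and `centers`.
#' @export
kmeans_fit <- function(x, k, seed = NULL, n_init = 10, max_iter = 100) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k exceeds the number of rows", call. = FALSE)
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      init <- x[sample.int(nrow(x), k), , drop = FALSE]
      fit <- cpp_kmeans_lloyd(x, init, as.integer(max_iter))
      if (is.null(best) || fit$wss < best$wss) best <- fit
    }
    structure(best$labels, wss = best$wss, centers = best$centers)
  })
}

#' PAM clustering (BUILD + SWAP)
#'
#' Partitioning Around Medoids on Euclidean dissimilarities: the BUILD phase
#' greedily seeds k medoids, then SWAP applies the best strictly
#' cost-reducing (medoid, non-medoid) exchange until none exists. The total
#' dissimilarity to the nearest medoid is non-increasing per SWAP step.
#' Deterministic (ties broken by lowest index).
#'
#' @param x numeric matrix, or `NULL` when `diss` is given.
#' @param k number of clusters.
#' @param diss optional precomputed full dissimilarity matrix.
#' @param idx optional row subset (1-based into `diss`) to cluster.
#' @param max_iter maximal SWAP steps (default 200).
#' @param trace_cost record the cost after every SWAP step?
#' @return list `labels`, `medoids` (indices into the clustered rows),
#'   `cost`, `cost_trace`.
#' @export
pam_fit <- function(x = NULL, k, diss = NULL, idx = NULL, max_iter = 200,
                    trace_cost = FALSE) {
  if (is.null(diss)) {
    stopifnot(!is.null(x))
    diss <- cpp_euclidean(as.matrix(x))
  }
  if (is.null(idx)) idx <- seq_len(nrow(diss))
  if (k > length(idx)) stop("k exceeds the number of rows", call. = FALSE)
  if (max(idx) > nrow(diss) || min(idx) < 1)
    stop("idx out of range for the dissimilarity matrix", call. = FALSE)
  fit <- cpp_pam(diss, as.integer(idx), as.integer(k), as.integer(max_iter),
                 isTRUE(trace_cost))
  fit
}

run_clusterer <- function(algorithm, x, k, diss = NULL, idx = NULL,
                          n_init = 10, max_iter = 100) {
  if (algorithm == "kmeans") {
    sub <- if (is.null(idx)) x else x[idx, , drop = FALSE]
    as.integer(kmeans_fit(sub, k, seed = NULL, n_init = n_init,
                          max_iter = max_iter))
  } else {
    pam_fit(x = NULL, k = k, diss = diss, idx = idx)$labels
  }
}

#' Consensus clustering
#'
#' `reps` subsamples of `ceiling(p_item * n)` items are each clustered with
#' the spec's algorithm at its k; consensus(i, j) is the fraction of
#' co-samplings in which i and j landed in the same cluster (pairs never
#' co-sampled get 0 and are logged). Final labels come from average-linkage
#' hierarchical clustering of `1 - consensus` cut at k; the cluster-consensus
#' score of a cluster is the mean pairwise consensus among its members
#' (singletons score 1, logged).
#'
#' @param x prepared numeric matrix (rows = patients, z-scored).
#' @param spec a [model_spec()].
#' @param reps number of subsampling repetitions (default 1000).
#' @param p_item item subsampling fraction (default 0.8).
#' @param seed RNG seed.
#' @param n_init,max_iter passed to the k-means inner clusterer.
#' @return a `consensus_result`: `consensus_matrix`, `labels` (named by
#'   rownames of `x` when present), `cluster_consensus`, `cdf_area`, `spec`,
#'   `notes`.
#' @export
consensus_cluster <- function(x, spec, reps = 1000, p_item = 0.8,
                              seed = NULL, n_init = 10, max_iter = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (reps < 2) stop("reps must be >= 2", call. = FALSE)
  if (p_item <= 0 || p_item > 1) stop("p_item must lie in (0, 1]", call. = FALSE)
  if (spec$k > n) stop("k exceeds the number of rows", call. = FALSE)
  m <- ceiling(p_item * n)

  conn <- matrix(0L, n, n)
  cosample <- matrix(0L, n, n)
  diss <- if (spec$algorithm == "pam") cpp_euclidean(x) else NULL

  with_seed(seed, {
    if (spec$algorithm == "pam") {
      # PAM uses no RNG, so all subsamples can be drawn up front and the
      # whole rep loop run in compiled code
      idxmat <- vapply(seq_len(reps), function(r) {
        if (m == n) seq_len(n) else sort(sample.int(n, m))
      }, integer(m))
      cpp_consensus_pam(diss, idxmat, spec$k, as.integer(max_iter),
                        conn, cosample)
    } else {
      for (r in seq_len(reps)) {
        idx <- if (m == n) seq_len(n) else sort(sample.int(n, m))
        labels <- run_clusterer(spec$algorithm, x, spec$k, diss = diss,
                                idx = idx, n_init = n_init,
                                max_iter = max_iter)
        cpp_consensus_accumulate(conn, cosample, as.integer(idx),
                                 as.integer(labels))
      }
    }

    upper <- upper.tri(conn)
    unseen <- sum(cosample[upper] == 0)
    n_pairs <- sum(upper)
    notes <- character()
    if (unseen > 0) {
      if (unseen / n_pairs > 0.01)
        stop("insufficient reps: ", unseen, " of ", n_pairs,
             " pairs never co-sampled", call. = FALSE)
      notes <- c(notes, sprintf("%d pair(s) never co-sampled; consensus 0",
                                unseen))
    }
    consensus <- matrix(0, n, n)
    seen <- cosample > 0
    consensus[seen] <- conn[seen] / cosample[seen]
    consensus <- consensus + t(consensus)
    diag(consensus) <- 1
    dimnames(consensus) <- list(rownames(x), rownames(x))

    hc <- hclust(as.dist(1 - consensus), method = "average")
    labels <- cutree(hc, k = spec$k)

    cluster_consensus <- vapply(seq_len(spec$k), function(cl) {
      members <- which(labels == cl)
      if (length(members) < 2) return(1)
      sub <- consensus[members, members]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
    singletons <- which(table(factor(labels, levels = seq_len(spec$k))) == 1)
    if (length(singletons) > 0)
      notes <- c(notes, sprintf("singleton cluster(s): %s (consensus 1)",
                                paste(singletons, collapse = ",")))

    vals <- consensus[upper]
    # exact area under the empirical CDF of consensus values on [0, 1]
    cdf_area <- 1 - mean(vals)

    structure(list(consensus_matrix = consensus, labels = labels,
                   cluster_consensus = cluster_consensus,
                   cdf_area = cdf_area, spec = spec, reps = reps,
                   p_item = p_item, notes = notes),
              class = "consensus_result")
  })
}

#' Write a consensus result to CSV
#'
#' Writes the square consensus matrix (`<stem>_consensus.csv`, with row
#' names) and the final labels (`<stem>_labels.csv`, columns `patient_id`,
#' `phenotype`).
#'
#' @param result a [consensus_cluster()] result.
#' @param stem output path stem.
#' @return the two paths, invisibly.
#' @export
write_consensus <- function(result, stem) {
  stopifnot(inherits(result, "consensus_result"))
  p1 <- paste0(stem, "_consensus.csv")
  p2 <- paste0(stem, "_labels.csv")
  write.csv(result$consensus_matrix, p1, row.names = TRUE)
  ids <- names(result$labels) %||% as.character(seq_along(result$labels))
  write.csv(data.frame(patient_id = ids,
                       phenotype = unname(result$labels)),
            p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Choose k from consensus-CDF areas
#'
#' Given consensus results for consecutive k starting at 2, computes the
#' relative change in the area under the consensus-value CDF as k increases
#' and returns the largest k whose relative increase exceeds `threshold`
#' (falling back to k = 2, with a warning, when none does).
#'
#' @param results list of [consensus_cluster()] results (or plain numeric
#'   CDF areas) for k = 2, 3, ... in order.
#' @param threshold relative-increase threshold (default 0.1).
#' @return list `k` (chosen), `areas`, `deltas` (named by k).
#' @export
cdf_k_selection <- function(results, threshold = 0.1) {
  if (length(results) < 2) stop("need results for at least 2 values of k",
                                call. = FALSE)
  areas <- vapply(results, function(r) {
    if (inherits(r, "consensus_result")) r$cdf_area else as.numeric(r)
  }, numeric(1))
  ks <- seq(2, length.out = length(areas))
  names(areas) <- ks
  deltas <- c(NA_real_, diff(areas) / areas[-length(areas)])
  names(deltas) <- ks
  exceed <- ks[-1][deltas[-1] > threshold]
  if (length(exceed) == 0) {
    warning("no k shows a relative CDF-area increase above ", threshold,
            "; falling back to k = 2", call. = FALSE)
    k <- 2L
  } else {
    k <- max(exceed)
  }
  list(k = as.integer(k), areas = areas, deltas = deltas)
}
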