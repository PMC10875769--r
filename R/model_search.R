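# Gated model search: enumerate variable subsets x algorithms x k, cluster
# each candidate, and keep models that pass the cluster-consensus gate
# (> 0.90 for every phenotype) and the efficacy gate (some phenotype with a
# significant log-rank benefit under active treatment); pick the model with
# the strongest separation (smallest benefiting-phenotype p).

#' Enumerate candidate clustering models
#'
#' All variable subsets in the size range, crossed with the algorithms and k
#' values, in a deterministic order (lexicographic by variable names, then
#' algorithm, then k).
#'
#' @param variables candidate variable pool.
#' @param size_range integer pair: smallest and largest subset size
#'   (default c(2, 5)). Size-1 models are excluded unless
#'   `allow_single = TRUE`.
#' @param algorithms clustering algorithms to cross in.
#' @param k_set k values to cross in (default 2).
#' @param allow_single permit single-variable models?
#' @return list of [model_spec()]s.
#' @export
enumerate_models <- function(variables, size_range = c(2, 5),
                             algorithms = c("kmeans", "pam"), k_set = 2,
                             allow_single = FALSE) {
  if (length(variables) == 0) stop("empty variable list", call. = FALSE)
  lo <- size_range[1]; hi <- min(size_range[2], length(variables))
  min_size <- if (allow_single) 1 else 2
  if (lo < min_size || lo > hi)
    stop("size_range must lie within [", min_size, ", ", length(variables),
         "]", call. = FALSE)
  variables <- sort(variables)
  subsets <- list()
  for (sz in lo:hi) {
    cmb <- combn(variables, sz, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  key <- vapply(subsets, paste, "", collapse = ",")
  subsets <- subsets[order(key)]
  specs <- list()
  for (vars in subsets) {
    for (alg in sort(algorithms)) {
      for (k in sort(k_set)) {
        specs[[length(specs) + 1]] <- model_spec(vars, alg, k)
      }
    }
  }
  specs
}

#' Search parameters for model evaluation
#'
#' @param reps consensus repetitions per candidate (default 100 during the
#'   search; rerun the short-list at 1000).
#' @param p_item subsampling fraction.
#' @param n_init k-means restarts per subsample.
#' @param consensus_threshold cluster-consensus gate (default 0.90,
#'   strict >).
#' @param p_threshold efficacy-gate significance level (default 0.05).
#' @param impute_seed,num_trees,max_iter imputation settings.
#' @param alpha,max_rounds outlier-test settings.
#' @param missing_threshold per-patient missingness filter.
#' @return a `search_params` list.
#' @export
search_params <- function(reps = 100, p_item = 0.8, n_init = 3,
                          consensus_threshold = 0.90, p_threshold = 0.05,
                          impute_seed = 1, num_trees = 100, max_iter = 10,
                          alpha = 0.05, max_rounds = 1,
                          missing_threshold = 0.5) {
  structure(list(reps = reps, p_item = p_item, n_init = n_init,
                 consensus_threshold = consensus_threshold,
                 p_threshold = p_threshold, impute_seed = impute_seed,
                 num_trees = num_trees, max_iter = max_iter, alpha = alpha,
                 max_rounds = max_rounds,
                 missing_threshold = missing_threshold),
            class = "search_params")
}

#' Evaluate one candidate model
#'
#' Runs preprocessing and consensus clustering for the spec, then, per
#' phenotype, the active-vs-placebo log-rank test on the MAKE90 event times.
#' The consensus gate requires every phenotype's cluster-consensus score to
#' exceed the threshold; the efficacy gate requires at least one phenotype
#' with log-rank p below threshold AND a lower event incidence in the active
#' arm (benefit, not harm).
#'
#' @param cohort a [cohort_table()].
#' @param outcomes result of [derive_make90()] on `cohort` (matched by
#'   patient id).
#' @param spec a [model_spec()].
#' @param params a [search_params()].
#' @param seed RNG seed for the consensus subsampling.
#' @param prepared optional precomputed [prepare_matrix()] result for the
#'   spec's variables (lets the search share preprocessing across
#'   algorithms).
#' @return a `model_evaluation` list: spec, n_used, cluster_consensus,
#'   gate_consensus, per_phenotype table, gate_efficacy, best_phenotype,
#'   p_best, incidence_gap, labels, removed.
#' @export
evaluate_model <- function(cohort, outcomes, spec, params = search_params(),
                           seed = NULL, prepared = NULL) {
  stopifnot(all(spec$variables %in% names(cohort)))
  if (is.null(prepared))
    prepared <- prepare_matrix(cohort, spec$variables,
                               threshold = params$missing_threshold,
                               seed = params$impute_seed,
                               alpha = params$alpha,
                               max_rounds = params$max_rounds,
                               num_trees = params$num_trees,
                               max_iter = params$max_iter)
  cr <- consensus_cluster(prepared$x, spec, reps = params$reps,
                          p_item = params$p_item, seed = seed,
                          n_init = params$n_init)
  labels <- cr$labels
  ids <- prepared$ids

  gate_consensus <- all(cr$cluster_consensus > params$consensus_threshold)

  oc <- outcomes[match(ids, outcomes$patient_id), , drop = FALSE]
  arm <- cohort$arm[match(ids, cohort$patient_id)]

  per <- data.frame(phenotype = seq_len(spec$k), n_active = NA_integer_,
                    n_placebo = NA_integer_, inc_active = NA_real_,
                    inc_placebo = NA_real_, p_value = NA_real_,
                    benefit = NA, note = "", stringsAsFactors = FALSE)
  for (ph in seq_len(spec$k)) {
    sel <- labels == ph
    a <- oc[sel & arm == "active", , drop = FALSE]
    b <- oc[sel & arm == "placebo", , drop = FALSE]
    per$n_active[ph] <- nrow(a)
    per$n_placebo[ph] <- nrow(b)
    if (nrow(a) < 2 || nrow(b) < 2) {
      per$note[ph] <- "fewer than 2 patients in an arm"
      next
    }
    per$inc_active[ph] <- cumulative_incidence(a, 90)
    per$inc_placebo[ph] <- cumulative_incidence(b, 90)
    lr <- tryCatch(logrank_test(a, b), error = function(e) NULL)
    if (is.null(lr)) {
      per$note[ph] <- "log-rank not computable (no events)"
      next
    }
    per$p_value[ph] <- lr$p_value
    per$benefit[ph] <- per$inc_active[ph] < per$inc_placebo[ph]
  }

  passing <- which(!is.na(per$p_value) & per$p_value < params$p_threshold &
                     per$benefit %in% TRUE)
  gate_efficacy <- length(passing) > 0
  best_phenotype <- if (gate_efficacy) passing[which.min(per$p_value[passing])]
                    else NA_integer_
  p_best <- if (gate_efficacy) per$p_value[best_phenotype] else NA_real_
  incidence_gap <- if (gate_efficacy)
    per$inc_placebo[best_phenotype] - per$inc_active[best_phenotype]
  else NA_real_

  structure(list(spec = spec, n_used = length(ids),
                 cluster_consensus = cr$cluster_consensus,
                 gate_consensus = gate_consensus, per_phenotype = per,
                 gate_efficacy = gate_efficacy,
                 best_phenotype = best_phenotype, p_best = p_best,
                 incidence_gap = incidence_gap,
                 labels = setNames(labels, ids), removed = prepared$removed),
            class = "model_evaluation")
}

#' Select the best passing model
#'
#' Among evaluations passing both gates, minimizes the benefiting
#' phenotype's log-rank p; ties broken by larger absolute incidence
#' difference, then fewer variables, then lexicographic spec order.
#'
#' @param evaluations list of [evaluate_model()] results.
#' @return the winning `model_evaluation`.
#' @export
select_best <- function(evaluations) {
  pass <- Filter(function(e) e$gate_consensus && e$gate_efficacy,
                 evaluations)
  if (length(pass) == 0) stop("no model passes gates", call. = FALSE)
  keys <- data.frame(
    p = vapply(pass, `[[`, 0, "p_best"),
    gap = -abs(vapply(pass, `[[`, 0, "incidence_gap")),
    nvar = vapply(pass, function(e) length(e$spec$variables), 0L),
    spec = vapply(pass, function(e) format(e$spec), "")
  )
  ord <- order(keys$p, keys$gap, keys$nvar, keys$spec)
  pass[[ord[1]]]
}

#' Run the gated model search
#'
#' Enumerates models over the variable pool, evaluates each (sharing
#' preprocessing across algorithms for the same variable subset), and
#' returns all evaluations plus the best passing model (or `NULL` with the
#' reason when none passes). Reproducible bit-for-bit for a given
#' (cohort, params, seed).
#'
#' @param cohort a [cohort_table()].
#' @param outcomes result of [derive_make90()].
#' @param variables variable pool.
#' @param size_range,algorithms,k_set passed to [enumerate_models()].
#' @param params a [search_params()].
#' @param seed top-level RNG seed.
#' @return list `evaluations`, `table` (one row per model), `best`.
#' @export
search_models <- function(cohort, outcomes, variables,
                          size_range = c(2, 5),
                          algorithms = c("kmeans", "pam"), k_set = 2,
                          params = search_params(), seed = 1) {
  specs <- enumerate_models(variables, size_range, algorithms, k_set)
  evaluations <- vector("list", length(specs))
  with_seed(seed, {
    model_seeds <- sample.int(.Machine$integer.max, length(specs))
    prepared_cache <- new.env(parent = emptyenv())
    for (i in seq_along(specs)) {
      spec <- specs[[i]]
      key <- paste(spec$variables, collapse = ",")
      if (!exists(key, envir = prepared_cache)) {
        assign(key,
               prepare_matrix(cohort, spec$variables,
                              threshold = params$missing_threshold,
                              seed = params$impute_seed,
                              alpha = params$alpha,
                              max_rounds = params$max_rounds,
                              num_trees = params$num_trees,
                              max_iter = params$max_iter),
               envir = prepared_cache)
      }
      evaluations[[i]] <- evaluate_model(
        cohort, outcomes, spec, params, seed = model_seeds[i],
        prepared = get(key, envir = prepared_cache)
      )
    }
  })
  tab <- do.call(rbind, lapply(evaluations, function(e) {
    data.frame(spec = format(e$spec),
               algorithm = e$spec$algorithm,
               n_vars = length(e$spec$variables),
               k = e$spec$k,
               n_used = e$n_used,
               min_cluster_consensus = min(e$cluster_consensus),
               gate_consensus = e$gate_consensus,
               gate_efficacy = e$gate_efficacy,
               best_phenotype = e$best_phenotype,
               p_best = e$p_best,
               incidence_gap = e$incidence_gap,
               stringsAsFactors = FALSE)
  }))
  best <- tryCatch(select_best(evaluations), error = function(e) NULL)
  list(evaluations = evaluations, table = tab, best = best)
}
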