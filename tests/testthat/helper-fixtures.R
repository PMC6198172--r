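# Shared fixtures: tiny systems built in code, no stored data.

quick_config <- function(K = 1e10, seed = 1L, n_bootstraps = 10, ...) {
  glv_config(carrying_capacity = K, master_seed = seed,
             n_bootstraps = n_bootstraps, ...)
}

subset_series_head <- function(s, k)
  abundance_series(s$taxa, s$times[1:k], s$P[1:k, , drop = FALSE])

# single taxon, pure logistic growth
logistic_params <- function(r = 0.5, K = 1e4) {
  glv_params("solo", r, matrix(0, 1, 1), K)
}

logistic_closed_form <- function(t, r, K, x0) {
  K * x0 * exp(r * t) / (K + x0 * (exp(r * t) - 1))
}

# two neutral taxa (no interactions, equal growth)
neutral_pair <- function(K = 100) {
  glv_params(c("a", "b"), c(1, 1), matrix(0, 2, 2), K)
}

# hand-built ensemble around given per-model A matrices (for aggregation
# and selection tests that need exact control over model contents)
fake_ensemble <- function(A_list, taxa = c("u", "v"), K = 1e10,
                          bics = NULL, r = NULL) {
  n <- length(taxa)
  cfg <- quick_config(K = K)
  models <- lapply(seq_along(A_list), function(i) {
    A <- A_list[[i]]
    dimnames(A) <- list(taxa, taxa)
    nz <- which(A != 0, arr.ind = TRUE)
    structure(list(
      select_set = active_set(nz[, 1], nz[, 2]),
      params = glv_params(taxa, if (is.null(r)) rep(1, n) else r, A, K),
      rss_full = 1, bic_full = if (is.null(bics)) -10 else bics[i],
      U = 10L, V = n + nrow(nz), bic_trace = numeric(0),
      train_times = 0:4, train_indices = 1:5,
      bootstrap_id = i, rng_seed = i), class = "candidate_model")
  })
  structure(list(models = models, n_requested = length(models),
                 n_failed = 0L,
                 filter_log = data.frame(bootstrap_id = integer(0),
                                         reason = character(0)),
                 taxa = taxa, series = NULL, config = cfg),
            class = "model_ensemble")
}
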