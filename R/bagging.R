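#' Random train/test partition of a time series
#'
#' Draws `round(train_fraction * T)` time points without replacement for
#' training, always including the first time point (it seeds every fitting
#' simulation, so all rounds must share it), and returns both subsets in
#' temporal order. Uses the current RNG stream: seeding before the call
#' makes the partition reproducible.
#'
#' @param series an [abundance_series] with at least 3 time points.
#' @param train_fraction fraction of time points to train on, in (0, 1].
#' @return List with [abundance_series] elements `train` and `test` (the
#'   complement; `NULL` when `train_fraction = 1`) and integer
#'   `train_indices`.
#' @export
partition_series <- function(series, train_fraction = 0.8) {
  stopifnot(inherits(series, "abundance_series"))
  T_ <- n_times(series)
  if (T_ < 3) stop("need at least 3 time points", call. = FALSE)
  m <- round(train_fraction * T_)
  if (m < 2)
    stop("train_fraction ", train_fraction, " keeps fewer than 2 of ",
         T_, " time points", call. = FALSE)
  idx <- if (m >= T_) seq_len(T_)
         else sort(c(1L, sample(2:T_, m - 1L)))
  test_idx <- setdiff(seq_len(T_), idx)
  list(train = subset_times(series, idx),
       test = if (length(test_idx)) subset_times(series, test_idx),
       train_indices = idx)
}

# Deterministic per-round child seed, kept below 2^31.
child_seed <- function(master_seed, round) {
  as.integer((as.double(master_seed) + as.double(round) * 1000003) %%
               2147483647)
}

#' Bootstrap-aggregated stepwise selection
#'
#' Runs `n_bootstraps` independent rounds of (random partition -> forward
#' stepwise selection). Each round seeds its own RNG stream with a child
#' seed derived deterministically from `config$master_seed` and the round
#' index, so the ensemble is identical for a fixed master seed regardless
#' of execution order or `config$threads` (rounds are embarrassingly
#' parallel and run via [parallel::mclapply] when `threads > 1`). Rounds
#' whose fits fail outright are counted in `n_failed`.
#'
#' @param series the observed [abundance_series].
#' @param config a [glv_config].
#' @return A `model_ensemble`: list with `models` (list of
#'   `candidate_model`, each carrying `bootstrap_id` and `rng_seed`),
#'   `n_requested`, `n_failed`, `filter_log` (empty until
#'   [filter_models]), `taxa`, `config`.
#' @export
run_bagging <- function(series, config) {
  stopifnot(inherits(series, "abundance_series"),
            inherits(config, "glv_config"))
  one_round <- function(b) {
    seed <- child_seed(config$master_seed, b)
    set.seed(seed)
    tryCatch({
      part <- partition_series(series, config$train_fraction)
      model <- stepwise_select(part$train, series, config)
      model$train_indices <- part$train_indices
      model$bootstrap_id <- b
      model$rng_seed <- seed
      model
    }, error = function(e) NULL)
  }
  rounds <- seq_len(config$n_bootstraps)
  results <- if (config$threads > 1)
    parallel::mclapply(rounds, one_round, mc.cores = config$threads,
                       mc.preschedule = TRUE)
  else lapply(rounds, one_round)
  ok <- !vapply(results, is.null, logical(1))
  structure(list(models = results[ok],
                 n_requested = config$n_bootstraps,
                 n_failed = sum(!ok),
                 filter_log = data.frame(bootstrap_id = integer(0),
                                         reason = character(0)),
                 taxa = series$taxa,
                 series = series,
                 config = config),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat("model ensemble:", length(x$models), "model(s) retained of",
      x$n_requested, "requested;", x$n_failed, "failed,",
      nrow(x$filter_log), "filtered\n")
  invisible(x)
}

#' Restrict an ensemble to its first bootstrap rounds
#'
#' Because every bootstrap round is seeded independently from the master
#' seed, the first `b` rounds of a large run are identical to a run with
#' `n_bootstraps = b`. Truncating one large ensemble therefore traces how
#' the inference would have looked at smaller bootstrap counts -- e.g. to
#' find the smallest count at which an interaction reaches significance --
#' without re-running anything.
#'
#' @param ensemble a `model_ensemble` from [run_bagging] (before
#'   filtering/selection).
#' @param b number of bootstrap rounds to keep.
#' @return A `model_ensemble` equal to a `run_bagging` call with
#'   `n_bootstraps = b`.
#' @export
truncate_ensemble <- function(ensemble, b) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  if (nrow(ensemble$filter_log) > 0)
    stop("truncate before filtering, not after", call. = FALSE)
  keep <- vapply(ensemble$models, function(m) m$bootstrap_id <= b,
                 logical(1))
  ensemble$models <- ensemble$models[keep]
  ensemble$n_requested <- as.integer(b)
  ensemble$n_failed <- b - sum(keep)
  ensemble$config$n_bootstraps <- as.integer(b)
  ensemble
}

#' Remove biologically implausible candidate models
#'
#' Simulates every candidate model over the full observed time span from
#' the standard initial state and discards models whose dynamics drive any
#' single taxon below `min_species_abundance` or the whole community below
#' `min_community_size` (absolute abundances, cells/g; thresholds of 0
#' disable the corresponding check). Removed models are recorded in
#' `filter_log` with the offending taxon and time. Idempotent.
#'
#' @param ensemble a `model_ensemble` from [run_bagging].
#' @param min_species_abundance,min_community_size thresholds; default to
#'   the values in the ensemble's config.
#' @return The filtered `model_ensemble`.
#' @export
filter_models <- function(ensemble,
                          min_species_abundance =
                            ensemble$config$min_species_abundance,
                          min_community_size =
                            ensemble$config$min_community_size) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  if (min_species_abundance <= 0 && min_community_size <= 0)
    return(ensemble)
  cfg <- ensemble$config
  x0 <- seed_state(ensemble$series, cfg)
  times <- ensemble$series$times
  keep <- logical(length(ensemble$models))
  log_id <- integer(0); log_reason <- character(0)
  for (m in seq_along(ensemble$models)) {
    model <- ensemble$models[[m]]
    res <- .glv_integrate_rk45(model$params$r, model$params$A,
                               cfg$carrying_capacity, x0, times,
                               rtol = 1e-6,
                               atol = 1e-9 * cfg$carrying_capacity)
    reason <- NA_character_
    if (res$status != 0) {
      reason <- "simulation failure"
    } else {
      X <- res$X
      N <- rowSums(X)
      if (min_species_abundance > 0 && any(X < min_species_abundance)) {
        w <- which(X < min_species_abundance, arr.ind = TRUE)[1, ]
        reason <- sprintf("taxon %s below %g at t = %g",
                          ensemble$taxa[w[2]], min_species_abundance,
                          times[w[1]])
      } else if (min_community_size > 0 && any(N < min_community_size)) {
        w <- which(N < min_community_size)[1]
        reason <- sprintf("community below %g at t = %g",
                          min_community_size, times[w])
      }
    }
    keep[m] <- is.na(reason)
    if (!is.na(reason)) {
      log_id <- c(log_id, model$bootstrap_id)
      log_reason <- c(log_reason, reason)
    }
  }
  ensemble$models <- ensemble$models[keep]
  ensemble$filter_log <- rbind(
    ensemble$filter_log,
    data.frame(bootstrap_id = log_id, reason = log_reason))
  ensemble
}

#' Retain the best-BIC slice of an ensemble
#'
#' Keeps models whose whole-series BIC lies within an allowance band above
#' the ensemble minimum `B*`: `BIC <= B* + allowance * |B*|` (relative
#' mode, the default -- the absolute value makes the band widen upward even
#' for the negative BICs typical here), or `BIC <= B* + allowance`
#' (absolute mode).
#'
#' @param ensemble a `model_ensemble`.
#' @param allowance band width (default from config, 0.10).
#' @param mode `"relative"` or `"absolute"` (default from config).
#' @return The reduced `model_ensemble`.
#' @export
select_best <- function(ensemble,
                        allowance = ensemble$config$bic_allowance,
                        mode = ensemble$config$allowance_mode) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  if (!length(ensemble$models))
    stop("no models remain in the ensemble; relax the biological ",
         "constraints or increase n_bootstraps", call. = FALSE)
  bics <- vapply(ensemble$models, `[[`, numeric(1), "bic_full")
  bstar <- min(bics)
  cutoff <- if (mode == "relative") bstar + allowance * abs(bstar)
            else bstar + allowance
  ensemble$models <- ensemble$models[bics <= cutoff]
  ensemble
}

#' Aggregate retained models and test coefficients against zero
#'
#' Compiles, for every ordered taxon pair `(i, j)`, the sample of fitted
#' `a_ij` values across the retained models -- by default an exact 0 when a
#' model did not select the pair, since that coefficient is zero in that
#' model by construction -- and applies a two-sided one-sample t-test of
#' mean zero. An interaction is significant when `p < 1 - confidence`.
#' Degenerate zero-variance samples use the natural conventions: all-zero
#' sample -> p = 1 (never significant), constant nonzero sample -> p = 0.
#' Growth rates are aggregated as means with standard errors.
#'
#' @param ensemble a `model_ensemble` (after [filter_models] and
#'   [select_best]).
#' @param confidence significance gate (default from config, 0.95).
#' @param include_zeros include non-selecting models as zeros (default
#'   from config, `TRUE`); with `FALSE`, only models that selected the
#'   pair contribute, and pairs selected by fewer than 2 models are
#'   reported with `p = NA`.
#' @return A `glv_aggregate`: list with data.frame `coefficients`
#'   (`target`, `source`, `mean`, `sd`, `t_statistic`, `p_value`,
#'   `selection_frequency`, `significant`), data.frame `growth_rates`
#'   (`taxon`, `mean`, `se`), `n_models`, `confidence`.
#' @export
aggregate_and_test <- function(ensemble,
                               confidence = ensemble$config$confidence,
                               include_zeros =
                                 ensemble$config$include_zero_coefficients) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  m <- length(ensemble$models)
  if (m < 1) stop("empty ensemble", call. = FALSE)
  if (m == 1)
    warning("only one retained model: significance is undefined (p = NA)")
  taxa <- ensemble$taxa
  n <- length(taxa)
  pairs <- all_pairs(n)

  Avals <- vapply(ensemble$models, function(md) md$params$A[pairs],
                  numeric(nrow(pairs)))
  Avals <- matrix(Avals, nrow = nrow(pairs))  # pairs x models
  selected <- vapply(ensemble$models, function(md) {
    key <- paste(md$select_set[, 1], md$select_set[, 2])
    paste(pairs[, 1], pairs[, 2]) %in% key
  }, logical(nrow(pairs)))
  selected <- matrix(selected, nrow = nrow(pairs))

  one_pair <- function(r) {
    vals <- if (include_zeros) Avals[r, ] else Avals[r, selected[r, ]]
    tt <- one_sample_t(vals)
    c(mean = tt$mean, sd = tt$sd, t = tt$t, p = tt$p,
      freq = mean(selected[r, ]))
  }
  stats <- t(vapply(seq_len(nrow(pairs)), one_pair, numeric(5)))
  coef_df <- data.frame(
    target = taxa[pairs[, 1]],
    source = taxa[pairs[, 2]],
    mean = stats[, "mean"],
    sd = stats[, "sd"],
    t_statistic = stats[, "t"],
    p_value = stats[, "p"],
    selection_frequency = stats[, "freq"],
    stringsAsFactors = FALSE)
  coef_df$significant <- !is.na(coef_df$p_value) &
    coef_df$p_value < (1 - confidence)

  R <- vapply(ensemble$models, function(md) md$params$r, numeric(n))
  R <- matrix(R, nrow = n)
  growth_df <- data.frame(
    taxon = taxa,
    mean = rowMeans(R),
    se = apply(R, 1, stats::sd) / sqrt(m),
    stringsAsFactors = FALSE)

  structure(list(coefficients = coef_df, growth_rates = growth_df,
                 n_models = m, confidence = confidence),
            class = "glv_aggregate")
}

# Two-sided one-sample t-test of mean 0 with the ensemble's degenerate-case
# conventions; equivalent to stats::t.test for non-degenerate samples.
one_sample_t <- function(vals) {
  m <- length(vals)
  if (m == 0) return(list(mean = 0, sd = NA_real_, t = NA_real_,
                          p = NA_real_))
  mu <- mean(vals)
  if (m == 1) return(list(mean = mu, sd = NA_real_, t = NA_real_,
                          p = NA_real_))
  s <- stats::sd(vals)
  if (s == 0) {
    p <- if (mu == 0) 1 else 0
    return(list(mean = mu, sd = s, t = if (mu == 0) 0 else Inf * sign(mu),
                p = p))
  }
  tstat <- mu / (s / sqrt(m))
  list(mean = mu, sd = s, t = tstat,
       p = 2 * stats::pt(abs(tstat), df = m - 1, lower.tail = FALSE))
}

#' @export
print.glv_aggregate <- function(x, ...) {
  sig <- x$coefficients[x$coefficients$significant, , drop = FALSE]
  cat("aggregated over", x$n_models, "models;", nrow(sig),
      "significant interaction(s) at", x$confidence, "confidence\n")
  if (nrow(sig)) print(sig, row.names = FALSE, digits = 4)
  invisible(x)
}
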