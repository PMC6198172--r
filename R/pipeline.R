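#' Infer a microbial interaction network from a time series
#'
#' The full pipeline: optional time-window restriction, bootstrap rounds
#' of train/test partitioning and forward stepwise BIC selection
#' ([run_bagging]), biological filtering ([filter_models]), best-BIC slice
#' ([select_best]), coefficient aggregation with one-sample t-tests
#' ([aggregate_and_test]), and network construction ([build_network]).
#' The result is a pure function of `(series, config)`: all randomness
#' derives from `config$master_seed`.
#'
#' @param series the observed [abundance_series].
#' @param config a [glv_config].
#' @return List with `network` (an `interaction_network`), `aggregate`,
#'   `ensemble` (post-selection), and `ensemble_raw` sizes
#'   (`n_requested`, `n_failed`, `n_filtered`, `n_retained`).
#' @examples
#' \donttest{
#' spec <- preset_cheese_like()
#' obs <- generate_series(spec)$observed
#' cfg <- glv_config(carrying_capacity = 2e10, master_seed = 1,
#'                   n_bootstraps = 20)
#' res <- infer_network(obs, cfg)
#' res$network
#' }
#' @export
infer_network <- function(series, config) {
  stopifnot(inherits(series, "abundance_series"),
            inherits(config, "glv_config"))
  if (!is.null(config$time_window))
    series <- apply_time_window(series, config$time_window)
  ens <- run_bagging(series, config)
  ens <- filter_models(ens)
  n_filtered <- nrow(ens$filter_log)
  ens <- select_best(ens)
  agg <- aggregate_and_test(ens)
  net <- build_network(agg)
  list(network = net, aggregate = agg, ensemble = ens,
       counts = list(n_requested = ens$n_requested,
                     n_failed = ens$n_failed,
                     n_filtered = n_filtered,
                     n_retained = length(ens$models)))
}
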