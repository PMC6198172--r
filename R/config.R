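#' Pipeline configuration
#'
#' Collects every tunable of the inference pipeline in one validated list.
#' Defaults follow the procedure's published study conditions: growth rates
#' initialized at 1 generation/day with all interactions at 0, 80% of time
#' points for training, 1,000 bootstraps, and a 95% significance gate.
#'
#' @param carrying_capacity community carrying capacity `K` (cells/g);
#'   required, no universal default exists (e.g. 2e10 CFU/g for a cheese
#'   rind community, 1e11 cells/g feces for the infant gut).
#' @param n_bootstraps bootstrap rounds (default 1000).
#' @param train_fraction fraction of time points used for training each
#'   round (default 0.8); the first time point is always included.
#' @param confidence one-sample t-test confidence for calling an
#'   interaction significant (default 0.95, i.e. p < 0.05).
#' @param bic_tie_delta candidates within this BIC distance of a round's
#'   best addition count as ties and one is chosen at random (default 2;
#'   0 disables the random tie break).
#' @param bic_allowance best-model band width after bagging: models with
#'   `BIC <= B* + bic_allowance * |B*|` are retained (default 0.10).
#' @param allowance_mode `"relative"` (default, the `|B*|` scaling above)
#'   or `"absolute"` (`BIC <= B* + bic_allowance`).
#' @param initial_growth_rate starting value for every `r_i` (1/day,
#'   default 1).
#' @param n0_fraction initial community size for fitting simulations as a
#'   fraction of `K` (default 0.01): the model is fitted to compositions
#'   but the dynamics need an absolute starting state.
#' @param zero_floor relative-abundance floor applied to exact zeros at the
#'   first time point before seeding a simulation (default 1e-6); zero is
#'   absorbing in the model, so an exactly-zero start could never match
#'   later nonzero observations.
#' @param rss_floor lower clamp on RSS before the BIC logarithm (default
#'   1e-12), so noiseless fits cannot produce `-Inf`.
#' @param min_species_abundance,min_community_size biological filter
#'   thresholds (cells/g; 0 disables): candidate models whose simulated
#'   dynamics drive any taxon / the community below the threshold are
#'   discarded before aggregation.
#' @param include_zero_coefficients if `TRUE` (default) a model that did
#'   not select a coefficient contributes an exact 0 to that coefficient's
#'   t-test sample; if `FALSE` only selecting models contribute.
#' @param bic_datapoints how `U` ("number of data points") in the BIC is
#'   counted: `"timepoints"` (default, `U = T`) or `"residuals"`
#'   (`U = T * n`). The `n` residuals at one time point are compositionally
#'   dependent (deviations sum to ~0), so counting them all overstates the
#'   independent information and under-penalizes added coefficients; see
#'   the methods vignette.
#' @param max_fit_iterations Levenberg-Marquardt iteration cap per fit
#'   (default 200).
#' @param r_bounds,a_bounds box constraints for growth rates (1/day) and
#'   interaction coefficients during fitting.
#' @param master_seed integer seed from which all per-round seeds derive;
#'   required explicitly (no silent time-based seeding).
#' @param time_window optional `c(t_min, t_max)` (days) restriction applied
#'   before inference.
#' @param threads worker processes for the bootstrap loop (results are
#'   independent of the thread count).
#' @return A validated list of class `glv_config`.
#' @export
glv_config <- function(carrying_capacity,
                       master_seed,
                       n_bootstraps = 1000,
                       train_fraction = 0.8,
                       confidence = 0.95,
                       bic_tie_delta = 2.0,
                       bic_allowance = 0.10,
                       allowance_mode = c("relative", "absolute"),
                       initial_growth_rate = 1.0,
                       n0_fraction = 0.01,
                       zero_floor = 1e-6,
                       rss_floor = 1e-12,
                       min_species_abundance = 0,
                       min_community_size = 0,
                       include_zero_coefficients = TRUE,
                       bic_datapoints = c("timepoints", "residuals"),
                       max_fit_iterations = 200,
                       r_bounds = c(-10, 10),
                       a_bounds = c(-50, 50),
                       time_window = NULL,
                       threads = 1) {
  cfg <- list(
    carrying_capacity = as.numeric(carrying_capacity),
    master_seed = as.integer(master_seed),
    n_bootstraps = as.integer(n_bootstraps),
    train_fraction = as.numeric(train_fraction),
    confidence = as.numeric(confidence),
    bic_tie_delta = as.numeric(bic_tie_delta),
    bic_allowance = as.numeric(bic_allowance),
    allowance_mode = match.arg(allowance_mode),
    initial_growth_rate = as.numeric(initial_growth_rate),
    n0_fraction = as.numeric(n0_fraction),
    zero_floor = as.numeric(zero_floor),
    rss_floor = as.numeric(rss_floor),
    min_species_abundance = as.numeric(min_species_abundance),
    min_community_size = as.numeric(min_community_size),
    include_zero_coefficients = isTRUE(include_zero_coefficients),
    bic_datapoints = match.arg(bic_datapoints),
    max_fit_iterations = as.integer(max_fit_iterations),
    r_bounds = as.numeric(r_bounds),
    a_bounds = as.numeric(a_bounds),
    time_window = if (!is.null(time_window)) as.numeric(time_window),
    threads = as.integer(threads))
  validate_config(cfg)
  structure(cfg, class = "glv_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(is.finite(cfg$carrying_capacity) && cfg$carrying_capacity > 0,
      "carrying_capacity must be > 0")
  chk(!is.na(cfg$master_seed), "master_seed must be set explicitly")
  chk(cfg$n_bootstraps >= 1, "n_bootstraps must be >= 1")
  chk(cfg$train_fraction > 0 && cfg$train_fraction <= 1,
      "train_fraction must be in (0, 1]")
  chk(cfg$confidence > 0 && cfg$confidence < 1,
      "confidence must be in (0, 1)")
  chk(cfg$bic_tie_delta >= 0, "bic_tie_delta must be >= 0")
  chk(cfg$bic_allowance >= 0, "bic_allowance must be >= 0")
  chk(cfg$n0_fraction > 0 && cfg$n0_fraction <= 1,
      "n0_fraction must be in (0, 1]")
  chk(cfg$zero_floor > 0 && cfg$zero_floor < 1,
      "zero_floor must be in (0, 1)")
  chk(cfg$rss_floor > 0, "rss_floor must be > 0")
  chk(length(cfg$r_bounds) == 2 && cfg$r_bounds[1] < cfg$r_bounds[2],
      "r_bounds must be c(lower, upper)")
  chk(length(cfg$a_bounds) == 2 && cfg$a_bounds[1] < cfg$a_bounds[2],
      "a_bounds must be c(lower, upper)")
  chk(is.null(cfg$time_window) || length(cfg$time_window) == 2,
      "time_window must be NULL or c(t_min, t_max)")
  chk(cfg$threads >= 1, "threads must be >= 1")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML file holds exactly the fields of [glv_config]; unknown keys are
#' rejected. Writing the resolved configuration next to a run's outputs
#' records its provenance; a write/read round trip is lossless.
#'
#' @param path YAML file path.
#' @return `read_config`: a `glv_config`. `write_config`: `path`,
#'   invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(glv_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(glv_config, vals)
}

#' @rdname read_config
#' @param config a `glv_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "glv_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path, precision = 15)
  invisible(path)
}
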