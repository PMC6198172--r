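#' Specification for a synthetic compositional time series
#'
#' Bundles everything needed to generate ground-truthed test data: true
#' gLV parameters, the initial absolute state, a sampling schedule and an
#' observation-noise model. Two noise models cover the two kinds of data
#' the pipeline targets: `"lognormal"` emulates plate-count-style
#' measurement error (each abundance multiplied by `exp(N(0, sigma^2))`,
#' then the composition renormalized), `"resampling"` emulates finite
#' sequencing depth (a `depth`-count multinomial draw from the true
#' composition). `"none"` returns the exact model composition.
#'
#' @param true_params a [glv_params]: the ground truth to recover.
#' @param x0 non-negative initial absolute abundances (cells/g).
#' @param times strictly increasing sampling times (days).
#' @param noise_model `"none"`, `"lognormal"` or `"resampling"`.
#' @param sigma lognormal noise scale (sd of log abundance; e.g. 0.05 for
#'   roughly 5% multiplicative noise).
#' @param depth multinomial resampling depth (reads per sample).
#' @param seed integer RNG seed used by [generate_series].
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(true_params, x0, times,
                           noise_model = c("none", "lognormal",
                                           "resampling"),
                           sigma = 0.05, depth = 1e5, seed = 1L) {
  stopifnot(inherits(true_params, "glv_params"))
  noise_model <- match.arg(noise_model)
  x0 <- as.numeric(x0)
  if (length(x0) != length(true_params$taxa) || any(x0 < 0))
    stop("`x0` must be non-negative with one entry per taxon",
         call. = FALSE)
  times <- as.numeric(times)
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("`times` must be strictly increasing with >= 2 points",
         call. = FALSE)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (depth < 1) stop("`depth` must be >= 1", call. = FALSE)
  structure(list(true_params = true_params, x0 = x0, times = times,
                 noise_model = noise_model, sigma = as.numeric(sigma),
                 depth = as.numeric(depth), seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a ground-truthed compositional time series
#'
#' Simulates the spec's true parameters from `x0` over `times`, converts
#' the trajectory to relative abundances, and applies the spec's
#' observation-noise model. Deterministic for a fixed `spec$seed`. The
#' returned ground truth carries the exact parameters and the noiseless
#' composition so downstream tests never have to re-derive them.
#'
#' @param spec a [generator_spec].
#' @return List with `observed` (the noisy [abundance_series]), `truth`
#'   (list: `params`, `x0`, `noiseless` series, `trajectory`), and the
#'   `spec` itself.
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  traj <- glv_simulate(spec$true_params, spec$x0, spec$times)
  clean <- to_relative(traj)
  P <- clean$P
  if (spec$noise_model == "none" ||
      (spec$noise_model == "lognormal" && spec$sigma == 0)) {
    # bit-identical to the noiseless truth, no re-normalization pass
    return(list(observed = clean,
                truth = list(params = spec$true_params, x0 = spec$x0,
                             noiseless = clean, trajectory = traj),
                spec = spec))
  }
  if (spec$noise_model != "none") {
    set.seed(spec$seed)
    if (spec$noise_model == "lognormal" && spec$sigma > 0) {
      noise <- matrix(stats::rnorm(length(P), 0, spec$sigma), nrow(P))
      P <- P * exp(noise)
      P <- P / rowSums(P)
    } else if (spec$noise_model == "resampling") {
      P <- t(apply(P, 1, function(p)
        as.numeric(stats::rmultinom(1, size = spec$depth, prob = p)) /
          spec$depth))
      # a depth-limited draw can zero out a rare taxon; the series must
      # keep every row sum positive, which multinomial draws guarantee
    }
  }
  observed <- abundance_series(clean$taxa, clean$times, P,
                               normalize = TRUE)
  list(observed = observed,
       truth = list(params = spec$true_params, x0 = spec$x0,
                    noiseless = clean, trajectory = traj),
       spec = spec)
}

#' Write / read the ground truth of a synthetic series
#'
#' Serializes the generating parameters and noiseless composition as JSON
#' next to the abundance table, so that acceptance checks can reload the
#' exact truth instead of re-deriving it.
#'
#' @param truth the `truth` element returned by [generate_series].
#' @param path JSON file path.
#' @return `write_truth`: `path`, invisibly. `read_truth`: a list with
#'   `params` ([glv_params]), `x0`, and `noiseless` ([abundance_series]).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(taxa = truth$params$taxa,
         r = unname(truth$params$r),
         A = unname(truth$params$A),
         K = truth$params$K,
         x0 = truth$x0,
         times = truth$noiseless$times,
         P = unname(truth$noiseless$P)),
    path, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- glv_params(v$taxa, v$r, v$A, v$K)
  list(params = params, x0 = v$x0,
       noiseless = abundance_series(v$taxa, v$times, v$P))
}

#' Preset: predator-prey community with a neutral spectator
#'
#' A three-taxon system built for parameter-recovery studies: a predator
#' (`X1`, intrinsically declining), a prey (`X3`, fast-growing) and a
#' neutral spectator (`X2`). The prey fuels the predator (`a_13 = +2.0`)
#' and the predator suppresses the prey (`a_31 = -1.4`), producing a
#' damped half-oscillation of the composition over 30 daily samples: the
#' predator's share rises then falls, the prey's crashes then partially
#' recovers, and the spectator's dips then climbs. All three taxa follow
#' distinct, non-monotone trajectories -- the regime in which
#' trajectory-based inference can attribute effects to the right source
#' taxon (monotone, mutually collinear trajectories cannot be told apart
#' under the compositional sum-to-one constraint).
#'
#' @param spectator_link optional weak extra coefficient `a_21` (effect of
#'   the predator on the spectator; default 0 = absent). A small positive
#'   value adds a deliberately weak third interaction, useful for studying
#'   how detection depends on interaction strength.
#' @param noise_model,sigma,seed forwarded to [generator_spec].
#' @return A [generator_spec] with `K = 1e10` cells/g, initial community
#'   size `0.01 K`, and times 0..29 days.
#' @export
preset_predator_prey <- function(spectator_link = 0,
                                 noise_model = "lognormal", sigma = 0.05,
                                 seed = 1L) {
  taxa <- c("X1", "X2", "X3")
  K <- 1e10
  A <- matrix(0, 3, 3, dimnames = list(taxa, taxa))
  A[1, 3] <- 2.0
  A[3, 1] <- -1.4
  A[2, 1] <- spectator_link
  r <- c(-0.15, 0.35, 0.59)
  x0 <- c(0.06, 0.44, 0.50) * 0.01 * K
  generator_spec(glv_params(taxa, r, A, K), x0, times = 0:29,
                 noise_model = noise_model, sigma = sigma, seed = seed)
}

#' Preset: neutral three-taxon community
#'
#' The interaction-free null: identical intrinsic growth rates and a zero
#' interaction matrix, so the expected composition is constant in time and
#' any structure in observed data is observation noise. This is the
#' canonical ecological null model for type-I-error studies of interaction
#' inference.
#'
#' @inheritParams preset_predator_prey
#' @return A [generator_spec] matching [preset_predator_prey] in all
#'   observational respects (K, initial community size, times, noise).
#' @export
preset_neutral <- function(noise_model = "lognormal", sigma = 0.05,
                           seed = 1L) {
  taxa <- c("X1", "X2", "X3")
  K <- 1e10
  r <- rep(0.2, 3)
  x0 <- c(0.06, 0.44, 0.50) * 0.01 * K
  generator_spec(glv_params(taxa, r, matrix(0, 3, 3), K), x0,
                 times = 0:29, noise_model = noise_model, sigma = sigma,
                 seed = seed)
}

#' Preset: two-taxon community with a single interaction
#'
#' The smallest system with a non-trivial selection problem (four possible
#' coefficient subsets): taxon `B` suppresses taxon `A` (`a_AB = -1.2`)
#' while `B` grows faster. Used to compare stepwise selection against
#' exhaustive best-subset search.
#'
#' @inheritParams preset_predator_prey
#' @return A [generator_spec] with 20 daily samples.
#' @export
preset_two_taxon <- function(noise_model = "lognormal", sigma = 0.05,
                             seed = 1L) {
  taxa <- c("A", "B")
  K <- 1e10
  A <- matrix(0, 2, 2, dimnames = list(taxa, taxa))
  A[1, 2] <- -1.2
  r <- c(0.45, 0.35)
  x0 <- c(0.55, 0.45) * 0.01 * K
  generator_spec(glv_params(taxa, r, A, K), x0, times = 0:19,
                 noise_model = noise_model, sigma = sigma, seed = seed)
}

#' Preset: cheese-rind-like five-taxon community
#'
#' A deterministic generator spec emulating a surface-ripened cheese
#' community: five taxa (three yeasts -- Dh, Yl, Gc -- one Leucobacter,
#' and a pooled bacterial group), carrying capacity 2e10 CFU/g, sampled
#' daily for 21 days. The interaction matrix has one strong positive
#' effect (Gc promoting the bacterial group) and several inhibitions,
#' qualitatively echoing the known ecology of such communities. This is a
#' synthetic stand-in for integration tests, not a reproduction of any
#' measured dataset.
#'
#' @param noise_model,sigma,seed forwarded to [generator_spec]
#'   (defaults: lognormal, 0.05, 1).
#' @return A [generator_spec].
#' @export
preset_cheese_like <- function(noise_model = "lognormal", sigma = 0.05,
                               seed = 1L) {
  taxa <- c("Dh", "Yl", "Gc", "Ls", "Bact")
  K <- 2e10
  r <- c(Dh = 0.9, Yl = 0.7, Gc = 0.8, Ls = 0.5, Bact = 0.6)
  A <- matrix(0, 5, 5, dimnames = list(taxa, taxa))
  A["Bact", "Gc"] <- 6    # strong promotion of the bacterial group by Gc
  A["Ls", "Gc"] <- 3      # promotion of Leucobacter by Gc
  A["Dh", "Gc"] <- -4     # Gc suppresses D. hansenii
  A["Yl", "Dh"] <- -3     # D. hansenii suppresses Y. lipolytica
  A["Gc", "Bact"] <- -2   # bacteria inhibit G. candidum
  x0 <- c(0.30, 0.25, 0.25, 0.10, 0.10) * 0.01 * K
  generator_spec(glv_params(taxa, r, A, K), x0, times = 0:20,
                 noise_model = noise_model, sigma = sigma, seed = seed)
}
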