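#' Longitudinal relative-abundance series
#'
#' The observed quantity the model is fitted to: a times x taxa matrix `P`
#' of relative abundances (compositions). Every entry lies in `[0, 1]` and
#' every row sums to one; the constructor renormalizes rows whose sum is
#' within `1e-8` of one and refuses anything further off (use
#' [read_abundance_table] for raw tables that need normalization).
#'
#' @param taxa character vector of taxon identifiers.
#' @param times strictly increasing numeric vector (days).
#' @param P times x taxa numeric matrix of relative abundances.
#' @param normalize if `TRUE`, rows are divided by their sums regardless of
#'   deviation (used by the I/O layer after count conversion).
#' @return An object of class `abundance_series`.
#' @export
abundance_series <- function(taxa, times, P, normalize = FALSE) {
  taxa <- as.character(taxa)
  times <- as.numeric(times)
  P <- as.matrix(P)
  storage.mode(P) <- "double"
  if (anyDuplicated(taxa)) stop("duplicate taxon identifiers", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (nrow(P) != length(times) || ncol(P) != length(taxa))
    stop("`P` must be ", length(times), " x ", length(taxa), call. = FALSE)
  if (any(!is.finite(P)) || any(P < 0))
    stop("relative abundances must be finite and non-negative",
         call. = FALSE)
  rs <- rowSums(P)
  if (any(rs == 0))
    stop("time point(s) with all-zero abundance: ",
         paste(times[rs == 0], collapse = ", "), call. = FALSE)
  if (!normalize && any(abs(rs - 1) > 1e-8))
    stop("rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), "); set normalize = TRUE to rescale",
         call. = FALSE)
  P <- P / rs
  dimnames(P) <- list(NULL, taxa)
  structure(list(taxa = taxa, times = times, P = P),
            class = "abundance_series")
}

#' @export
print.abundance_series <- function(x, ...) {
  cat("abundance series:", length(x$taxa), "taxa x", length(x$times),
      "time points; t in [", x$times[1], ",", x$times[length(x$times)],
      "] days\n")
  cat("taxa:", paste(x$taxa, collapse = ", "), "\n")
  invisible(x)
}

n_times <- function(series) length(series$times)

subset_times <- function(series, idx) {
  abundance_series(series$taxa, series$times[idx],
                   series$P[idx, , drop = FALSE])
}

#' Restrict a series to a time window
#'
#' Keeps only time points `t` with `t_min <= t <= t_max`, e.g. to analyse
#' age windows such as the first 365 days of an infant cohort.
#'
#' @param series an [abundance_series].
#' @param window numeric length-2 vector `c(t_min, t_max)` in days.
#' @param min_points minimum number of retained points (default 3; fitting
#'   needs at least this many).
#' @return The restricted [abundance_series].
#' @export
apply_time_window <- function(series, window, min_points = 3) {
  stopifnot(inherits(series, "abundance_series"))
  if (length(window) != 2 || window[1] > window[2])
    stop("`window` must be c(t_min, t_max) with t_min <= t_max",
         call. = FALSE)
  keep <- series$times >= window[1] & series$times <= window[2]
  if (sum(keep) < min_points)
    stop("only ", sum(keep), " time point(s) in [", window[1], ", ",
         window[2], "]; need at least ", min_points, call. = FALSE)
  subset_times(series, which(keep))
}
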