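#' Read a longitudinal abundance table
#'
#' Reads a delimited text table of taxon abundances over time. The default
#' layout has one row per taxon, one column per time point, the taxon
#' identifier in the first column and the sampling times (days) in the
#' header row. Values may be counts / cell densities (converted to relative
#' abundances by normalizing each time point) or relative abundances
#' (renormalized with a warning if any time point's sum deviates from one
#' by more than `1e-6`). Columns are sorted by time.
#'
#' @param path file path of a TSV/CSV table.
#' @param values `"counts"` or `"relative"`.
#' @param orientation `"taxa_by_times"` (default) or `"times_by_taxa"`
#'   (one row per time point, taxa in the header, time in the first
#'   column).
#' @param sep field separator; `NULL` (default) picks `,` for `.csv` paths
#'   and tab otherwise.
#' @return An [abundance_series].
#' @export
read_abundance_table <- function(path, values = c("counts", "relative"),
                                 orientation = c("taxa_by_times",
                                                 "times_by_taxa"),
                                 sep = NULL) {
  values <- match.arg(values)
  orientation <- match.arg(orientation)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (ncol(raw) < 2)
    stop("table must have an identifier column plus data columns",
         call. = FALSE)
  ids <- as.character(raw[[1]])
  M <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(M)) {
    Mn <- suppressWarnings(matrix(as.numeric(M), nrow(M)))
    bad <- which(is.na(Mn) & !is.na(M), arr.ind = TRUE)
    if (nrow(bad))
      stop("non-numeric cell at row ", bad[1, 1], ", column ",
           bad[1, 2] + 1, " of ", path, call. = FALSE)
    M <- Mn
  }
  if (anyNA(M)) stop("missing values in ", path, call. = FALSE)
  if (any(M < 0)) {
    bad <- which(M < 0, arr.ind = TRUE)
    stop("negative value at row ", bad[1, 1], ", column ", bad[1, 2] + 1,
         " of ", path, call. = FALSE)
  }
  hdr <- suppressWarnings(as.numeric(colnames(raw)[-1]))

  if (orientation == "taxa_by_times") {
    taxa <- ids
    times <- hdr
    P <- t(M)                        # -> times x taxa
  } else {
    taxa <- colnames(raw)[-1]
    times <- suppressWarnings(as.numeric(ids))
    P <- M
  }
  if (anyNA(times))
    stop("time labels must be numeric (days) in ", path, call. = FALSE)
  if (anyDuplicated(times))
    stop("duplicate time point(s): ",
         paste(unique(times[duplicated(times)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(taxa))
    stop("duplicate taxon identifier(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "),
         call. = FALSE)
  ord <- order(times)
  times <- times[ord]
  P <- P[ord, , drop = FALSE]

  if (values == "relative") {
    dev <- abs(rowSums(P) - 1)
    if (any(dev > 1e-6))
      warning("renormalizing ", sum(dev > 1e-6),
              " time point(s) whose relative abundances do not sum to 1 ",
              "(max deviation ", format(max(dev), digits = 3), ")")
  }
  abundance_series(taxa, times, P, normalize = TRUE)
}

#' Write an abundance series as a delimited table
#'
#' Inverse of [read_abundance_table] with the default layout (rows = taxa,
#' header = times in days). Full double precision is kept so a write/read
#' round trip reproduces the series.
#'
#' @param series an [abundance_series].
#' @param path output file path; `.csv` selects comma separation.
#' @param sep field separator; `NULL` as in [read_abundance_table].
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(series, path, sep = NULL) {
  stopifnot(inherits(series, "abundance_series"))
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  M <- t(series$P)                    # taxa x times
  lines <- c(
    paste(c("taxon", formatC(series$times, format = "g", digits = 15)),
          collapse = sep),
    vapply(seq_along(series$taxa), function(i) {
      paste(c(series$taxa[i],
              formatC(M[i, ], format = "g", digits = 17)),
            collapse = sep)
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
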