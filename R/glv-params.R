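#' Generalized Lotka-Volterra parameter set
#'
#' Bundles the unknowns of the community model: per-taxon intrinsic growth
#' rates `r` (1/day), the interaction matrix `A` whose entry `A[i, j]` is the
#' effect of taxon `j` on taxon `i` (a dimensionless multiplier of taxon j's
#' relative abundance), and the community-wide carrying capacity `K`
#' (cells or CFU per gram). Intra-species terms are excluded by construction:
#' the diagonal of `A` must be identically zero.
#'
#' @param taxa character vector of taxon identifiers (length n).
#' @param r numeric vector of intrinsic growth rates, one per taxon (1/day).
#' @param A n x n numeric matrix of interaction coefficients; `A[i, j]` is
#'   the effect of taxon `j` upon taxon `i`; diagonal must be zero.
#' @param K positive scalar carrying capacity of the whole community.
#' @return An object of class `glv_params`.
#' @examples
#' p <- glv_params(c("A", "B"), r = c(1, 1),
#'                 A = matrix(c(0, -2, 0, 0), 2, 2), K = 1e10)
#' @export
glv_params <- function(taxa, r, A, K) {
  taxa <- as.character(taxa)
  n <- length(taxa)
  if (n < 1) stop("need at least one taxon", call. = FALSE)
  if (anyDuplicated(taxa)) stop("duplicate taxon identifiers", call. = FALSE)
  r <- as.numeric(r)
  if (length(r) != n || any(!is.finite(r)))
    stop("`r` must be a finite numeric vector of length ", n, call. = FALSE)
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  if (!all(dim(A) == c(n, n)))
    stop("`A` must be a ", n, "x", n, " matrix", call. = FALSE)
  if (any(!is.finite(A))) stop("`A` must be finite", call. = FALSE)
  if (any(diag(A) != 0))
    stop("diagonal of `A` must be zero (no intra-species interactions)",
         call. = FALSE)
  if (!is.numeric(K) || length(K) != 1 || !is.finite(K) || K <= 0)
    stop("`K` must be a positive finite scalar", call. = FALSE)
  dimnames(A) <- list(taxa, taxa)
  names(r) <- taxa
  structure(list(taxa = taxa, r = r, A = A, K = as.numeric(K)),
            class = "glv_params")
}

#' @export
print.glv_params <- function(x, ...) {
  cat("gLV parameters:", length(x$taxa), "taxa, K =",
      format(x$K, digits = 4), "\n")
  cat("growth rates (1/day):\n")
  print(round(x$r, 4))
  cat("interaction matrix A[i, j] (effect of j on i):\n")
  print(round(x$A, 4))
  invisible(x)
}

n_taxa <- function(params) length(params$taxa)
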