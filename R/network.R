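#' Classify a taxon pair by its interaction signs
#'
#' Maps the significance-resolved signs of the reciprocal coefficients
#' `(a_ij, a_ji)` (0 meaning "not significant") onto the six ecological
#' interaction forms: `+/+` mutualism, `-/-` competition, `+/-` parasitism,
#' `+/0` commensalism, `-/0` amensalism, `0/0` neutral. Symmetric in its
#' arguments; vectorized.
#'
#' @param sign_ij,sign_ji integer signs in `{-1, 0, 1}` (or any numeric:
#'   the sign is taken).
#' @return Character vector of labels.
#' @examples
#' classify_pair(1, -1)   # "parasitism"
#' classify_pair(0, 0)    # "neutral"
#' @export
classify_pair <- function(sign_ij, sign_ji) {
  s1 <- sign(sign_ij); s2 <- sign(sign_ji)
  lab <- function(a, b) {
    if (a == 0 && b == 0) return("neutral")
    if (a > 0 && b > 0) return("mutualism")
    if (a < 0 && b < 0) return("competition")
    if ((a > 0 && b < 0) || (a < 0 && b > 0)) return("parasitism")
    if (a > 0 || b > 0) return("commensalism")
    "amensalism"
  }
  mapply(lab, s1, s2, USE.NAMES = FALSE)
}

#' Build the significant interaction network
#'
#' Turns an aggregation ([aggregate_and_test]) into a directed weighted
#' network: an edge `source -> target` exists iff the coefficient
#' `a[target, source]` is significant, its weight is the aggregated mean,
#' and every unordered taxon pair receives one of the six ecological
#' labels from the significance-resolved signs. A significant mean within
#' `1e-12` of zero carries no sign information and is treated as zero.
#'
#' @param aggregate a `glv_aggregate`.
#' @return An `interaction_network`: list with data.frames `nodes`
#'   (`taxon`, `growth_rate_mean`, `growth_rate_se`), `edges` (`source`,
#'   `target`, `coefficient_mean`, `p_value`, `selection_frequency`),
#'   `pair_labels` (`taxon_a`, `taxon_b`, `label`), and the full
#'   `aggregate` for audit.
#' @export
build_network <- function(aggregate) {
  stopifnot(inherits(aggregate, "glv_aggregate"))
  co <- aggregate$coefficients
  taxa <- aggregate$growth_rates$taxon
  eff_sign <- ifelse(co$significant & abs(co$mean) > 1e-12,
                     sign(co$mean), 0)
  edges <- data.frame(
    source = co$source[eff_sign != 0],
    target = co$target[eff_sign != 0],
    coefficient_mean = co$mean[eff_sign != 0],
    p_value = co$p_value[eff_sign != 0],
    selection_frequency = co$selection_frequency[eff_sign != 0],
    stringsAsFactors = FALSE)

  key <- paste(co$target, co$source, sep = "\r")
  sgn <- function(tgt, src) {
    k <- match(paste(tgt, src, sep = "\r"), key)
    if (is.na(k)) 0 else eff_sign[k]
  }
  pl <- list()
  if (length(taxa) > 1) {
    for (a in seq_along(taxa)[-length(taxa)]) {
      for (b in (a + 1):length(taxa)) {
        pl[[length(pl) + 1L]] <- data.frame(
          taxon_a = taxa[a], taxon_b = taxa[b],
          label = classify_pair(sgn(taxa[a], taxa[b]),
                                sgn(taxa[b], taxa[a])),
          stringsAsFactors = FALSE)
      }
    }
  }
  pair_labels <- if (length(pl)) do.call(rbind, pl)
    else data.frame(taxon_a = character(0), taxon_b = character(0),
                    label = character(0), stringsAsFactors = FALSE)

  nodes <- data.frame(
    taxon = taxa,
    growth_rate_mean = aggregate$growth_rates$mean,
    growth_rate_se = aggregate$growth_rates$se,
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, pair_labels = pair_labels,
                 aggregate = aggregate),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction network:", nrow(x$nodes), "taxa,", nrow(x$edges),
      "significant directed edge(s)\n")
  if (nrow(x$edges)) {
    e <- x$edges
    e$relation <- vapply(seq_len(nrow(e)), function(r) {
      pl <- x$pair_labels
      hit <- (pl$taxon_a == e$source[r] & pl$taxon_b == e$target[r]) |
             (pl$taxon_b == e$source[r] & pl$taxon_a == e$target[r])
      pl$label[hit][1]
    }, character(1))
    print(e, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

num_fmt <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 17))
}

#' Export an interaction network
#'
#' Writes the network in up to four plain-text forms: an edge-list TSV
#' (`source`, `target`, `coefficient_mean`, `p_value`,
#' `selection_frequency`, `pair_label`; direction `source -> target`
#' encodes the effect OF the source ON the target, i.e. `a[target,
#' source]`), a node TSV (`taxon`, `growth_rate_mean`, `growth_rate_se`),
#' a GraphML file for network tools, and a JSON audit dump of the full
#' aggregation (all ordered pairs, significant or not). Numeric output is
#' fixed-format so identical networks serialize byte-identically.
#'
#' @param network an `interaction_network`.
#' @param edges_path,nodes_path,graphml_path,json_path output paths;
#'   `NULL` skips that file.
#' @return Invisibly, the written paths.
#' @export
write_network <- function(network, edges_path = NULL, nodes_path = NULL,
                          graphml_path = NULL, json_path = NULL) {
  stopifnot(inherits(network, "interaction_network"))
  written <- character(0)
  if (!is.null(edges_path)) {
    e <- network$edges
    pl <- network$pair_labels
    lab <- vapply(seq_len(nrow(e)), function(r) {
      hit <- (pl$taxon_a == e$source[r] & pl$taxon_b == e$target[r]) |
             (pl$taxon_b == e$source[r] & pl$taxon_a == e$target[r])
      pl$label[hit][1]
    }, character(1))
    lines <- c(paste(c("source", "target", "coefficient_mean", "p_value",
                       "selection_frequency", "pair_label"),
                     collapse = "\t"),
               if (nrow(e)) paste(e$source, e$target,
                                  num_fmt(e$coefficient_mean),
                                  num_fmt(e$p_value),
                                  num_fmt(e$selection_frequency),
                                  lab, sep = "\t"))
    writeLines(lines, edges_path)
    written <- c(written, edges_path)
  }
  if (!is.null(nodes_path)) {
    nd <- network$nodes
    lines <- c("taxon\tgrowth_rate_mean\tgrowth_rate_se",
               paste(nd$taxon, num_fmt(nd$growth_rate_mean),
                     num_fmt(nd$growth_rate_se), sep = "\t"))
    writeLines(lines, nodes_path)
    written <- c(written, nodes_path)
  }
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      network$edges, directed = TRUE,
      vertices = network$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(confidence = network$aggregate$confidence,
           n_models = network$aggregate$n_models,
           coefficients = network$aggregate$coefficients,
           growth_rates = network$aggregate$growth_rates,
           pair_labels = network$pair_labels),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
      na = "null")
    written <- c(written, json_path)
  }
  invisible(written)
}

#' Read an edge-list / node TSV pair back into a network
#'
#' Inverse of the TSV outputs of [write_network] (the aggregate audit is
#' not reconstructed). Used for round-trip checks and for re-labelling
#' exported networks.
#'
#' @param edges_path,nodes_path paths written by [write_network].
#' @return An `interaction_network` (with `aggregate = NULL`).
#' @export
read_network <- function(edges_path, nodes_path) {
  e <- utils::read.table(edges_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  nd <- utils::read.table(nodes_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  taxa <- nd$taxon
  eff <- function(tgt, src) {
    hit <- e$target == tgt & e$source == src
    if (any(hit)) sign(e$coefficient_mean[hit][1]) else 0
  }
  pl <- list()
  if (length(taxa) > 1) {
    for (a in seq_along(taxa)[-length(taxa)]) {
      for (b in (a + 1):length(taxa)) {
        pl[[length(pl) + 1L]] <- data.frame(
          taxon_a = taxa[a], taxon_b = taxa[b],
          label = classify_pair(eff(taxa[a], taxa[b]),
                                eff(taxa[b], taxa[a])),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    nodes = data.frame(taxon = taxa,
                       growth_rate_mean = nd$growth_rate_mean,
                       growth_rate_se = nd$growth_rate_se,
                       stringsAsFactors = FALSE),
    edges = e[, c("source", "target", "coefficient_mean", "p_value",
                  "selection_frequency")],
    pair_labels = if (length(pl)) do.call(rbind, pl)
      else data.frame(taxon_a = character(0), taxon_b = character(0),
                      label = character(0), stringsAsFactors = FALSE),
    aggregate = NULL), class = "interaction_network")
}
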