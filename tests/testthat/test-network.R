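test_that("all nine sign pairs map onto the six ecological forms", {
  expect_identical(classify_pair(1, 1), "mutualism")
  expect_identical(classify_pair(-1, -1), "competition")
  expect_identical(classify_pair(1, -1), "parasitism")
  expect_identical(classify_pair(-1, 1), "parasitism")
  expect_identical(classify_pair(1, 0), "commensalism")
  expect_identical(classify_pair(0, 1), "commensalism")
  expect_identical(classify_pair(-1, 0), "amensalism")
  expect_identical(classify_pair(0, -1), "amensalism")
  expect_identical(classify_pair(0, 0), "neutral")
  # exhaustive: exactly six labels, symmetric in argument order
  signs <- c(-1, 0, 1)
  grid <- expand.grid(s1 = signs, s2 = signs)
  labs <- classify_pair(grid$s1, grid$s2)
  expect_setequal(unique(labs),
                  c("mutualism", "competition", "parasitism",
                    "commensalism", "amensalism", "neutral"))
  expect_identical(labs, classify_pair(grid$s2, grid$s1))
  # magnitudes do not matter, only signs
  expect_identical(classify_pair(3.7, -0.01), "parasitism")
})

fake_aggregate <- function(taxa, sig_edges) {
  # sig_edges: data.frame(target, source, mean)
  pairs <- expand.grid(i = seq_along(taxa), j = seq_along(taxa))
  pairs <- pairs[pairs$i != pairs$j, ]
  co <- data.frame(target = taxa[pairs$i], source = taxa[pairs$j],
                   mean = 0, sd = 0, t_statistic = 0, p_value = 1,
                   selection_frequency = 0, significant = FALSE,
                   stringsAsFactors = FALSE)
  for (k in seq_len(nrow(sig_edges))) {
    hit <- co$target == sig_edges$target[k] &
           co$source == sig_edges$source[k]
    co$mean[hit] <- sig_edges$mean[k]
    co$p_value[hit] <- 0.001
    co$significant[hit] <- TRUE
    co$selection_frequency[hit] <- 0.9
  }
  structure(list(coefficients = co,
                 growth_rates = data.frame(taxon = taxa,
                                           mean = seq_along(taxa) / 10,
                                           se = 0.01,
                                           stringsAsFactors = FALSE),
                 n_models = 10, confidence = 0.95),
            class = "glv_aggregate")
}

test_that("networks carry exactly the significant edges, labelled", {
  taxa <- c("A", "B", "C")
  # single significant a_AB < 0: edge B -> A, pair {A, B} amensalism
  agg <- fake_aggregate(taxa, data.frame(target = "A", source = "B",
                                         mean = -0.7))
  net <- build_network(agg)
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$source, "B")
  expect_identical(net$edges$target, "A")
  expect_lt(net$edges$coefficient_mean, 0)
  lab <- net$pair_labels
  expect_identical(lab$label[lab$taxon_a == "A" & lab$taxon_b == "B"],
                   "amensalism")
  expect_identical(lab$label[lab$taxon_a == "B" & lab$taxon_b == "C"],
                   "neutral")
  # no significant pairs: nodes only, all neutral
  empty <- build_network(fake_aggregate(taxa, data.frame(
    target = character(0), source = character(0), mean = numeric(0))))
  expect_identical(nrow(empty$edges), 0L)
  expect_true(all(empty$pair_labels$label == "neutral"))
  expect_identical(nrow(empty$nodes), 3L)
  # edge count always equals the significant count
  agg2 <- fake_aggregate(taxa, data.frame(
    target = c("A", "B"), source = c("B", "A"), mean = c(0.5, 0.2)))
  net2 <- build_network(agg2)
  expect_identical(nrow(net2$edges), 2L)
  expect_identical(net2$pair_labels$label[1], "mutualism")
})

test_that("a significant mean within 1e-12 of zero carries no sign", {
  agg <- fake_aggregate(c("A", "B"), data.frame(target = "A",
                                                source = "B",
                                                mean = 5e-13))
  net <- build_network(agg)
  expect_identical(nrow(net$edges), 0L)
  expect_identical(net$pair_labels$label, "neutral")
})

test_that("edge/node TSV round trip reproduces the network", {
  taxa <- c("A", "B", "C")
  agg <- fake_aggregate(taxa, data.frame(
    target = c("A", "C"), source = c("B", "B"), mean = c(-0.712, 0.318)))
  net <- build_network(agg)
  ed <- tempfile(fileext = ".tsv"); nd <- tempfile(fileext = ".tsv")
  gm <- tempfile(fileext = ".graphml"); js <- tempfile(fileext = ".json")
  write_network(net, ed, nd, gm, js)
  back <- read_network(ed, nd)
  expect_identical(back$nodes$taxon, net$nodes$taxon)
  expect_equal(back$nodes$growth_rate_mean, net$nodes$growth_rate_mean)
  expect_equal(back$edges$coefficient_mean, net$edges$coefficient_mean)
  expect_identical(back$pair_labels, net$pair_labels)
  # GraphML is consumable by igraph with the same structure
  gr <- igraph::read_graph(gm, format = "graphml")
  expect_equal(igraph::vcount(gr), 3)
  expect_equal(igraph::ecount(gr), 2)
  # JSON audit retains every ordered pair, significant or not
  aud <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(nrow(aud$coefficients), 6L)
  expect_identical(aud$n_models, 10L)
})

test_that("the edge set is invariant under taxon relabelling", {
  e <- data.frame(target = "A", source = "B", mean = -0.4)
  net1 <- build_network(fake_aggregate(c("A", "B"), e))
  e2 <- data.frame(target = "X", source = "Y", mean = -0.4)
  net2 <- build_network(fake_aggregate(c("X", "Y"), e2))
  expect_identical(nrow(net1$edges), nrow(net2$edges))
  expect_identical(net1$pair_labels$label, net2$pair_labels$label)
  expect_equal(net1$edges$coefficient_mean, net2$edges$coefficient_mean)
})
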