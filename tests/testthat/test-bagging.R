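make_series <- function(T_ = 20) {
  P <- matrix(runif(T_ * 2, 0.2, 0.8), T_, 2)
  abundance_series(c("u", "v"), seq_len(T_) - 1, P, normalize = TRUE)
}

test_that("partitioning keeps the first point and the requested fraction", {
  set.seed(1)
  s <- make_series(20)
  part <- partition_series(s, 0.8)
  expect_identical(length(part$train$times), 16L)  # round(0.8 * 20)
  expect_identical(part$train_indices[1], 1L)
  expect_identical(part$train$times[1], s$times[1])
  # temporal order and exact complement
  expect_true(all(diff(part$train$times) > 0))
  expect_identical(sort(c(part$train$times, part$test$times)), s$times)
  # fraction 1 trains on everything
  full <- partition_series(s, 1)
  expect_identical(full$train$times, s$times)
  expect_null(full$test)
  expect_error(partition_series(subset_series_head(s, 2), 0.8), "3 time")
})

test_that("partitions are reproducible under a fixed seed", {
  s <- make_series(15)
  draw <- function(seed) {
    set.seed(seed)
    partition_series(s, 0.8)$train_indices
  }
  expect_identical(draw(5), draw(5))
  expect_false(identical(draw(5), draw(6)))
})

test_that("bagging is deterministic and thread-count independent", {
  spec <- preset_two_taxon(seed = 4)
  g <- generate_series(spec)
  cfg <- quick_config(seed = 99, n_bootstraps = 6)
  e1 <- run_bagging(g$observed, cfg)
  e2 <- run_bagging(g$observed, cfg)
  expect_identical(length(e1$models), length(e2$models))
  for (i in seq_along(e1$models)) {
    expect_identical(e1$models[[i]]$select_set, e2$models[[i]]$select_set)
    expect_identical(e1$models[[i]]$params$A, e2$models[[i]]$params$A)
  }
  cfg2 <- quick_config(seed = 99, n_bootstraps = 6, threads = 2)
  e3 <- run_bagging(g$observed, cfg2)
  expect_identical(lapply(e1$models, `[[`, "params"),
                   lapply(e3$models, `[[`, "params"))
  # a single bootstrap yields a single model (or one recorded failure)
  e4 <- run_bagging(g$observed, quick_config(seed = 1, n_bootstraps = 1))
  expect_identical(length(e4$models) + e4$n_failed, 1L)
})

test_that("truncating an ensemble equals running fewer bootstraps", {
  spec <- preset_two_taxon(seed = 8)
  g <- generate_series(spec)
  big <- run_bagging(g$observed, quick_config(seed = 7, n_bootstraps = 8))
  small <- run_bagging(g$observed, quick_config(seed = 7, n_bootstraps = 3))
  cut <- truncate_ensemble(big, 3)
  expect_identical(length(cut$models), length(small$models))
  expect_identical(lapply(cut$models, `[[`, "params"),
                   lapply(small$models, `[[`, "params"))
})

test_that("biological filtering removes extinction-driving models", {
  spec <- preset_two_taxon(seed = 2)
  g <- generate_series(spec)
  cfg <- quick_config(seed = 3, n_bootstraps = 4)
  ens <- run_bagging(g$observed, cfg)
  ens$series <- g$observed
  # no constraints: untouched
  expect_identical(filter_models(ens, 0, 0), ens)
  # plant a model whose strong self-reinforcing suppression kills taxon 1
  bad <- ens$models[[1]]
  A_bad <- matrix(c(0, 0, -40, 0), 2, 2,
                  dimnames = list(ens$taxa, ens$taxa))
  bad$params <- glv_params(ens$taxa, c(-2, 2), A_bad, 1e10)
  bad$bootstrap_id <- 999L
  ens$models <- c(ens$models, list(bad))
  filtered <- filter_models(ens, min_species_abundance = 1e6)
  expect_lt(length(filtered$models), length(ens$models))
  expect_true(999L %in% filtered$filter_log$bootstrap_id)
  expect_match(filtered$filter_log$reason[
    filtered$filter_log$bootstrap_id == 999L], "below")
  # idempotent
  again <- filter_models(filtered, min_species_abundance = 1e6)
  expect_identical(length(again$models), length(filtered$models))
})

test_that("the best-BIC slice follows minimum + allowance", {
  A0 <- matrix(0, 2, 2)
  ens <- fake_ensemble(list(A0, A0, A0), bics = c(-100, -95, -50))
  kept <- select_best(ens, allowance = 0.10, mode = "relative")
  expect_identical(vapply(kept$models, `[[`, numeric(1), "bic_full"),
                   c(-100, -95))  # cutoff -90
  only_min <- select_best(ens, allowance = 0)
  expect_identical(vapply(only_min$models, `[[`, numeric(1), "bic_full"),
                   -100)
  same <- fake_ensemble(list(A0, A0), bics = c(-7, -7))
  expect_identical(length(select_best(same)$models), 2L)
  abs_mode <- select_best(ens, allowance = 6, mode = "absolute")
  expect_identical(length(abs_mode$models), 2L)  # cutoff -94
  empty <- fake_ensemble(list(A0))
  empty$models <- list()
  expect_error(select_best(empty), "no models")
})

test_that("aggregation reproduces the textbook one-sample t-test", {
  vals <- c(0.5, 0.6, 0.4, 0.0, 0.5)
  A_list <- lapply(vals, function(v)
    matrix(c(0, 0, v, 0), 2, 2))  # a_uv = v (entry [1, 2]); 0 stays absent
  ens <- fake_ensemble(A_list)
  agg <- aggregate_and_test(ens, confidence = 0.95)
  row <- agg$coefficients[agg$coefficients$target == "u" &
                          agg$coefficients$source == "v", ]
  tt <- stats::t.test(vals, mu = 0)
  expect_equal(row$mean, mean(vals))
  expect_equal(row$t_statistic, unname(tt$statistic))
  expect_equal(row$p_value, tt$p.value)
  expect_equal(row$t_statistic, mean(vals) / (sd(vals) / sqrt(5)))
  expect_identical(row$selection_frequency, 0.8)  # the 0 was never selected
  # never-selected pair: all zeros, p = 1 by convention
  other <- agg$coefficients[agg$coefficients$target == "v", ]
  expect_identical(other$p_value, 1)
  expect_false(other$significant)
})

test_that("zero-variance aggregation conventions hold", {
  A_const <- matrix(c(0, 0, 0.4, 0), 2, 2)
  ens <- fake_ensemble(list(A_const, A_const, A_const))
  agg <- aggregate_and_test(ens)
  row <- agg$coefficients[agg$coefficients$target == "u" &
                          agg$coefficients$source == "v", ]
  expect_identical(row$p_value, 0)
  expect_true(row$significant)
  expect_equal(row$mean, 0.4)
  # one model only: significance undefined, flagged
  ens1 <- fake_ensemble(list(A_const))
  expect_warning(agg1 <- aggregate_and_test(ens1), "one retained")
  expect_true(all(is.na(agg1$coefficients$p_value)))
})

test_that("raising the confidence never adds significant edges", {
  spec <- preset_predator_prey(seed = 6)
  g <- generate_series(spec)
  cfg <- quick_config(seed = 5, n_bootstraps = 25)
  ens <- select_best(run_bagging(g$observed, cfg))
  a95 <- aggregate_and_test(ens, confidence = 0.95)
  a99 <- aggregate_and_test(ens, confidence = 0.99)
  sig95 <- a95$coefficients$significant
  sig99 <- a99$coefficients$significant
  expect_true(all(!sig99 | sig95))
})

test_that("growth rates aggregate to means with standard errors", {
  A0 <- matrix(0, 2, 2)
  ens <- fake_ensemble(list(A0, A0, A0))
  for (i in 1:3) ens$models[[i]]$params$r <- c(u = i, v = 2 * i)
  agg <- aggregate_and_test(ens)
  expect_equal(agg$growth_rates$mean, c(2, 4))
  expect_equal(agg$growth_rates$se,
               c(sd(1:3), sd(c(2, 4, 6))) / sqrt(3))
})
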