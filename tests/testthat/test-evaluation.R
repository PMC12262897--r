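test_that("partitioning is person-level, disjoint and exhaustive", {
  ch <- small_cohort(10, sigma_b = 0.5, seed = 51)
  pt <- partition_by_individual(ch, 0.7, seed = 1)
  expect_equal(length(unique(pt$train$person_id)), 7L)
  expect_equal(nrow(pt$train), 14L)
  expect_equal(nrow(pt$test), 6L)
  expect_length(intersect(pt$train$person_id, pt$test$person_id), 0)
  recombined <- rbind(pt$train, pt$test)
  recombined <- recombined[order(recombined$person_id, recombined$side), ]
  expect_equal(recombined, ch, ignore_attr = TRUE)
  expect_error(partition_by_individual(ch[1:2, ], 0.7, seed = 1),
               "at least 2")
})

test_that("AUC matches the worked example and edge cases", {
  expect_equal(compute_auc(c(0, 0, 1, 1), c(0.1, 0.6, 0.4, 0.8)), 0.75)
  expect_equal(compute_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(compute_auc(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  expect_error(compute_auc(c(1, 1), c(0.2, 0.3)),
               class = "bimm_degenerate_outcome")
})

test_that("AUC equals brute-force pair counting on random instances", {
  set.seed(61)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    scores <- round(runif(n), sample(1:3, 1))  # induce ties
    expect_equal(compute_auc(y, scores), auc_brute(y, scores),
                 tolerance = 1e-12)
  }
})

test_that("confusion metrics follow the strict-threshold rule", {
  perfect <- confusion_metrics(c(1, 1, 0, 0), c(0.9, 0.9, 0.1, 0.1), 0.5)
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1,
                                  accuracy = 1, fpr = 0))
  inverted <- confusion_metrics(c(1, 0), c(0.2, 0.9), 0.5)
  expect_equal(unlist(inverted), c(sensitivity = 0, specificity = 0,
                                   accuracy = 0, fpr = 1))
  # 3 positives (2 detected), 7 negatives (1 false positive)
  y <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  s <- c(0.9, 0.8, 0.2, 0.7, 0.3, 0.3, 0.2, 0.1, 0.1, 0.1)
  cm <- confusion_metrics(y, s, 0.5)
  expect_equal(cm$sensitivity, 2 / 3)
  expect_equal(cm$specificity, 6 / 7)
  expect_equal(cm$fpr, 1 - cm$specificity, tolerance = 1e-12)
  # ties at the threshold go to class 0
  expect_equal(confusion_metrics(c(1, 0), c(0.5, 0.1), 0.5)$sensitivity, 0)
})

test_that("phi coefficient matches direct arithmetic", {
  expect_equal(phi_coefficient(40, 10, 10, 40), 0.6)
  expect_equal(phi_coefficient(25, 25, 25, 25), 0.0)
  expect_equal(phi_coefficient(50, 0, 0, 50), 1.0)
  set.seed(62)
  for (i in 1:100) {
    cells <- rpois(4, 20) + 1
    direct <- (cells[1] * cells[4] - cells[2] * cells[3]) /
      sqrt((cells[1] + cells[2]) * (cells[3] + cells[4]) *
             (cells[1] + cells[3]) * (cells[2] + cells[4]))
    expect_equal(do.call(phi_coefficient, as.list(cells)), direct,
                 tolerance = 1e-12)
  }
  expect_error(phi_coefficient(10, 0, 5, 0), class = "bimm_degenerate_table")
  expect_error(phi_coefficient(-1, 2, 3, 4), "non-negative")
})

test_that("the Welch test matches the textbook formulas", {
  a <- c(0.71, 0.74, 0.73, 0.70, 0.76)
  b <- c(0.69, 0.72, 0.70, 0.68, 0.71)
  res <- two_sample_t(a, b)
  oracle <- welch_oracle(a, b)
  expect_equal(res$t, oracle$t, tolerance = 1e-8)
  expect_equal(res$p, oracle$p, tolerance = 1e-8)
  expect_true(res$ci_low <= res$mean_difference &&
                res$mean_difference <= res$ci_high)
  # identical samples with internal variance: exact null
  same <- c(0.1, 0.2, 0.3)
  res0 <- two_sample_t(same, same)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  expect_equal(res0$ci_low, -res0$ci_high)
  expect_error(two_sample_t(rep(1, 3), rep(1, 3)),
               class = "bimm_degenerate_variance")
})

test_that("importance aggregation counts unions and averages scores", {
  mk <- function(vars, scores)
    data.frame(variable = vars, mean_decrease_gini = scores)
  lst <- replicate(100, mk(paste0("v", 1:20), 20:1), simplify = FALSE)
  expect_equal(aggregate_importance(lst)$unique_count, 20L)
  disjoint <- list(mk(paste0("a", 1:20), 20:1), mk(paste0("b", 1:20), 20:1))
  expect_equal(aggregate_importance(disjoint)$unique_count, 40L)
  # hand-computed means over partitions where the variable appears
  p1 <- mk(c("u", "v", "w"), c(9, 6, 3))
  p2 <- mk(c("u", "v", "x"), c(3, 2, 8))
  p3 <- mk(c("u", "y", "z"), c(6, 5, 1))
  agg <- aggregate_importance(list(p1, p2, p3), top_k_unique = 3L,
                              top_k_mean = 3L)
  expect_equal(agg$unique_count, 6L)
  means <- setNames(agg$top_mean$mean_gini, agg$top_mean$variable)
  expect_equal(means[["x"]], 8)     # present once
  expect_equal(means[["u"]], 6)     # (9 + 3 + 6) / 3
  zeroed <- aggregate_importance(list(p1, p2, p3), top_k_unique = 3L,
                                 top_k_mean = 6L, absent_as_zero = TRUE)
  zmeans <- setNames(zeroed$top_mean$mean_gini, zeroed$top_mean$variable)
  expect_equal(zmeans[["x"]], 8 / 3)
  expect_error(aggregate_importance(list()), "empty")
  expect_error(aggregate_importance(list(p1), top_k_unique = 5L), "exactly")
})

test_that("the repeated-holdout harness aggregates its own partitions", {
  ch <- small_cohort(80, sigma_b = 1, seed = 71)
  ex <- run_experiment(ch, split_spec("h1", k1 = 0.5),
                       rf_params = list(num_trees = 60),
                       n_partitions = 2, threshold = 0.5, seed = 5)
  expect_equal(nrow(ex$metrics), 4L)
  for (method in c("BiMM", "RF")) {
    rows <- ex$metrics[ex$metrics$method == method, ]
    means <- ex$summary$mean[ex$summary$mean$method == method, ]
    expect_equal(means$auc, mean(rows$auc))
    expect_equal(means$sensitivity, mean(rows$sensitivity))
    expect_equal(means$fpr, mean(rows$fpr))
  }
  expect_true(all(abs(ex$metrics$fpr - (1 - ex$metrics$specificity)) < 1e-12))
  # reproducibility from the master seed
  ex2 <- run_experiment(ch, split_spec("h1", k1 = 0.5),
                        rf_params = list(num_trees = 60),
                        n_partitions = 2, threshold = 0.5, seed = 5)
  expect_identical(ex$metrics, ex2$metrics)
  expect_identical(ex$summary, ex2$summary)
})
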