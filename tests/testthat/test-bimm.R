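rf_small <- list(num_trees = 100)

test_that("update_outcome applies the split function elementwise", {
  expect_identical(update_outcome(c(0L, 0L, 1L), c(0.3, 0.2, 0.1),
                                  split_spec("h1", k1 = 0.25)),
                   c(1L, 0L, 1L))
  expect_identical(update_outcome(c(1L, 0L), c(0.4, 0.6),
                                  split_spec("h2", k2 = 1.5)),
                   c(0L, 0L))
  # h1 can only raise labels
  set.seed(1)
  y <- rbinom(200, 1, 0.4); q <- runif(200, 0.01, 0.99)
  for (k1 in c(0.1, 0.5, 0.9))
    expect_true(all(update_outcome(y, q, split_spec("h1", k1 = k1)) >= y))
  for (k2 in c(1.1, 1.5, 1.9))
    expect_true(all(update_outcome(y, q, split_spec("h2", k2 = k2)) <= y))
})

test_that("a degenerate tolerance stops after exactly two iterations", {
  ch <- small_cohort(80, sigma_b = 1, seed = 21)
  m <- fit_bimm(ch, split_spec("h1", k1 = 0.9), rf_params = rf_small,
                tolerance = 1e9, seed = 3)
  expect_equal(m$n_iterations, 2L)
  expect_true(m$converged)
  expect_equal(nrow(m$trajectory), 2L)
})

test_that("identical seeds give identical trajectories and predictions", {
  ch <- small_cohort(100, sigma_b = 1.5, seed = 22)
  m1 <- fit_bimm(ch, split_spec("h3"), rf_params = rf_small, seed = 9)
  m2 <- fit_bimm(ch, split_spec("h3"), rf_params = rf_small, seed = 9)
  expect_identical(m1$trajectory, m2$trajectory)
  expect_identical(predict(m1, ch), predict(m2, ch))
})

test_that("the working outcome moves one way only, per split family", {
  ch <- small_cohort(150, sigma_b = 2, seed = 23)
  m1 <- fit_bimm(ch, split_spec("h1", k1 = 0.4), rf_params = rf_small,
                 seed = 4)
  expect_gte(mean(m1$working_outcome), mean(ch$outcome))
  expect_true(all(m1$working_outcome >= ch$outcome))
  m2 <- fit_bimm(ch, split_spec("h2", k2 = 1.6), rf_params = rf_small,
                 seed = 4)
  expect_lte(mean(m2$working_outcome), mean(ch$outcome))
  expect_true(all(m2$working_outcome <= ch$outcome))
})

test_that("with no flips BiMM equals a plain forest on the original outcome", {
  ch <- small_cohort(150, sigma_b = 1, seed = 24, effects = rep(0.3, 5))
  m <- fit_bimm(ch, split_spec("h1", k1 = 0.9), rf_params = rf_small,
                seed = 14)
  expect_equal(sum(m$trajectory$n_outcome_flips), 0L)
  rfp <- bimmknee:::resolve_rf_params(rf_small)
  rfp$majority_class <- 0L
  plain <- bimmknee:::fit_forest(bimmknee:::cohort_covariates(ch),
                                 ch$outcome, rfp, 14)
  expect_identical(
    predict(m, ch),
    unname(predict(plain, bimmknee:::cohort_covariates(ch),
                   type = "prob")[, "1"]))
})

test_that("predictions reproduce the final forest fit and stay in [0, 1]", {
  ch <- small_cohort(100, sigma_b = 1, seed = 25)
  m <- fit_bimm(ch, split_spec("h1", k1 = 0.25), rf_params = rf_small,
                seed = 5)
  expect_identical(predict(m, ch), m$fitted_probabilities)
  expect_identical(predict_bimm(m, ch), predict(m, ch))
  fresh <- small_cohort(50, sigma_b = 1, seed = 26)
  pr <- predict(m, fresh)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_error(predict(m, fresh[, 1:4]), "lacks covariate")
})

test_that("a fully determining covariate yields near-perfect test AUC", {
  make_det <- function(seed) {
    set.seed(seed)
    n <- 200
    x1 <- runif(2 * n, -1, 1)
    out <- data.frame(person_id = rep(seq_len(n), each = 2),
                      side = rep(c(1L, 2L), n),
                      outcome = as.integer(x1 > 0),
                      x1 = x1, x2 = rnorm(2 * n))
    class(out) <- c("cohort", "data.frame")
    out
  }
  m <- fit_bimm(make_det(31), split_spec("h1", k1 = 0.25),
                rf_params = rf_small, seed = 6)
  test_set <- make_det(32)
  expect_gt(compute_auc(test_set$outcome, predict(m, test_set)), 0.95)
})

test_that("an outcome collapse is flagged and the last model returned", {
  # h2 with k2 near 2 flips almost every 1 to 0 on a weak-signal cohort
  cfg <- generator_config(60, 1, 1, c(0.1, 0.1), intercept = -1,
                          random_intercept_sd = 0.5, seed = 41)
  ch <- generate_cohort(cfg)
  m <- fit_bimm(ch, split_spec("h2", k2 = 1.95), rf_params = rf_small,
                seed = 7, max_iter = 10)
  expect_true(m$collapsed || m$converged)
  if (m$collapsed) {
    expect_false(m$converged)
    expect_s3_class(m$final_forest, "randomForest")
    expect_true(all(m$working_outcome %in% c(0L, 1L)))
  }
})

test_that("reaching max_iter is flagged", {
  ch <- small_cohort(80, sigma_b = 1, seed = 27)
  # h3 flips in both directions, so the trajectory keeps moving
  m <- fit_bimm(ch, split_spec("h3"), rf_params = rf_small,
                tolerance = 1e-9, max_iter = 3, seed = 8)
  expect_equal(m$n_iterations, 3L)
  expect_true(m$max_iter_reached)
  expect_false(m$converged)
})

test_that("trajectories serialise to CSV", {
  ch <- small_cohort(60, sigma_b = 1, seed = 28)
  m <- fit_bimm(ch, split_spec("h1", k1 = 0.5), rf_params = rf_small,
                seed = 10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(m, f)
  back <- read.csv(f)
  expect_equal(back, m$trajectory)
})
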