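#' Update the working outcome through a split function
#'
#' Applies \eqn{Y^* = h(Y + Q)} elementwise, dispatching on the split-function
#' family. The stochastic family \code{h3} consumes R's RNG (one uniform per
#' element); seed beforehand for reproducibility.
#'
#' @param y current working outcome (0/1 vector).
#' @param q mixed-model probabilities \eqn{Q_{it}}, strictly inside (0, 1).
#' @param spec a \code{\link{split_spec}}.
#' @return Integer vector of 0/1, same length as \code{y}.
#' @examples
#' update_outcome(c(0L, 0L, 1L), c(0.3, 0.2, 0.1), split_spec("h1", k1 = 0.25))
#' @export
update_outcome <- function(y, q, spec) {
  stopifnot(inherits(spec, "split_spec"))
  if (!is_binary01(y)) stop("y must be a 0/1 vector")
  if (length(y) != length(q)) stop("y and q must have equal length")
  switch(spec$kind,
         h1 = apply_h1(y + q, spec$k1),
         h2 = apply_h2(y + q, spec$k2),
         h3 = apply_h3(y, q))
}

# Resolve forest configuration with defaults.
resolve_rf_params <- function(rf_params) {
  defaults <- list(num_trees = 500L, class_weight = NULL, mtry = NULL)
  unknown <- setdiff(names(rf_params), names(defaults))
  if (length(unknown))
    stop("unknown rf_params field(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, rf_params)
}

# classwt vector for randomForest: weight w on the majority class of the
# *original* training outcome, minority fixed at 1 (so w = 0.37 gives the
# minority class 1/0.37 ~ 2.7x the influence of the majority).
class_weights_for <- function(class_weight, majority_class) {
  if (is.null(class_weight)) return(NULL)
  cw <- c("0" = 1, "1" = 1)
  cw[as.character(majority_class)] <- class_weight
  cw
}

# Fit a seeded classification forest on covariates `x` and 0/1 outcome `y`.
fit_forest <- function(x, y, rf, seed) {
  cw <- class_weights_for(rf$class_weight, rf$majority_class)
  with_seed(seed, {
    args <- list(x = x, y = factor(y, levels = c(0L, 1L)),
                 ntree = rf$num_trees, keep.forest = TRUE)
    if (!is.null(cw)) args$classwt <- cw
    if (!is.null(rf$mtry)) args$mtry <- rf$mtry
    do.call(randomForest::randomForest, args)
  })
}

cohort_covariates <- function(cohort) {
  cols <- setdiff(colnames(cohort), c("person_id", "side", "outcome"))
  cohort[, cols, drop = FALSE]
}

#' Fit a Binary Mixed Model (BiMM)
#'
#' Alternates a classification random forest with the Bayesian logistic
#' random-intercept model of \code{\link{fit_mixed}}: each iteration (1) fits
#' a forest on the current working outcome, (2) extracts the fitted (in-bag)
#' class-1 probabilities, (3) fits the mixed model on the working outcome
#' with those probabilities as the fixed effect and the person ID as the
#' cluster, (4) records the posterior log-likelihood, and (5) stops when its
#' absolute change between consecutive iterations falls below
#' \code{tolerance}, otherwise updates the outcome through the split function
#' and repeats. The forest RNG seed is identical across iterations, so a
#' fixed-point working outcome reproduces an identical forest — in
#' particular, if the split function never flips a label, the final forest
#' equals a plain forest fit on the original outcome with the same seed.
#'
#' @param train a \code{"cohort"} table (see \code{\link{generate_cohort}} or
#'   \code{\link{read_cohort}}).
#' @param spec a \code{\link{split_spec}}.
#' @param rf_params list with any of \code{num_trees} (default 500),
#'   \code{class_weight} (weight on the majority class, minority fixed at 1;
#'   \code{NULL} for equal weights), \code{mtry}.
#' @param tolerance convergence tolerance on the absolute change in posterior
#'   log-likelihood (default 0.5).
#' @param max_iter iteration cap; reaching it is flagged in the result.
#' @param seed integer seed controlling all randomness (forest bootstraps,
#'   stochastic split draws).
#' @param prior_sd passed to \code{\link{fit_mixed}}.
#' @param oob use out-of-bag (default) or in-bag fitted probabilities in step
#'   (2). In-bag probabilities from a fully grown forest interpolate the
#'   training outcome almost perfectly, which saturates the mixed model,
#'   suppresses every label flip and collapses the iteration to a plain
#'   forest refit; out-of-bag probabilities keep the update informative.
#' @return An object of class \code{"bimm"}: \code{final_forest},
#'   \code{mixed_fit}, \code{split_spec}, \code{n_iterations},
#'   \code{trajectory} (data frame with \code{iteration},
#'   \code{posterior_log_likelihood}, \code{n_outcome_flips}),
#'   \code{fitted_probabilities} (final forest, training rows),
#'   \code{converged} / \code{collapsed} / \code{max_iter_reached} flags, and
#'   the configuration used.
#' @export
fit_bimm <- function(train, spec, rf_params = list(), tolerance = 0.5,
                     max_iter = 50L, seed = 1L, prior_sd = 2.5, oob = TRUE) {
  check_cohort(train)
  stopifnot(inherits(spec, "split_spec"))
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be a positive number")
  rf <- resolve_rf_params(rf_params)
  y0 <- as.integer(train$outcome)
  rf$majority_class <- if (mean(y0) > 0.5) 1L else 0L
  x <- cohort_covariates(train)
  if (ncol(x) == 0L) stop("cohort has no covariate columns")
  ids <- train$person_id

  y <- y0
  trajectory <- data.frame(iteration = integer(0),
                           posterior_log_likelihood = numeric(0),
                           n_outcome_flips = integer(0))
  converged <- FALSE; collapsed <- FALSE
  pll_prev <- NA_real_
  forest <- NULL; mm <- NULL; p_raw <- NULL

  for (it in seq_len(max_iter)) {
    forest <- fit_forest(x, y, rf, seed)
    p_raw <- if (oob) forest$votes[, "1"] else
      stats::predict(forest, x, type = "prob")[, "1"]
    if (anyNA(p_raw)) {
      # rows never out-of-bag (tiny forests): fall back to in-bag votes
      fill <- stats::predict(forest, x, type = "prob")[, "1"]
      p_raw[is.na(p_raw)] <- fill[is.na(p_raw)]
    }
    mm <- fit_mixed(y, p_raw, ids, prior_sd = prior_sd)
    pll <- mm$posterior_log_likelihood
    trajectory <- rbind(trajectory, data.frame(
      iteration = it, posterior_log_likelihood = pll,
      n_outcome_flips = 0L))
    if (it >= 2L && abs(pll - pll_prev) < tolerance) {
      converged <- TRUE
      break
    }
    pll_prev <- pll
    if (it == max_iter) break
    y_new <- with_seed(derive_seed(seed, stream = 31L, index = it),
                       update_outcome(y, mm$fitted_q, spec))
    flips <- sum(y_new != y)
    trajectory$n_outcome_flips[it] <- as.integer(flips)
    if (length(unique(y_new)) < 2L) {
      # Updated outcome collapsed to one class: keep this iteration's model.
      collapsed <- TRUE
      break
    }
    y <- y_new
  }

  structure(list(
    final_forest = forest,
    mixed_fit = mm,
    split_spec = spec,
    n_iterations = nrow(trajectory),
    trajectory = trajectory,
    fitted_probabilities =
      unname(stats::predict(forest, x, type = "prob")[, "1"]),
    loop_probabilities = unname(p_raw),
    working_outcome = y,
    converged = converged,
    collapsed = collapsed,
    max_iter_reached = !converged && !collapsed,
    tolerance = tolerance,
    rf_params = rf[c("num_trees", "class_weight", "mtry")],
    covariate_names = colnames(x),
    seed = as.integer(seed)),
    class = "bimm")
}

#' Predict from a fitted BiMM
#'
#' Population-level prediction: class-1 probabilities from the final forest.
#' Random effects of unseen persons are zero by definition, so no
#' random-effect adjustment is applied.
#'
#' @param object a \code{"bimm"} model.
#' @param newdata a cohort table or a data frame containing the training
#'   covariate columns.
#' @param ... unused.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict.bimm <- function(object, newdata, ...) {
  cols <- object$covariate_names
  missing_cols <- setdiff(cols, colnames(newdata))
  if (length(missing_cols))
    stop("newdata lacks covariate column(s): ",
         paste(missing_cols, collapse = ", "))
  unname(stats::predict(object$final_forest,
                        newdata[, cols, drop = FALSE],
                        type = "prob")[, "1"])
}

#' @rdname predict.bimm
#' @param model a \code{"bimm"} model.
#' @param covariates as \code{newdata} above.
#' @export
predict_bimm <- function(model, covariates) predict(model, covariates)

#' Variable importance of the final BiMM forest
#'
#' Mean Decrease Gini scores of the final forest, sorted decreasingly. Gini
#' importance is node-based and therefore remains meaningful under BiMM's
#' outcome updating (unlike attribution methods tied to the observed outcome
#' values).
#'
#' @param model a \code{"bimm"} model or a \code{randomForest} object.
#' @param top number of variables to return (default all).
#' @return Data frame with columns \code{variable}, \code{mean_decrease_gini}.
#' @export
bimm_importance <- function(model, top = Inf) {
  forest <- if (inherits(model, "bimm")) model$final_forest else model
  imp <- randomForest::importance(forest, type = 2)
  out <- data.frame(variable = rownames(imp),
                    mean_decrease_gini = unname(imp[, 1L]))
  out <- out[order(-out$mean_decrease_gini), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top)
}

#' @export
print.bimm <- function(x, ...) {
  cat("Binary Mixed Model (forest + logistic random intercept)\n")
  print(x$split_spec)
  status <- if (x$converged) "converged" else if (x$collapsed)
    "stopped (outcome collapsed)" else "stopped (max_iter reached)"
  cat(sprintf("  %d iteration(s), %s, tolerance %.3g\n",
              x$n_iterations, status, x$tolerance))
  cat(sprintf("  final posterior log-likelihood: %.3f\n",
              x$trajectory$posterior_log_likelihood[x$n_iterations]))
  cat(sprintf("  forest: %d trees over %d covariates\n",
              x$rf_params$num_trees, length(x$covariate_names)))
  invisible(x)
}

#' Write a BiMM iteration trajectory to CSV
#'
#' @param model a \code{"bimm"} model.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(model, path) {
  stopifnot(inherits(model, "bimm"))
  utils::write.csv(model$trajectory, path, row.names = FALSE)
  invisible(path)
}
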