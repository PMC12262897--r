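#' Split a bilateral cohort into train and test sets at the person level
#'
#' Persons (not knees) are sampled without replacement into the training set,
#' so both knees of a person always land on the same side of the split and
#' the test set contains only unseen persons.
#'
#' @param cohort a \code{"cohort"} table.
#' @param train_fraction fraction of persons assigned to training (rounded to
#'   the nearest person).
#' @param seed integer seed.
#' @return List with elements \code{train} and \code{test}, both cohorts.
#' @export
partition_by_individual <- function(cohort, train_fraction = 0.7, seed = 1L) {
  check_cohort(cohort)
  ids <- unique(cohort$person_id)
  if (length(ids) < 2L) stop("need at least 2 persons to partition")
  n_train <- round(train_fraction * length(ids))
  train_ids <- with_seed(seed, sample(ids, n_train))
  in_train <- cohort$person_id %in% train_ids
  list(train = cohort[in_train, , drop = FALSE],
       test = cohort[!in_train, , drop = FALSE])
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted one half — computed from midranks, so
#' it is exact and \eqn{O(n \log n)}.
#'
#' @param y binary outcome vector with both classes present.
#' @param scores numeric prediction scores.
#' @return AUC in \[0, 1\].
#' @examples
#' compute_auc(c(0, 0, 1, 1), c(0.1, 0.6, 0.4, 0.8))  # 0.75
#' @export
compute_auc <- function(y, scores) {
  if (length(y) != length(scores)) stop("y and scores must have equal length")
  if (!is_binary01(y)) stop("y must be a 0/1 vector")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop_degenerate("AUC undefined: only one outcome class present",
                    "bimm_degenerate_outcome")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold classification metrics
#'
#' Classifies as 1 exactly when \code{score > threshold} (ties at the
#' threshold go to class 0) and returns the standard confusion-matrix
#' summaries. By construction \code{fpr = 1 - specificity}.
#'
#' @param y binary outcome vector with both classes present.
#' @param scores numeric prediction scores.
#' @param threshold classification cut-off.
#' @return Named list with \code{sensitivity}, \code{specificity},
#'   \code{accuracy}, \code{fpr}.
#' @export
confusion_metrics <- function(y, scores, threshold) {
  if (length(y) != length(scores)) stop("y and scores must have equal length")
  if (!is_binary01(y)) stop("y must be a 0/1 vector")
  if (sum(y == 1) == 0L || sum(y == 0) == 0L)
    stop_degenerate("confusion metrics undefined with a single outcome class",
                    "bimm_degenerate_outcome")
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / length(y), fpr = 1 - spec)
}

#' Phi coefficient of a 2x2 contingency table
#'
#' Pearson correlation of two binary variables:
#' \deqn{\phi = (ad - bc) / \sqrt{(a+b)(c+d)(a+c)(b+d)}}
#' for the table with cells \code{a} (1,1), \code{b} (1,0), \code{c} (0,1),
#' \code{d} (0,0).
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return Phi in \[-1, 1\]. A zero margin raises a condition of class
#'   \code{"bimm_degenerate_table"}.
#' @examples
#' phi_coefficient(40, 10, 10, 40)  # 0.6
#' @export
phi_coefficient <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells)))
    stop("cell counts must be non-negative integers")
  a <- as.double(a); b <- as.double(b); c <- as.double(c); d <- as.double(d)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    stop_degenerate("phi undefined: a margin of the 2x2 table is zero",
                    "bimm_degenerate_table")
  (a * d - b * c) / sqrt(prod(margins))
}

#' Welch two-sample t-test on per-partition AUC vectors
#'
#' Thin wrapper around \code{stats::t.test} (Welch by default; set
#' \code{paired = TRUE} for the paired variant when both methods share the
#' same partitions) returning the pieces the evaluation summary reports.
#'
#' @param auc_a,auc_b numeric vectors, length >= 2 each.
#' @param paired use the paired test instead of Welch.
#' @return Named list with \code{t}, \code{p}, \code{ci_low}, \code{ci_high},
#'   \code{mean_difference}.
#' @export
two_sample_t <- function(auc_a, auc_b, paired = FALSE) {
  if (length(auc_a) < 2L || length(auc_b) < 2L)
    stop("each sample needs at least 2 values")
  if (stats::var(auc_a) == 0 && stats::var(auc_b) == 0)
    stop_degenerate("t-test undefined: both samples have zero variance",
                    "bimm_degenerate_variance")
  tt <- stats::t.test(auc_a, auc_b, paired = paired)
  list(t = unname(tt$statistic), p = tt$p.value,
       ci_low = tt$conf.int[1L], ci_high = tt$conf.int[2L],
       mean_difference = mean(auc_a) - mean(auc_b))
}

#' Aggregate per-partition variable-importance lists
#'
#' Takes one top-\code{top_k_unique} Mean Decrease Gini list per partition and
#' reports (a) the number of unique variables appearing in any list and
#' (b) the \code{top_k_mean} variables with the highest average score. By
#' default a variable's score is averaged over the partitions where it enters
#' the top list; \code{absent_as_zero = TRUE} averages over all partitions,
#' counting absences as zero.
#'
#' @param per_partition list of data frames with columns \code{variable} and
#'   \code{mean_decrease_gini}, each with exactly \code{top_k_unique} rows.
#' @param top_k_unique required length of each input list.
#' @param top_k_mean how many top-average variables to report.
#' @param absent_as_zero count partitions where a variable is absent as zero
#'   score.
#' @return List with \code{unique_count} and \code{top_mean} (data frame of
#'   \code{variable}, \code{mean_gini}, sorted decreasingly).
#' @export
aggregate_importance <- function(per_partition, top_k_unique = 20L,
                                 top_k_mean = 10L, absent_as_zero = FALSE) {
  if (length(per_partition) == 0L) stop("empty importance list")
  ok <- vapply(per_partition, function(d)
    is.data.frame(d) && nrow(d) == top_k_unique &&
      all(c("variable", "mean_decrease_gini") %in% colnames(d)),
    logical(1))
  if (!all(ok))
    stop("each per-partition list must have exactly ", top_k_unique,
         " rows with columns variable, mean_decrease_gini")
  all_rows <- do.call(rbind, per_partition)
  sums <- tapply(all_rows$mean_decrease_gini, all_rows$variable, sum)
  counts <- tapply(all_rows$mean_decrease_gini, all_rows$variable, length)
  denom <- if (absent_as_zero) length(per_partition) else counts
  means <- sums / denom
  top <- data.frame(variable = names(sort(means, decreasing = TRUE)),
                    mean_gini = unname(sort(means, decreasing = TRUE)))
  list(unique_count = length(means),
       top_mean = utils::head(top, top_k_mean))
}

# Fit + score one partition for one method; returns a PartitionMetrics row
# plus the top-20 importance list.
score_partition <- function(train, test, method, spec, rf, tolerance,
                            max_iter, threshold, seed, prior_sd,
                            top_k = 20L) {
  if (method == "BiMM") {
    model <- fit_bimm(train, spec, rf_params = rf, tolerance = tolerance,
                      max_iter = max_iter, seed = seed, prior_sd = prior_sd)
    scores <- predict(model, test)
    n_iter <- model$n_iterations
    imp <- bimm_importance(model, top = top_k)
  } else {
    rfp <- resolve_rf_params(rf)
    rfp$majority_class <- if (mean(train$outcome) > 0.5) 1L else 0L
    forest <- fit_forest(cohort_covariates(train), train$outcome, rfp, seed)
    scores <- unname(stats::predict(forest, cohort_covariates(test),
                                    type = "prob")[, "1"])
    n_iter <- NA_integer_
    imp <- bimm_importance(forest, top = top_k)
  }
  cm <- confusion_metrics(test$outcome, scores, threshold)
  list(metrics = data.frame(method = method,
                            auc = compute_auc(test$outcome, scores),
                            sensitivity = cm$sensitivity,
                            specificity = cm$specificity,
                            accuracy = cm$accuracy,
                            fpr = cm$fpr,
                            n_iterations = n_iter),
       importance = imp)
}

#' Repeated-holdout evaluation of BiMM against a plain random forest
#'
#' The full evaluation protocol: for each of \code{n_partitions} seeded
#' person-level 70/30 splits, fit both a plain classification forest and a
#' BiMM on the training knees, score the held-out knees, and record AUC,
#' threshold metrics, BiMM iteration counts and the top-20 Mean Decrease
#' Gini variables per method. Partition metrics are aggregated into means and
#' SDs, a two-sample t-test on the AUC vectors, and per-method importance
#' summaries. Fully reproducible from the master seed. Partitions whose
#' train or test outcome is single-class are re-drawn with a fresh derived
#' seed (up to 10 attempts, logged via \code{message}).
#'
#' @param cohort a \code{"cohort"} table.
#' @param spec the \code{\link{split_spec}} used by every BiMM fit.
#' @param rf_params forest configuration (see \code{\link{fit_bimm}}),
#'   shared by both methods.
#' @param n_partitions number of train/test partitions (the full protocol
#'   uses 100).
#' @param threshold classification cut-off for the threshold metrics.
#' @param train_fraction person-level training fraction.
#' @param tolerance,max_iter,prior_sd BiMM controls.
#' @param seed master seed; per-partition seeds are derived from it.
#' @return An object of class \code{"bimm_experiment"}: per-partition
#'   \code{metrics} data frame, \code{importance} lists, aggregated
#'   \code{summary}, \code{t_test}, and per-method importance aggregation.
#' @export
run_experiment <- function(cohort, spec, rf_params = list(),
                           n_partitions = 100L, threshold = 0.5,
                           train_fraction = 0.7, tolerance = 0.5,
                           max_iter = 50L, prior_sd = 2.5, seed = 1L) {
  check_cohort(cohort)
  metrics <- NULL
  importance <- list(BiMM = list(), RF = list())
  top_k <- min(20L, ncol(cohort_covariates(cohort)))
  for (part in seq_len(n_partitions)) {
    parts <- NULL
    for (attempt in 0:9) {
      pseed <- derive_seed(seed, stream = 11L, index = part * 101L + attempt)
      cand <- partition_by_individual(cohort, train_fraction, seed = pseed)
      if (length(unique(cand$train$outcome)) == 2L &&
          length(unique(cand$test$outcome)) == 2L) {
        parts <- cand
        break
      }
      message("partition ", part, ": single-class outcome, resampling ",
              "(attempt ", attempt + 1, ")")
    }
    if (is.null(parts))
      stop("partition ", part, ": could not draw a two-class split in 10 tries")
    fit_seed <- derive_seed(seed, stream = 13L, index = part)
    for (method in c("BiMM", "RF")) {
      sc <- score_partition(parts$train, parts$test, method, spec, rf_params,
                            tolerance, max_iter, threshold, fit_seed, prior_sd,
                            top_k = top_k)
      sc$metrics <- cbind(partition_id = part, sc$metrics)
      metrics <- rbind(metrics, sc$metrics)
      importance[[method]][[part]] <- sc$importance
    }
  }
  rownames(metrics) <- NULL

  agg <- function(method, f) {
    m <- metrics[metrics$method == method, ]
    vapply(c("auc", "sensitivity", "specificity", "accuracy", "fpr",
             "n_iterations"),
           function(col) f(m[[col]]), numeric(1))
  }
  summary_tab <- data.frame(
    method = c("BiMM", "RF"),
    rbind(agg("BiMM", function(v) mean(v)),
          agg("RF", function(v) mean(v))))
  sd_tab <- data.frame(
    method = c("BiMM", "RF"),
    rbind(agg("BiMM", function(v) stats::sd(v)),
          agg("RF", function(v) stats::sd(v))))
  ttest <- two_sample_t(metrics$auc[metrics$method == "BiMM"],
                        metrics$auc[metrics$method == "RF"])
  imp_summary <- lapply(importance, aggregate_importance,
                        top_k_unique = top_k,
                        top_k_mean = min(10L, top_k))

  structure(list(metrics = metrics,
                 importance = importance,
                 summary = list(mean = summary_tab, sd = sd_tab),
                 t_test = ttest,
                 importance_summary = imp_summary,
                 threshold = threshold,
                 n_partitions = n_partitions,
                 split_spec = spec,
                 seed = as.integer(seed)),
            class = "bimm_experiment")
}

#' @export
print.bimm_experiment <- function(x, ...) {
  cat("Repeated-holdout evaluation:", x$n_partitions,
      "person-level partitions\n\n")
  m <- x$summary$mean; s <- x$summary$sd
  for (i in seq_len(nrow(m))) {
    it <- if (is.na(m$n_iterations[i])) "NA" else
      sprintf("%.2f ± %.2f", m$n_iterations[i], s$n_iterations[i])
    cat(sprintf(
      "%-5s AUC %.3f ± %.3f | iter %s | sens %.3f | spec %.3f | acc %.3f | FPR %.3f\n",
      m$method[i], m$auc[i], s$auc[i], it, m$sensitivity[i],
      m$specificity[i], m$accuracy[i], m$fpr[i]))
  }
  cat(sprintf(
    "\nAUC difference (BiMM - RF): %.4f, t = %.3f, p = %.4g, 95%% CI [%.4f, %.4f]\n",
    x$t_test$mean_difference, x$t_test$t, x$t_test$p, x$t_test$ci_low,
    x$t_test$ci_high))
  cat(sprintf("Unique top-20 variables: BiMM %d, RF %d\n",
              x$importance_summary$BiMM$unique_count,
              x$importance_summary$RF$unique_count))
  invisible(x)
}
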