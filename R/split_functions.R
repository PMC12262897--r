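#' Split-function specification
#'
#' A split function maps the sum of the working binary outcome and the
#' mixed-model probability, \eqn{s = Y + Q \in [0, 2]}, back to \{0, 1\}.
#' Three families are supported:
#' \describe{
#'   \item{\code{h1}}{\eqn{h_1(s) = 0} if \eqn{s \le k_1}, else 1, with
#'     \eqn{k_1 \in (0,1)}. Can only flip an original 0 to 1, so it preserves
#'     (and tends to raise) sensitivity.}
#'   \item{\code{h2}}{\eqn{h_2(s) = 0} if \eqn{s < k_2}, else 1, with
#'     \eqn{k_2 \in (1,2)}. Can only flip an original 1 to 0, preserving
#'     specificity.}
#'   \item{\code{h3}}{deterministically 0 below 0.5 and 1 above 1.5; in the
#'     middle band the output is Bernoulli(\eqn{Q}). Both flip directions are
#'     possible. The band edges 0.5 and 1.5 are fixed.}
#' }
#'
#' @param kind one of \code{"h1"}, \code{"h2"}, \code{"h3"}.
#' @param k1 threshold constant for \code{h1}, strictly inside (0, 1).
#' @param k2 threshold constant for \code{h2}, strictly inside (1, 2).
#' @return An object of class \code{"split_spec"}.
#' @examples
#' split_spec("h1", k1 = 0.25)
#' split_spec("h3")
#' @export
split_spec <- function(kind = c("h1", "h2", "h3"), k1 = NULL, k2 = NULL) {
  kind <- match.arg(kind)
  if (kind == "h1") {
    if (is.null(k1)) stop("h1 requires a threshold constant k1")
    check_k1(k1)
    k2 <- NULL
  } else if (kind == "h2") {
    if (is.null(k2)) stop("h2 requires a threshold constant k2")
    check_k2(k2)
    k1 <- NULL
  } else {
    # h3 has no free constants: its band edges are k1 = 0.5, k2 = 1.5.
    k1 <- 0.5
    k2 <- 1.5
  }
  structure(list(kind = kind, k1 = k1, k2 = k2), class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  const <- switch(x$kind,
                  h1 = sprintf(" (k1 = %g)", x$k1),
                  h2 = sprintf(" (k2 = %g)", x$k2),
                  h3 = " (fixed band 0.5/1.5, stochastic middle)")
  cat("Split function ", x$kind, const, "\n", sep = "")
  invisible(x)
}

check_k1 <- function(k1) {
  if (!is.numeric(k1) || length(k1) != 1L || is.na(k1) || k1 <= 0 || k1 >= 1)
    stop("k1 must be a single number strictly inside (0, 1)")
  invisible(k1)
}

check_k2 <- function(k2) {
  if (!is.numeric(k2) || length(k2) != 1L || is.na(k2) || k2 <= 1 || k2 >= 2)
    stop("k2 must be a single number strictly inside (1, 2)")
  invisible(k2)
}

check_s <- function(s) {
  if (!is.numeric(s) || anyNA(s) || any(s < 0) || any(s > 2))
    stop("s = y + q must lie in [0, 2]")
  invisible(s)
}

#' Sensitivity-preserving split function h1
#'
#' Returns 0 where \code{s <= k1} and 1 otherwise. Because \code{s >= 1}
#' whenever the original outcome is 1 and \code{k1 < 1}, an original 1 is
#' never flipped to 0.
#'
#' @param s numeric vector in \[0, 2\], the sum \eqn{Y + Q}.
#' @param k1 threshold constant in (0, 1).
#' @return Integer vector of 0/1, same length as \code{s}.
#' @examples
#' apply_h1(c(0.30, 0.25, 1.0), k1 = 0.25)
#' @export
apply_h1 <- function(s, k1) {
  check_s(s); check_k1(k1)
  as.integer(s > k1)
}

#' Specificity-preserving split function h2
#'
#' Returns 0 where \code{s < k2} and 1 where \code{s >= k2}. Because
#' \code{s < 1 < k2} whenever the original outcome is 0, an original 0 is
#' never flipped to 1.
#'
#' @param s numeric vector in \[0, 2\].
#' @param k2 threshold constant in (1, 2).
#' @return Integer vector of 0/1.
#' @examples
#' apply_h2(c(1.5, 1.2), k2 = 1.5)
#' @export
apply_h2 <- function(s, k2) {
  check_s(s); check_k2(k2)
  as.integer(s >= k2)
}

#' Stochastic split function h3
#'
#' Deterministic outside the (0.5, 1.5) band of \eqn{s = y + q}; inside the
#' band the output is 1 with probability \code{q}. Consumes one uniform draw
#' from R's RNG per element (seed with \code{set.seed} for reproducibility).
#'
#' @param y integer vector of 0/1, the current working outcome.
#' @param q numeric vector of probabilities strictly inside (0, 1).
#' @return Integer vector of 0/1.
#' @examples
#' set.seed(1)
#' apply_h3(c(0L, 1L, 0L), c(0.4, 0.8, 0.7))
#' @export
apply_h3 <- function(y, q) {
  if (!is_binary01(y)) stop("y must be a 0/1 vector")
  if (!is.numeric(q) || anyNA(q) || any(q <= 0) || any(q >= 1))
    stop("q must lie strictly inside (0, 1)")
  if (length(y) != length(q)) stop("y and q must have equal length")
  s <- y + q
  u <- stats::runif(length(s))          # one draw per element, in order
  out <- ifelse(s < 0.5, 0L, ifelse(s > 1.5, 1L, as.integer(u < q)))
  as.integer(out)
}

#' Grid search for the optimal split function and threshold constant
#'
#' Fits a full BiMM for every candidate (function, constant) pair on a fixed
#' training set, records the AUC of each fitted model on a fixed evaluation
#' set, and returns the candidate with the highest AUC. The default grids are
#' \eqn{k_1 \in \{0.05, 0.10, \ldots, 0.95\}} for \code{h1} and
#' \eqn{k_2 \in \{1.05, 1.10, \ldots, 1.95\}} for \code{h2}; \code{h3} has no
#' constant and is evaluated once. Ties are broken by family order
#' (h1, h2, h3), then by the smaller constant.
#'
#' @param train,eval_set cohort tables sharing the covariate schema (see
#'   \code{\link{generate_cohort}}); evaluation is on \code{eval_set}.
#' @param rf_params forest configuration list passed to
#'   \code{\link{fit_bimm}} (fields \code{num_trees}, \code{class_weight},
#'   \code{mtry}).
#' @param k1_grid,k2_grid candidate threshold constants; set to
#'   \code{numeric(0)} to drop a family.
#' @param include_h3 evaluate the stochastic split function as well?
#' @param tolerance,max_iter BiMM convergence controls.
#' @param seed integer seed; every candidate fit is seeded identically so the
#'   comparison differs only in the split function.
#' @param eval_role \code{"validation"} (default) or \code{"test"}. Selecting
#'   on the final test set leaks information into model choice, so
#'   \code{"test"} triggers a warning; carve a validation split from the
#'   training data instead when possible.
#' @return List of class \code{"split_grid_search"} with elements
#'   \code{spec} (the winning \code{\link{split_spec}}), \code{best_auc}, and
#'   \code{trace} (data frame of \code{kind}, \code{constant}, \code{auc},
#'   one row per candidate in evaluation order).
#' @export
grid_search_split <- function(train, eval_set, rf_params = list(),
                              k1_grid = seq(0.05, 0.95, by = 0.05),
                              k2_grid = seq(1.05, 1.95, by = 0.05),
                              include_h3 = TRUE,
                              tolerance = 0.5, max_iter = 50L, seed = 1L,
                              eval_role = c("validation", "test")) {
  eval_role <- match.arg(eval_role)
  if (eval_role == "test")
    warning("selecting the split function on the final test set leaks the ",
            "test outcome into model choice; prefer a validation split")
  candidates <- c(
    lapply(k1_grid, function(k) split_spec("h1", k1 = k)),
    lapply(k2_grid, function(k) split_spec("h2", k2 = k)),
    if (include_h3) list(split_spec("h3"))
  )
  if (length(candidates) == 0L) stop("empty candidate grid")
  y_eval <- eval_set$outcome
  if (length(unique(y_eval)) < 2L)
    stop_degenerate("evaluation set has a single outcome class; AUC undefined",
                    "bimm_degenerate_outcome")

  trace <- data.frame(kind = character(0), constant = numeric(0),
                      auc = numeric(0))
  for (spec in candidates) {
    fit <- fit_bimm(train, spec, rf_params = rf_params,
                    tolerance = tolerance, max_iter = max_iter, seed = seed)
    auc <- compute_auc(y_eval, predict_bimm(fit, eval_set))
    trace <- rbind(trace, data.frame(
      kind = spec$kind,
      constant = switch(spec$kind, h1 = spec$k1, h2 = spec$k2, h3 = NA_real_),
      auc = auc))
  }
  # Candidate order is h1 (ascending k1), h2 (ascending k2), h3, so the first
  # maximum realises the documented tie-break.
  best <- which.max(trace$auc)
  structure(list(spec = candidates[[best]], best_auc = trace$auc[best],
                 trace = trace),
            class = "split_grid_search")
}

#' @export
print.split_grid_search <- function(x, ...) {
  cat("Split-function grid search over", nrow(x$trace), "candidates\n")
  cat("Best AUC:", format(x$best_auc, digits = 4), "\n")
  print(x$spec)
  invisible(x)
}

#' Write a grid-search trace to CSV
#'
#' @param x a \code{"split_grid_search"} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_grid_trace <- function(x, path) {
  stopifnot(inherits(x, "split_grid_search"))
  utils::write.csv(x$trace, path, row.names = FALSE)
  invisible(path)
}
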