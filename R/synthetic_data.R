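#' Configuration for the synthetic bilateral cohort generator
#'
#' Describes a cohort of persons with two knees each. Person-level covariates
#' are shared by a person's two rows; knee-level covariates are drawn
#' independently per knee. The outcome is Bernoulli with
#' \deqn{logit P(Y_{it} = 1) = \beta_0 + f(X_{it}) + b_i,\qquad
#'       b_i \sim N(0, \sigma_b^2),}
#' where \eqn{b_i} is shared by the two knees of person \eqn{i} and induces
#' the within-person correlation (observable as the left-right phi
#' coefficient). \eqn{f} is either a linear predictor
#' (\code{mechanism = "linear"}) or a sum of threshold-interaction terms
#' (\code{mechanism = "tree"}).
#'
#' Within each covariate block a fraction \code{binary_fraction} of the
#' columns (the trailing ones, rounded down) are Bernoulli(0.5) indicators
#' standing in for recoded categorical variables; the rest are standard
#' normal.
#'
#' For the tree mechanism each element of \code{effect_sizes} is the
#' coefficient of one interaction term
#' \eqn{c \cdot 1[x_j > \tau_j]\, 1[x_k > \tau_k]} over a consecutive pair of
#' covariate columns (wrapping around), with thresholds \eqn{\tau} drawn once,
#' deterministically from \code{seed}.
#'
#' @param n_persons number of persons (rows = \code{2 * n_persons}).
#' @param n_person_covariates,n_knee_covariates covariate counts per block.
#' @param effect_sizes coefficients; for \code{mechanism = "linear"} the
#'   length must equal the total covariate count.
#' @param intercept fixed intercept \eqn{\beta_0} on the log-odds scale.
#' @param random_intercept_sd \eqn{\sigma_b \ge 0}; 0 gives independent knees.
#' @param mechanism \code{"linear"} or \code{"tree"}.
#' @param binary_fraction fraction of each covariate block generated as 0/1
#'   indicators.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return An object of class \code{"generator_config"}.
#' @examples
#' cfg <- generator_config(n_persons = 100, n_person_covariates = 2,
#'                         n_knee_covariates = 1,
#'                         effect_sizes = c(0.5, 0.5, 0.5),
#'                         random_intercept_sd = 1, seed = 42)
#' cohort <- generate_cohort(cfg)
#' @export
generator_config <- function(n_persons,
                             n_person_covariates = 0L,
                             n_knee_covariates = 0L,
                             effect_sizes = numeric(0),
                             intercept = 0,
                             random_intercept_sd = 0,
                             mechanism = c("linear", "tree"),
                             binary_fraction = 0,
                             seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(n_persons) || length(n_persons) != 1L || n_persons < 1)
    stop("n_persons must be a positive integer")
  n_persons <- as.integer(n_persons)
  n_person_covariates <- as.integer(n_person_covariates)
  n_knee_covariates <- as.integer(n_knee_covariates)
  if (n_person_covariates < 0L || n_knee_covariates < 0L)
    stop("covariate counts must be non-negative")
  if (random_intercept_sd < 0) stop("random_intercept_sd must be >= 0")
  if (binary_fraction < 0 || binary_fraction > 1)
    stop("binary_fraction must lie in [0, 1]")
  p <- n_person_covariates + n_knee_covariates
  if (mechanism == "linear" && length(effect_sizes) != p)
    stop("for the linear mechanism, length(effect_sizes) must equal the ",
         "total covariate count (", p, ")")
  if (mechanism == "tree" && length(effect_sizes) > 0L && p < 1L)
    stop("tree mechanism requires at least one covariate")
  structure(list(n_persons = n_persons,
                 n_person_covariates = n_person_covariates,
                 n_knee_covariates = n_knee_covariates,
                 effect_sizes = as.numeric(effect_sizes),
                 intercept = as.numeric(intercept),
                 random_intercept_sd = as.numeric(random_intercept_sd),
                 mechanism = mechanism,
                 binary_fraction = as.numeric(binary_fraction),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Number of binary (indicator) columns in a block of `n` covariates.
n_binary_cols <- function(n, fraction) as.integer(floor(n * fraction))

# Draw one covariate block: persons x ncol, trailing columns binary.
draw_covariate_block <- function(nrow, ncol, binary_fraction) {
  if (ncol == 0L) return(matrix(numeric(0), nrow = nrow, ncol = 0L))
  nb <- n_binary_cols(ncol, binary_fraction)
  x <- matrix(stats::rnorm(nrow * ncol), nrow = nrow, ncol = ncol)
  if (nb > 0L) {
    cols <- (ncol - nb + 1L):ncol
    x[, cols] <- matrix(stats::rbinom(nrow * nb, 1L, 0.5),
                        nrow = nrow, ncol = nb)
  }
  x
}

# Thresholds for the tree mechanism, drawn once per config seed so that
# generate_cohort() and the intercept calibration see the same trees.
draw_tree_terms <- function(config) {
  p <- config$n_person_covariates + config$n_knee_covariates
  m <- length(config$effect_sizes)
  if (m == 0L) return(NULL)
  with_seed(derive_seed(config$seed, stream = 777L), {
    idx1 <- ((seq_len(m) * 2L - 2L) %% p) + 1L
    idx2 <- ((seq_len(m) * 2L - 1L) %% p) + 1L
    # Indicator covariates split at 0.5; continuous ones at a N(0,1) draw.
    tau <- stats::rnorm(2L * m)
    list(j = idx1, k = idx2,
         tau_j = tau[seq_len(m)], tau_k = tau[m + seq_len(m)],
         coef = config$effect_sizes)
  })
}

# Covariate threshold for tree terms: indicator columns use 0.5.
term_threshold <- function(config, col, tau) {
  p_pers <- config$n_person_covariates
  nb_p <- n_binary_cols(p_pers, config$binary_fraction)
  nb_k <- n_binary_cols(config$n_knee_covariates, config$binary_fraction)
  binary_cols <- c(if (nb_p > 0L) (p_pers - nb_p + 1L):p_pers,
                   if (nb_k > 0L) (p_pers + config$n_knee_covariates - nb_k +
                                     1L):(p_pers + config$n_knee_covariates))
  ifelse(col %in% binary_cols, 0.5, tau)
}

# Covariate contribution to the log-odds, given the full covariate matrix.
covariate_logodds <- function(config, x) {
  if (config$mechanism == "linear") {
    if (ncol(x) == 0L) return(rep(0, nrow(x)))
    return(drop(x %*% config$effect_sizes))
  }
  terms <- draw_tree_terms(config)
  if (is.null(terms)) return(rep(0, nrow(x)))
  eta <- rep(0, nrow(x))
  tj <- term_threshold(config, terms$j, terms$tau_j)
  tk <- term_threshold(config, terms$k, terms$tau_k)
  for (m in seq_along(terms$coef)) {
    eta <- eta + terms$coef[m] *
      (x[, terms$j[m]] > tj[m]) * (x[, terms$k[m]] > tk[m])
  }
  eta
}

#' Generate a synthetic bilateral cohort
#'
#' Draws a cohort with exactly two rows (knees) per person according to the
#' configuration: shared person-level covariates, independent knee-level
#' covariates, a shared person random intercept, and a Bernoulli outcome on
#' the logistic scale. Identical configurations (including seed) give
#' identical tables.
#'
#' @param config a \code{\link{generator_config}}.
#' @return A \code{data.frame} of class \code{"cohort"} with columns
#'   \code{person_id}, \code{side} (1 = left, 2 = right), \code{outcome}
#'   (0/1) and covariates \code{x1..xp} (person-level block first).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_persons
  pp <- config$n_person_covariates
  pk <- config$n_knee_covariates
  with_seed(config$seed, {
    xp <- draw_covariate_block(n, pp, config$binary_fraction)
    xk <- draw_covariate_block(2L * n, pk, config$binary_fraction)
    b <- stats::rnorm(n, 0, config$random_intercept_sd)
    # rows ordered person 1 side 1, person 1 side 2, person 2 side 1, ...
    person <- rep(seq_len(n), each = 2L)
    x <- cbind(xp[person, , drop = FALSE], xk)
    eta <- config$intercept + covariate_logodds(config, x) + b[person]
    y <- stats::rbinom(2L * n, 1L, stats::plogis(eta))
    out <- data.frame(person_id = person, side = rep(c(1L, 2L), times = n),
                      outcome = y)
    if (ncol(x) > 0L) {
      colnames(x) <- paste0("x", seq_len(ncol(x)))
      out <- cbind(out, as.data.frame(x))
    }
    class(out) <- c("cohort", "data.frame")
    out
  })
}

#' Calibrate the generator intercept to a target prevalence
#'
#' Finds the intercept \eqn{\beta_0} such that the marginal outcome
#' prevalence of cohorts drawn from \code{config} matches
#' \code{target_prevalence}. The marginal prevalence is estimated by Monte
#' Carlo over the non-intercept part of the linear predictor (covariate
#' contribution plus random intercept) under a fixed inner seed, and the
#' intercept is found by root finding on \eqn{[-10, 10]}.
#'
#' @param config a \code{\link{generator_config}}; its own intercept is
#'   ignored.
#' @param target_prevalence target marginal prevalence in (0, 1).
#' @param n_mc Monte Carlo sample size (knees).
#' @return The calibrated intercept (a single number).
#' @export
calibrate_intercept <- function(config, target_prevalence, n_mc = 200000L) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.numeric(target_prevalence) || length(target_prevalence) != 1L ||
      target_prevalence <= 0 || target_prevalence >= 1)
    stop("target_prevalence must lie strictly inside (0, 1)")
  eta0 <- simulate_linpred(config, n_mc)
  prev <- function(c0) mean(stats::plogis(c0 + eta0)) - target_prevalence
  lo <- prev(-10); hi <- prev(10)
  if (lo > 0 || hi < 0)
    stop("target prevalence cannot be bracketed by an intercept in [-10, 10]")
  stats::uniroot(prev, c(-10, 10), tol = 1e-6)$root
}

# Monte Carlo draw of the linear predictor minus the intercept, for
# calibration. Uses a fixed inner seed derived from the config seed.
simulate_linpred <- function(config, n_knees) {
  n_pers <- ceiling(n_knees / 2)
  with_seed(derive_seed(config$seed, stream = 555L), {
    xp <- draw_covariate_block(n_pers, config$n_person_covariates,
                               config$binary_fraction)
    xk <- draw_covariate_block(2L * n_pers, config$n_knee_covariates,
                               config$binary_fraction)
    b <- stats::rnorm(n_pers, 0, config$random_intercept_sd)
    person <- rep(seq_len(n_pers), each = 2L)
    x <- cbind(xp[person, , drop = FALSE], xk)
    covariate_logodds(config, x) + b[person]
  })
}

#' Empirical phi coefficient of a bilateral cohort
#'
#' Cross-tabulates each person's left-knee outcome against the right-knee
#' outcome and returns the phi coefficient of the resulting 2x2 table (see
#' \code{\link{phi_coefficient}}). This is the standard summary of
#' within-person outcome correlation for paired organs.
#'
#' @param cohort a \code{"cohort"} table with two rows per person.
#' @return The phi coefficient in \[-1, 1\]. A table with a zero margin
#'   (e.g. one knee side always 0) raises a condition of class
#'   \code{"bimm_degenerate_table"}.
#' @export
empirical_phi <- function(cohort) {
  check_cohort(cohort)
  left <- cohort$outcome[cohort$side == 1L][order(cohort$person_id[cohort$side == 1L])]
  right <- cohort$outcome[cohort$side == 2L][order(cohort$person_id[cohort$side == 2L])]
  a <- sum(left == 1 & right == 1)
  b <- sum(left == 1 & right == 0)
  cc <- sum(left == 0 & right == 1)
  d <- sum(left == 0 & right == 0)
  phi_coefficient(a, b, cc, d)
}

#' Calibrate the random-intercept scale to a target phi coefficient
#'
#' Sweeps \eqn{\sigma_b} over a grid, generating one cohort per grid value
#' (with the intercept re-calibrated to \code{target_prevalence} at each
#' step when supplied), measures the empirical left-right phi coefficient,
#' and linearly interpolates between the bracketing grid points. Because phi
#' is monotone in \eqn{\sigma_b}, this pins the generator to an observed
#' correlation regime rather than to a latent variance.
#'
#' @param config a \code{\link{generator_config}} providing everything except
#'   \code{random_intercept_sd} (and, optionally, the intercept).
#' @param target_phi target left-right phi coefficient.
#' @param target_prevalence optional marginal prevalence to maintain while
#'   sweeping; when supplied the returned config has a freshly calibrated
#'   intercept.
#' @param sigma_grid grid of candidate \eqn{\sigma_b} values.
#' @return The input config with \code{random_intercept_sd} (and possibly
#'   \code{intercept}) replaced; the sweep table is attached as attribute
#'   \code{"sweep"}.
#' @export
calibrate_random_intercept_sd <- function(config, target_phi,
                                          target_prevalence = NULL,
                                          sigma_grid = seq(0, 4, by = 0.5)) {
  stopifnot(inherits(config, "generator_config"))
  phi_at <- function(sigma) {
    cfg <- config
    cfg$random_intercept_sd <- sigma
    if (!is.null(target_prevalence))
      cfg$intercept <- calibrate_intercept(cfg, target_prevalence)
    empirical_phi(generate_cohort(cfg))
  }
  phis <- vapply(sigma_grid, phi_at, numeric(1))
  sweep <- data.frame(sigma_b = sigma_grid, phi = phis)
  if (target_phi <= phis[1L]) {
    sigma <- sigma_grid[1L]
  } else if (target_phi >= phis[length(phis)]) {
    sigma <- sigma_grid[length(sigma_grid)]
  } else {
    hi <- min(which(phis >= target_phi))
    lo <- hi - 1L
    w <- (target_phi - phis[lo]) / (phis[hi] - phis[lo])
    sigma <- sigma_grid[lo] + w * (sigma_grid[hi] - sigma_grid[lo])
  }
  out <- config
  out$random_intercept_sd <- sigma
  if (!is.null(target_prevalence))
    out$intercept <- calibrate_intercept(out, target_prevalence)
  attr(out, "sweep") <- sweep
  out
}

#' Default study-scale cohort configuration
#'
#' A calibrated configuration emulating the scale and dependence structure of
#' a large bilateral knee cohort: ~2 knees per person, a mix of continuous
#' and indicator covariates at both the person and knee level, an imbalanced
#' outcome, and a within-person phi coefficient near 0.3. The random
#' intercept scale is tuned by \code{\link{calibrate_random_intercept_sd}}
#' and the intercept by \code{\link{calibrate_intercept}}, so construction
#' involves a short Monte Carlo sweep.
#'
#' @param n_persons cohort size (default 3000 persons = 6000 knees).
#' @param prevalence target marginal outcome prevalence.
#' @param target_phi target left-right phi coefficient.
#' @param seed integer seed.
#' @return A calibrated \code{\link{generator_config}}.
#' @export
default_cohort_config <- function(n_persons = 3000L, prevalence = 0.27,
                                  target_phi = 0.30, seed = 1L) {
  base <- generator_config(
    n_persons = n_persons,
    n_person_covariates = 10L, n_knee_covariates = 5L,
    effect_sizes = c(rep(0.2, 10), rep(0.3, 5)),
    intercept = 0, random_intercept_sd = 1,
    mechanism = "linear", binary_fraction = 0.4, seed = seed)
  calibrate_random_intercept_sd(base, target_phi = target_phi,
                                target_prevalence = prevalence)
}
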