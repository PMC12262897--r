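# Independent oracles used across the suite. These deliberately re-derive
# quantities by the most direct route available (brute force, closed form,
# numerical optimisation) and never call the implementation paths they check.

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

# All-pairs Mann-Whitney AUC: fraction of positive-negative pairs where the
# positive outscores the negative, ties counted one half.
auc_brute <- function(y, scores) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (sp in pos) total <- total + sum(sp > neg) + 0.5 * sum(sp == neg)
  total / (length(pos) * length(neg))
}

# Textbook Welch two-sample t statistic and p-value.
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# Laplace-approximate log joint posterior of the logistic random-intercept
# model, recomputed by per-cluster 1-D numerical optimisation (independent of
# the package's vectorised Newton path).
laplace_oracle <- function(beta0, beta1, sigma, y, p, id, prior_sd = 2.5) {
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  ll <- 0
  for (cl in unique(id)) {
    idx <- id == cl
    eta0 <- beta0 + beta1 * p[idx]
    g <- function(b)
      sum(y[idx] * (eta0 + b) - log1p(exp(eta0 + b))) +
      stats::dnorm(b, 0, sigma, log = TRUE)
    opt <- stats::optimize(g, c(-60, 60), maximum = TRUE, tol = 1e-10)
    mu <- stats::plogis(eta0 + opt$maximum)
    h <- sum(mu * (1 - mu)) + 1 / sigma^2
    ll <- ll + opt$objective + 0.5 * log(2 * pi) - 0.5 * log(h)
  }
  ll + 0.5 * log(2) - 0.5 * log(pi) - log(prior_sd) -
    sigma^2 / (2 * prior_sd^2)
}

# Small informative bilateral cohort used by several fits.
small_cohort <- function(n_persons = 150, sigma_b = 1, seed = 42,
                         effects = rep(0.5, 5)) {
  cfg <- generator_config(n_persons, 3, 2, effects, intercept = -0.5,
                          random_intercept_sd = sigma_b, seed = seed)
  generate_cohort(cfg)
}

# Cohort whose 2x2 left/right outcome table is exactly (a, b, c, d) =
# (both 1, left only, right only, neither), with one noise covariate.
cohort_from_counts <- function(a, b, c, d) {
  pat <- rbind(matrix(rep(c(1, 1), a), ncol = 2, byrow = TRUE),
               matrix(rep(c(1, 0), b), ncol = 2, byrow = TRUE),
               matrix(rep(c(0, 1), c), ncol = 2, byrow = TRUE),
               matrix(rep(c(0, 0), d), ncol = 2, byrow = TRUE))
  n <- nrow(pat)
  out <- data.frame(person_id = rep(seq_len(n), each = 2),
                    side = rep(c(1L, 2L), n),
                    outcome = as.integer(as.vector(t(pat))),
                    x1 = seq_len(2 * n) / (2 * n))
  class(out) <- c("cohort", "data.frame")
  out
}
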