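# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation; stays inside 32-bit integer range.
derive_seed <- function(seed, stream, index = 0L) {
  s <- (as.double(seed) * 48271 + stream * 104729 + index * 7919) %% 2147483629
  as.integer(s) + 1L
}

stop_degenerate <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

clamp_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# log(1 + exp(x)) without overflow for large x.
log1pexp <- function(x) ifelse(x > 33, x, log1p(exp(pmin(x, 33))))

is_binary01 <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x %in% c(0, 1))
}
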