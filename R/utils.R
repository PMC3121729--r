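# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so no function leaks global randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Replicate-level seeds derived from a master seed: a deterministic function
# of (master, index), so parallel or re-ordered execution cannot change
# results.
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

# Empirical percentile by the order-statistic definition: the smallest value
# whose empirical CDF is >= prob (no interpolation).
percentile_exact <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 1, names = FALSE)
}

stop_if_not_scalar_prob <- function(tau, name = "tau") {
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau <= 0) || any(tau >= 1))
    stop(sprintf("`%s` must lie strictly inside (0, 1)", name), call. = FALSE)
  invisible(tau)
}
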