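# Shared fixtures: small random regression instances and planted-effect
# quantile structures used across the solver, pipeline and resampling tests.

random_instance <- function(n, p, seed) {
  set.seed(seed)
  x <- cbind(rep(1, n), if (p > 1) matrix(rnorm(n * (p - 1)), n) else NULL)
  colnames(x) <- c("(Intercept)", if (p > 1) paste0("x", seq_len(p - 1)))
  list(x = x, y = rnorm(n))
}

# Race effect shrinking from -0.15 at tau = 0.1 to 0 at tau = 0.9 (constant
# beyond the knots), over a linear intercept curve that keeps the clamp
# inactive.
qcf_shrinking_race <- function(low = -0.15, high = 0) {
  qcf(intercept = function(tau) 0.3 + 0.7 * tau,
      race_nhb = cbind(tau = c(0.1, 0.9), value = c(low, high)))
}

# Mean of beta_race(U), U ~ Uniform(0,1), for the shrinking-race curve:
# constant `low` below 0.1, linear to `high` at 0.9, constant above.
shrinking_race_mean <- function(low = -0.15, high = 0) {
  0.1 * low + 0.8 * (low + high) / 2 + 0.1 * high
}

# Small cohort with a race_nhb dummy column and planted MPR outcome.
planted_cohort <- function(n, q = qcf_shrinking_race(), seed = 1) {
  cfg <- cohort_config(n_patients = n, seed = seed)
  coh <- generate_covariates(cfg)
  coh$race_nhb <- as.numeric(!is.na(coh$race) & coh$race == "NHB")
  coh$mpr <- generate_mpr(coh, q, seed = seed + 1000L)
  coh
}

# Independent L1/check-loss oracle used to cross-check the solver: brute-force
# enumeration of exact fits through p-subsets, scoring with a plain R loop so
# it shares no code with the package objective.
loop_check_objective <- function(beta, x, y, tau) {
  s <- 0
  for (i in seq_len(nrow(x))) {
    r <- y[i] - sum(x[i, ] * beta)
    s <- s + r * (tau - as.numeric(r < 0))
  }
  s
}

enumerate_best_objective <- function(x, y, tau) {
  n <- nrow(x); p <- ncol(x)
  best <- Inf
  subsets <- combn(n, p)
  for (j in seq_len(ncol(subsets))) {
    idx <- subsets[, j]
    b <- tryCatch(solve(x[idx, , drop = FALSE], y[idx]), error = function(e) NULL)
    if (is.null(b) || anyNA(b)) next
    best <- min(best, loop_check_objective(b, x, y, tau))
  }
  best
}
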