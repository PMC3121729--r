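# Synthetic cohort generator: covariate prevalences, planted quantile
# structure, determinism.

test_that("config validation catches bad probabilities and counts", {
  expect_error(cohort_config(0), "n_patients")
  expect_error(cohort_config(10, race_probs = c(NHW = 0.5, NHB = 0.4, Other = 0.2)),
               "sum to 1")
  expect_error(cohort_config(10, race_probs = c(A = 0.5, B = 0.3, C = 0.2)),
               "named NHW, NHB, Other")
  expect_error(cohort_config(10, covariate_prevalences = c(male = 1.2)),
               "\\[0, 1\\]")
  expect_error(cohort_config(10, periods_per_patient = 0), "periods_per_patient")
})

test_that("covariate tables have the right shape and are seed-deterministic", {
  expect_equal(nrow(generate_covariates(cohort_config(1, seed = 1))), 1L)
  a <- generate_covariates(cohort_config(500, seed = 42))
  b <- generate_covariates(cohort_config(500, seed = 42))
  expect_identical(a, b)
  c <- generate_covariates(cohort_config(500, seed = 43))
  expect_false(identical(a, c))
  expect_true(all(a$age >= 19))
  expect_true(all(a$male %in% 0:1))
})

test_that("sample prevalences recover configured probabilities", {
  n <- 50000
  coh <- generate_covariates(cohort_config(n, seed = 7))
  p <- 0.257   # hypertension prevalence
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(coh$hypertension) - p), 3 * se)
  # missing race close to its configured rate
  pm <- 0.086
  expect_lt(abs(mean(is.na(coh$race)) - pm), 3 * sqrt(pm * (1 - pm) / n))
  # race split conditional on observed
  obs <- coh$race[!is.na(coh$race)]
  expect_lt(abs(mean(obs == "NHB") - 3061 / 10298), 0.015)
})

test_that("constant quantile curves generate x'beta exactly", {
  coh <- data.frame(z = c(0, 1, 1, 0))
  q <- qcf(intercept = function(tau) rep(0.5, length(tau)),
           z = function(tau) rep(0.2, length(tau)))
  y1 <- generate_mpr(coh, q, seed = 1)
  y2 <- generate_mpr(coh, q, seed = 999)
  expect_equal(y1, 0.5 + 0.2 * coh$z)
  expect_identical(y1, y2)   # no randomness reaches the outcome
})

test_that("outcomes are clamped to the unit interval", {
  coh <- data.frame(z = rep(c(0, 1), 50))
  q <- qcf(intercept = cbind(tau = c(0.01, 0.99), value = c(-0.5, 1.5)),
           z = function(tau) rep(0.1, length(tau)))
  y <- generate_mpr(coh, q, seed = 3)
  expect_gte(min(y), 0)
  expect_lte(max(y), 1)
  expect_true(any(y %in% c(0, 1)))   # the wide curve does hit the clamp
})

test_that("monotonicity violations are rejected naming the offender", {
  coh <- data.frame(z = c(0, 1))
  q <- qcf(intercept = function(tau) 0.5 + 0.1 * tau,
           z = function(tau) -0.5 * tau)   # decreasing for z = 1
  expect_error(generate_mpr(coh, q, seed = 1), "not monotone.*profile")
  # same curves are fine on a support without z = 1
  expect_silent(generate_mpr(data.frame(z = c(0, 0)), q, seed = 1))
})

test_that("planted conditional quantiles are recovered by empirical quantiles", {
  # fixed profile x = (1, 1); inverse-CDF construction implies
  # P(Y <= x'beta(tau)) = tau, checked through the empirical CDF
  q <- qcf_shrinking_race()
  n <- 200000
  coh <- data.frame(race_nhb = rep(1, n))
  y <- generate_mpr(coh, q, seed = 11)
  for (tau in c(0.1, 0.25, 0.5, 0.9)) {
    truth <- (0.3 + 0.7 * tau) +
      approx(c(0.1, 0.9), c(-0.15, 0), xout = tau, rule = 2)$y
    se <- sqrt(tau * (1 - tau) / n)
    expect_lt(abs(mean(y <= truth) - tau), 3 * se)
  }
})

test_that("repeated-measure mode adds a patient-level latent shift", {
  cfg <- cohort_config(400, seed = 5, periods_per_patient = 4)
  coh <- generate_covariates(cfg)
  q <- qcf(intercept = function(tau) qnorm(tau, 0.5, 0.1))
  long <- generate_mpr(coh, q, seed = 6, periods = 4, subject_sd = 0.15)
  expect_equal(nrow(long), 1600L)
  expect_equal(sort(unique(long$period)), 1:4)
  # between-patient variance of patient means exceeds the no-shift case
  pm <- tapply(long$mpr, long$patient_id, mean)
  long0 <- generate_mpr(coh, q, seed = 6, periods = 4, subject_sd = 0)
  pm0 <- tapply(long0$mpr, long0$patient_id, mean)
  expect_gt(var(pm), var(pm0) + 0.24 * 0.15^2)
})

test_that("the cohort-like preset is a valid quantile structure", {
  q <- qcf_cohort_preset()
  coh <- generate_covariates(cohort_config(20000, seed = 9))
  coh$race_nhb <- as.numeric(!is.na(coh$race) & coh$race == "NHB")
  coh$race_other <- as.numeric(is.na(coh$race) | coh$race == "Other")
  y <- generate_mpr(coh, q, seed = 10)
  expect_true(all(y >= 0 & y <= 1))
  # left-skewed with median near 0.97 and the clinical cutoffs in the low tail
  expect_gt(median(y), 0.9)
  expect_lt(mean(y <= 0.4), 0.06)
  expect_lt(mean(y <= 0.9), 0.45)
  expect_gt(mean(y <= 0.9), 0.15)
})

test_that("configs load from YAML and JSON with validation", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("n_patients: 25",
               "seed: 4",
               "missing_race_rate: 0.1",
               "covariate_prevalences:",
               "  male: 0.9",
               "  hypertension: 0.3"), f)
  cfg <- read_cohort_config(f)
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$n_patients, 25L)
  expect_equal(unname(cfg$covariate_prevalences["hypertension"]), 0.3)
  coh <- generate_covariates(cfg)
  expect_equal(nrow(coh), 25L)
  # the resolved config and seed travel with the table
  expect_equal(attr(coh, "config")$seed, 4)
  j <- tempfile(fileext = ".json")
  writeLines('{"n_patients": 5, "seed": 1}', j)
  expect_equal(read_cohort_config(j)$n_patients, 5L)
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("n_patients: 5", "not_a_key: 1"), bad)
  expect_error(read_cohort_config(bad), "unknown config keys")
  expect_error(read_cohort_config(tempfile(fileext = ".txt")), "yaml")
})

test_that("cohort tables round-trip through delimited text", {
  coh <- generate_covariates(cohort_config(50, seed = 12))
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 50L)
  expect_equal(sum(is.na(back$race)) + sum(back$race == "", na.rm = TRUE),
               sum(is.na(coh$race)))
})
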