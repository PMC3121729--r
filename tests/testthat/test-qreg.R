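# Check-loss quantile regression: loss, objective, solver, oracle, inference.

test_that("check loss is the asymmetric piecewise-linear loss", {
  expect_equal(check_loss(0, 0.3), 0)
  expect_equal(check_loss(-3, 0.5), 1.5)   # |r|/2 at the median
  expect_equal(check_loss(2, 0.5), 1)
  expect_equal(check_loss(-1, 0.25), 0.75)
  expect_equal(check_loss(1, 0.25), 0.25)
  expect_error(check_loss(1, 0), "inside \\(0, 1\\)")
  expect_error(check_loss(1, 1.2), "inside \\(0, 1\\)")
})

test_that("objective matches a naive loop oracle and hand values", {
  x <- cbind(rep(1, 3))
  expect_equal(qreg_objective(2, x, c(1, 2, 3), 0.5), 1.0)
  set.seed(11)
  for (i in 1:20) {
    inst <- random_instance(n = sample(5:15, 1), p = sample(1:3, 1), seed = i)
    beta <- rnorm(ncol(inst$x))
    tau <- runif(1, 0.05, 0.95)
    expect_equal(qreg_objective(beta, inst$x, inst$y, tau),
                 loop_check_objective(beta, inst$x, inst$y, tau),
                 tolerance = 1e-12)
  }
  # perfect fit
  inst <- random_instance(8, 2, seed = 99)
  yhat <- inst$x %*% c(1, -2)
  expect_equal(qreg_objective(c(1, -2), inst$x, yhat, 0.3), 0)
  expect_error(qreg_objective(c(1, 2, 3), inst$x, inst$y, 0.5), "length")
})

test_that("intercept-only fit attains the sample-quantile objective", {
  set.seed(2)
  y <- rnorm(25)
  for (tau in c(0.1, 0.25, 0.5, 0.9)) {
    fit <- qreg_fit(cbind(rep(1, 25)), y, tau)
    target <- sum(check_loss(y - quantile(y, tau, type = 1), tau))
    expect_lte(fit$objective, target + 1e-10)
  }
})

test_that("solver matches the vertex-enumeration oracle on small instances", {
  set.seed(3)
  for (i in 1:60) {
    n <- sample(5:12, 1); p <- sample(1:3, 1)
    inst <- random_instance(n, p, seed = 300 + i)
    tau <- sample(c(0.1, 0.25, 0.5, 0.75, 0.9), 1)
    fit <- suppressWarnings(qreg_fit(inst$x, inst$y, tau))
    oracle <- exact_small_fit(inst$x, inst$y, tau)
    expect_lte(abs(fit$objective - oracle$objective), 1e-8)
    # stored objective is recomputable from the stored solution
    expect_equal(fit$objective,
                 qreg_objective(coef(fit), inst$x, inst$y, fit$tau),
                 tolerance = 1e-10)
  }
})

test_that("exact_small_fit recovers exact lines and refuses big instances", {
  x <- cbind(1, 1:6)
  y <- 2 + 3 * (1:6)
  fit <- exact_small_fit(x, y, 0.3)
  expect_equal(fit$objective, 0)
  expect_equal(unname(coef(fit)), c(2, 3))
  expect_equal(exact_small_fit(cbind(rep(1, 3)), c(1, 2, 3), 0.5)$objective, 1.0)
  expect_error(exact_small_fit(cbind(1, rnorm(20)), rnorm(20), 0.5), "cap")
  expect_error(exact_small_fit(matrix(rnorm(44), 11, 4), rnorm(11), 0.5),
               "at most p = 3")
})

test_that("median regression halves the L1 optimum", {
  set.seed(4)
  for (i in 1:20) {
    inst <- random_instance(sample(6:10, 1), 2, seed = 400 + i)
    fit <- qreg_fit(inst$x, inst$y, 0.5)
    # independent L1 oracle: enumerate basic solutions, score sum |r| by loop
    subsets <- combn(nrow(inst$x), 2)
    l1_best <- Inf
    for (j in seq_len(ncol(subsets))) {
      idx <- subsets[, j]
      b <- tryCatch(solve(inst$x[idx, ], inst$y[idx]), error = function(e) NULL)
      if (is.null(b)) next
      l1_best <- min(l1_best, sum(abs(inst$y - inst$x %*% b)))
    }
    expect_equal(fit$objective, l1_best / 2, tolerance = 1e-8)
  }
})

test_that("solutions satisfy the quantile subgradient condition", {
  set.seed(5)
  for (i in 1:30) {
    n <- sample(20:80, 1); p <- sample(1:3, 1)
    inst <- random_instance(n, p, seed = 500 + i)
    tau <- runif(1, 0.1, 0.9)
    fit <- qreg_fit(inst$x, inst$y, tau)
    r <- residuals(fit)
    expect_lte(sum(r < -1e-9), n * fit$tau)
    expect_gte(sum(r <= 1e-9) + p, n * fit$tau)
  }
})

test_that("estimates are scale and shift equivariant", {
  inst <- random_instance(40, 3, seed = 6)
  tau <- 0.3
  fit <- qreg_fit(inst$x, inst$y, tau)
  # response scaling by c > 0 scales beta by c
  fit_scaled <- qreg_fit(inst$x, 7 * inst$y, tau)
  expect_equal(unname(coef(fit_scaled)), unname(7 * coef(fit)), tolerance = 1e-8)
  # shifting a covariate moves only the intercept
  x2 <- inst$x
  x2[, 2] <- x2[, 2] + 10
  fit_shift <- qreg_fit(x2, inst$y, tau)
  expect_equal(unname(coef(fit_shift)[2:3]), unname(coef(fit)[2:3]),
               tolerance = 1e-8)
  expect_equal(unname(coef(fit_shift)[1]),
               unname(coef(fit)[1] - 10 * coef(fit)[2]), tolerance = 1e-8)
})

test_that("fits are robust to response outliers with unchanged residual sign", {
  inst <- random_instance(60, 2, seed = 7)
  fit <- qreg_fit(inst$x, inst$y, 0.5)
  y2 <- inst$y
  i_max <- which.max(residuals(fit))   # already above the fitted plane
  y2[i_max] <- y2[i_max] + 1e6
  fit2 <- qreg_fit(inst$x, y2, 0.5)
  expect_equal(unname(coef(fit2)), unname(coef(fit)), tolerance = 1e-6)
})

test_that("intercept-only quantiles are monotone in tau", {
  set.seed(8)
  y <- rnorm(50)
  x <- cbind(rep(1, 50))
  taus <- seq(0.1, 0.9, by = 0.1)
  q <- vapply(taus, function(tt) unname(coef(qreg_fit(x, y, tt))), numeric(1))
  expect_true(all(diff(q) >= -1e-10))
})

test_that("degenerate inputs are rejected or clipped", {
  x <- cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))
  colnames(x) <- c("(Intercept)", "a", "b")
  expect_error(qreg_fit(x, rnorm(4), 0.5), "rank deficient.*b")
  inst <- random_instance(20, 2, seed = 9)
  expect_warning(qreg_fit(inst$x, inst$y, 0.001), "clipped")
  expect_error(qreg_fit(inst$x, inst$y, 0), "inside \\(0, 1\\)")
  expect_error(qreg_fit(inst$x[1:2, ], inst$y[1:2], 0.5), "n > p")
})

test_that("formula interface, methods and prediction behave", {
  set.seed(10)
  d <- data.frame(x = runif(100))
  d$y <- 1 + 2 * d$x + rnorm(100, sd = 0.1)
  fit <- qreg(y ~ x, d, tau = 0.5)
  expect_s3_class(fit, "qreg")
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 0.1)
  # prediction at an observed row equals the fitted value
  expect_equal(predict(fit, d[3, , drop = FALSE]), fitted(fit)[3])
  # reference row (intercept 1, covariates 0) returns the intercept
  expect_equal(predict(fit, data.frame(x = 0)), unname(coef(fit)[1]))
  # encoded-matrix predict with clamping
  pr <- predict(fit, c(1, 10), clamp = TRUE)
  expect_equal(as.numeric(pr), 1)
  expect_equal(attr(pr, "clamped"), 1L)
  expect_error(predict(fit, matrix(1, 1, 3)), "columns")
  # multiple taus give a qreg_list with a coefficient matrix
  fits <- qreg(y ~ x, d, tau = c(0.25, 0.75))
  expect_s3_class(fits, "qreg_list")
  expect_equal(dim(coef(fits)), c(2L, 2L))
  expect_output(print(fit), "tau = 0.5")
})

test_that("bootstrap intervals: B = 2 gives min/max, seeds reproduce", {
  inst <- random_instance(30, 2, seed = 12)
  fit <- qreg_fit(inst$x, inst$y, 0.5)
  ci2 <- qreg_boot_ci(fit, B = 2, seed = 21)
  reps <- attr(ci2, "replicates")
  expect_equal(ci2$ci_low, unname(apply(reps, 2, min)))
  expect_equal(ci2$ci_high, unname(apply(reps, 2, max)))
  ci_a <- qreg_boot_ci(fit, B = 25, seed = 33)
  ci_b <- qreg_boot_ci(fit, B = 25, seed = 33)
  expect_identical(ci_a$ci_low, ci_b$ci_low)
  expect_identical(ci_a$ci_high, ci_b$ci_high)
  ci_c <- qreg_boot_ci(fit, B = 25, seed = 34)
  expect_false(identical(ci_a$ci_low, ci_c$ci_low))
  expect_error(qreg_boot_ci(fit, B = 1), "at least 2")
})
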