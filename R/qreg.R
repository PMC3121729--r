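#' Check (pinball) loss
#'
#' The asymmetric absolute loss whose expected value is minimized by the
#' tau-th conditional quantile: `rho_tau(r) = r * (tau - 1[r < 0])`. Slope is
#' `tau` for positive residuals and `tau - 1` for negative ones; at `tau =
#' 0.5` it is `|r| / 2`, so median regression is a special case.
#'
#' @param r numeric vector of residuals.
#' @param tau quantile level, strictly inside (0, 1).
#' @return Nonnegative numeric vector, zero only at zero residuals.
#' @examples
#' check_loss(c(-1, 0, 1), tau = 0.25)
#' @export
check_loss <- function(r, tau) {
  stop_if_not_scalar_prob(tau)
  r * (tau - (r < 0))
}

#' Check-loss objective of a coefficient vector
#'
#' The exact (unsmoothed, unregularized) sum of [check_loss()] over the
#' residuals `y - x %*% beta`. This is the quantity [qreg()] minimizes and the
#' quantity all solver tests compare, since quantile-regression solutions can
#' be set-valued while the optimal objective is unique.
#'
#' @param beta coefficient vector of length `ncol(x)`.
#' @param x design matrix (include a column of ones for an intercept).
#' @param y response vector of length `nrow(x)`.
#' @param tau quantile level in (0, 1).
#' @return A single nonnegative number.
#' @export
qreg_objective <- function(beta, x, y, tau) {
  x <- as.matrix(x)
  stop_if_not_scalar_prob(tau)
  if (length(beta) != ncol(x))
    stop("length(beta) must equal ncol(x)", call. = FALSE)
  if (length(y) != nrow(x))
    stop("length(y) must equal nrow(x)", call. = FALSE)
  .qreg_check_objective_cpp(as.numeric(y - x %*% beta), tau)
}

#' Solver control parameters for [qreg()]
#'
#' The kink of the check loss is smoothed by a quadratic of half-width
#' `gamma`, the smoothed convex objective is minimized by damped Newton
#' iterations, and `gamma` is shrunk geometrically (`gamma <- gamma * shrink`)
#' from `gamma0` until it falls below `gamma_tol`, with a final solve at the
#' floor. A basic-solution polish then evaluates exact-fit candidates through
#' the `p` observations nearest the fitted hyperplane and keeps whichever has
#' the smaller exact objective.
#'
#' @param tolerance Newton convergence tolerance on gradient and step.
#' @param max_iter maximum Newton iterations per smoothing level.
#' @param gamma0 initial smoothing half-width; default `median(|y - mean(y)|)`
#'   computed from the data at fit time.
#' @param shrink geometric shrink factor for the smoothing schedule.
#' @param gamma_tol terminal smoothing half-width.
#' @param polish logical; try exact basic solutions near the active set.
#' @return A list of class `"qreg_control"`.
#' @export
qreg_control <- function(tolerance = 1e-10, max_iter = 200L, gamma0 = NULL,
                         shrink = 0.1, gamma_tol = 1e-8, polish = TRUE) {
  stopifnot(tolerance > 0, max_iter >= 1, shrink > 0, shrink < 1, gamma_tol > 0)
  structure(list(tolerance = tolerance, max_iter = as.integer(max_iter),
                 gamma0 = gamma0, shrink = shrink, gamma_tol = gamma_tol,
                 polish = isTRUE(polish)),
            class = "qreg_control")
}

#' Linear quantile regression by check-loss minimization
#'
#' Fits the linear conditional-quantile model `Q_y(tau | x) = x' beta_tau` by
#' minimizing `sum_i rho_tau(y_i - x_i' beta)` with a finite-smoothing Newton
#' algorithm: the check-loss kink is replaced by a quadratic of shrinking
#' half-width so Newton-Raphson applies, and the smoothing width is driven to
#' (effectively) zero over a geometric schedule. `tau = 0.5` is median (L1)
#' regression. The estimator is robust to outlying responses but not to
#' leverage points in covariate space (see [leverage_flags()]).
#'
#' @param formula,data model formula and data frame (standard modelling
#'   interface). Alternatively call [qreg_fit()] on a design matrix directly.
#' @param tau quantile level(s) in (0, 1); a fit is returned per level.
#'   Levels within `0.5/n` of 0 or 1 are clipped with a warning (extreme-tail
#'   fits are fragile).
#' @param boot number of xy-pair bootstrap replicates for percentile
#'   confidence intervals; 0 (default) skips inference.
#' @param level confidence level for bootstrap intervals.
#' @param seed integer seed controlling all bootstrap randomness.
#' @param control a [qreg_control()] list.
#' @return For a single `tau`, an object of class `"qreg"` with components
#'   `coefficients`, `tau`, `objective` (exact check-loss sum at the
#'   solution), `iterations`, `converged`, `gamma_final`, `residuals`,
#'   `fitted.values`, and (when `boot > 0`) `ci` with percentile intervals
#'   and two-sided percentile-bootstrap p-values. For several `tau`, a list of
#'   class `"qreg_list"` of such fits.
#' @seealso [exact_small_fit()] for the enumeration oracle,
#'   [qreg_boot_ci()] to add inference to an existing fit.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = runif(200))
#' d$y <- 1 + 2 * d$x + rnorm(200, sd = 0.2)
#' fit <- qreg(y ~ x, d, tau = 0.5)
#' coef(fit)
#' @export
qreg <- function(formula, data, tau = 0.5, boot = 0L, level = 0.95,
                 seed = NULL, control = qreg_control()) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  fits <- lapply(tau, function(tt) {
    fit <- qreg_fit(x, y, tt, control = control)
    fit$call <- match.call()
    fit$terms <- attr(mf, "terms")
    if (boot > 0)
      fit$ci <- qreg_boot_ci(fit, B = boot, seed = seed, level = level)
    fit
  })
  if (length(fits) == 1L) return(fits[[1L]])
  structure(fits, class = "qreg_list", tau = tau)
}

#' Quantile regression on a prepared design matrix
#'
#' Workhorse behind [qreg()]; use it when the design matrix is already encoded
#' (e.g. from [encode_design()]).
#'
#' @param x numeric design matrix, first column typically the intercept; must
#'   have full column rank.
#' @param y numeric response vector.
#' @param tau quantile level in (0, 1).
#' @param control a [qreg_control()] list.
#' @return An object of class `"qreg"`; see [qreg()].
#' @export
qreg_fit <- function(x, y, tau, control = qreg_control()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in design or response", call. = FALSE)
  if (n <= p) stop("need more observations than parameters (n > p)", call. = FALSE)
  stop_if_not_scalar_prob(tau)
  qrx <- qr(x)
  if (qrx$rank < p) {
    dep <- colnames(x)[qrx$pivot[(qrx$rank + 1L):p]]
    stop("design matrix is rank deficient; dependent columns: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  tau_min <- 0.5 / n
  if (tau < tau_min || tau > 1 - tau_min) {
    warning(sprintf("tau = %g clipped to [%g, %g]; extreme-tail fits are fragile",
                    tau, tau_min, 1 - tau_min))
    tau <- min(max(tau, tau_min), 1 - tau_min)
  }

  gamma0 <- control$gamma0
  if (is.null(gamma0)) gamma0 <- median(abs(y - mean(y)))
  if (!is.finite(gamma0) || gamma0 <= 0) gamma0 <- 1
  beta0 <- qr.coef(qrx, y)                      # least-squares start
  res <- .qreg_smooth_fit_cpp(x, y, tau, as.numeric(beta0), gamma0,
                              control$shrink, control$gamma_tol / 10,
                              control$tolerance, control$max_iter)
  beta <- as.numeric(res$beta)
  obj <- qreg_objective(beta, x, y, tau)

  if (control$polish) {
    pol <- polish_basic(x, y, tau, beta)
    if (pol$objective < obj - 1e-15) {
      beta <- pol$beta
      obj <- pol$objective
    }
  }
  names(beta) <- colnames(x)
  fitted <- as.numeric(x %*% beta)
  structure(list(coefficients = beta, tau = tau, objective = obj,
                 iterations = res$iterations, converged = res$converged,
                 gamma_final = res$gamma_final,
                 residuals = y - fitted, fitted.values = fitted,
                 n = n, p = p, x = x, y = y, ci = NULL,
                 call = sys.call()),
            class = "qreg")
}

# An optimal check-loss solution interpolates p observations (a basic
# solution). After the smoothed solve, try the exact fits through p-subsets of
# the observations nearest the fitted hyperplane and keep the best.
polish_basic <- function(x, y, tau, beta) {
  n <- nrow(x); p <- ncol(x)
  r <- as.numeric(y - x %*% beta)
  cand <- order(abs(r))[seq_len(min(n, p + 3L))]
  best <- list(beta = beta, objective = qreg_objective(beta, x, y, tau))
  subsets <- combn(cand, p)
  for (j in seq_len(ncol(subsets))) {
    idx <- subsets[, j]
    b <- tryCatch(solve(x[idx, , drop = FALSE], y[idx]),
                  error = function(e) NULL)
    if (is.null(b) || anyNA(b) || any(!is.finite(b))) next
    o <- qreg_objective(b, x, y, tau)
    if (o < best$objective) best <- list(beta = as.numeric(b), objective = o)
  }
  best
}

#' Exact small-instance quantile regression by vertex enumeration
#'
#' Independent oracle for the iterative solver: some minimizer of the convex
#' piecewise-linear check-loss objective interpolates `p` observations, so on
#' small instances the global optimum is found by solving the exact fit
#' through every `p`-subset of rows and keeping the feasible solution with the
#' smallest objective. Combinatorial cost restricts it to `n <= cap`,
#' `p <= 3`.
#'
#' @inheritParams qreg_fit
#' @param cap largest `n` accepted (default 12).
#' @return An object of class `"qreg"` with the globally optimal objective.
#' @export
exact_small_fit <- function(x, y, tau, cap = 12L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  stop_if_not_scalar_prob(tau)
  if (n > cap) stop(sprintf("n = %d exceeds the enumeration cap (%d)", n, cap),
                    call. = FALSE)
  if (p > 3L) stop("exact_small_fit supports at most p = 3", call. = FALSE)
  if (n <= p) stop("need n > p", call. = FALSE)
  best_beta <- NULL
  best_obj <- Inf
  subsets <- combn(n, p)
  for (j in seq_len(ncol(subsets))) {
    idx <- subsets[, j]
    b <- tryCatch(solve(x[idx, , drop = FALSE], y[idx]),
                  error = function(e) NULL)
    if (is.null(b) || anyNA(b) || any(!is.finite(b))) next
    o <- qreg_objective(b, x, y, tau)
    if (o < best_obj) { best_obj <- o; best_beta <- as.numeric(b) }
  }
  if (is.null(best_beta)) stop("no nonsingular p-subset found", call. = FALSE)
  names(best_beta) <- colnames(x)
  fitted <- as.numeric(x %*% best_beta)
  structure(list(coefficients = best_beta, tau = tau, objective = best_obj,
                 iterations = ncol(subsets), converged = TRUE,
                 gamma_final = 0, residuals = y - fitted,
                 fitted.values = fitted, n = n, p = p, x = x, y = y,
                 ci = NULL, call = sys.call()),
            class = "qreg")
}

#' xy-pair bootstrap percentile intervals for quantile-regression coefficients
#'
#' Resamples whole observations (covariate row + response) with replacement,
#' refits at the same `tau`, and reports per-coefficient empirical percentile
#' intervals (order-statistic definition, no interpolation) plus a two-sided
#' percentile p-value: the smallest level at which the interval excludes zero,
#' computed as `2 * min(frac <= 0, frac >= 0)` and floored at `1/B`.
#' Rank-deficient resamples are redrawn (and counted).
#'
#' @param object a `"qreg"` fit.
#' @param B number of bootstrap replicates (>= 2).
#' @param seed integer seed; the same seed reproduces the intervals exactly.
#' @param level confidence level.
#' @return A data frame with one row per coefficient: `term`, `estimate`,
#'   `ci_low`, `ci_high`, `p`, and attributes `B`, `level`, `redraws`, and
#'   `replicates` (the B x p matrix of replicate estimates).
#' @export
qreg_boot_ci <- function(object, B = 1000L, seed = NULL, level = 0.95) {
  stopifnot(inherits(object, "qreg"))
  if (B < 2) stop("B must be at least 2", call. = FALSE)
  x <- object$x; y <- object$y; tau <- object$tau
  n <- nrow(x); p <- ncol(x)
  if (is.null(colnames(x)))
    colnames(x) <- c("(Intercept)", paste0("b", seq_len(p - 1L)))[seq_len(p)]
  seeds <- derive_seeds(seed, B)
  est <- matrix(NA_real_, B, p, dimnames = list(NULL, colnames(x)))
  redraws <- 0L
  ctrl <- qreg_control()
  for (b in seq_len(B)) {
    est[b, ] <- with_seed(seeds[b], {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        xb <- x[idx, , drop = FALSE]
        if (qr(xb)$rank == p) break
        redraws <- redraws + 1L
        if (redraws > 100L * B)
          stop("too many rank-deficient bootstrap resamples", call. = FALSE)
      }
      coef(suppressWarnings(qreg_fit(xb, y[idx], tau, control = ctrl)))
    })
  }
  alpha <- (1 - level) / 2
  lo <- apply(est, 2, percentile_exact, probs = alpha)
  hi <- apply(est, 2, percentile_exact, probs = 1 - alpha)
  pval <- apply(est, 2, function(e)
    max(1 / B, min(1, 2 * min(mean(e <= 0), mean(e >= 0)))))
  out <- data.frame(term = colnames(x), estimate = coef(object),
                    ci_low = lo, ci_high = hi, p = pval,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "B") <- B
  attr(out, "level") <- level
  attr(out, "redraws") <- redraws
  attr(out, "replicates") <- est
  out
}
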