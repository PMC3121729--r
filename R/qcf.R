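# Conditional quantile structure for the synthetic cohort.
#
# A quantile coefficient function (QCF) specifies per-covariate coefficient
# curves beta_j(tau) on (0, 1). Outcomes are generated by inverse-CDF
# construction: draw U ~ Uniform(0,1) and set Y = clamp(x' beta(U), 0, 1).
# Under this construction beta(tau) is the literal estimand of quantile
# regression at every tau, so planted effects have an exact simulation truth.
# Validity requires x' beta(tau) to be non-decreasing in tau on the covariate
# support (otherwise the curves are not quantile functions).

#' Quantile coefficient function
#'
#' Build the conditional quantile structure used by [generate_mpr()]: one
#' coefficient curve per design column, each given either as a function of
#' `tau` or as a two-column knot table `(tau, value)` interpolated linearly
#' (constant beyond the outer knots).
#'
#' @param intercept the intercept curve `beta_0(tau)`: a function or a knot
#'   matrix/data frame with columns `tau` and `value`.
#' @param ... further named curves; each name must match a numeric column of
#'   the cohort table passed to [generate_mpr()].
#' @return An object of class `"qcf"`: a named list of functions with the
#'   intercept stored under `"(Intercept)"`.
#' @examples
#' q <- qcf(intercept = cbind(tau = c(0.1, 0.5, 0.9), value = c(0.5, 0.9, 1)),
#'          race_nhb = function(tau) -0.05 * (1 - tau))
#' @export
qcf <- function(intercept, ...) {
  curves <- c(list(`(Intercept)` = intercept), list(...))
  if (is.null(names(curves)) || any(names(curves)[-1] == ""))
    stop("all coefficient curves must be named", call. = FALSE)
  structure(lapply(curves, as_qcf_curve), class = "qcf")
}

as_qcf_curve <- function(cur) {
  if (is.function(cur)) return(cur)
  cur <- as.data.frame(cur)
  if (ncol(cur) != 2L)
    stop("a knot table must have two columns (tau, value)", call. = FALSE)
  names(cur) <- c("tau", "value")
  stop_if_not_scalar_prob(cur$tau)
  if (is.unsorted(cur$tau, strictly = TRUE))
    stop("knot tau values must be strictly increasing", call. = FALSE)
  force(cur)
  function(tau) approx(cur$tau, cur$value, xout = tau, rule = 2)$y
}

qcf_terms <- function(q) names(q)

# Evaluate all curves at a vector of tau values -> length(tau) x p matrix.
qcf_eval <- function(q, tau) {
  m <- vapply(q, function(f) as.numeric(f(tau)), numeric(length(tau)))
  if (length(tau) == 1L)
    m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(q)))
  m
}

# Build the numeric matrix matching the QCF terms from a cohort table:
# "(Intercept)" is a column of ones, any other term must be a numeric (or
# logical) cohort column.
qcf_design <- function(q, cohort) {
  n <- nrow(cohort)
  cols <- lapply(qcf_terms(q), function(term) {
    if (term == "(Intercept)") return(rep(1, n))
    v <- cohort[[term]]
    if (is.null(v))
      stop(sprintf("cohort table has no column '%s' required by the qcf", term),
           call. = FALSE)
    if (is.logical(v)) v <- as.numeric(v)
    if (!is.numeric(v))
      stop(sprintf("cohort column '%s' must be numeric (encode factors first)",
                   term), call. = FALSE)
    v
  })
  matrix(unlist(cols), nrow = n,
         dimnames = list(NULL, qcf_terms(q)))
}

#' Validate monotonicity of a quantile coefficient function
#'
#' Checks that `x' beta(tau)` is non-decreasing in `tau` for every covariate
#' profile in `x`, on a grid of tau values. A violation means the configured
#' curves are not conditional quantile functions and is treated as a
#' configuration error naming the offending profile and tau pair.
#'
#' @param q a [qcf()] object.
#' @param x numeric matrix of covariate profiles with columns matching the
#'   qcf terms (from `qcf_design()`), or a cohort table.
#' @param tau_grid grid of levels to check.
#' @param max_profiles cap on distinct profiles checked exhaustively; above
#'   it, an evenly spaced subset of the sorted unique profiles plus all
#'   column-wise extremes is used.
#' @return Invisibly `TRUE`; errors on violation.
#' @export
validate_qcf <- function(q, x, tau_grid = seq(0.01, 0.99, by = 0.02),
                         max_profiles = 5000L) {
  if (is.data.frame(x)) x <- qcf_design(q, x)
  ux <- unique(x)
  if (nrow(ux) > max_profiles) {
    ord <- do.call(order, as.data.frame(ux))
    keep <- unique(c(round(seq(1, nrow(ux), length.out = max_profiles)),
                     unlist(lapply(seq_len(ncol(ux)), function(j)
                       c(which.min(ux[ord, j]), which.max(ux[ord, j]))))))
    ux <- ux[ord[keep], , drop = FALSE]
  }
  bmat <- qcf_eval(q, tau_grid)                # grid x p
  pred <- ux %*% t(bmat)                       # profiles x grid
  d <- pred[, -1L, drop = FALSE] - pred[, -ncol(pred), drop = FALSE]
  bad <- which(d < -1e-10, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf(paste0("qcf is not monotone: profile [%s] has x'beta(%.3f) ",
                        "> x'beta(%.3f)"),
                 paste(signif(ux[i, ], 4), collapse = ", "),
                 tau_grid[j], tau_grid[j + 1L]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Cohort-like default quantile structure
#'
#' A convenience preset whose intercept curve reproduces the left-skewed MPR
#' shape seen in VA diabetes cohorts (clinical cutoffs 0.40/0.60/0.80/0.90
#' sitting near the 2nd/4th/15th/27th percentiles, median near 0.97) and
#' whose race effects shrink from the lower to the upper tail: NHB and Other
#' deficits are largest in the low quantiles and small near the top. It is a
#' qualitative emulation for testing, not a reproduction of any cohort.
#'
#' @param race_scale multiplier on the race-effect curves (set 0 for no race
#'   effect).
#' @return A [qcf()] with terms `(Intercept)`, `race_nhb`, `race_other`.
#' @export
qcf_cohort_preset <- function(race_scale = 1) {
  qcf(
    intercept = cbind(tau = c(0.005, 0.02, 0.04, 0.15, 0.27, 0.50, 0.80, 0.99),
                      value = c(0.20, 0.40, 0.60, 0.80, 0.90, 0.97, 0.995, 1.0)),
    race_nhb = cbind(tau = c(0.02, 0.04, 0.15, 0.27, 0.50, 0.90),
                     value = race_scale *
                       c(-0.034, -0.054, -0.031, -0.020, -0.013, -0.005)),
    race_other = cbind(tau = c(0.02, 0.04, 0.15, 0.27, 0.50, 0.90),
                       value = race_scale *
                         c(-0.063, -0.038, -0.009, 0.000, -0.001, -0.001))
  )
}
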