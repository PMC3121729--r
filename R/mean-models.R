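# Mean-model comparators: homoscedastic OLS and a random-intercept linear
# mixed model. These model the conditional mean of MPR and serve as the
# contrast to quantile regression: a covariate effect that varies across the
# conditional distribution shows up in them only as its average.

#' Ordinary least squares on an encoded design
#'
#' Normal-equation (QR) least squares with classical homoscedastic standard
#' errors. Because MPR-type outcomes routinely violate the normality and
#' constant-variance assumptions, the fit always carries assumption
#' diagnostics: a studentized Breusch-Pagan test for heteroscedasticity and an
#' Anderson-Darling test of residual normality.
#'
#' @param x numeric design matrix including the intercept column; full column
#'   rank required.
#' @param y numeric response.
#' @return An object of class `"mean_fit"` with `method = "ols"`:
#'   coefficients, standard errors, `sigma2_resid`, Gaussian log-likelihood,
#'   residuals/fitted values and a `diagnostics` list with the two tests.
#' @export
fit_ols <- function(x, y) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)", call. = FALSE)
  if (n <= p) stop("need n > p", call. = FALSE)
  qrx <- qr(x)
  if (qrx$rank < p)
    stop("design matrix is rank deficient; dependent columns: ",
         paste(colnames(x)[qrx$pivot[(qrx$rank + 1L):p]], collapse = ", "),
         call. = FALSE)
  lmfit <- lm(y ~ x - 1)
  beta <- setNames(unname(coef(lmfit)), colnames(x))
  res <- residuals(lmfit)
  sigma2 <- sum(res^2) / (n - p)
  se <- setNames(sqrt(diag(chol2inv(qr.R(qrx))) * sigma2), colnames(x))
  has_regressor <- any(apply(x, 2, function(v) length(unique(v)) > 1L))
  bp <- if (has_regressor) lmtest::bptest(lmfit, studentize = TRUE)
        else list(statistic = NA_real_, p.value = NA_real_)
  norm_test <- if (n >= 8) nortest::ad.test(res) else stats::shapiro.test(res)
  structure(list(method = "ols",
                 coefficients = beta, se = se,
                 sigma2_resid = sigma2, sigma2_subject = NA_real_,
                 loglik = as.numeric(logLik(lmfit)),
                 residuals = as.numeric(res),
                 fitted.values = as.numeric(fitted(lmfit)),
                 n = n, p = p,
                 diagnostics = list(
                   heteroscedasticity = list(statistic = unname(bp$statistic),
                                             p.value = unname(bp$p.value),
                                             test = "studentized Breusch-Pagan"),
                   normality = list(statistic = unname(norm_test$statistic),
                                    p.value = unname(norm_test$p.value),
                                    test = norm_test$method)),
                 fallback = FALSE),
            class = "mean_fit")
}

#' Random-intercept linear mixed model
#'
#' Gaussian linear mixed model `y = x' beta + b_subject + e` with
#' `b ~ N(0, sigma2_subject)`, `e ~ N(0, sigma2_resid)`, fitted by maximum
#' likelihood (profiled over the random-intercept structure) via
#' \pkg{lme4}; `reml = TRUE` switches to REML. Variance components are only
#' identifiable with repeated measures: when every subject contributes a
#' single observation the function warns and falls back to [fit_ols()] for
#' the fixed effects, reporting `sigma2_subject` as not estimable (`NA`).
#'
#' @inheritParams fit_ols
#' @param subject vector of subject identifiers, one per row of `x`.
#' @param reml use REML instead of ML.
#' @return An object of class `"mean_fit"` with `method = "lmm"`, including
#'   both variance components and the log-likelihood; `fallback` is `TRUE`
#'   when the singleton-subject OLS path was taken.
#' @export
fit_lmm <- function(x, y, subject, reml = FALSE) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x)
  if (length(subject) != n) stop("subject must have one entry per row", call. = FALSE)
  if (max(table(subject)) < 2L) {
    warning(paste("every subject has a single observation;",
                  "sigma2_subject is not estimable - falling back to OLS",
                  "for the fixed effects"))
    out <- fit_ols(x, y)
    out$method <- "lmm"
    out$fallback <- TRUE
    return(out)
  }
  dat <- as.data.frame(x)
  safe <- paste0("V", seq_len(ncol(x)))
  names(dat) <- safe
  dat$.y <- y
  dat$.subject <- factor(subject)
  form <- stats::reformulate(c("0", safe, "(1 | .subject)"), response = ".y")
  fit <- lme4::lmer(form, data = dat, REML = reml)
  beta <- setNames(unname(lme4::fixef(fit)), colnames(x))
  se <- setNames(sqrt(diag(as.matrix(vcov(fit)))), colnames(x))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2_subj <- vc$vcov[vc$grp == ".subject"]
  s2_res <- vc$vcov[vc$grp == "Residual"]
  structure(list(method = "lmm",
                 coefficients = beta, se = se,
                 sigma2_resid = s2_res, sigma2_subject = s2_subj,
                 loglik = as.numeric(logLik(fit)),
                 residuals = as.numeric(residuals(fit)),
                 fitted.values = as.numeric(fitted(fit)),
                 n = n, p = ncol(x),
                 diagnostics = list(reml = reml),
                 fallback = FALSE),
            class = "mean_fit")
}

#' @export
print.mean_fit <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat(sprintf("%s fit (n = %d)\n", toupper(x$method), x$n))
  tab <- cbind(estimate = x$coefficients, se = x$se)
  print(round(tab, digits))
  cat(sprintf("sigma2_resid = %.6g", x$sigma2_resid))
  if (!is.na(x$sigma2_subject))
    cat(sprintf(", sigma2_subject = %.6g", x$sigma2_subject))
  if (isTRUE(x$fallback)) cat("  [singleton-subject OLS fallback]")
  cat("\n")
  invisible(x)
}

#' @export
coef.mean_fit <- function(object, ...) object$coefficients

#' @export
residuals.mean_fit <- function(object, ...) object$residuals

#' @export
fitted.mean_fit <- function(object, ...) object$fitted.values

#' Predict mean outcomes from a mean-model fit
#'
#' @param object a `"mean_fit"`.
#' @param newdata encoded design matrix (or vector for one row) matching the
#'   fit's columns; `NULL` returns fitted values.
#' @param clamp clamp predictions into `[0, 1]`.
#' @param ... unused.
#' @export
predict.mean_fit <- function(object, newdata = NULL, clamp = FALSE, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  xm <- rbind(newdata)
  if (ncol(xm) != length(object$coefficients))
    stop("newdata columns do not match the fit", call. = FALSE)
  pred <- as.numeric(xm %*% object$coefficients)
  if (clamp) pred <- pmin(1, pmax(0, pred))
  pred
}
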