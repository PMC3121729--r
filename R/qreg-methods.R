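#' @export
print.qreg <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat(sprintf("Quantile regression fit (tau = %g)\n", x$tau))
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("Check-loss objective: %.6g  (n = %d, %s)\n",
              x$objective, x$n,
              if (isTRUE(x$converged)) "converged" else "NOT CONVERGED"))
  invisible(x)
}

#' @export
coef.qreg <- function(object, ...) object$coefficients

#' @export
residuals.qreg <- function(object, ...) object$residuals

#' @export
fitted.qreg <- function(object, ...) object$fitted.values

#' Summarize a quantile-regression fit
#'
#' Returns the coefficient table; when the fit carries bootstrap intervals
#' (from `qreg(..., boot = B)` or [qreg_boot_ci()]) these are included,
#' otherwise only point estimates are shown.
#'
#' @param object a `"qreg"` fit.
#' @param ... unused.
#' @export
summary.qreg <- function(object, ...) {
  tab <- if (!is.null(object$ci)) object$ci else
    data.frame(term = names(object$coefficients),
               estimate = unname(object$coefficients),
               stringsAsFactors = FALSE)
  structure(list(tau = object$tau, coefficients = tab,
                 objective = object$objective, n = object$n,
                 converged = object$converged),
            class = "summary.qreg")
}

#' @export
print.summary.qreg <- function(x, digits = 4, ...) {
  cat(sprintf("tau = %g, n = %d, objective = %.6g\n", x$tau, x$n, x$objective))
  tab <- x$coefficients
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Predict conditional quantiles from a fit
#'
#' Evaluates `x' beta_tau` at new covariate rows. For MPR reporting the
#' prediction can be clamped to the unit interval; the number of clamped
#' values is recorded in the `"clamped"` attribute.
#'
#' @param object a `"qreg"` fit.
#' @param newdata a data frame (when the fit came from a formula), or a
#'   numeric matrix/vector of already-encoded covariate rows matching the
#'   fit's design columns (include the intercept column).
#' @param clamp logical; clamp predictions into `[0, 1]`.
#' @param ... unused.
#' @return Numeric vector of predicted quantiles.
#' @export
predict.qreg <- function(object, newdata = NULL, clamp = FALSE, ...) {
  beta <- object$coefficients
  if (is.null(newdata)) {
    xm <- object$x
  } else if (is.data.frame(newdata)) {
    if (is.null(object$terms))
      stop("fit has no formula terms; supply an encoded matrix instead",
           call. = FALSE)
    xm <- stats::model.matrix(stats::delete.response(object$terms), newdata)
  } else {
    xm <- rbind(newdata)
    if (ncol(xm) != length(beta))
      stop(sprintf("newdata has %d columns but the fit has %d coefficients",
                   ncol(xm), length(beta)), call. = FALSE)
    cn <- colnames(xm)
    if (!is.null(cn) && !is.null(names(beta)) && !identical(cn, names(beta))) {
      if (!setequal(cn, names(beta)))
        stop("newdata columns do not match fit columns: ",
             paste(setdiff(cn, names(beta)), collapse = ", "), call. = FALSE)
      xm <- xm[, names(beta), drop = FALSE]
    }
  }
  pred <- as.numeric(xm %*% beta)
  if (clamp) {
    nclamp <- sum(pred < 0 | pred > 1)
    pred <- pmin(1, pmax(0, pred))
    attr(pred, "clamped") <- nclamp
  }
  pred
}

#' @export
print.qreg_list <- function(x, ...) {
  for (f in x) { print(f, ...); cat("\n") }
  invisible(x)
}

#' @export
coef.qreg_list <- function(object, ...) {
  do.call(cbind, setNames(lapply(object, coef),
                          paste0("tau=", vapply(object, `[[`, 0, "tau"))))
}
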