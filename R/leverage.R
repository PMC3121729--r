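#' Leverage-point flags from robust coordinatewise distances
#'
#' Quantile regression is robust to outlying responses but not to leverage
#' points in covariate space, so extreme design rows are flagged (never
#' removed). Each non-constant design column is standardized by its median
#' and MAD (consistency constant 1.4826), the squared coordinatewise
#' distances are summed, and rows exceeding the chi-square quantile at
#' `level` with degrees of freedom equal to the number of usable columns are
#' flagged. Under a clean multivariate Gaussian design the flag rate is
#' approximately `1 - level`. Columns with zero MAD (constants, including the
#' intercept) carry no distance information and are excluded with a warning.
#'
#' @param x numeric design matrix (dummy columns allowed) or an
#'   `"mpr_design"`.
#' @param level chi-square quantile used as the flag threshold (default
#'   0.975).
#' @return Logical vector of per-row flags, with attributes `distance`
#'   (robust squared distances), `df` (columns used) and `threshold`.
#' @examples
#' set.seed(1)
#' x <- cbind(a = rnorm(100), b = rnorm(100))
#' x[1, ] <- c(10, 10)
#' which(leverage_flags(x))
#' @export
leverage_flags <- function(x, level = 0.975) {
  if (inherits(x, "mpr_design")) x <- x$x
  x <- as.matrix(x)
  stop_if_not_scalar_prob(level, "level")
  med <- apply(x, 2, median)
  scale <- apply(x, 2, mad)
  usable <- scale > 0
  if (any(!usable)) {
    nm <- colnames(x)[!usable]
    if (is.null(nm)) nm <- which(!usable)
    warning("zero-MAD column(s) excluded from leverage distance: ",
            paste(nm, collapse = ", "))
  }
  n <- nrow(x)
  if (!any(usable)) {
    flags <- rep(FALSE, n)
    attr(flags, "distance") <- rep(0, n)
    attr(flags, "df") <- 0L
    attr(flags, "threshold") <- NA_real_
    return(flags)
  }
  z <- sweep(sweep(x[, usable, drop = FALSE], 2, med[usable]), 2,
             scale[usable], `/`)
  d2 <- rowSums(z^2)
  df <- sum(usable)
  thr <- qchisq(level, df = df)
  flags <- d2 > thr
  attr(flags, "distance") <- d2
  attr(flags, "df") <- df
  attr(flags, "threshold") <- thr
  flags
}
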