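#' Fit a log-log mass-length allometry
#'
#' Fits the power-law allometry \eqn{\ln M = \ln a + b \ln L} by one of the
#' three line-fitting estimators used by the classical condition indices:
#' ordinary least squares (\code{"OLS"}, error in mass only), major axis
#' (\code{"MA"}, minimizes squared perpendicular distances, error in both
#' variables on a common scale) and reduced / standardized major axis
#' (\code{"RMA"}, slope = ratio of standard deviations signed by the
#' correlation; equivalently the OLS slope divided by the correlation).
#'
#' All three lines pass through the centroid
#' \eqn{(\overline{\ln L}, \overline{\ln M})}; they differ only in slope.
#'
#' @param ln_length numeric vector of log lengths (natural log of mm).
#' @param ln_mass numeric vector of log masses (natural log of grams),
#'   same length as \code{ln_length}.
#' @param method one of \code{"OLS"}, \code{"MA"}, \code{"RMA"}.
#'
#' @return An object of class \code{allometric_fit}: a list with
#'   \code{method}, \code{slope_b}, \code{intercept_ln_a} (in ln grams),
#'   \code{L0} (arithmetic mean of the lengths, mm), \code{r} (Pearson
#'   correlation of the log variables) and \code{n}.
#'
#' @examples
#' ln_L <- log(c(800, 900, 1000, 1100, 1200))
#' ln_M <- 2 + 3 * ln_L             # exact power law, b = 3
#' fit_allometry(ln_L, ln_M, "RMA")
#' @export
fit_allometry <- function(ln_length, ln_mass, method = c("OLS", "MA", "RMA")) {
  method <- match.arg(method)
  keep <- is.finite(ln_length) & is.finite(ln_mass)
  x <- ln_length[keep]
  y <- ln_mass[keep]
  n <- length(x)
  if (n < 3L)
    stop("fit_allometry() needs at least 3 complete (length, mass) points, got ",
         n, call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  if (sxx == 0)
    stop("degenerate allometric fit: all lengths identical (zero variance)",
         call. = FALSE)

  slope <- switch(method,
    OLS = sxy / sxx,
    MA = {
      if (sxy == 0)
        stop("major-axis slope undefined: covariance of ln(L) and ln(M) is zero",
             call. = FALSE)
      (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
    },
    RMA = {
      if (syy == 0)
        stop("degenerate RMA fit: all masses identical (zero variance)",
             call. = FALSE)
      sign2 <- if (sxy < 0) -1 else 1  # sign(0) treated as + (slope magnitude only)
      sign2 * sqrt(syy / sxx)
    }
  )
  r <- if (syy > 0) sxy / sqrt(sxx * syy) else NA_real_

  structure(
    list(
      method         = method,
      slope_b        = slope,
      intercept_ln_a = mean(y) - slope * mean(x),
      L0             = mean(exp(x)),
      r              = r,
      n              = n
    ),
    class = "allometric_fit"
  )
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf(
    "Allometric fit (%s): ln(M) = %.4f + %.4f * ln(L)   [n = %d, r = %.3f, L0 = %.1f mm]\n",
    x$method, x$intercept_ln_a, x$slope_b, x$n, x$r, x$L0
  ))
  invisible(x)
}

#' Predict ln-mass from an allometric fit
#'
#' @param object an \code{\link{fit_allometry}} result.
#' @param ln_length numeric vector of log lengths.
#' @param ... unused.
#' @return predicted \eqn{\ln M} values.
#' @export
predict.allometric_fit <- function(object, ln_length, ...) {
  object$intercept_ln_a + object$slope_b * ln_length
}
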