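#' Calibrate the alkaline-hematin hemoglobin assay
#'
#' The assay reads absorbance at 580 nm; concentration is recovered from a
#' log-log ordinary least squares calibration against samples of known
#' hemoglobin concentration: \eqn{\log(Hb) = intercept + slope \cdot
#' \log(A_{580})}.
#'
#' @param absorbance positive absorbance readings of the calibration
#'   samples.
#' @param hb_g_dl known hemoglobin concentrations (g/dL) of the same
#'   samples.
#' @return object of class \code{hb_calibration}: slope, intercept,
#'   \code{r_squared}, n.
#' @examples
#' a <- c(0.1, 0.2, 0.4, 0.8)
#' calibrate_hemoglobin(a, 2 * a^1.5)   # exact power law: slope 1.5, r2 = 1
#' @export
calibrate_hemoglobin <- function(absorbance, hb_g_dl) {
  if (length(absorbance) != length(hb_g_dl))
    stop("absorbance and hb vectors must have equal length", call. = FALSE)
  ok <- is.finite(absorbance) & is.finite(hb_g_dl)
  absorbance <- absorbance[ok]; hb_g_dl <- hb_g_dl[ok]
  if (length(absorbance) < 3L)
    stop("need >= 3 calibration pairs", call. = FALSE)
  if (any(absorbance <= 0) || any(hb_g_dl <= 0))
    stop("calibration values must be strictly positive", call. = FALSE)
  fit <- lm(log(hb_g_dl) ~ log(absorbance))
  y <- log(hb_g_dl)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, n = length(absorbance)),
    class = "hb_calibration"
  )
}

#' @export
print.hb_calibration <- function(x, ...) {
  cat(sprintf(
    "Hemoglobin calibration: log(Hb) = %.4f + %.4f log(A580)  [n = %d, R^2 = %.3f]\n",
    x$intercept, x$slope, x$n, x$r_squared))
  invisible(x)
}

#' Convert an absorbance reading to hemoglobin concentration
#'
#' @param cal an \code{\link{calibrate_hemoglobin}} result.
#' @param absorbance positive absorbance reading(s) at 580 nm.
#' @return hemoglobin concentration(s) in g/dL.
#' @export
absorbance_to_hb <- function(cal, absorbance) {
  if (any(!is.finite(absorbance) | absorbance <= 0))
    stop("absorbance must be strictly positive", call. = FALSE)
  exp(cal$intercept + cal$slope * log(absorbance))
}
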