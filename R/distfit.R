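#' Candidate distribution families for index standardization
#'
#' Standard continuous families for positive biological measures plus two
#' location families usable for sign-changing residual indices.  Names
#' follow the base-R distribution abbreviations.
#' @export
default_families <- function() c("norm", "lnorm", "gamma", "weibull", "logis")

.DENS <- list(norm = dnorm, lnorm = dlnorm, gamma = dgamma,
              weibull = dweibull, logis = dlogis)
.RAND <- list(norm = rnorm, lnorm = rlnorm, gamma = rgamma,
              weibull = rweibull, logis = rlogis)
.QUANT <- list(norm = qnorm, lnorm = qlnorm, gamma = qgamma,
               weibull = qweibull, logis = qlogis)
.POSITIVE_ONLY <- c("lnorm", "gamma", "weibull")

#' Fit a species-specific distribution by maximum goodness of fit
#'
#' Fits every applicable candidate family to the sample by minimizing the
#' Anderson-Darling statistic (maximum goodness-of-fit estimation) and
#' selects the family with the smallest AD statistic.  Log-likelihood at
#' the AD optimum is reported for every candidate so that the two rankings
#' can be compared; when they disagree the minimum-AD family still wins
#' (AD is the fitting criterion).
#'
#' Families requiring positive support are skipped, with a diagnostic, for
#' samples containing non-positive values (residual-type indices).
#'
#' @param values numeric sample (>= 8 finite values; non-degenerate).
#' @param families candidate family names, default
#'   \code{\link{default_families}}.
#' @return object of class \code{bbci_distfit}: list with \code{family},
#'   \code{params} (named numeric), \code{loglik}, \code{ad_stat},
#'   \code{n_obs}, \code{candidates} (per-family AD/loglik table, including
#'   skip/failure diagnostics) and \code{data} (the fitting sample, kept
#'   for KS comparison).
#' @examples
#' set.seed(1)
#' f <- fit_distribution(rnorm(200, 100, 10))
#' f$family
#' @export
fit_distribution <- function(values, families = default_families()) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 8L)
    stop("fit_distribution() needs >= 8 observations (got ", n,
         "); use empirical percentiles below that", call. = FALSE)
  if (sd(values) == 0)
    stop("degenerate sample: zero variance", call. = FALSE)
  unknown <- setdiff(families, names(.DENS))
  if (length(unknown))
    stop("unsupported families: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  cand <- lapply(families, function(fam) {
    if (fam %in% .POSITIVE_ONLY && any(values <= 0))
      return(list(family = fam, status = "skipped: non-positive values"))
    fit <- tryCatch(
      suppressWarnings(
        fitdistrplus::fitdist(values, fam, method = "mge", gof = "AD")),
      error = function(e) e)
    if (inherits(fit, "error"))
      return(list(family = fam, status = paste("failed:", conditionMessage(fit))))
    ad <- tryCatch(
      suppressWarnings(unname(fitdistrplus::gofstat(fit)$ad)),
      error = function(e) NA_real_)
    ll <- suppressWarnings(sum(do.call(
      .DENS[[fam]], c(list(values), as.list(fit$estimate), log = TRUE))))
    list(family = fam, status = "ok", params = fit$estimate,
         ad_stat = ad, loglik = ll)
  })
  names(cand) <- families
  ok <- vapply(cand, function(z) identical(z$status, "ok") &&
                 is.finite(z$ad_stat), logical(1))
  if (!any(ok)) {
    diag <- vapply(cand, function(z) z$status, character(1))
    stop("no candidate family could be fitted:\n  ",
         paste(names(diag), diag, sep = ": ", collapse = "\n  "),
         call. = FALSE)
  }
  ads <- vapply(cand[ok], function(z) z$ad_stat, numeric(1))
  win <- cand[ok][[which.min(ads)]]

  cand_table <- do.call(rbind, lapply(cand, function(z)
    data.frame(family = z$family, status = z$status,
               ad_stat = if (is.null(z$ad_stat)) NA_real_ else z$ad_stat,
               loglik = if (is.null(z$loglik)) NA_real_ else z$loglik,
               stringsAsFactors = FALSE)))
  rownames(cand_table) <- NULL

  structure(
    list(family = win$family, params = win$params, loglik = win$loglik,
         ad_stat = win$ad_stat, n_obs = n, candidates = cand_table,
         data = values),
    class = "bbci_distfit"
  )
}

#' @export
print.bbci_distfit <- function(x, ...) {
  cat(sprintf("Fitted distribution: %s (n = %d)\n", x$family, x$n_obs))
  cat("  params:", paste(names(x$params), signif(x$params, 5),
                         sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  AD = %.4f, logLik = %.2f\n", x$ad_stat, x$loglik))
  invisible(x)
}

#' Simulate draws from a fitted distribution
#'
#' @param dist a \code{bbci_distfit} object (or a list with \code{family}
#'   and \code{params}).
#' @param n number of draws (default 10,000, the standard simulation size
#'   for index distributions).
#' @param seed optional integer; when given the draw is reproducible.
#' @return numeric vector of n draws.
#' @export
simulate_draws <- function(dist, n = 10000L, seed = NULL) {
  stopifnot(n >= 1)
  if (!dist$family %in% names(.RAND))
    stop("unknown family: ", dist$family, call. = FALSE)
  if (any(!is.finite(dist$params)))
    stop("invalid distribution parameters", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  do.call(.RAND[[dist$family]], c(list(n), as.list(dist$params)))
}

#' Quantile function of a fitted distribution
#'
#' @param dist a \code{bbci_distfit}-like list.
#' @param p probabilities in (0,1).
#' @return quantiles.
#' @export
quantile_of_fit <- function(dist, p) {
  do.call(.QUANT[[dist$family]], c(list(p), as.list(dist$params)))
}

#' Percentile of a value within a simulated distribution
#'
#' Midrank empirical percentile with a continuity correction:
#' \eqn{p = (k + 0.5)/(n + 1)} where \eqn{k} is the number of draws
#' strictly below the value plus half the number of ties.  The result is
#' always strictly inside (0, 1), so the downstream logit is finite even
#' for values outside the simulated range.
#'
#' @param value numeric vector of values to be ranked.
#' @param draws non-empty numeric sample defining the distribution.
#' @return percentiles in the open interval (0, 1), one per value.
#' @examples
#' percentile_of(5, c(1, 2, 3, 4, 6, 7, 8, 9, 10))  # (4 + 0.5)/10 = 0.45
#' @export
percentile_of <- function(value, draws) {
  if (length(draws) == 0L)
    stop("empty draw sample", call. = FALSE)
  n <- length(draws)
  sorted <- sort(draws)
  le <- findInterval(value, sorted)                        # draws <= value
  lt <- findInterval(value, sorted, left.open = TRUE)      # draws <  value
  ties <- le - lt
  (lt + 0.5 * ties + 0.5) / (n + 1)
}

#' Two-sample Kolmogorov-Smirnov p-value
#'
#' Used to compare an observed sample against the simulated draws of its
#' fitted (or fused) distribution.  Rank-based, hence invariant to common
#' strictly monotone transforms of both samples.
#'
#' @param observed,draws non-empty numeric samples.
#' @return p-value in [0, 1].
#' @export
ks_pvalue <- function(observed, draws) {
  if (length(observed) == 0L || length(draws) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  suppressWarnings(ks.test(observed, draws))$p.value
}
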