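#' The beta-PERT distribution
#'
#' A Beta distribution rescaled to \code{[min, max]} and parameterized by a
#' mode, with shape constant \eqn{\lambda = 4}: shape parameters
#' \eqn{\alpha = 1 + \lambda (mode-min)/(max-min)},
#' \eqn{\beta = 1 + \lambda (max-mode)/(max-min)}, giving mean
#' \eqn{(min + \lambda \cdot mode + max)/(\lambda + 2)}.  The standard way
#' to encode a published reference interval (min, most-likely, max) as an
#' "expert opinion" distribution.
#'
#' @param x,q quantiles; \code{p} probabilities; \code{n} number of draws.
#' @param min,mode,max distribution support and mode; require
#'   \code{min <= mode <= max} and \code{min < max}.
#' @param lambda shape constant (default 4, the classical PERT).
#' @return density, distribution function, quantiles or random draws.
#' @name pert
NULL

.pert_shapes <- function(min, mode, max, lambda = 4) {
  stopifnot(min < max, mode >= min, mode <= max)
  range <- max - min
  list(a = 1 + lambda * (mode - min) / range,
       b = 1 + lambda * (max - mode) / range)
}

#' @rdname pert
#' @export
dpert <- function(x, min, mode, max, lambda = 4) {
  s <- .pert_shapes(min, mode, max, lambda)
  stats::dbeta((x - min) / (max - min), s$a, s$b) / (max - min)
}

#' @rdname pert
#' @export
ppert <- function(q, min, mode, max, lambda = 4) {
  s <- .pert_shapes(min, mode, max, lambda)
  stats::pbeta((q - min) / (max - min), s$a, s$b)
}

#' @rdname pert
#' @export
qpert <- function(p, min, mode, max, lambda = 4) {
  s <- .pert_shapes(min, mode, max, lambda)
  min + (max - min) * qbeta(p, s$a, s$b)
}

#' @rdname pert
#' @export
rpert <- function(n, min, mode, max, lambda = 4) {
  s <- .pert_shapes(min, mode, max, lambda)
  min + (max - min) * rbeta(n, s$a, s$b)
}

#' Beta-PERT model of a published reference range
#'
#' Published reference ranges report mean, minimum and maximum.  The PERT
#' distribution is parameterized by its mode, so the mode is recovered from
#' the lambda = 4 mean identity
#' \eqn{mode = (6 \cdot mean - min - max)/4} and clipped into
#' \code{[min, max]} with a warning when the reported mean is too close to
#' an endpoint for the identity to give an interior mode.  A range with
#' \code{ref_min == ref_max} degenerates to a point mass.
#'
#' @param ref one-row data.frame (or list) with \code{ref_mean},
#'   \code{ref_min}, \code{ref_max} (see
#'   \code{\link{validate_reference_ranges}}).
#' @return list with \code{min}, \code{mode}, \code{max}, \code{mean}
#'   (analytic PERT mean after any clipping), \code{degenerate} flag and
#'   \code{clipped} flag.
#' @examples
#' pert_distribution(list(ref_min = 0, ref_mean = 0.5, ref_max = 1))$mode
#' @export
pert_distribution <- function(ref) {
  mn <- ref$ref_min; mu <- ref$ref_mean; mx <- ref$ref_max
  if (is.na(mn) || is.na(mu) || is.na(mx) || mn > mu || mu > mx)
    stop("invalid reference range: need ref_min <= ref_mean <= ref_max",
         call. = FALSE)
  if (mn == mx)
    return(list(min = mn, mode = mn, max = mx, mean = mn,
                degenerate = TRUE, clipped = FALSE))
  mode <- (6 * mu - mn - mx) / 4
  clipped <- FALSE
  if (mode < mn || mode > mx) {
    mode <- min(max(mode, mn), mx)
    clipped <- TRUE
    warning(sprintf(
      "PERT mode outside [min, max] for reported mean %.4g; clipped to %.4g",
      mu, mode), call. = FALSE)
  }
  list(min = mn, mode = mode, max = mx,
       mean = (mn + 4 * mode + mx) / 6,
       degenerate = FALSE, clipped = clipped)
}

#' Draw from a reference-range PERT model
#'
#' @param pert result of \code{\link{pert_distribution}}.
#' @param n number of draws.
#' @return numeric vector of n draws (a constant vector for a degenerate
#'   range).
#' @export
rpert_ref <- function(pert, n) {
  if (pert$degenerate) return(rep(pert$min, n))
  rpert(n, pert$min, pert$mode, pert$max)
}

#' Fuse a published reference range with study observations
#'
#' Sample-size-weighted probability-tree fusion: each posterior draw comes
#' from the reference-range beta-PERT with probability
#' \eqn{w = n_{ref}/(n_{ref} + n_{obs})}, and is otherwise a uniform
#' resample (with replacement) of the raw observations.  With no
#' observations the posterior is the pure PERT; as observations dominate
#' the posterior approaches their empirical distribution.
#'
#' @param ref one-row reference range (needs \code{ref_mean},
#'   \code{ref_min}, \code{ref_max}, \code{n_ref}).
#' @param observations numeric vector of study measurements (may be empty).
#' @param n_draws number of posterior draws (default 1,000, the standard
#'   size for physiology posteriors).
#' @param seed optional integer for reproducibility.
#' @return numeric vector of \code{n_draws} posterior draws; attribute
#'   \code{"w_ref"} records the reference-branch weight.
#' @export
fuse_reference <- function(ref, observations = numeric(0), n_draws = 1000L,
                           seed = NULL) {
  observations <- observations[is.finite(observations)]
  n_obs <- length(observations)
  n_ref <- ref$n_ref
  if (is.null(n_ref) || is.na(n_ref) || n_ref < 1)
    stop("reference range needs n_ref >= 1", call. = FALSE)
  pert <- pert_distribution(ref)
  if (!is.null(seed)) set.seed(seed)
  w <- n_ref / (n_ref + n_obs)
  take_ref <- if (n_obs == 0) rep(TRUE, n_draws) else runif(n_draws) < w
  out <- numeric(n_draws)
  if (any(take_ref)) out[take_ref] <- rpert_ref(pert, sum(take_ref))
  if (any(!take_ref))
    out[!take_ref] <- sample(observations, sum(!take_ref), replace = TRUE)
  attr(out, "w_ref") <- w
  out
}
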