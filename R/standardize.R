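#' Standardize one sample to percentiles through a fitted distribution
#'
#' Workhorse for species-specific percentile standardization: fits a
#' distribution by minimum Anderson-Darling (\code{\link{fit_distribution}}),
#' simulates \code{n_draws} values from it, and returns the midrank
#' percentile of every observation within the simulated sample.  With
#' fewer than 8 observations no family is fitted; the empirical percentile
#' of the raw sample is used instead, with a warning.
#'
#' @param values numeric sample (one species, one variable).
#' @param n_draws simulation size (default 10,000).
#' @param seed optional integer for reproducible simulation.
#' @param families candidate families, see \code{\link{default_families}}.
#' @return list with \code{percentiles} (same length/order as
#'   \code{values}; NA where the input is NA), \code{method}
#'   (\code{"fitted_distribution"} or \code{"empirical"}), \code{fit}
#'   (\code{bbci_distfit} or NULL), \code{draws}, and \code{ks_p} (observed
#'   sample vs simulated draws; NA for the empirical fallback).
#' @export
standardize_values <- function(values, n_draws = 10000L, seed = NULL,
                               families = default_families()) {
  ok <- is.finite(values)
  out <- rep(NA_real_, length(values))
  n <- sum(ok)
  if (n == 0L)
    return(list(percentiles = out, method = "empty", fit = NULL,
                draws = NULL, ks_p = NA_real_))
  if (n < 8L) {
    warning("fewer than 8 observations; falling back to empirical percentiles",
            call. = FALSE)
    out[ok] <- percentile_of(values[ok], values[ok])
    return(list(percentiles = out, method = "empirical", fit = NULL,
                draws = values[ok], ks_p = NA_real_))
  }
  fit <- fit_distribution(values[ok], families)
  draws <- simulate_draws(fit, n_draws, seed = seed)
  out[ok] <- percentile_of(values[ok], draws)
  list(percentiles = out, method = "fitted_distribution", fit = fit,
       draws = draws, ks_p = ks_pvalue(values[ok], draws))
}

.subseed <- function(seed, key, keys) {
  if (is.null(seed)) return(NULL)
  (seed + 7919L * match(key, sort(keys))) %% .Machine$integer.max
}

#' Species-specific percentile standardization of condition indices
#'
#' For every species x index combination, fits a distribution to the
#' observed index values, simulates from it and converts each animal's
#' value to its percentile (see \code{\link{standardize_values}}).
#'
#' @param index_table result of \code{\link{compute_indices}} (or any
#'   data.frame with \code{animal_id}, \code{species} and index columns).
#' @param indices index columns to standardize (default all eight).
#' @param n_draws simulated values per distribution (default 10,000).
#' @param seed optional integer; sub-seeds are derived per species x index
#'   so results do not depend on processing order.
#' @param families candidate families.
#' @return data.frame \code{animal_id}, \code{species} plus one percentile
#'   column per index, all strictly in (0, 1); attribute \code{"report"}
#'   holds the per species x index fit report (family, AD, loglik, KS p,
#'   method, n).
#' @export
standardize_indices <- function(index_table,
                                indices = c("MLR", "BMI", "FKI", "RC",
                                            "OLSR", "MAR", "RMAR", "SMI"),
                                n_draws = 10000L, seed = NULL,
                                families = default_families()) {
  indices <- intersect(indices, names(index_table))
  if (!length(indices))
    stop("no index columns found to standardize", call. = FALSE)
  out <- index_table[c("animal_id", "species")]
  for (ix in indices) out[[ix]] <- NA_real_
  keys <- as.vector(outer(sort(unique(index_table$species)), indices,
                          paste, sep = ":"))
  report <- list()
  for (sp in sort(unique(index_table$species))) {
    sel <- index_table$species == sp
    for (ix in indices) {
      key <- paste(sp, ix, sep = ":")
      std <- standardize_values(index_table[[ix]][sel], n_draws = n_draws,
                                seed = .subseed(seed, key, keys),
                                families = families)
      out[[ix]][sel] <- std$percentiles
      report[[key]] <- data.frame(
        species = sp, variable = ix, method = std$method,
        family = if (is.null(std$fit)) NA_character_ else std$fit$family,
        params = if (is.null(std$fit)) NA_character_ else
          paste(names(std$fit$params), signif(std$fit$params, 6),
                sep = "=", collapse = ";"),
        ad_stat = if (is.null(std$fit)) NA_real_ else std$fit$ad_stat,
        loglik = if (is.null(std$fit)) NA_real_ else std$fit$loglik,
        ks_p = std$ks_p,
        n_obs = sum(is.finite(index_table[[ix]][sel])),
        stringsAsFactors = FALSE)
    }
  }
  attr(out, "report") <- do.call(rbind, c(report, make.row.names = FALSE))
  out
}

#' Species-specific percentile standardization of the physiology panel
#'
#' For every species x parameter, builds the posterior distribution by
#' fusing the published reference range (beta-PERT "expert opinion") with
#' the study observations, weighted by their sample sizes
#' (\code{\link{fuse_reference}}), then converts each animal's measurement
#' to its percentile within the posterior draws.  Parameters without a
#' published range for a species fall back to the fitted-distribution
#' route (\code{\link{standardize_values}}), with the route recorded in the
#' report.
#'
#' @param records animal records containing physiology columns
#'   (concentration units).
#' @param ranges reference-range table (see
#'   \code{\link{validate_reference_ranges}}).
#' @param parameters physiology columns to standardize (default: those of
#'   \code{\link{physiology_parameters}} present in \code{records}).
#' @param n_draws posterior draws per species x parameter (default 1,000).
#' @param seed optional integer, sub-seeded per species x parameter.
#' @return data.frame \code{animal_id}, \code{species} plus one percentile
#'   column per parameter; attribute \code{"report"} with the fusion
#'   weight, KS p-value and provenance per species x parameter.
#' @export
standardize_physiology <- function(records, ranges = NULL,
                                   parameters = intersect(
                                     physiology_parameters(), names(records)),
                                   n_draws = 1000L, seed = NULL) {
  if (!length(parameters))
    stop("no physiology columns found in records", call. = FALSE)
  if (!is.null(ranges)) ranges <- validate_reference_ranges(ranges)
  out <- records[c("animal_id", "species")]
  for (p in parameters) out[[p]] <- NA_real_
  keys <- as.vector(outer(sort(unique(records$species)), parameters,
                          paste, sep = ":"))
  report <- list()
  for (sp in sort(unique(records$species))) {
    sel <- records$species == sp
    for (p in parameters) {
      key <- paste(sp, p, sep = ":")
      obs <- records[[p]][sel]
      obs_ok <- obs[is.finite(obs)]
      ref <- if (is.null(ranges)) NULL else
        ranges[ranges$species == sp & ranges$parameter == p, , drop = FALSE]
      if (!is.null(ref) && nrow(ref) >= 1L) {
        ref1 <- as.list(ref[1L, ])
        draws <- fuse_reference(ref1, obs_ok, n_draws = n_draws,
                                seed = .subseed(seed, key, keys))
        if (length(obs_ok))
          out[[p]][sel][is.finite(obs)] <- percentile_of(obs_ok, draws)
        report[[key]] <- data.frame(
          species = sp, variable = p, method = "fused_posterior",
          w_ref = attr(draws, "w_ref"),
          ks_p = if (length(obs_ok)) ks_pvalue(obs_ok, draws) else NA_real_,
          n_obs = length(obs_ok), n_ref = ref1$n_ref,
          stringsAsFactors = FALSE)
      } else {
        std <- suppressWarnings(
          standardize_values(obs, n_draws = n_draws,
                             seed = .subseed(seed, key, keys)))
        out[[p]][sel] <- std$percentiles
        report[[key]] <- data.frame(
          species = sp, variable = p, method = std$method,
          w_ref = 0, ks_p = std$ks_p, n_obs = length(obs_ok),
          n_ref = 0L, stringsAsFactors = FALSE)
      }
    }
  }
  attr(out, "report") <- do.call(rbind, c(report, make.row.names = FALSE))
  out
}
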