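#' Default run configuration
#'
#' Defaults for the end-to-end analyses: 10,000 simulated values per index
#' distribution, 1,000 posterior draws per fused physiology distribution,
#' 3 MCMC chains of 30,000 kept-phase iterations after 10,000 burn-in
#' thinned by 10, collinearity threshold 0.7.
#'
#' @param ... overrides of any default field.
#' @return list of class \code{bbci_run_config}.
#' @export
run_config <- function(...) {
  cfg <- list(
    length_field = NULL,          # NULL = select by correlation with mass
    families = default_families(),
    index_draws = 10000L,
    physiology_draws = 1000L,
    chains = 3L, iter = 30000L, burnin = 10000L, thin = 10L,
    rho_threshold = 0.7,
    indices = c("MLR", "BMI", "FKI", "RC", "OLSR", "MAR", "RMAR", "SMI"),
    retained_indices = c("FKI", "MAR", "SMI"),
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown run_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "bbci_run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file; keys as in \code{\link{run_config}}.
#' @return \code{bbci_run_config}.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Compare the eight condition indices for sex/age independence
#'
#' The first modeling stage: computes all eight indices, standardizes each
#' to species-specific percentiles, and fits — per index — the logit-scale
#' hierarchical model with age dummies, the male dummy and the z-scored
#' linear and quadratic day-of-year terms.  An index is \emph{retained}
#' when none of its age or sex coefficients is informative (95\% credible
#' interval includes zero), i.e. when it effectively controls for class
#' structure.  For a non-converged model the retention decision is
#' withheld and flagged rather than reported.
#'
#' @param records animal records (physiology columns not required).
#' @param config a \code{\link{run_config}}.
#' @return object of class \code{bbci_index_comparison}: list with
#'   \code{coefficients} (long data.frame: index x parameter with mean,
#'   se, CI, ES, informative, rhat), \code{retained}, \code{withheld},
#'   \code{length_field}, \code{percentiles}, \code{fit_report},
#'   \code{fits} and \code{warnings}.
#' @export
run_index_comparison <- function(records, config = run_config()) {
  records <- validate_records(records)
  if (length(unique(records$species)) < 2L)
    stop("index comparison needs >= 2 species", call. = FALSE)
  warn <- character(0)
  wcollect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
  })

  length_field <- config$length_field
  if (is.null(length_field))
    length_field <- wcollect(as.character(select_size_measure(records)))
  idx <- compute_indices(records, length_field)
  pct <- wcollect(standardize_indices(
    idx, indices = config$indices, n_draws = config$index_draws,
    seed = config$seed, families = config$families))

  class_terms <- c("age_juvenile", "age_subadult", "age_old", "sex_male")
  fits <- list(); coef_rows <- list()
  retained <- character(0); withheld <- character(0)
  for (ix in config$indices) {
    des <- build_design(pct[[ix]], records)
    fit <- wcollect(fit_condition_model(
      des$y, des$X, des$species,
      chains = config$chains, iter = config$iter, burnin = config$burnin,
      thin = config$thin,
      seed = (config$seed + 101L * match(ix, config$indices)) %%
        .Machine$integer.max))
    fits[[ix]] <- fit
    s <- summarize_posterior(fit)
    coef_rows[[ix]] <- cbind(index = ix, s, stringsAsFactors = FALSE)
    present <- intersect(class_terms, s$parameter)
    if (!fit$converged) {
      withheld <- c(withheld, ix)
    } else if (!any(s$informative[s$parameter %in% present])) {
      retained <- c(retained, ix)
    }
  }

  structure(
    list(coefficients = do.call(rbind, c(coef_rows, make.row.names = FALSE)),
         retained = retained, withheld = withheld,
         length_field = length_field,
         percentiles = pct, fit_report = attr(pct, "report"),
         fits = fits, config = config, warnings = warn),
    class = "bbci_index_comparison")
}

#' @export
print.bbci_index_comparison <- function(x, ...) {
  cat("Index comparison (size measure:", x$length_field, ")\n")
  cat("  retained (age & sex uninformative):",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else "none",
      "\n")
  if (length(x$withheld))
    cat("  decision withheld (non-converged):",
        paste(x$withheld, collapse = ", "), "\n")
  cf <- x$coefficients
  cf$es <- round(cf$es, 2)
  print(head(cf, 14))
  invisible(x)
}

#' Model the physiological correlates of the retained indices
#'
#' The second modeling stage: standardizes the physiology panel to
#' species-specific percentiles by reference-range fusion, screens the
#' covariates for rank collinearity, and fits — per retained index — the
#' logit-scale hierarchical model of the condition percentile on the
#' physiology percentiles (no class or seasonal terms).  Requires at least
#' 8 animals with a complete panel; below that the analysis refuses to
#' run.
#'
#' @param records animal records including physiology columns
#'   (concentration units; hemoglobin already converted from absorbance if
#'   needed, see \code{\link{absorbance_to_hb}}).
#' @param ranges published reference-range table.
#' @param config a \code{\link{run_config}}; \code{config$retained_indices}
#'   names the indices to model (default FKI, MAR, SMI — override with the
#'   retained set of \code{\link{run_index_comparison}} when re-deriving).
#' @return object of class \code{bbci_physiology_model}: list with
#'   \code{coefficients} (ES reported to 2 decimals in the print layer),
#'   \code{screened} (retained covariates per index), \code{percentiles},
#'   \code{physiology_report}, \code{fits}, \code{n_complete} and
#'   \code{warnings}.
#' @export
run_physiology_model <- function(records, ranges, config = run_config()) {
  records <- validate_records(records)
  warn <- character(0)
  wcollect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
  })

  params <- intersect(physiology_parameters(), names(records))
  if (!length(params))
    stop("records carry no physiology columns", call. = FALSE)
  complete <- rowSums(is.na(records[params])) == 0
  if (sum(complete) < 8L)
    stop("only ", sum(complete), " animals have a complete physiology panel; ",
         "at least 8 are required for a defensible model", call. = FALSE)

  length_field <- config$length_field
  if (is.null(length_field))
    length_field <- wcollect(as.character(select_size_measure(records)))
  idx <- compute_indices(records, length_field)
  pct_idx <- wcollect(standardize_indices(
    idx, indices = config$retained_indices, n_draws = config$index_draws,
    seed = config$seed, families = config$families))
  pct_phys <- wcollect(standardize_physiology(
    records, ranges, parameters = params,
    n_draws = config$physiology_draws, seed = config$seed))

  sub <- which(complete)
  fits <- list(); coef_rows <- list(); screened <- list()
  for (ix in config$retained_indices) {
    resp <- pct_idx[[ix]][sub]
    covs <- pct_phys[sub, params, drop = FALSE]
    keep_cov <- wcollect(screen_collinearity(covs, qlogis(resp),
                                             config$rho_threshold))
    screened[[ix]] <- as.character(keep_cov)
    des <- build_design(resp, records[sub, ],
                        covariates = covs[, keep_cov, drop = FALSE],
                        include_class_terms = FALSE, include_season = FALSE)
    fit <- wcollect(fit_condition_model(
      des$y, des$X, des$species,
      chains = config$chains, iter = config$iter, burnin = config$burnin,
      thin = config$thin,
      seed = (config$seed + 211L * match(ix, config$retained_indices)) %%
        .Machine$integer.max))
    fits[[ix]] <- fit
    coef_rows[[ix]] <- cbind(index = ix, summarize_posterior(fit),
                             stringsAsFactors = FALSE)
  }

  structure(
    list(coefficients = do.call(rbind, c(coef_rows, make.row.names = FALSE)),
         screened = screened, percentiles = pct_idx,
         physiology_percentiles = pct_phys,
         physiology_report = attr(pct_phys, "report"),
         fits = fits, n_complete = sum(complete), config = config,
         warnings = warn),
    class = "bbci_physiology_model")
}

#' @export
print.bbci_physiology_model <- function(x, ...) {
  cat("Physiology model on", x$n_complete, "complete panels\n")
  cf <- x$coefficients
  cf$es <- round(cf$es, 2)
  for (ix in unique(cf$index)) {
    cat("\n--", ix, "--\n")
    print(cf[cf$index == ix,
             c("parameter", "mean", "se", "es", "informative", "rhat")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write a pipeline result to CSV files
#'
#' Writes the coefficient table, percentile table(s) and fit/fusion
#' reports of an index-comparison or physiology-model result into a
#' directory, plus a plain-text run report with the retained-index
#' decision and all collected warnings.
#'
#' @param result a \code{bbci_index_comparison} or
#'   \code{bbci_physiology_model}.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_result <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  cf <- result$coefficients
  cf$es <- round(cf$es, 2)
  wr(cf, "coefficients.csv")
  wr(result$percentiles, "index_percentiles.csv")
  if (!is.null(result$fit_report)) wr(result$fit_report, "fit_report.csv")
  if (!is.null(result$physiology_report))
    wr(result$physiology_report, "physiology_report.csv")
  if (!is.null(result$physiology_percentiles))
    wr(result$physiology_percentiles, "physiology_percentiles.csv")

  rpt <- file.path(outdir, "run_report.md")
  lines <- c("# Run report", "",
             if (!is.null(result$retained))
               c(paste("Retained indices:",
                       paste(result$retained, collapse = ", ")),
                 if (length(result$withheld))
                   paste("Withheld (non-converged):",
                         paste(result$withheld, collapse = ", "))),
             if (!is.null(result$n_complete))
               paste("Complete physiology panels:", result$n_complete),
             paste("Seed:", result$config$seed),
             "", "## Warnings",
             if (length(result$warnings)) paste("-", result$warnings)
             else "- none")
  writeLines(lines, rpt)
  invisible(c(paths, rpt))
}
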