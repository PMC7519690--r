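#' Ratio-based condition indices for one or more animals
#'
#' The three ratio indices derived from mass \eqn{M} (g) and a structural
#' length \eqn{L} (mm): mass/length ratio \eqn{MLR = M/L} (g/mm), body mass
#' index \eqn{BMI = M/L^2 \times 10^3} and Fulton's K index
#' \eqn{FKI = M/L^3 \times 10^6} (both dimensionless after scaling).
#'
#' @param records data.frame of animal records (see
#'   \code{\link{validate_records}}).
#' @param length_field name of the length column to use (default
#'   \code{"total_length"}).
#' @return data.frame with \code{animal_id}, \code{MLR}, \code{BMI},
#'   \code{FKI}; animals missing the selected length get \code{NA} rows.
#' @examples
#' rec <- data.frame(animal_id = "a1", species = "fox", sex = "female",
#'                   age_class = "adult", day_of_year = 100,
#'                   body_mass = 3000, total_length = 1000)
#' compute_ratio_indices(rec)   # MLR = BMI = FKI = 3 at L = 10^3 mm
#' @export
compute_ratio_indices <- function(records, length_field = "total_length") {
  if (!length_field %in% names(records))
    stop("missing length field: ", length_field, call. = FALSE)
  M <- records$body_mass
  L <- records[[length_field]]
  data.frame(
    animal_id = records$animal_id,
    MLR = M / L,
    BMI = M / L^2 * 1e3,
    FKI = M / L^3 * 1e6,
    stringsAsFactors = FALSE
  )
}

#' Regression-based condition indices for a single species
#'
#' Fits the three allometric lines (OLS, MA, RMA) once on the species'
#' complete records and derives the regression indices: relative condition
#' \eqn{RC_i = M_i / (a L_i^b)} with \eqn{a, b} from OLS; the three
#' residual indices OLSR/MAR/RMAR, \eqn{\ln M_i - (\ln a + b \ln L_i)}
#' under the respective estimator (ln-grams); and the scaled mass index
#' \eqn{SMI_i = M_i (L_0/L_i)^{b_{RMA}}} (grams), where \eqn{L_0} is the
#' mean length of the fitting set.
#'
#' @inheritParams compute_ratio_indices
#' @return list with \code{indices} (data.frame: animal_id, RC, OLSR, MAR,
#'   RMAR, SMI) and \code{fits} (named list of \code{allometric_fit}
#'   objects).  Records missing mass or the selected length receive
#'   \code{NA} indices and are excluded from the fits.
#' @export
compute_regression_indices <- function(records, length_field = "total_length") {
  if (!length_field %in% names(records))
    stop("missing length field: ", length_field, call. = FALSE)
  if (length(unique(records$species)) > 1L)
    stop("compute_regression_indices() expects records of a single species; ",
         "use compute_indices() for multi-species tables", call. = FALSE)
  M <- records$body_mass
  L <- records[[length_field]]
  ok <- !is.na(M) & !is.na(L)
  if (sum(ok) < 3L)
    stop("need >= 3 complete records per species for regression indices",
         call. = FALSE)
  lnL <- log(L[ok])
  lnM <- log(M[ok])
  fits <- list(
    OLS = fit_allometry(lnL, lnM, "OLS"),
    MA  = fit_allometry(lnL, lnM, "MA"),
    RMA = fit_allometry(lnL, lnM, "RMA")
  )
  a_ols <- exp(fits$OLS$intercept_ln_a)
  b_ols <- fits$OLS$slope_b
  L0    <- fits$RMA$L0

  out <- data.frame(
    animal_id = records$animal_id,
    RC   = M / (a_ols * L^b_ols),
    OLSR = log(M) - predict(fits$OLS, log(L)),
    MAR  = log(M) - predict(fits$MA, log(L)),
    RMAR = log(M) - predict(fits$RMA, log(L)),
    SMI  = M * (L0 / L)^fits$RMA$slope_b,
    stringsAsFactors = FALSE
  )
  list(indices = out, fits = fits)
}

#' All eight condition indices, per species
#'
#' Computes MLR, BMI, FKI, RC, OLSR, MAR, RMAR and SMI for a multi-species
#' table.  Regression indices are fitted per species on all of that
#' species' complete records (no sex/age stratification, so that class
#' independence can be tested downstream).  Animals missing the selected
#' length are flagged in the \code{excluded} attribute and carry NA
#' indices.
#'
#' @inheritParams compute_ratio_indices
#' @return data.frame keyed by \code{animal_id} with \code{species} and the
#'   eight index columns; attribute \code{"fits"} holds the per-species fit
#'   report (see \code{\link{allometry_report}}), attribute
#'   \code{"excluded"} the ids of flagged animals.
#' @export
compute_indices <- function(records, length_field = "total_length") {
  records <- validate_records(records)
  ratio <- compute_ratio_indices(records, length_field)
  pieces <- lapply(split(records, records$species), function(sp) {
    reg <- compute_regression_indices(sp, length_field)
    cbind(species = sp$species, reg$indices[, -1, drop = FALSE],
          animal_id = sp$animal_id, stringsAsFactors = FALSE)
  })
  fits <- lapply(split(records, records$species), function(sp)
    compute_regression_indices(sp, length_field)$fits)
  reg_all <- do.call(rbind, pieces)
  out <- merge(cbind(records[c("animal_id", "species")], ratio[-1]),
               reg_all[, c("animal_id", "RC", "OLSR", "MAR", "RMAR", "SMI")],
               by = "animal_id", sort = FALSE)
  out <- out[match(records$animal_id, out$animal_id), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "excluded") <-
    records$animal_id[is.na(records$body_mass) |
                        is.na(records[[length_field]])]
  out
}

#' Per-species allometric fit report
#'
#' @param index_table result of \code{\link{compute_indices}}.
#' @return data.frame with one row per species x method: slope, intercept,
#'   L0, r, n.
#' @export
allometry_report <- function(index_table) {
  fits <- attr(index_table, "fits")
  rows <- lapply(names(fits), function(sp) {
    do.call(rbind, lapply(fits[[sp]], function(f)
      data.frame(species = sp, method = f$method, slope = f$slope_b,
                 intercept_ln_a = f$intercept_ln_a, L0 = f$L0, r = f$r,
                 n = f$n, stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the structural size measure most correlated with mass
#'
#' Computes, for each candidate length column, the Pearson correlation
#' between \eqn{\ln(\mathrm{length})} and \eqn{\ln(\mathrm{mass})} over
#' complete pairs, and returns the candidate with the greatest absolute
#' correlation.  Ties are broken by candidate order with a warning.
#'
#' @param records data.frame of animal records.
#' @param candidates character vector of length column names (default the
#'   three standard measures present in the table).
#' @return the selected column name; attribute \code{"correlations"}
#'   reports all candidate correlations.
#' @export
select_size_measure <- function(records,
                                candidates = intersect(
                                  c("total_length", "body_length",
                                    "tarsus_length"), names(records))) {
  if (length(candidates) < 1L)
    stop("no candidate size measures supplied", call. = FALSE)
  cors <- vapply(candidates, function(col) {
    if (!col %in% names(records)) return(NA_real_)
    L <- records[[col]]
    M <- records$body_mass
    ok <- !is.na(L) & !is.na(M)
    if (sum(ok) < 3L) return(NA_real_)
    cor(log(L[ok]), log(M[ok]))
  }, numeric(1))
  if (all(is.na(cors)))
    stop("no candidate size measure has >= 3 complete values", call. = FALSE)
  best <- abs(cors)
  winner <- candidates[which.max(best)]   # which.max: first on ties
  tied <- sum(!is.na(best) & abs(best - max(best, na.rm = TRUE)) < 1e-12)
  if (tied > 1L)
    warning("tie between candidate size measures; keeping first in order: ",
            winner, call. = FALSE)
  structure(winner, correlations = cors)
}
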