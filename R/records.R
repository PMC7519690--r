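#' @keywords internal
.SEXES <- c("female", "male")

#' @keywords internal
.AGE_CLASSES <- c("adult", "juvenile", "subadult", "old")  # adult = reference

#' Physiology panel parameter names (serum units per the clinical convention)
#'
#' albumin and globulins in g/dL; urea, creatinine, cholesterol,
#' triglycerides and total bilirubin in mg/dL; hemoglobin in g/dL.
#' @export
physiology_parameters <- function() {
  c("albumin", "urea", "creatinine", "cholesterol",
    "triglycerides", "globulins", "total_bilirubin", "hemoglobin")
}

#' Validate a table of animal capture records
#'
#' Checks the invariants of the animal-record schema: strictly positive body
#' mass and lengths, day of year in 1..366, sex in \{female, male\} and age
#' class in \{juvenile, subadult, adult, old\}.  Length columns other than
#' \code{total_length} and physiology columns are optional; missing values
#' are allowed (empty CSV cells) and flagged downstream, not imputed.
#'
#' @param records data.frame with columns \code{animal_id}, \code{species},
#'   \code{sex}, \code{age_class}, \code{day_of_year}, \code{body_mass}
#'   (g), \code{total_length} (mm) and optionally \code{body_length},
#'   \code{tarsus_length} (mm) and physiology columns named as in
#'   \code{\link{physiology_parameters}}.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c("animal_id", "species", "sex", "age_class",
                "day_of_year", "body_mass", "total_length")
  miss <- setdiff(required, names(records))
  if (length(miss))
    stop("animal records are missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(records$animal_id))
    stop("duplicated animal_id values", call. = FALSE)

  bad_sex <- !is.na(records$sex) & !(records$sex %in% .SEXES)
  if (any(bad_sex))
    stop("invalid sex value(s): ",
         paste(unique(records$sex[bad_sex]), collapse = ", "), call. = FALSE)
  bad_age <- !is.na(records$age_class) & !(records$age_class %in% .AGE_CLASSES)
  if (any(bad_age))
    stop("invalid age_class value(s): ",
         paste(unique(records$age_class[bad_age]), collapse = ", "),
         call. = FALSE)
  doy <- records$day_of_year
  if (any(!is.na(doy) & (doy < 1 | doy > 366 | doy != round(doy))))
    stop("day_of_year must be an integer in [1, 366]", call. = FALSE)

  for (col in intersect(c("body_mass", "total_length", "body_length",
                          "tarsus_length"), names(records))) {
    v <- records[[col]]
    if (any(!is.na(v) & v <= 0))
      stop("non-positive values in ", col, call. = FALSE)
  }
  records
}

#' Read animal records from CSV
#'
#' One row per animal; empty cells are missing values.  The table is
#' validated with \code{\link{validate_records}}.
#'
#' @param path CSV file path.
#' @return validated data.frame of records.
#' @export
read_records <- function(path) {
  validate_records(read.csv(path, stringsAsFactors = FALSE,
                            na.strings = c("", "NA")))
}

#' Read a published reference-range table from CSV
#'
#' Columns: \code{parameter}, \code{species}, \code{ref_mean},
#' \code{ref_min}, \code{ref_max}, \code{n_ref}.  Invariants
#' (min <= mean <= max, n_ref >= 1) are enforced.
#'
#' @param path CSV file path.
#' @return validated data.frame of reference ranges.
#' @export
read_reference_ranges <- function(path) {
  validate_reference_ranges(read.csv(path, stringsAsFactors = FALSE,
                                     na.strings = c("", "NA")))
}

#' @rdname read_reference_ranges
#' @param ranges data.frame of reference ranges to validate.
#' @export
validate_reference_ranges <- function(ranges) {
  required <- c("parameter", "species", "ref_mean", "ref_min", "ref_max",
                "n_ref")
  miss <- setdiff(required, names(ranges))
  if (length(miss))
    stop("reference ranges are missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  with(ranges, {
    if (any(ref_min > ref_mean | ref_mean > ref_max))
      stop("reference range violates ref_min <= ref_mean <= ref_max",
           call. = FALSE)
    if (any(n_ref < 1))
      stop("reference range n_ref must be >= 1", call. = FALSE)
  })
  ranges
}
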