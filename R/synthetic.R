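#' Default species table for the synthetic generator
#'
#' Six carnivore species spanning the realistic mass/length range of a
#' Southern European assemblage (wolf to stone marten), each with a
#' power-law mass-length allometry \eqn{\ln M = \ln a + b \ln L} (mass in
#' g, total length in mm, exponent near the isometric 3) and a lognormal
#' length distribution.  Relative frequencies follow the field mix: foxes
#' and mongooses most common, wildcats rarest.
#' @return data.frame with one row per species.
#' @export
default_species_table <- function() {
  sp <- data.frame(
    species = c("red_fox", "egyptian_mongoose", "common_genet",
                "stone_marten", "wolf", "wildcat"),
    b = c(3.0, 3.0, 3.0, 3.0, 3.0, 3.0),
    length_mean_mm = c(1050, 950, 900, 700, 1600, 850),
    ln_length_sd = c(0.06, 0.06, 0.06, 0.06, 0.06, 0.06),
    mass_mean_g = c(6000, 2700, 1800, 1700, 30000, 4500),
    prob = c(104, 100, 82, 72, 53, 23) / 434,
    stringsAsFactors = FALSE
  )
  sp$ln_a <- log(sp$mass_mean_g) - sp$b * log(sp$length_mean_mm)
  sp
}

#' Default generating distributions of the physiology panel
#'
#' Lognormal concentration distributions with typical carnivore serum
#' values (clinical units), shared across species.
#' @return data.frame: parameter, meanlog, sdlog.
#' @export
default_physiology_table <- function() {
  data.frame(
    parameter = physiology_parameters(),
    meanlog = log(c(3.2, 40, 1.0, 200, 60, 3.0, 0.3, 14)),
    sdlog = rep(0.15, 8),
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic-population configuration
#'
#' Defaults reproduce the structure of the field study the package is
#' designed around: 434 animals of 6 species, an even sex ratio, the
#' empirical age mix (256 adult : 97 juvenile : 57 subadult : 24 old),
#' lognormal residual mass variation of SD 0.08 on the ln scale, and a
#' condition-percentile noise SD of 1.8 on the logit scale (approximately
#' the SD of a standard logistic variate, so that with no effects the
#' condition percentile is close to uniform).  All sex/age, seasonal and
#' physiology effects default to zero — effects are always explicit.
#'
#' @param n_animals population size.
#' @param species_table per-species allometry/length/frequency table
#'   (see \code{\link{default_species_table}}).
#' @param resid_sd SD of the lognormal residual on ln-mass (the raw
#'   material of condition).
#' @param sex_effect additive male effect on ln-mass.
#' @param age_effects named additive ln-mass effects for
#'   \code{juvenile}, \code{subadult}, \code{old} (adult = reference 0).
#' @param season length-2 numeric: coefficients of the z-scored day of year
#'   and z-scored squared day on the condition logit scale.
#' @param phys_slopes named numeric: per-parameter slope linking the
#'   physiology percentile to the condition logit-percentile (0 = no
#'   coupling; parameters named here get generated panels).
#' @param sigma_sp SD of the species random intercept on the condition
#'   logit.
#' @param cond_noise_sd SD of the animal-level condition noise (logit
#'   scale).
#' @param age_probs sampling probabilities of the four age classes.
#' @param physiology_table generating concentration distributions
#'   (see \code{\link{default_physiology_table}}).
#' @param n_ref reference-range sample size attached to every generated
#'   published range.
#' @param seed integer seed; generation is fully reproducible.
#' @return list of class \code{bbci_synth_config}.
#' @export
synthetic_config <- function(n_animals = 434L,
                             species_table = default_species_table(),
                             resid_sd = 0.08,
                             sex_effect = 0,
                             age_effects = c(juvenile = 0, subadult = 0,
                                             old = 0),
                             season = c(day = 0, day2 = 0),
                             phys_slopes = setNames(
                               numeric(length(physiology_parameters())),
                               physiology_parameters()),
                             sigma_sp = 0,
                             cond_noise_sd = 1.8,
                             age_probs = c(adult = 256, juvenile = 97,
                                           subadult = 57, old = 24) / 434,
                             physiology_table = default_physiology_table(),
                             n_ref = 30L,
                             seed = 1L) {
  cfg <- structure(
    list(n_animals = as.integer(n_animals), species_table = species_table,
         resid_sd = resid_sd, sex_effect = sex_effect,
         age_effects = age_effects, season = season,
         phys_slopes = phys_slopes, sigma_sp = sigma_sp,
         cond_noise_sd = cond_noise_sd, age_probs = age_probs,
         physiology_table = physiology_table, n_ref = as.integer(n_ref),
         seed = as.integer(seed)),
    class = "bbci_synth_config")
  validate_synth_config(cfg)
}

#' @rdname synthetic_config
#' @param config a configuration to validate.
#' @export
validate_synth_config <- function(config) {
  st <- config$species_table
  if (any(st$b <= 0))
    stop("allometric exponents b must be positive", call. = FALSE)
  if (any(c(st$ln_length_sd, config$resid_sd, config$sigma_sp,
            config$cond_noise_sd) < 0))
    stop("all SDs must be >= 0", call. = FALSE)
  if (config$n_animals < nrow(st))
    stop("n_animals must be >= number of species", call. = FALSE)
  if (!setequal(names(config$age_effects), c("juvenile", "subadult", "old")))
    stop("age_effects must be named juvenile/subadult/old", call. = FALSE)
  if (abs(sum(config$age_probs) - 1) > 1e-8 ||
      abs(sum(st$prob) - 1) > 1e-8)
    stop("age_probs and species prob must each sum to 1", call. = FALSE)
  config
}

#' Null copy of a synthetic configuration
#'
#' Returns a copy with every sex, age, seasonal and physiology effect and
#' the species random-intercept SD set to zero (allometry and noise
#' retained) — the configuration used for type-I-error calibration suites.
#' Idempotent.
#'
#' @param base a \code{\link{synthetic_config}}.
#' @return the nulled configuration.
#' @export
make_null_config <- function(base) {
  base$sex_effect <- 0
  base$age_effects[] <- 0
  base$season[] <- 0
  base$phys_slopes[] <- 0
  base$sigma_sp <- 0
  validate_synth_config(base)
}

#' Generate a synthetic multi-species population with known truth
#'
#' Generation model, per animal of species s:
#' \enumerate{
#'   \item length: \eqn{\ln L \sim N(\ln(\mathrm{length\ mean}), sd)};
#'   \item latent condition on the logit-percentile scale:
#'     \eqn{\ell = \gamma_s + c_1 z(day) + c_2 z(day^2) +
#'     \sum_k s_k p_k + e}, where \eqn{p_k \sim U(0,1)} are the
#'     physiology percentiles, \eqn{\gamma_s \sim N(0, \sigma_{sp}^2)}
#'     and \eqn{e \sim N(0, \sigma_c^2)};
#'   \item mass: \eqn{\ln M = \ln a_s + b_s \ln L +
#'     \mathrm{sex/age\ effects} + \sigma_r \Phi^{-1}(\mathrm{logit}^{-1}(\ell))},
#'     so the condition signal enters mass as its residual from the
#'     allometric line;
#'   \item concentrations: \eqn{conc_k = F_k^{-1}(p_k)} through the
#'     species' generating lognormal, so physiology percentiles are
#'     uniform by construction;
#'   \item published reference ranges: generating mean and central 95\%
#'     interval, with sample size \code{n_ref}.
#' }
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with \code{records} (animal CSV schema, concentrations
#'   included), \code{ranges} (reference-range schema), \code{truth}
#'   (generating value of every model coefficient, with its scale), and
#'   \code{latent} (the generator's own condition logit, condition
#'   percentile and physiology percentiles — the ground truth the fitted
#'   model is compared against).
#' @export
generate_population <- function(config) {
  config <- validate_synth_config(config)
  set.seed(config$seed)
  n <- config$n_animals
  st <- config$species_table
  S <- nrow(st)

  si <- sample.int(S, n, replace = TRUE, prob = st$prob)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  age <- sample(names(config$age_probs), n, replace = TRUE,
                prob = config$age_probs)
  day <- sample.int(366L, n, replace = TRUE)

  lnL <- rnorm(n, log(st$length_mean_mm[si]), st$ln_length_sd[si])

  active <- names(config$phys_slopes)
  pcov <- matrix(runif(n * length(active)), n,
                 dimnames = list(NULL, active))

  gamma_s <- rnorm(S, 0, config$sigma_sp)
  ell <- gamma_s[si] +
    config$season[["day"]] * as.numeric(scale(day)) +
    config$season[["day2"]] * as.numeric(scale(day^2)) +
    drop(pcov %*% config$phys_slopes[active]) +
    rnorm(n, 0, config$cond_noise_sd)
  p_cond <- plogis(ell)

  class_eff <- config$sex_effect * (sex == "male") +
    ifelse(age == "adult", 0, config$age_effects[age])
  resid <- if (config$resid_sd > 0)
    config$resid_sd * qnorm(p_cond) else 0
  lnM <- st$ln_a[si] + st$b[si] * lnL + class_eff + resid

  records <- data.frame(
    animal_id = sprintf("syn%04d", seq_len(n)),
    species = st$species[si],
    sex = sex, age_class = age, day_of_year = day,
    body_mass = exp(lnM),
    total_length = exp(lnL),
    stringsAsFactors = FALSE
  )

  pt <- config$physiology_table
  pt <- pt[pt$parameter %in% active, , drop = FALSE]
  for (k in seq_len(nrow(pt)))
    records[[pt$parameter[k]]] <-
      qlnorm(pcov[, pt$parameter[k]], pt$meanlog[k], pt$sdlog[k])

  ranges <- do.call(rbind, lapply(seq_len(nrow(pt)), function(k)
    data.frame(parameter = pt$parameter[k], species = st$species,
               ref_mean = exp(pt$meanlog[k] + pt$sdlog[k]^2 / 2),
               ref_min = qlnorm(0.025, pt$meanlog[k], pt$sdlog[k]),
               ref_max = qlnorm(0.975, pt$meanlog[k], pt$sdlog[k]),
               n_ref = config$n_ref, stringsAsFactors = FALSE)))

  truth <- rbind(
    data.frame(parameter = "(Intercept)", value = 0, scale = "logit"),
    data.frame(parameter = c("age_juvenile", "age_subadult", "age_old"),
               value = unname(config$age_effects[c("juvenile", "subadult",
                                                   "old")]),
               scale = "ln_mass"),
    data.frame(parameter = "sex_male", value = config$sex_effect,
               scale = "ln_mass"),
    data.frame(parameter = c("day_z", "day2_z"),
               value = unname(config$season), scale = "logit"),
    data.frame(parameter = active, value = unname(config$phys_slopes[active]),
               scale = "logit"),
    data.frame(parameter = "sigma_sp", value = config$sigma_sp,
               scale = "logit")
  )

  latent <- data.frame(records[c("animal_id", "species")],
                       cond_logit = ell, cond_percentile = p_cond,
                       pcov, stringsAsFactors = FALSE)

  list(records = records, ranges = ranges, truth = truth, latent = latent)
}
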