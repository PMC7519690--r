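#' Screen covariates for rank collinearity
#'
#' Computes all pairwise Spearman correlations among candidate covariates;
#' for every pair with \eqn{|\rho| \ge} the threshold (processed in
#' descending \eqn{|\rho|}), the member with the weaker absolute Spearman
#' correlation against the response is dropped, iterating until no
#' offending pair remains.  Constant covariates are excluded up front with
#' a warning (their rank correlation is undefined).
#'
#' @param covariates data.frame of numeric covariate columns.
#' @param response numeric response vector (same rows).
#' @param rho_threshold collinearity threshold (default 0.7).
#' @return character vector of retained covariate names; attribute
#'   \code{"dropped"} lists removals with the pair that triggered each.
#' @export
screen_collinearity <- function(covariates, response, rho_threshold = 0.7) {
  stopifnot(is.data.frame(covariates), nrow(covariates) >= 2L)
  keep <- names(covariates)
  const <- vapply(covariates, function(v) sd(v, na.rm = TRUE) == 0 ||
                    all(is.na(v)), logical(1))
  if (any(const)) {
    warning("excluding constant covariate(s): ",
            paste(keep[const], collapse = ", "), call. = FALSE)
    keep <- keep[!const]
  }
  resp_rho <- vapply(keep, function(nm)
    abs(suppressWarnings(cor(covariates[[nm]], response, method = "spearman",
                             use = "pairwise.complete.obs"))), numeric(1))
  dropped <- character(0)
  repeat {
    if (length(keep) < 2L) break
    rho <- suppressWarnings(cor(covariates[keep], method = "spearman",
                                use = "pairwise.complete.obs"))
    diag(rho) <- 0
    if (max(abs(rho), na.rm = TRUE) < rho_threshold) break
    worst <- which(abs(rho) == max(abs(rho), na.rm = TRUE), arr.ind = TRUE)[1L, ]
    pair <- keep[worst]
    loser <- pair[which.min(resp_rho[pair])]
    dropped <- c(dropped,
                 sprintf("%s (|rho|=%.2f with %s)", loser,
                         abs(rho[worst[1L], worst[2L]]),
                         setdiff(pair, loser)))
    keep <- setdiff(keep, loser)
  }
  structure(keep, dropped = dropped)
}

#' Build the logit-scale design for the condition model
#'
#' Assembles the response and design matrix of the hierarchical model:
#' response \eqn{y = \mathrm{logit}(p)} of the condition-index percentile;
#' binary dummies for the non-reference classes (age: juvenile, subadult,
#' old — adult is the reference; sex: male — female is the reference);
#' z-scored day-of-year linear term and independently z-scored squared
#' day-of-year; and any physiology covariates, entered as percentiles in
#' (0, 1).
#'
#' @param response_percentile condition percentiles, strictly in (0, 1).
#' @param records animal records providing \code{species} and, when class
#'   or seasonal terms are requested, \code{sex}, \code{age_class},
#'   \code{day_of_year}.
#' @param covariates optional data.frame of additional covariate columns
#'   (physiology percentiles), same rows as \code{records}.
#' @param include_class_terms include the age/sex dummies (default TRUE).
#' @param include_season include the day-of-year linear + quadratic terms
#'   (default TRUE).
#' @return list with \code{y} (logit response), \code{X} (design matrix
#'   with intercept), \code{species} (factor), \code{keep} (logical rows
#'   retained: complete cases).
#' @export
build_design <- function(response_percentile, records, covariates = NULL,
                         include_class_terms = TRUE, include_season = TRUE) {
  p <- response_percentile
  if (any(is.finite(p) & (p <= 0 | p >= 1)))
    stop("response percentiles must lie strictly inside (0, 1); ",
         "a value on the boundary indicates a broken standardization step",
         call. = FALSE)
  X <- data.frame(`(Intercept)` = rep(1, nrow(records)), check.names = FALSE)
  if (include_class_terms) {
    X$age_juvenile <- as.numeric(records$age_class == "juvenile")
    X$age_subadult <- as.numeric(records$age_class == "subadult")
    X$age_old      <- as.numeric(records$age_class == "old")
    X$sex_male     <- as.numeric(records$sex == "male")
  }
  if (include_season) {
    d <- records$day_of_year
    X$day_z  <- as.numeric(scale(d))
    X$day2_z <- as.numeric(scale(d^2))  # quadratic z-scored independently
  }
  if (!is.null(covariates)) {
    bad <- vapply(covariates, function(v)
      any(is.finite(v) & (v <= 0 | v >= 1)), logical(1))
    if (any(bad))
      stop("covariate percentiles on the (0,1) boundary: ",
           paste(names(covariates)[bad], collapse = ", "), call. = FALSE)
    X <- cbind(X, covariates)
  }
  X <- as.matrix(X)
  keep <- is.finite(p) & rowSums(!is.finite(X)) == 0
  # drop all-zero dummy columns (class absent from the data)
  nonconst <- c(TRUE, apply(X[keep, -1, drop = FALSE], 2, sd) > 0)
  list(y = qlogis(p[keep]), X = X[keep, nonconst, drop = FALSE],
       species = factor(records$species[keep]), keep = keep)
}

# One univariate slice-sampling update (Neal 2003, stepping out + shrinkage).
.slice1 <- function(x0, logf, w = 1, max_steps = 50L) {
  f0 <- logf(x0)
  z <- f0 - stats::rexp(1)
  u <- runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(max_steps * runif(1)); k <- max_steps - 1 - j
  while (j > 0 && logf(L) > z) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > z) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) > z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

#' Fit the logit-scale Bayesian condition model
#'
#' Gaussian hierarchical linear model of the logit condition percentile:
#' \deqn{y_i = x_i' \beta + \varepsilon_{s(i)} + e_i, \quad
#'       e_i \sim N(0, \sigma^2), \quad
#'       \varepsilon_s \sim N(0, \sigma_{sp}^2),}
#' with near-flat \eqn{N(0, 1000^2)} priors on every coefficient and
#' half-normal(0, 10) priors on the two standard deviations.  The species
#' term \eqn{\varepsilon_s} absorbs inter-species variability; it is
#' dropped (with a warning) when fewer than two species are present.
#'
#' Sampling is Metropolis-within-Gibbs: conjugate multivariate-normal
#' updates for \eqn{\beta}, conjugate normal updates for each
#' \eqn{\varepsilon_s}, and univariate slice sampling for
#' \eqn{\log \sigma} and \eqn{\log \sigma_{sp}}.  The default schedule is
#' 3 chains of 30,000 kept-phase iterations after 10,000 burn-in, thinned
#' by 10 (3,000 retained draws per chain); chains are seeded
#' deterministically from \code{seed}.
#'
#' @param y numeric response (logit percentiles).
#' @param X design matrix including the intercept column
#'   (\code{\link{build_design}}).
#' @param species factor of species labels, one per row.
#' @param chains number of MCMC chains (default 3).
#' @param iter kept-phase iterations per chain (default 30,000).
#' @param burnin burn-in iterations per chain (default 10,000).
#' @param thin thinning interval (default 10).
#' @param seed integer seed; chain c uses \code{seed + c}.
#' @param prior_beta_sd coefficient prior SD (default 1000; near-flat on
#'   the logit scale).
#' @param prior_sigma_scale,prior_sigma_sp_scale half-normal scales of the
#'   observation and species SD priors (default 10).
#' @return object of class \code{bbci_fit}: list with \code{draws} (3-d
#'   array: retained iteration x parameter x chain), \code{parameters},
#'   \code{species_levels}, \code{rhat} (per parameter),
#'   \code{converged} (all R-hat < 1.1), and the call settings.
#' @export
fit_condition_model <- function(y, X, species,
                                chains = 3L, iter = 30000L, burnin = 10000L,
                                thin = 10L, seed = 1L,
                                prior_beta_sd = 1000,
                                prior_sigma_scale = 10,
                                prior_sigma_sp_scale = 10) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  n <- length(y); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p)
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):p]], collapse = ", "),
         call. = FALSE)
  species <- factor(species)
  S <- nlevels(species)
  use_species <- S >= 2L
  if (!use_species)
    warning("fewer than 2 species: dropping the inter-species error term",
            call. = FALSE)
  sp_i <- as.integer(species)
  XtX <- crossprod(X)
  Xt <- t(X)
  n_s <- tabulate(sp_i, nbins = S)

  kept <- iter %/% thin
  par_names <- c(colnames(X), "sigma", "sigma_sp",
                 if (use_species) paste0("eps[", levels(species), "]"))
  draws <- array(NA_real_,
                 dim = c(kept, length(par_names), chains),
                 dimnames = list(NULL, par_names, NULL))

  for (ch in seq_len(chains)) {
    set.seed((seed + ch) %% .Machine$integer.max)
    beta <- qr.coef(qrX, y)                      # start at the LS solution
    eps <- rep(0, S)
    sigma <- max(sd(y - X %*% beta), 0.1)
    sigma_sp <- 0.5
    total <- burnin + iter
    keep_row <- 0L
    for (it in seq_len(total)) {
      # beta | rest  (conjugate MVN)
      resid_y <- y - if (use_species) eps[sp_i] else 0
      A <- XtX / sigma^2 + diag(1 / prior_beta_sd^2, p)
      cA <- chol(A)
      m <- backsolve(cA, forwardsolve(t(cA), Xt %*% resid_y / sigma^2))
      beta <- m + backsolve(cA, rnorm(p))
      fitted <- drop(X %*% beta)
      # eps_s | rest (conjugate normal per species)
      if (use_species) {
        r_sum <- rowsum(y - fitted, sp_i)[, 1L]
        prec <- n_s / sigma^2 + 1 / sigma_sp^2
        eps <- rnorm(S, (r_sum / sigma^2) / prec, sqrt(1 / prec))
      }
      # sigma | rest (slice on log scale; half-normal(0, scale) prior)
      ss <- sum((y - fitted - if (use_species) eps[sp_i] else 0)^2)
      lt <- .slice1(log(sigma), function(t) {
        s <- exp(t)
        -n * t - ss / (2 * s^2) - s^2 / (2 * prior_sigma_scale^2) + t
      }, w = 0.5)
      sigma <- exp(lt)
      # sigma_sp | rest
      if (use_species) {
        se <- sum(eps^2)
        lt <- .slice1(log(sigma_sp), function(t) {
          s <- exp(t)
          -S * t - se / (2 * s^2) - s^2 / (2 * prior_sigma_sp_scale^2) + t
        }, w = 0.5)
        sigma_sp <- exp(lt)
      }
      if (it > burnin && (it - burnin) %% thin == 0L) {
        keep_row <- keep_row + 1L
        draws[keep_row, , ch] <- c(beta, sigma,
                                   if (use_species) sigma_sp else 0,
                                   if (use_species) eps)
      }
    }
  }

  rhat <- apply(draws, 2, function(m) gelman_rubin(m))
  # a dropped species term is stored as the constant 0: no R-hat defined
  rhat[apply(draws, 2, function(m) sd(m) == 0)] <- NA_real_
  fit <- structure(
    list(draws = draws, parameters = par_names,
         coef_names = colnames(X),
         species_levels = levels(species), use_species = use_species,
         rhat = rhat,
         converged = all(rhat[!is.na(rhat)] < 1.1),
         settings = list(chains = chains, iter = iter, burnin = burnin,
                         thin = thin, seed = seed)),
    class = "bbci_fit"
  )
  if (!fit$converged)
    warning("chains not converged (max R-hat = ",
            signif(max(fit$rhat, na.rm = TRUE), 4),
            "); summaries are still returned, flagged non-converged",
            call. = FALSE)
  fit
}

#' @export
print.bbci_fit <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "Logit-scale Bayesian condition model: %d chains x %d kept draws (burn-in %d, thin %d)\n",
    s$chains, dim(x$draws)[1], s$burnin, s$thin))
  cat(sprintf("  species term: %s | converged (all R-hat < 1.1): %s\n",
              if (x$use_species) paste0("random intercept over ",
                                        length(x$species_levels), " species")
              else "dropped (single species)",
              x$converged))
  print(summarize_posterior(x))
  invisible(x)
}

#' Pooled posterior draws of a fitted model
#'
#' @param fit a \code{bbci_fit}.
#' @param parameters subset of parameter names (default all).
#' @return matrix of pooled draws (all chains stacked) x parameters.
#' @export
posterior_draws <- function(fit, parameters = fit$parameters) {
  d <- fit$draws[, parameters, , drop = FALSE]
  matrix(aperm(d, c(1, 3, 2)),
         ncol = length(parameters),
         dimnames = list(NULL, parameters))
}

#' Split Gelman-Rubin statistic (potential scale reduction factor)
#'
#' Each chain is split in half; R-hat is computed over the resulting
#' 2 x chains half-chains from the between/within variance ratio.  Values
#' below 1.1 are conventionally read as convergence.
#'
#' @param chains matrix (iterations x chains, >= 2 columns) or list of
#'   equal-length numeric vectors.
#' @return the split-R-hat value.
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  stopifnot(is.matrix(chains))
  if (ncol(chains) < 2L)
    stop("gelman_rubin() needs >= 2 chains", call. = FALSE)
  n <- nrow(chains)
  if (n < 10L)
    stop("chains too short for a stable R-hat (need >= 10 draws)",
         call. = FALSE)
  half <- n %/% 2L
  split_mat <- cbind(chains[seq_len(half), , drop = FALSE],
                     chains[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split_mat); len <- nrow(split_mat)
  means <- colMeans(split_mat)
  vars <- apply(split_mat, 2, var)
  W <- mean(vars)
  B <- len * var(means)
  if (W == 0) return(1)
  sqrt(((len - 1) / len * W + B / len) / W)
}

#' Summarize a posterior into coefficient estimates and effect sizes
#'
#' Per parameter: posterior mean, SE (posterior SD), equal-tailed 95\%
#' credible interval, precision-weighted effect size
#' \eqn{ES = \hat\beta / SE}, the informativeness flag (CI excludes zero)
#' and split-R-hat.
#'
#' @param fit a \code{bbci_fit}, or a matrix of pooled draws (columns =
#'   parameters).
#' @param parameters parameters to summarize; for a \code{bbci_fit} the
#'   default is the fixed coefficients plus the two SDs.
#' @return data.frame with columns \code{parameter}, \code{mean},
#'   \code{se}, \code{ci_lower}, \code{ci_upper}, \code{es},
#'   \code{informative}, \code{rhat}.
#' @export
summarize_posterior <- function(fit, parameters = NULL) {
  if (inherits(fit, "bbci_fit")) {
    if (is.null(parameters))
      parameters <- c(fit$coef_names, "sigma",
                      if (fit$use_species) "sigma_sp")
    draws <- posterior_draws(fit, parameters)
    rhat <- fit$rhat[parameters]
  } else {
    draws <- as.matrix(fit)
    if (is.null(parameters))
      parameters <- colnames(draws) %||% paste0("par", seq_len(ncol(draws)))
    rhat <- rep(NA_real_, length(parameters))
  }
  if (nrow(draws) < 100L)
    stop("need >= 100 pooled draws per parameter to summarize",
         call. = FALSE)
  mu <- colMeans(draws)
  se <- apply(draws, 2, sd)
  if (any(se == 0))
    stop("zero-variance posterior draws: effect size undefined for ",
         paste(parameters[se == 0], collapse = ", "), call. = FALSE)
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(
    parameter = parameters,
    mean = unname(mu),
    se = unname(se),
    ci_lower = qs[1L, ],
    ci_upper = qs[2L, ],
    es = unname(mu / se),
    informative = qs[1L, ] > 0 | qs[2L, ] < 0,
    rhat = unname(rhat),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Precision-weighted effect size
#'
#' \eqn{ES = \hat\beta / SE}: the posterior mean weighted by its precision.
#' Reported to 2 decimals in the report layer.
#'
#' @param mean posterior mean(s).
#' @param se posterior SD(s) (> 0).
#' @return effect size(s).
#' @export
effect_size <- function(mean, se) {
  if (any(se <= 0)) stop("se must be > 0", call. = FALSE)
  mean / se
}

#' Posterior response curve over a covariate grid
#'
#' For each grid point evaluates the inverse-logit of the linear predictor
#' for every retained posterior draw (species term at zero), and returns
#' the posterior mean curve with central credible bands at the 75, 80, 85,
#' 90 and 95 per cent levels.
#'
#' @param fit a \code{bbci_fit}.
#' @param newX matrix of grid rows in the model's design-column order
#'   (including the intercept).
#' @param levels credible-band levels (default
#'   \code{c(.75, .80, .85, .90, .95)}).
#' @param warn_range optional 2-column matrix of observed covariate ranges;
#'   grid values outside produce a warning (never an error).
#' @return data.frame: one row per grid point with \code{mean} and
#'   \code{lo_}/\code{hi_} columns per band level, on the percentile
#'   (probability) scale.
#' @export
predict_curve <- function(fit, newX, levels = c(0.75, 0.80, 0.85, 0.90, 0.95),
                          warn_range = NULL) {
  stopifnot(inherits(fit, "bbci_fit"), is.matrix(newX))
  if (!is.null(warn_range)) {
    out_of <- any(newX < matrix(warn_range[, 1], nrow(newX), ncol(newX),
                                byrow = TRUE) |
                    newX > matrix(warn_range[, 2], nrow(newX), ncol(newX),
                                  byrow = TRUE))
    if (out_of)
      warning("prediction grid extends outside the observed covariate range",
              call. = FALSE)
  }
  beta <- posterior_draws(fit, fit$coef_names)
  lin <- newX %*% t(beta)                 # grid x draws
  prob <- plogis(lin)
  out <- data.frame(mean = rowMeans(prob))
  for (lv in levels) {
    a <- (1 - lv) / 2
    q <- apply(prob, 1, quantile, probs = c(a, 1 - a), names = FALSE)
    out[[sprintf("lo_%02d", round(lv * 100))]] <- q[1L, ]
    out[[sprintf("hi_%02d", round(lv * 100))]] <- q[2L, ]
  }
  out
}
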