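# Shared fixtures, all generated in code.

# Minimal single-species record table on an exact power law ln M = a + b ln L,
# optionally with lognormal noise.
power_law_records <- function(n = 6, a = 2, b = 3, noise_sd = 0,
                              lengths = seq(800, 1300, length.out = n),
                              species = "fox", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lnM <- a + b * log(lengths) + rnorm(n, 0, noise_sd)
  data.frame(
    animal_id = paste0(species, seq_len(n)),
    species = species,
    sex = rep(c("female", "male"), length.out = n),
    age_class = "adult",
    day_of_year = round(seq(10, 350, length.out = n)),
    body_mass = exp(lnM),
    total_length = lengths,
    stringsAsFactors = FALSE
  )
}

# Independent numerical oracle for the major-axis slope: minimize the summed
# squared perpendicular distances of (x, y) points to a line through the
# centroid, by dense optimization over the slope.
ma_slope_oracle <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  perp_ss <- function(b) sum((y - (yb - b * xb) - b * x)^2) / (1 + b^2)
  best <- optimize(perp_ss, c(-50, 50), tol = 1e-12)
  # refine around the optimum to be safe near the interval edges
  stats::optimize(perp_ss, best$minimum + c(-1, 1), tol = 1e-12)$minimum
}

# Independently coded RMA slope (ratio of SDs, sign of the correlation).
rma_slope_oracle <- function(x, y) {
  s <- sign(cor(x, y))
  if (s == 0) s <- 1
  s * sd(y) / sd(x)
}

# Draws from the model y = X beta + eps_species + noise on the logit scale.
simulate_model_data <- function(n = 300, n_species = 4, beta = c(0, 1.5),
                                sigma = 1, sigma_sp = 0, seed = 1) {
  set.seed(seed)
  p <- length(beta) - 1
  X <- cbind(1, matrix(runif(n * p), n))
  colnames(X) <- c("(Intercept)", if (p > 0) paste0("cov", seq_len(p)))
  species <- factor(sample(paste0("sp", seq_len(n_species)), n, replace = TRUE))
  eps <- rnorm(n_species, 0, sigma_sp)
  y <- drop(X %*% beta) + eps[as.integer(species)] + rnorm(n, 0, sigma)
  list(y = y, X = X, species = species, beta = beta, sigma = sigma,
       sigma_sp = sigma_sp)
}

# Short MCMC schedule for tests.
fast_mcmc <- list(chains = 3L, iter = 1500L, burnin = 500L, thin = 3L)

fit_fast <- function(dat, seed = 1, ...) {
  fit_condition_model(dat$y, dat$X, dat$species,
                      chains = fast_mcmc$chains, iter = fast_mcmc$iter,
                      burnin = fast_mcmc$burnin, thin = fast_mcmc$thin,
                      seed = seed, ...)
}
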