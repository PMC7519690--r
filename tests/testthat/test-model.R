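test_that("collinearity screen drops duplicates and follows the rule by hand", {
  set.seed(401)
  n <- 60
  a <- runif(n)
  resp <- a + rnorm(n, 0, 0.3)
  covs <- data.frame(a = a, a_copy = a, b = runif(n))
  kept <- suppressWarnings(screen_collinearity(covs, resp))
  expect_length(intersect(c("a", "a_copy"), kept), 1)
  expect_true("b" %in% kept)

  # all pairwise |rho| below threshold: no-op
  covs2 <- data.frame(x = rnorm(n), y = rnorm(n), z = rnorm(n))
  expect_equal(as.character(screen_collinearity(covs2, resp)),
               names(covs2))

  # three-covariate case checked against exhaustive application of the rule:
  # u and v strongly rank-correlated; v is closer to the response, u drops.
  u <- sort(runif(n))
  v <- u + runif(n, 0, 0.05)
  w <- rnorm(n)
  resp3 <- v + rnorm(n, 0, 0.1)
  rho_uv <- cor(u, v, method = "spearman")
  stopifnot(rho_uv >= 0.7)
  loser <- if (abs(cor(u, resp3, method = "spearman")) <
               abs(cor(v, resp3, method = "spearman"))) "u" else "v"
  kept3 <- screen_collinearity(data.frame(u = u, v = v, w = w), resp3)
  expect_equal(sort(as.character(kept3)), sort(setdiff(c("u", "v", "w"), loser)))

  # constant covariates are excluded with a warning
  expect_warning(k <- screen_collinearity(data.frame(c = rep(1, n), d = resp),
                                          resp), "constant")
  expect_equal(as.character(k), "d")
})

test_that("the design matrix uses reference-class dummies and z-scored day terms", {
  rec <- data.frame(
    animal_id = paste0("a", 1:8), species = rep(c("s1", "s2"), 4),
    sex = c("female", "male", "female", "male", "female", "male", "female",
            "male"),
    age_class = c("adult", "juvenile", "subadult", "old", "adult", "adult",
                  "juvenile", "old"),
    day_of_year = c(10, 60, 120, 160, 200, 250, 300, 360),
    body_mass = rep(1000, 8), total_length = rep(500, 8),
    stringsAsFactors = FALSE)
  p <- c(0.5, 0.2, 0.9, 0.4, 0.6, 0.3, 0.7, 0.55)
  des <- build_design(p, rec)
  expect_equal(des$y[1], 0)                       # logit(0.5) = 0
  adult_female <- des$X[1, c("age_juvenile", "age_subadult", "age_old",
                             "sex_male")]
  expect_equal(unname(adult_female), rep(0, 4))   # reference classes
  expect_equal(mean(des$X[, "day_z"]), 0, tolerance = 1e-10)
  expect_equal(sd(des$X[, "day_z"]), 1, tolerance = 1e-10)
  expect_equal(sd(des$X[, "day2_z"]), 1, tolerance = 1e-10)
  # the quadratic is the z-score of the squared raw day, not the squared z
  expect_equal(des$X[, "day2_z"],
               as.numeric(scale(rec$day_of_year^2)), ignore_attr = TRUE)
  # boundary percentile is a hard error naming the standardization contract
  expect_error(build_design(c(p[-1], 1), rec), "standardization")
})

test_that("split R-hat is near 1 for well-mixed chains and large for separated chains", {
  set.seed(402)
  base <- rnorm(4000)
  chains <- cbind(base[1:2000], base[2001:4000])
  r <- gelman_rubin(chains)
  expect_gte(r, 0.999)
  expect_lt(r, 1.01)
  bad <- cbind(rnorm(500, 0), rnorm(500, 10))
  expect_gt(gelman_rubin(bad), 1.5)
  # affine invariance
  expect_equal(gelman_rubin(bad), gelman_rubin(3 * bad - 7), tolerance = 1e-12)
  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), ">= 2 chains")
})

test_that("split R-hat agrees with the coda implementation on split chains", {
  skip_if_not_installed("coda")
  set.seed(403)
  ch <- cbind(cumsum(rnorm(1000)) * 0.02 + rnorm(1000),
              cumsum(rnorm(1000)) * 0.02 + rnorm(1000))
  half <- 500
  split4 <- cbind(ch[1:half, ], ch[(half + 1):1000, ])
  ml <- coda::mcmc.list(lapply(seq_len(4), function(j) coda::mcmc(split4[, j])))
  ref <- unname(coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1, 1])
  expect_equal(gelman_rubin(ch), ref, tolerance = 0.02)
})

test_that("null simulations keep slope credible intervals on zero most of the time", {
  covers <- replicate(20, {
    dat <- simulate_model_data(n = 150, n_species = 4,
                               beta = c(0.5, 0, 0), sigma = 1,
                               seed = sample.int(1e6, 1))
    fit <- suppressWarnings(fit_fast(dat, seed = sample.int(1e6, 1)))
    s <- summarize_posterior(fit)
    slopes <- s[s$parameter %in% c("cov1", "cov2"), ]
    !any(slopes$informative)
  })
  expect_gte(mean(covers), 0.9)
})

test_that("a known slope on the logit scale is recovered within posterior uncertainty", {
  dat <- simulate_model_data(n = 300, n_species = 4, beta = c(0, 1.5),
                             sigma = 1, sigma_sp = 0.3, seed = 404)
  fit <- fit_fast(dat, seed = 2)
  s <- summarize_posterior(fit)
  b <- s[s$parameter == "cov1", ]
  expect_lt(abs(b$mean - 1.5), 3 * b$se)
  expect_true(all(s$rhat[!is.na(s$rhat)] < 1.1))
})

test_that("the species variance component is recoverable", {
  hits <- replicate(20, {
    dat <- simulate_model_data(n = 400, n_species = 8, beta = c(0, 1),
                               sigma = 0.5, sigma_sp = 0.5,
                               seed = sample.int(1e6, 1))
    fit <- suppressWarnings(fit_fast(dat, seed = sample.int(1e6, 1)))
    s <- summarize_posterior(fit, "sigma_sp")
    s$ci_lower <= 0.5 && 0.5 <= s$ci_upper
  })
  expect_gte(mean(hits), 0.8)
})

test_that("posterior means are invariant to species relabeling", {
  dat <- simulate_model_data(n = 200, n_species = 4, beta = c(0.3, 1),
                             sigma = 1, sigma_sp = 0.4, seed = 405)
  fit1 <- fit_fast(dat, seed = 3)
  relab <- factor(paste0("z", as.integer(dat$species)))
  fit2 <- fit_condition_model(dat$y, dat$X, relab,
                              chains = 3, iter = 1500, burnin = 500,
                              thin = 3, seed = 3)
  s1 <- summarize_posterior(fit1)
  s2 <- summarize_posterior(fit2)
  expect_equal(s1$mean, s2$mean, tolerance = 1e-10)  # same seed, same draws
})

test_that("degenerate designs and single species are handled explicitly", {
  dat <- simulate_model_data(n = 60, beta = c(0, 1), seed = 406)
  X_bad <- cbind(dat$X, dup = dat$X[, 2])
  expect_error(fit_condition_model(dat$y, X_bad, dat$species,
                                   iter = 100, burnin = 50, thin = 1),
               "rank deficient")
  one_sp <- factor(rep("only", length(dat$y)))
  expect_warning(
    fit <- fit_condition_model(dat$y, dat$X, one_sp, chains = 2,
                               iter = 400, burnin = 200, thin = 2, seed = 1),
    "fewer than 2 species")
  expect_false(fit$use_species)
})

test_that("the sampler agrees with an independent JAGS fit of the same model", {
  skip_if_not_installed("rjags")
  dat <- simulate_model_data(n = 200, n_species = 4, beta = c(0.3, 1.2),
                             sigma = 0.8, sigma_sp = 0.4, seed = 407)
  fit <- fit_condition_model(dat$y, dat$X, dat$species,
                             chains = 3, iter = 4000, burnin = 1000,
                             thin = 2, seed = 11)
  s <- summarize_posterior(fit)

  model_str <- "
  model {
    for (i in 1:n) {
      y[i] ~ dnorm(inprod(X[i,], beta) + eps[sp[i]], tau)
    }
    for (j in 1:p) { beta[j] ~ dnorm(0, 1.0E-6) }
    for (s in 1:S) { eps[s] ~ dnorm(0, tau_sp) }
    sigma ~ dnorm(0, 0.01) T(0,)
    sigma_sp ~ dnorm(0, 0.01) T(0,)
    tau <- pow(sigma, -2)
    tau_sp <- pow(sigma_sp, -2)
  }"
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = dat$y, X = dat$X, sp = as.integer(dat$species),
                n = length(dat$y), p = ncol(dat$X),
                S = nlevels(dat$species)),
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 5),
    n.chains = 2, quiet = TRUE)
  update(jm, 2000, progress.bar = "none")
  post <- rjags::coda.samples(jm, c("beta", "sigma", "sigma_sp"), 8000,
                              progress.bar = "none")
  pj <- as.matrix(post)

  for (k in seq_len(ncol(dat$X))) {
    mine <- s[s$parameter == colnames(dat$X)[k], ]
    ref_mean <- mean(pj[, paste0("beta[", k, "]")])
    ref_sd <- sd(pj[, paste0("beta[", k, "]")])
    # both sides are Monte-Carlo estimates with autocorrelated draws;
    # agreement is asserted to a quarter of the posterior SD
    expect_lt(abs(mine$mean - ref_mean), 0.25 * ref_sd + 0.01)
    expect_equal(mine$se, ref_sd, tolerance = 0.2)
  }
  expect_equal(s$mean[s$parameter == "sigma"], mean(pj[, "sigma"]),
               tolerance = 0.05)
})

test_that("posterior summaries reproduce the reported effect-size arithmetic", {
  # ES = mean/SD on sign-definite draws
  set.seed(408)
  d <- matrix(1 + rnorm(2000, 0, 1e-3), ncol = 1,
              dimnames = list(NULL, "coef"))
  s <- summarize_posterior(d)
  expect_true(s$informative)
  expect_equal(s$es, s$mean / s$se)
  expect_error(summarize_posterior(matrix(rep(2, 500), ncol = 1)),
               "zero-variance")
  expect_error(summarize_posterior(matrix(rnorm(50), ncol = 1)), ">= 100")
  expect_equal(effect_size(-1.94, 1.17), -1.94 / 1.17)
})

test_that("posterior curves are flat for intercept-only models and have nested bands", {
  dat <- simulate_model_data(n = 150, n_species = 3, beta = 0.8,
                             sigma = 0.6, seed = 409)
  fit <- fit_condition_model(dat$y, dat$X[, 1, drop = FALSE], dat$species,
                             chains = 2, iter = 2000, burnin = 500,
                             thin = 2, seed = 4)
  grid <- matrix(1, nrow = 5, ncol = 1)
  cv <- predict_curve(fit, grid)
  expect_equal(diff(range(cv$mean)), 0)
  b0 <- posterior_draws(fit, "(Intercept)")
  expect_equal(cv$mean[1], mean(plogis(b0)), tolerance = 1e-12)

  # nested bands and brute-force recomputation on a sloped model
  dat2 <- simulate_model_data(n = 150, n_species = 3, beta = c(0, 1.5),
                              sigma = 0.6, seed = 410)
  fit2 <- fit_condition_model(dat2$y, dat2$X, dat2$species,
                              chains = 2, iter = 2000, burnin = 500,
                              thin = 2, seed = 5)
  grid2 <- cbind(1, seq(0, 1, length.out = 7))
  cv2 <- predict_curve(fit2, grid2)
  expect_true(all(cv2$lo_95 <= cv2$lo_75 & cv2$hi_75 <= cv2$hi_95))
  beta_draws <- posterior_draws(fit2, fit2$coef_names)
  brute <- rowMeans(plogis(grid2 %*% t(beta_draws)))
  expect_equal(cv2$mean, brute, tolerance = 1e-12)
  expect_warning(predict_curve(fit2, cbind(1, 5),
                               warn_range = cbind(c(1, 0), c(1, 1))),
                 "outside")
})
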