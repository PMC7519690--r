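test_that("ratio indices follow the mass-length formulas and their homogeneity", {
  rec <- power_law_records(2)
  rec$body_mass <- c(3000, 1000)
  rec$total_length <- c(1000, 500)
  r <- compute_ratio_indices(rec)
  expect_equal(r$MLR, c(3, 2))
  expect_equal(r$BMI, c(3, 4))
  expect_equal(r$FKI, c(3, 8))
  # doubling L at fixed M: MLR halves, BMI quarters, FKI divides by 8
  rec2 <- rec; rec2$total_length <- 2 * rec$total_length
  r2 <- compute_ratio_indices(rec2)
  expect_equal(r2$MLR, r$MLR / 2)
  expect_equal(r2$BMI, r$BMI / 4)
  expect_equal(r2$FKI, r$FKI / 8)
  expect_error(compute_ratio_indices(rec, "tarsus_length"), "missing length")
})

test_that("regression indices vanish on collinear data and SMI equals mass at L0", {
  rec <- power_law_records(6)
  out <- compute_regression_indices(rec)
  expect_equal(out$indices$OLSR, rep(0, 6), tolerance = 1e-10)
  expect_equal(out$indices$MAR, rep(0, 6), tolerance = 1e-10)
  expect_equal(out$indices$RMAR, rep(0, 6), tolerance = 1e-10)
  expect_equal(out$indices$RC, rep(1, 6), tolerance = 1e-10)

  # an animal measured exactly at the mean length L0 keeps its mass as SMI
  rec2 <- power_law_records(7, noise_sd = 0.1, seed = 21)
  rec2$total_length[3] <- mean(rec2$total_length[-3])   # makes L3 = mean(L)
  out2 <- compute_regression_indices(rec2)
  L0 <- out2$fits$RMA$L0
  expect_equal(rec2$total_length[3], L0)
  expect_equal(out2$indices$SMI[3], rec2$body_mass[3])
  # and in general SMI_i = M_i (L0/L_i)^b with the reported fit
  b <- out2$fits$RMA$slope_b
  expect_equal(rec2$body_mass * (L0 / rec2$total_length)^b, out2$indices$SMI)
})

test_that("SMI matches brute force with an independently coded RMA slope", {
  rec <- power_law_records(6, noise_sd = 0.15, seed = 5)
  out <- compute_regression_indices(rec)
  lnL <- log(rec$total_length); lnM <- log(rec$body_mass)
  b_oracle <- rma_slope_oracle(lnL, lnM)
  smi_oracle <- rec$body_mass * (mean(rec$total_length) / rec$total_length)^b_oracle
  expect_equal(out$indices$SMI, smi_oracle, tolerance = 1e-12)
})

test_that("residual indices sum to zero over the species fitting set", {
  set.seed(31)
  rec <- rbind(power_law_records(20, noise_sd = 0.1, species = "fox", seed = 1),
               power_law_records(15, a = 1, b = 2.8, noise_sd = 0.1,
                                 species = "genet", seed = 2))
  idx <- compute_indices(rec)
  for (sp in c("fox", "genet")) {
    sel <- idx$species == sp
    expect_equal(sum(idx$OLSR[sel]), 0, tolerance = 1e-9)
    expect_equal(sum(idx$MAR[sel]), 0, tolerance = 1e-9)
    expect_equal(sum(idx$RMAR[sel]), 0, tolerance = 1e-9)
  }
})

test_that("residual indices are shift-invariant and SMI scales with mass", {
  rec <- power_law_records(12, noise_sd = 0.1, seed = 7)
  base <- compute_regression_indices(rec)
  rec_shift <- rec; rec_shift$body_mass <- rec$body_mass * exp(0.3)
  shifted <- compute_regression_indices(rec_shift)
  # adding a constant to all ln-masses leaves residuals unchanged after refit
  for (col in c("OLSR", "MAR", "RMAR"))
    expect_equal(shifted$indices[[col]], base$indices[[col]],
                 tolerance = 1e-9)
  rec_scaled <- rec; rec_scaled$body_mass <- 2 * rec$body_mass
  scaled <- compute_regression_indices(rec_scaled)
  expect_equal(scaled$indices$SMI, 2 * base$indices$SMI, tolerance = 1e-9)
})

test_that("for collinear data every index is monotone in mass at fixed length", {
  rec <- power_law_records(5)
  masses <- seq(2000, 4000, length.out = 5)
  vals <- sapply(masses, function(m) {
    r <- rec; r$body_mass[3] <- m
    i <- compute_indices(r)
    unlist(i[3, c("MLR", "BMI", "FKI", "RC", "OLSR", "MAR", "RMAR", "SMI")])
  })
  for (k in seq_len(nrow(vals)))
    expect_true(all(diff(vals[k, ]) > 0),
                info = rownames(vals)[k])
})

test_that("SMI is uncorrelated with length under perfect noisy allometry", {
  # The RMA slope exceeds the OLS slope by 1/r, which induces an intrinsic
  # ln-scale correlation of -sqrt((1 - r)/2) between SMI and length; the
  # near-zero property therefore holds for tight allometries (r ~ 0.99+),
  # which this fixture provides.
  rec <- power_law_records(500, noise_sd = 0.04, seed = 99)
  out <- compute_regression_indices(rec)
  rho <- cor(out$indices$SMI, rec$total_length, method = "spearman")
  expect_lt(abs(rho), 0.1)
})

test_that("size-measure selection picks the stronger log-log mass correlate", {
  set.seed(41)
  rec <- power_law_records(10, noise_sd = 0.05)
  rec$tarsus_length <- exp(rnorm(10, 5, 0.2))    # pure noise
  sel <- select_size_measure(rec, c("total_length", "tarsus_length"))
  expect_equal(as.character(sel), "total_length")
  cors <- attr(sel, "correlations")
  # matches an independent correlation computation
  expect_equal(unname(cors["tarsus_length"]),
               cor(log(rec$tarsus_length), log(rec$body_mass)))
  # identical candidates tie: first in order wins, with a warning
  rec$body_length <- rec$total_length
  expect_warning(
    sel2 <- select_size_measure(rec, c("body_length", "total_length")),
    "tie")
  expect_equal(as.character(sel2), "body_length")
  # argmax oracle on a fresh synthetic set
  rec2 <- power_law_records(10, noise_sd = 0.3, seed = 10)
  rec2$body_length <- rec2$total_length * exp(rnorm(10, 0, 0.3))
  sel3 <- select_size_measure(rec2, c("total_length", "body_length"))
  ora <- c(total_length = abs(cor(log(rec2$total_length), log(rec2$body_mass))),
           body_length = abs(cor(log(rec2$body_length), log(rec2$body_mass))))
  expect_equal(as.character(sel3), names(which.max(ora)))
})

test_that("multi-species tables are fitted per species and flag missing lengths", {
  rec <- rbind(power_law_records(8, noise_sd = 0.05, species = "fox", seed = 1),
               power_law_records(8, a = 0.5, b = 2.7, noise_sd = 0.05,
                                 species = "genet", seed = 2))
  rec$total_length[3] <- NA
  idx <- compute_indices(rec)
  expect_true(all(is.na(unlist(idx[3, c("MLR", "SMI")]))))
  expect_equal(attr(idx, "excluded"), rec$animal_id[3])
  rep_fit <- allometry_report(idx)
  expect_equal(nrow(rep_fit), 6)        # 2 species x 3 methods
  expect_true(all(rep_fit$n[rep_fit$species == "fox"] == 7))
  # mixed species rejected at the single-species entry point
  expect_error(compute_regression_indices(rec), "single species")
})
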