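# bbci — biometric body condition indices and their physiological correlates

`bbci` is an R package for wildlife ecophysiologists who work with
mass–length body condition indices (bBCI) in multi-species carnivore
datasets and want to know (a) which indices actually control for sex and
age, and (b) what blood physiology those indices reflect. It implements,
as a tested and reusable pipeline, the full analysis chain from raw
capture records to posterior effect sizes, plus a synthetic-data generator
with known ground truth so every stage can be exercised and calibrated
without field data.

## What it computes

**Eight condition indices.** From body mass *M* (g) and a structural
length *L* (mm):

| Index | Formula |
|---|---|
| Mass/length ratio (MLR) | *M/L* |
| Body mass index (BMI) | *M/L²·10³* |
| Fulton's K index (FKI) | *M/L³·10⁶* |
| Relative condition (RC) | *M/(aL^b)*, *a, b* from OLS of ln *M* on ln *L* |
| OLS / major-axis / reduced-major-axis residuals (OLSR, MAR, RMAR) | ln *M* − (ln *a* + *b* ln *L*) under the respective estimator |
| Scaled mass index (SMI) | *Mᵢ (L₀/Lᵢ)^b*, *b* from the standardized (reduced) major axis, *L₀* = mean length |

The three line estimators are implemented from their closed forms (OLS:
*Sxy/Sxx*; MA: perpendicular-distance minimizer; RMA: *sd(y)/sd(x)*
signed by the correlation) and are tested against numerical oracles.
The structural measure is chosen per dataset as the length with the
strongest log–log correlation with mass.

**Species-specific percentile standardization.** Index values are mapped
to percentiles of a species-specific distribution selected by minimum
Anderson–Darling statistic over a configurable candidate set
(normal, lognormal, gamma, Weibull, logistic; via `fitdistrplus`),
simulated at 10,000 draws. Physiology parameters (albumin, urea,
creatinine, cholesterol, triglycerides, globulins, total bilirubin,
hemoglobin) are standardized through a posterior that fuses published
reference ranges — encoded as beta-PERT "expert opinion" from their
mean/min/max — with the study observations, weighted by the two sample
sizes. Hemoglobin can be recovered from 580 nm absorbance through a
log–log OLS calibration.

**The condition model.** Percentiles are pooled across species on the
logit scale and modeled hierarchically:

    logit(pBCI_i) = β₀ + β₁·pCov1_i + β₂·pCov2_i + … + ε_species(i) + e_i,
    ε_s ~ N(0, σ_sp²),  e_i ~ N(0, σ²)

with near-flat N(0, 1000²) coefficient priors and half-normal(0, 10)
priors on both SDs. Covariates are reference-class dummies (adult,
female), z-scored day-of-year linear and quadratic terms, and/or
physiology percentiles, screened beforehand for rank collinearity
(|Spearman ρ| ≥ 0.7). Sampling is a Metropolis-within-Gibbs sampler
written in the package (conjugate updates for coefficients and species
intercepts, slice sampling for the SDs), run as 3 chains × 30,000
kept-phase iterations after 10,000 burn-in, thinned by 10; convergence is
judged by split-R-hat < 1.1. Each coefficient is summarized by its
posterior mean, SE (posterior SD), equal-tailed 95% credible interval,
the precision-weighted effect size **ES = β̂/SE**, and an *informative*
flag (CI excludes zero). The test suite cross-checks the sampler against
an independent JAGS fit of the same model.

## Worked example

Simulate a 250-animal, six-species population in which the condition
percentile is coupled to albumin (slope −1.5 on the logit scale) and urea
(+1.5), then recover those couplings through the full pipeline —
reference-range fusion, percentile standardization, collinearity screen
and hierarchical model:

```r
library(bbci)
cfg <- synthetic_config(n_animals = 250, seed = 42,
                        phys_slopes = c(albumin = -1.5, urea = 1.5,
                                        creatinine = 0, total_bilirubin = 0),
                        sigma_sp = 0.3, cond_noise_sd = 1.2)
pop <- generate_population(cfg)
res <- run_physiology_model(pop$records, pop$ranges,
  run_config(retained_indices = "SMI", index_draws = 5000,
             physiology_draws = 1000, chains = 3, iter = 6000,
             burnin = 2000, thin = 3, seed = 1))
print(res)
#> Physiology model on 250 complete panels
#>
#> -- SMI --
#>        parameter   mean     se    es informative rhat
#>      (Intercept) -0.277 0.3352 -0.83       FALSE    1
#>          albumin -1.206 0.3156 -3.82        TRUE    1
#>             urea  1.622 0.3105  5.22        TRUE    1
#>       creatinine  0.469 0.3177  1.48       FALSE    1
#>  total_bilirubin -0.333 0.3182 -1.05       FALSE    1
#>            sigma  1.533 0.0684 22.40        TRUE    1
#>         sigma_sp  0.137 0.1366  1.00        TRUE    1
```

The two coupled parameters come out informative with the configured
signs; the two null parameters do not. `run_index_comparison()` is the
companion driver for the first analysis stage (which of the eight indices
are independent of sex and age); `predict_curve()` draws posterior
response curves with nested 75–95% credible bands.

A thin command-line front end with subcommands `simulate`, `indices`,
`standardize`, `compare-indices` and `physiology-model` is installed at
`inst/cli/bbci.R`.

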