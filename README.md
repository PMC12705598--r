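# fernfusion

Integrated spatiotemporal distribution models (ISDMs) for small networks of
intensively monitored plant populations, built for the data situation of
relict fern conservation in Mediterranean ravine microhabitats: a decade of
structured abundance censuses over ~50 population polygons with many
unsurveyed years, a few dozen road-biased opportunistic presence records,
and environmental covariates on a 100 m analysis grid. The monitoring data
themselves are restricted-access, so the package ships a synthetic-data
generator with the same statistical shape, making every stage reproducible
and testable offline.

## The model

For species *j* the latent state is a log-Gaussian Cox process,
λ_j(s,t) = exp(η_j(s,t)), with

    η_j(s,t) = Σ_i β_i X_i(s,t) + u(s,t) + δ_j(s,t) + ω_j(s)·T(s,t)

- β: covariate fixed effects (shared across species or species-specific);
- u(s,t): spatio-temporal Gaussian Markov random field shared by all
  species — Matérn (ν = 1) via the SPDE finite-element approximation on a
  triangulation mesh, Kronecker-combined with a unit-variance AR(1) over
  years;
- δ_j(s,t): species-specific fields of the same form;
- ω_j(s): a spatially varying coefficient on the (centered) year covariate,
  with species 2 and 3 exact linear scalings b_j·ω(s) of species 1's field.

Observation models: census counts are Poisson (species 1, 3) or negative
binomial (species 2; variance μ + μ²/ψ) with mean |a_s|·λ_j(s,t), where
|a_s| is the population-polygon/cell intersection area (log offset);
population totals are spread over cells proportionally to intersection area
with sum-preserving largest-remainder rounding. Presences are Bernoulli with
a complementary log-log link, p = 1 − exp(−λ), species intercepts, and a
log-road-distance bias covariate; records are replicated as timeless annual
observations. Penalized-complexity priors calibrate the fields
(P(range < 5000 m) = 0.1, P(sd > 2) = 0.5, P(ρ > 0) = 0.9), and 22
model configurations (`make_configs()`) switch fusion, fixed-effect sharing,
and the random-effect structure.

Inference is a Laplace approximation: sparse-Cholesky Newton for the latent
field nested inside Nelder–Mead optimization of the approximate log marginal
posterior of the hyperparameters, with a finite-difference Hessian providing
hyperparameter uncertainty for posterior sampling. Model comparison uses
leave-population-out cross-validation (explicit refits) with the
log-score, plus WAIC and interval-coverage/MAE reports.

## Worked example

```r
library(fernfusion)

# a desk-scale synthetic study: 10x10 grid of 150 m cells, 8 years,
# 18 populations across 3 species, road-biased presences
sim <- fern_simulate(seed = 11, extent_m = 1500, cell_size_m = 150,
                     n_years = 8, mesh_edge = 500,
                     populations_spec = list(n_pops = c(8L, 6L, 4L),
                                             area_range_ha = c(0.11, 3.81),
                                             area_median_ha = 0.68))

data <- list(domain = sim$domain, mesh = sim$mesh,
             covariates = sim$covariates$table, counts = sim$obs$counts,
             covariate_names = c("bio01", "tpi"))

# shared + species-specific spatio-temporal fields, no fusion
fit <- fit_isdm(make_configs()$M21, data,
                options = fit_options(tie_species_hypers = TRUE,
                                      outer_maxit = 120L), seed = 1)
hyper_intervals(fit)
#>      name         mode        lower        upper
#> 1 u.range 1.228545e+04 8.925021e+02 1.691115e+05
#> 2 u.sigma 1.099563e+00 6.261672e-02 1.930858e+01
#> 3   u.rho 9.918876e-01 7.335184e-01 9.997842e-01
#> 4 d.range 1.905199e+03 1.055578e+03 3.438668e+03
#> 5 d.sigma 8.193969e+00 4.057892e+00 1.654581e+01
#> 6   d.rho 9.989342e-01 9.892349e-01 9.998949e-01
#> 7     psi 8.960080e-01 3.498049e-01 2.295080e+00
```

The intervals are 95% credible intervals from the Gaussian hyperparameter
approximation. The pattern is characteristic of these data: a very long,
weakly identified range for the shared field, temporal autocorrelations
pushed toward one, and the species-specific fields carrying most of the
variance. The overdispersion interval [0.35, 2.30] covers the generative
ψ = 2 (smaller ψ means more overdispersion). Prediction and comparison:

```r
surf <- predict_intensity(fit, n_samples = 200, seed = 2,
                          return_samples = TRUE)   # per cell/year/species
cm <- change_map(surf, 2014, 2021)                 # net log-intensity change
sum(cm$significant)   # cells whose 95% CI excludes 0 -> 0 here: with eight
                      # noisy years the net change is nowhere credible

ls21 <- lpocv_logscore(make_configs()$M21, data, n_samples = 60, seed = 3,
                       options = fit_options(tie_species_hypers = TRUE,
                                             outer_maxit = 120L),
                       fold_outer_maxit = 25L)
ls1 <- lpocv_logscore(make_configs()$M1, data, n_samples = 60, seed = 3)
c(M21 = ls21$log_score, M1 = ls1$log_score)
#>       M21        M1
#> -1.096745 -1.518476
```

Higher log-score is better: the joint spatio-temporal model assigns clearly
more predictive mass to held-out populations than the fixed-effects
baseline. `run_pipeline(run_config(...))` chains simulate → covariates →
fit → predict → change map → evaluation into a checksummed artifacts
directory.

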