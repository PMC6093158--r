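# rangedyn

Dynamic occupancy modelling of species range change on gridded
presence–absence surveys, with habitat-suitability surfaces, WAIC model
selection, climate/land-use change decomposition and stochastic range
projection under future scenarios.

## The problem

Two national presence–absence censuses of a species on a ~5-km grid
(e.g. sika deer surveyed across Japan in 1978 and 2003) record where a
range expanded or contracted, but not *why*. `rangedyn` implements a
persistence–colonization transition model that attributes the observed
range dynamics to two per-cell drivers:

* **D** — the *probability of dispersal*: a distance-weighted proportion
  of occupied cells within a neighborhood radius (10–100 km; equal,
  inverse-distance or inverse-squared-distance weights),
  `D_i = Σ_j w_ij X_j / Σ_j w_ij`, `w_ij = d_ij^(−p)`;
* **H** — *habitat suitability*: the log-odds linear predictor of a
  logistic habitat model fitted to the first survey,
  `H_i = α + β₁x_1i + … + β_k x_ki`, with land-use proportions (forest,
  wasteland, agriculture + quadratic, built-up), a snow covariate (snow
  cover period or maximum snow depth) interacting with region
  (Hokkaido vs the other islands), and slope inclination.

Occupancy at the second survey is Bernoulli with

```
q_i = φ_i X_i  + γ_i (1 − X_i),      X_i = occupancy at the first survey
logit(φ_i) = φ0 + φ_d D_i + φ_h H_i   (persistence)
logit(γ_i) = γ0 + γ_d D_i + γ_h H_i   (colonization)
```

The six parameters are sampled by MCMC under flat priors; candidate
models — 84 habitat formulae × 2 surface epochs × 15 dispersal kernels =
2,520 — are ranked by per-observation WAIC. The selected habitat model
decomposes per-cell suitability change into exact climate and land-use
fractions, and the fitted transition model projects occupancy forward
(2028–2103) under baseline / land-use-only / climate-only / combined
scenario bundles, 1,000 stochastic replicates each, reporting the
potential-distribution area above a 95%-sensitivity threshold.

A synthetic-landscape generator (spatially autocorrelated snow and
terrain fields, compositional land use, occupancy simulated from
published reference coefficients) makes every stage testable without
survey data.

## Worked example

Simulate a 40 × 40 landscape from the reference coefficients, refit the
transition model, and decompose the suitability change:

```r
library(rangedyn)

land    <- generate_landscape(landscape_config(n_rows = 40, n_cols = 40, seed = 42))
model   <- sika_habitat_model()                 # published habitat coefficients
occ1978 <- simulate_initial_occupancy(model, land$env_first, land$grid, seed = 42)
d       <- neighborhood_occupancy(occ1978, land$grid, neighborhood_spec(25, 2))
h2003   <- suitability(model, land$env_second, land$grid)
occ2003 <- simulate_transition(sika_dynamics_params(), occ1978, d,
                               as.numeric(h2003), seed = 42)

fit <- fit_dynamics_mcmc(
  transition_data(unclass(occ1978), unclass(occ2003), d, as.numeric(h2003)),
  seed = 1)
fit
#> dynamics_fit: 1600 cells, 3 chains x 1000 iterations (burn-in 100)
#> WAIC per observation = 0.6764; converged: TRUE
#>             mean   sd    2.5%     25%     50%     75%   97.5% rhat
#> phi0       -0.37 0.80   -2.00   -0.89   -0.40    0.18    1.11 1.02
#> phi_d       6.81 2.00    3.19    5.44    6.79    8.06   11.07 1.02
#> phi_h       0.27 0.31   -0.33    0.07    0.25    0.48    0.87 1.02
#> gam0       -1.88 0.38   -2.67   -2.11   -1.88   -1.62   -1.14 1.00
#> gam_d      10.09 1.00    8.17    9.38   10.12   10.76   12.09 1.00
#> gam_h       0.50 0.14    0.21    0.40    0.49    0.59    0.76 1.00
#> deviance 1076.58 3.44 1071.70 1074.07 1075.96 1078.58 1084.37 1.00
```

Colonization responds strongly to neighborhood occupancy (`gam_d`) and
positively to habitat suitability (`gam_h`), and the generating medians
(−0.04, 5.94, 0.50, −1.34, 8.28, 0.64) all fall inside the posterior
intervals. The change decomposition on the same landscape:

```r
decompose_change(model, land$env_first, land$env_second, land$grid)
#> suitability change over 1600 cells: 94.8% increased
#>       increased decreased
#> LU>CL         0        84
#> LU<CL      1516         0
#> continuity-corrected chi-square = 1580.0 (df = 1, p < 2.22e-16)
```

On this synthetic landscape (snow cover shrinking nearly everywhere)
almost every suitability gain is climate-dominated, while every loss is
land-use-dominated — the same association structure the national
analysis reports.

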