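# hexdose

Dose-response analysis of areal event counts on hexagonal grids.

`hexdose` is for analysts studying whether place-based interventions —
prototypically the demolition or rehabilitation of vacant buildings — are
associated with changes in nearby event counts such as neighbourhood crime.
It implements the full pipeline: a regular hexagonal tessellation of a study
region, assembly of a lagged hexagon-quarter panel with ordinal "dose"
coding, a Bayesian Poisson spatio-temporal model fitted by MCMC, and
posterior relative-risk summaries, together with spatial-autocorrelation
diagnostics and a synthetic-data generator with known ground truth so that
every stage can be validated end to end.

## The model

Events in cell *k* and quarter *t* are counted as `Y[k,t]` and modelled as

```
Y[k,t] ~ Poisson(mu[k,t])
log mu[k,t] = x[k,t]' beta + O[k,t] + phi[k,t]
```

where `x[k,t]` collects the lagged design columns (dose-by-vacancy
interaction dummies, vacancy strata, a rehabilitation indicator by stratum,
remediation-history windows, principal-component composites of covariate
blocks, and seasonal dummies), `O` is a known offset (zero when all cells
have equal area), and `phi` is a latent spatio-temporal field:

```
phi[,1]   ~ N(0, tau2 * Q(W, rho_s)^-1)
phi[,t]   ~ N(rho_t * phi[,t-1], tau2 * Q(W, rho_s)^-1)
Q(W, rho) = rho * (diag(W 1) - W) + (1 - rho) * I        (Leroux CAR)
```

with `W` the binary edge-adjacency matrix of the hexagons, `beta ~ N(mu_b,
Sigma_b)`, `tau2 ~ Inverse-Gamma(a, b)` and `rho_s, rho_t ~ Uniform(0, 1)`.
Dose effects are reported as relative risks `exp(c' beta)` with 95%
credible intervals from the pooled posterior draws.

Inference is Metropolis-within-Gibbs (C++ core): componentwise adaptive
random-walk updates for `beta`, single-site updates for `phi` plus a
likelihood-invariant joint translation of the intercept and the field,
a conjugate inverse-gamma Gibbs step for `tau2`, and logit-scale random
walks for the dependence parameters. Fixed seeds give bit-identical chains.

## Worked example

```r
library(hexdose)

# a synthetic study: 61-cell hexagon disc, 24 quarters, known truth
study <- simulate_study(rings = 4, n_quarters = 24, seed = 42)
study$grid
#> <hex_grid> 61 cells, width 2000 (corner-to-corner)

fit <- fit_car_ar(study$panel,
                  car_config(n_chains = 3, n_iter = 12000,
                             burn_in = 4000, thin = 8, seed = 42))
glance(fit)
#> # A tibble: 1 × 8
#>   n_chains n_retained n_iter burn_in  thin max_rhat accept_beta accept_phi
#>      <int>      <int>  <int>   <int> <int>    <dbl>       <dbl>      <dbl>
#> 1        3       3000  12000    4000     8     1.01       0.400      0.405

rr_table(fit)[c(7, 9), ]   # high-dose rows; truth injects RR 1.5 at high/high
#> # A tibble: 2 × 8
#>   outcome exposure   dose  vacancy    rr lower upper significant
#> 1 crime   demolition high  low      1.23 0.918  1.62 FALSE
#> 2 crime   demolition high  high     1.77 1.27   2.45 TRUE
```

The `rr` column is the posterior median relative risk for that dose level
versus zero demolitions within the vacancy stratum; `significant` flags
intervals excluding 1. In this run the 95% interval for the injected
high-dose/high-vacancy effect (true RR 1.5) covers the truth and is
flagged, while a null cell stays unflagged.

Diagnostics follow the same data-frame-first style:

```r
morans_i_permutation_test(rowMeans(log1p(study$panel$Y)),
                          attr(study$grid, "W"), n_perm = 9999, seed = 1)
#> Moran's I permutation test (greater)
#> I = 0.1454, n_perm = 9999, p = 0.023
```

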