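---
title: "Methods: dose-response modelling of areal counts on hexagonal grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response modelling of areal counts on hexagonal grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexdose)
```

## The problem

Cities that demolish or rehabilitate vacant buildings want to know whether
those interventions change nearby crime, and whether the association depends
on the *dose* — how many properties were treated in a neighbourhood in a
quarter — and on the neighbourhood's vacancy level. The statistical
obstacles are the usual ones for small-area count data: counts are Poisson-
like and sparse, neighbouring areas are correlated because they share
populations and unmeasured conditions, and successive quarters are
correlated for the same reasons. `hexdose` packages a complete pipeline for
this design: areal aggregation on a hexagonal grid, exposure coding and
lagging, a Bayesian Poisson spatio-temporal model, and posterior
relative-risk summaries.

## Hexagonal tessellation

The study region (a planar polygon; geographic coordinates are rejected) is
tiled with flat-topped regular hexagons. `width` is by default the
corner-to-corner diameter — a hexagon of corner-to-corner width $w$ has area
$\tfrac{3\sqrt3}{8}w^2$ — with the flat-to-flat convention available via
`width_type = "flat"`, since the informal term "width" is ambiguous and
analyses should state which they mean. Hexagons are attractive areal units
because all cells are congruent and every neighbour relation is the same
kind (a shared edge); adjacency needs no rook/queen distinction beyond
excluding corner contact, which cannot occur between lattice cells anyway.

Cells are kept when at least a configurable fraction (conventionally 80%)
of their area lies inside the region; an explicit exclusion list handles
ad-hoc removals such as cells with no residential parcels. Event counts
observed in a boundary-straddling cell are inflated by the inverse of the
inside fraction and rounded, with exact .5 ties rounded away from zero so
results do not depend on the platform's banker's rounding.

The lattice anchor is the lower-left corner of the region's bounding box,
making the grid a deterministic function of region and width. Synthetic
regions built by `generate_region()` carry their generating-lattice anchor
as an attribute that overrides the default: a bounding-box corner anchor
can never reproduce the generating cells of a hexagon-disc region (the
offset from the bbox corner to the nearest cell centre is not a lattice
vector), and reproducing known cells exactly is what makes the generator's
closed-form cell counts testable.

Polygon operations (areas, hexagon-region intersection by clipping the
region against the convex hexagon, point-in-cell assignment by axial
rounding) are implemented in the package because no general planar-geometry
stack is among its dependencies; tests verify them against Monte-Carlo and
brute-force point-in-polygon oracles. Regions are single- or multi-part
polygons without holes.

## Panel assembly

Counts are aggregated to cells by point location, with points on a shared
edge assigned to the smaller `cell_id` and points outside every retained
cell reported in an "unassigned" bucket rather than dropped. Exposures are
coded ordinally at the cutpoints used in the demolition literature:
demolition dose 0 (reference) / 1 (low) / 2 (medium) / 3+ (high); vacancy
strata 0–1 / 2–11 / 12+; rehabilitation as a presence indicator because
non-zero counts are rare and small. All exposure and control columns are
lagged one quarter relative to the outcome so that a quarter's crime cannot
influence its own predictors. Remediation history enters as four columns:
demolition sums over quarters $t-4..t-1$ and $t-8..t-5$, and rehabilitation
indicators over the same two windows, requiring an 8-quarter lead-in.

Because covariate rosters differ by site and are typically long and
collinear, covariates enter as the first principal component of each named
block (property, community, crime), computed on the correlation scale
(centred, unit variance) since the variables mix counts, prices, and
proportions. The loading sign is pinned (largest-magnitude loading
positive) because PCA signs are otherwise arbitrary and irreproducible.
Seasonality enters as quarter-of-year dummies with Q1 as reference.

The design matrix contains the 9 dose-by-stratum interaction dummies with
zero demolitions as the within-stratum reference, 2 vacancy main effects
(low reference), 3 rehabilitation-by-stratum dummies, the 4 history
columns, one score per composite, and the 3 seasonal dummies. Cells without
parcels carry zeros in all parcel-derived columns via a zero-parcel
indicator. With this reference-cell coding, the within-stratum relative
risk of a dose level is `exp` of that interaction coefficient alone — the
stratum main effect cancels — so the reported risks are invariant to
switching to an equivalent cell-means coding. Missing covariate values are
rejected by the modelling path; a within-cell linear interpolation utility
is provided as a simple stand-in for a proper imputation model.

## The model and its sampler

$$Y_{kt} \sim \mathrm{Poisson}(\mu_{kt}), \qquad
\log \mu_{kt} = x_{kt}^\top\beta + O_{kt} + \phi_{kt}$$

$$\phi_1 \sim N(0,\ \tau^2 Q(W,\rho_S)^{-1}), \qquad
\phi_t \mid \phi_{t-1} \sim N(\rho_T\,\phi_{t-1},\ \tau^2 Q(W,\rho_S)^{-1})$$

with the Leroux precision $Q(W,\rho) = \rho(\mathrm{diag}(W\mathbf 1) - W)
+ (1-\rho)I$, priors $\beta \sim N(\mu_\beta, \Sigma_\beta)$ (default mean
0, diagonal variance $10^5$ — effectively flat), $\tau^2 \sim
\mathrm{IG}(a=1, b=0.01)$, and $\rho_S, \rho_T \sim U(0,1)$. The Leroux
form interpolates between independence ($\rho=0$, $Q=I$) and the intrinsic
CAR ($\rho=1$) and is the precision used by the standard spatio-temporal
areal-count software; offsets default to zero because equal-area cells need
none.

Sampling is Metropolis-within-Gibbs in C++:

* $\beta$: componentwise random-walk Metropolis with per-coordinate
  proposal scales adapted during burn-in toward roughly 40% acceptance,
  frozen afterwards so the retained chain is a valid fixed-kernel chain.
* $\phi$: single-site Metropolis. The Gaussian part of the full conditional
  is available in closed form from the sparse neighbour structure (the
  joint prior precision is $(M \otimes Q)/\tau^2$ with $M$ the AR(1)
  tridiagonal), so each site needs only its neighbours and temporal
  partners.
* a joint translation move $\beta_0 \mapsto \beta_0 + \delta$, $\phi
  \mapsto \phi - \delta$. The likelihood is exactly invariant, and because
  $(\mathrm{diag}(W\mathbf 1) - W)\mathbf 1 = 0$ implies $Q\mathbf 1 =
  (1-\rho_S)\mathbf 1$ for any adjacency, the prior ratio is closed-form.
  Without this move the intercept and the field's global mean form a slowly
  mixing direction under single-site updates; with it, fixed-truth coverage
  of the intercept is nominal.
* $\tau^2$: conjugate Gibbs from
  $\mathrm{IG}\!\left(a + \tfrac{KN}{2},\ b + \tfrac{1}{2}\big[\phi_1^\top Q\phi_1
  + \sum_{t\ge2}(\phi_t-\rho_T\phi_{t-1})^\top Q(\phi_t-\rho_T\phi_{t-1})\big]\right)$.
* $\rho_S, \rho_T$: logit-scale random walks with Jacobian correction. The
  $\rho_S$ update needs $\log\det Q(\rho)$, computed in $O(K)$ from the
  precomputed eigenvalues of the Laplacian $\mathrm{diag}(W\mathbf 1)-W$,
  of which $Q(\rho)$ is a polynomial.

Chain $i$ is seeded `seed + (i-1)*1e6` through R's RNG, so runs are
bit-identical given the seed. The latent field is *not* mean-centred by
default: the Leroux prior is proper for $\rho_S < 1$, the posterior is well
defined, and the uncentred posterior is the one the package's brute-force
oracle tests integrate; per-quarter centring remains available
(`center_phi = TRUE`) for near-intrinsic regimes, at the cost of targeting
a slightly modified distribution. A `latent = FALSE` fit disables the field
entirely, reducing the model to a Bayesian Poisson GLM — used as a limiting
cross-check against importance sampling around the MLE.

Default chain settings (3 chains × 42,000 iterations, 2,000 burn-in, thin
10) are desk-scale; production analyses of the kind this model serves have
used three chains of 4.2 million with 200,000 burn-in and thinning 1,000,
pooling 12,000 draws, and those settings are reachable through
`car_config()`.

## Relative risks

For a contrast $c$ over design columns, draws $s_i = c^\top\beta_i$ are
summarised by the empirical 2.5/50/97.5% quantiles (linear interpolation of
order statistics) and exponentiated. Exponentiation commutes with
quantiles up to the interpolation rule: exactly when $(n-1)p$ lands on an
order statistic, and within the interpolation gap otherwise. An interval
excluding 1 is flagged "significant"; no multiplicity adjustment is applied
across the 12 reported contrasts, matching conventional reporting for this
design. `rr_table()` emits 9 demolition rows (3 doses × 3 strata) and 3
rehabilitation rows per outcome.

## Diagnostics

Moran's I with binary edge weights is tested by label permutation with the
add-one correction $p = (1 + \#\{I^{perm} \ge I^{obs}\})/(1 + n_{perm})$,
one-sided for positive autocorrelation by default (two-sided available),
deterministic given a seed, minimum attainable $p = 1/(1+n_{perm})$, and
default $n_{perm} = 9999$. Event-window summaries average outcome counts at
relative quarters $-3..+3$ around each treated cell-quarter, grouped by
dose at the event quarter; windows crossing the panel boundary are dropped
(complete-window rule), consecutive-quarter treatments contribute one
window per event, and an untreated comparison series is available for
presence/absence treatments.

## The synthetic generator

`simulate_study()` draws every input from known truth so the whole pipeline
can be validated end to end. Defaults: a 61-cell hexagon disc (4 rings,
2000-unit width) over 24 quarters — large enough that all dose levels and
strata occur, small enough that full MCMC runs take seconds. Demolition
counts are zero-inflated negative binomial ($\pi_0 = 0.45$, NB mean 0.9,
size 0.7), giving roughly a quarter of cell-quarters treated with treated
mean near 2 and occasional double-digit counts — the right-skewed regime
reported for city demolition programmes. Rehabilitation is Bernoulli(0.069)
with a small positive count when present; vacancy counts are negative
binomial with a persistent per-cell gamma multiplier so all three strata
occur; covariate blocks share a latent factor (intra-block correlation 0.7)
so the first principal component is meaningful by construction. The latent
field is drawn exactly from the model via the Cholesky factor of $Q$, and
outcomes are Poisson draws from the implied means, with the field truth
($\rho_S = 0.8$, $\rho_T = 0.7$, $\tau^2 = 0.3$) and a coefficient vector
that injects one known demolition effect (RR 1.5 at high dose/high
vacancy) and one rehabilitation effect (RR 1.3 at medium vacancy), all
other dose effects null.

What the generator does *not* emulate: real covariate rosters (dozens of
correlated administrative variables with missingness), geocoding error,
boundary under-reporting, population offsets, or policy-driven treatment
assignment (treatment here is independent of the latent field, so there is
no confounding by construction). Passing tests therefore demonstrate that
the machinery is correct under the stated model, not that the model is
adequate for any particular city's data.

## Numerical choices and test design

* Equal-area check at relative tolerance $10^{-9}$; cells within
  $10^{-9}$ of fully interior are snapped to fraction 1 so the
  threshold-1.0 filter is stable against clipping noise.
* Half-away-from-zero rounding in the boundary correction (tie rule pinned
  deliberately).
* Proposal adaptation multiplies scales by 1.2 outside the 30–50%
  acceptance window, every 100 iterations, burn-in only; acceptance rates
  outside [0.1, 0.6] after adaptation raise a warning.
* The Gelman-Rubin factor is clamped at 1 (the $(n-1)/n$ deflation
  otherwise dips just below 1 for identical chains).
* Validation problem sizes were chosen as the smallest that make each check
  sharp: the grid-integration oracle uses a 4-cell path over 2 quarters
  (9-dimensional posterior integrated on a product grid: 7 points per
  latent site over ±1.4, a wide 241-point coefficient grid — wide because
  truncating the coefficient tails biases the oracle mean); parameter
  recovery uses 20 replicates of the default 61 × 24 study with single
  chains of 30,000; the conjugacy check uses $10^5$ Gibbs draws; the
  Moran's I calibration uses 500 null replicates at 199 permutations.

## Known limitations

* No population or exposure offsets beyond a user-supplied matrix; the
  equal-area design is what justifies the zero default.
* Single spatio-temporal structure (Leroux CAR × AR(1)); no ANOVA-style or
  adaptive-adjacency variants, and no variational or ML fitting path.
* PCA composites may under-adjust relative to including individual
  covariates; this mirrors the design the pipeline reproduces.
* The permutation test assumes exchangeability under the null; with strong
  temporal structure, test per-quarter or on time-averaged values.
* Multi-part regions must have disjoint parts and no holes.
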