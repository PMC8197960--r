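---
title: "Joint small-area mortality mapping with mortmap: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint small-area mortality mapping with mortmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`mortmap` fits a multivariate disease-mapping model (an *M-model*) to
area-level death counts. For tract `i` and cause `j`,

- `O_ij ~ Poisson(theta_ij * E_ij)`, `SMR_ij = 100 * theta_ij`;
- `log theta = Phi M`, with `Phi` an `n x K` matrix of latent spatial fields
  and `M` a `K x J` loading matrix (`K = J` by default);
- each `Phi` column follows a zero-mean Leroux prior with precision
  `lam_k (D - W) + (1 - lam_k) I` and unit scale, `lam_k ~ U(0, 1)`;
- `M[k, j] ~ N(0, sigma_j^2)` with `sigma_j ~ U(0, 5)` on the sd scale.

The matrix product mixes the latent fields into the causes' log-risk
surfaces, and the implied between-cause covariance `Sigma = M'M` is a
first-class output: it quantifies how strongly the spatial mortality
patterns of different causes agree.

Two modelling readings deserve explicit statement, because the construction
admits more than one:

1. **Link scale.** The latent product acts on the *log*-risk scale,
   `log theta = Phi M`, the standard M-model formulation: it guarantees
   positive risks and makes `Sigma` the covariance of the log-SMR surfaces.
   Applying the product on the identity scale would not keep `theta`
   positive under Gaussian fields.
2. **Per-cause spatial variance.** Cause-specific variability enters through
   the column scales `sigma_j` of `M`. The latent fields keep unit Leroux
   scale, so all amplitude lives in `M` — this avoids scale aliasing between
   `Phi` and `M`, and one parameter per cause reproduces "different spatial
   variances per cause" parsimoniously.

`Phi` and `M` are not individually identifiable: any orthogonal rotation
`(Phi R, R'M)` leaves the likelihood, `theta` and `Sigma` unchanged (a
property-tested invariant). Only identifiable quantities — `theta`, `Sigma`,
`lam`, `sigma` — are retained, monitored and reported.

## Standardization

Expected deaths use internal indirect standardization: city-wide
age-specific rates per cause, applied to each tract's person-years, so
`sum_i E_ij = sum_i O_ij` exactly (a 1e-9 relative identity in the tests).
No external standard population is involved; `theta` is therefore risk
relative to the city's own average. Cells with `E = 0` cannot enter the
Poisson likelihood on the log scale; they are retained in the data, excluded
from the likelihood with a flag, and their `theta` draws are
prior-predictive.

## Sampler

Inference is Metropolis-within-Gibbs, written in R with sparse-matrix
algebra:

- **Fields** `Phi`: site-wise Gaussian random-walk proposals applied
  simultaneously to all areas of one color class of the adjacency graph
  (greedy proper coloring; 2 classes on a lattice). Within a class, sites
  are conditionally independent given the rest, so simultaneous single-site
  acceptance is exact, and the sweep vectorizes.
- **Loadings** `M` and scales `sigma`: entry-wise random-walk Metropolis
  (`sigma` on the log scale with Jacobian, rejecting values above the prior
  bound).
- **Mixing parameters** `lam`: random walk on the logit scale, using the
  precomputed eigenvalues `gamma` of `D - W` so the determinant term
  `sum log(lam * gamma + 1 - lam)` costs O(n).
- **Joint `(lam, Phi)` move**: a logit-scale `lam` proposal combined with a
  rescaling of the field in the eigenbasis of `D - W` that keeps the prior
  quadratic form invariant, so the prior and Jacobian cancel exactly and
  acceptance reduces to the likelihood ratio. Without it, `lam` can only
  track the slow drift of the field's realized roughness under single-site
  updates, and its effective sample size per iteration is poor.

Proposal scales adapt in batches (Robbins-Monro on the log scale, gain
`1/sqrt(batch)`) toward ~30% acceptance during burn-in only; they freeze
afterwards, preserving detailed balance in the retained phase. Chains start
from overdispersed random states. One master seed derives per-chain seeds
through a dedicated RNG stream, so adding chains or cities never reshuffles
existing streams; fits are bitwise reproducible for a fixed seed.

Defaults are 3 chains, 5,000 burn-in, 5,000 retained iterations thinned by
5 — a conventional disease-mapping setup; all run lengths are configurable,
and the tests use shorter chains sized to their problem (reported below).

Convergence is declared when split-chain R-hat `< 1.1` and ESS `> 100` for
every monitored quantity. R-hat follows the split-half form
`sqrt(((n-1)/n W + B/n) / W)`; ESS uses within-chain autocovariances against
the pooled variance with Geyer's initial-positive-sequence truncation.
Constant quantities make both diagnostics undefined; they are reported as
passed with a warning rather than silently dropped.

## Numerical choices and degenerate inputs

- Leroux draws in `sample_leroux_field()` are exact (dense Cholesky
  backsolve), not MCMC; at `lam = 1` the ICAR is improper and requires the
  per-component sum-to-zero constraint, which is refused on graphs with
  islands.
- Disconnected graphs and islands are allowed for `lam < 1` (islands behave
  as pure-heterogeneity areas); `lam = 1` on such graphs is rejected.
- Queen contiguity from polygons uses exact segment-segment intersection
  with a small absolute tolerance (1e-9), so boundaries need not share
  vertices to be detected as touching.
- Risk classes are left-closed, right-open at the cuts
  0.7/0.8/0.9/1.1/1.2/1.3 — the cut list fixes six boundaries, and a
  boundary convention had to be chosen; left-closed keeps a risk exactly at
  a cut in the higher class.
- Cross-city percentiles use linear interpolation between order statistics
  (R's default type-7 quantile). With 26 cities the 2.5% point interpolates
  between the two smallest values.
- The two-way ANOVA of the variability table is additive without
  interaction: with one observation per city-cause cell, the interaction
  would saturate the model. Exactly additive (noise-free) tables give a
  zero residual and degenerate F tests; these are flagged, and F for a
  zero-SS factor is reported as 0.
- The cross-gender comparison of pairwise correlations uses a
  pooled-variance two-sample t test — the plain-vanilla reading of "t-test"
  on two sets of correlation values.

## The synthetic generator

`synthetic_config()`/`generate_city()` draw data from the model's own law:
lattice tracts, latent Leroux fields, loadings with per-cause scales (or a
fixed `M` from `loading_from_sigma()` when a known `Sigma` is wanted), and
Poisson deaths with mean `person_years * rate * theta`. The relative risk
multiplies every age band identically — exactly the proportionality
assumption under which indirect standardization is unbiased.

Default demography emulates census-tract-sized areas over a 20-year period:
area populations uniform on (500, 3000) persons, five age bands with
population shares (0.25, 0.25, 0.2, 0.2, 0.1) and annual baseline rates
`1e-4 * 3^(band-1)` — geometric ageing of mortality, giving a few dozen
expected deaths per tract and cause over the period, the order of magnitude
of a leading cause of death. Sparser causes are emulated by scaling the rate
schedule down (the convergence integration test uses a tenth of it, ~5
expected deaths per cell).

What the generator does *not* emulate: real tract geographies (it uses
lattices), deprivation gradients or any covariate structure, ICD coding
artefacts, population change over the period, and model misspecification of
any kind — the data are drawn from the fitted family itself. Passing
recovery tests therefore demonstrate the correctness of the implementation
and the internal consistency of the pipeline, not robustness of the model
on real registries.

## Validation built into the tests

- Exact-sampler check: the empirical covariance of 50,000 Leroux draws on a
  3x3 lattice matches the dense inverse precision within 5% relative
  Frobenius error.
- Prior-only runs (likelihood switched off) reproduce the declared priors:
  `M` moments match `N(0, sigma_j^2)`, `lam` passes a Kolmogorov-Smirnov
  uniformity test.
- Simulation-based calibration on a 5x5 lattice (`J = 2`, `sigma` and `lam`
  fixed in generator and fit, 48 replicates): ranks of the true `Sigma_11`
  within thinned posterior draws are chi-square-uniform.
- Parameter recovery on 20 replicate 10x10 cities with true between-cause
  correlation 0.7: the 95% credible interval covers the truth in 19/20
  replicates and the posterior-mean sign is correct in 20/20 (short chains:
  2 x 1500/1500 thinned by 3).
- The shipped 26-city variability tables reproduce their published margins
  at the printed precision, the cause ranking (AIDS, cirrhosis, COPD at the
  top for men), and the cross-gender correlation 0.38 of per-cause mean
  variabilities over the 10 shared causes. That correlation is 0.38 only
  when computed from the margins at their published 2-decimal rounding
  (`margins = "printed"`); full-precision margins recomputed from the
  rounded cells give 0.36, since the original margins were derived from
  unrounded standard deviations that the publication does not contain.

## Known limitations

- The sampler is plain R; very large cities (thousands of tracts) would
  want the field updates in compiled code or a sparse-precision joint
  update. The eigendecomposition of `D - W` is dense, O(n^3) once per fit.
- `lam` remains the slowest-mixing quantity; runs should always be judged
  by the convergence report, not iteration counts.
- Binary contiguity weights only: estimating a non-binary spatial weights
  matrix is out of scope.
- No spatio-temporal structure; person-years are totals over the study
  period, and tract boundaries are assumed fixed throughout.
- Deprivation or other ecological regressors are not modelled; the
  correlation structure is descriptive.
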