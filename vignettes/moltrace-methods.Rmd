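---
title: "Methods: multi-isotope inference of molt origin and diet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-isotope inference of molt origin and diet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`moltrace` infers where migratory birds grew their feathers (molt origin)
and what they ate while growing them, from stable isotope ratios measured
in feather keratin. Feathers are metabolically inert once grown, so their
δ²H, δ¹³C and δ¹⁵N values (‰, on the VSMOW-SLAP, VPDB and AIR scales
respectively) record the environment at the molt site. This vignette
documents the statistical machinery, its assumptions, the tunable
parameters, and the choices made where the design was genuinely open.

## 1. Calibration: from precipitation to feather δ²H

Growing-season precipitation δ²H (δ²Hₚ) varies smoothly across continents
and propagates through food webs into feathers. The package models feather
δ²H (δ²H_f) as an affine function of δ²Hₚ,

$$\delta^2H_f = a + b\,\delta^2H_p + \varepsilon,\qquad
  \varepsilon \sim N(0, \sigma_{ind}^2),$$

and estimates $(a, b)$ by **bootstrap regression over site summaries**
(`fit_rescaling_bootstrap()`). Each replicate draws, per calibration site,
a feather site mean from $N(\bar f_i, s_i/\sqrt{n_i})$ and a precipitation
value from $N(\bar p_i, sp_i)$, then fits unweighted OLS across sites.
Reported coefficients are means of the replicate draws; reported SDs are
the SDs of the draws, so uncertainty in *both* variables is propagated.
Key choices:

* **Site means, not per-bird resampling.** The calibration inputs are
  site-level means and SDs; drawing the site mean with its standard error
  is the minimal faithful generative reading. A per-bird variant (draw
  $n_i$ birds, then average — distributionally identical for the mean) is
  available via `site_mean_se = FALSE`.
* **One precipitation draw per site per replicate**: the precipitation
  value is a property of the site, not of each bird.
* **Missing SDs** (single-bird sites) are substituted with the mean SD of
  the remaining sites by default (`missing_sd = "substitute"`), or the
  site is dropped.
* **OLS is unweighted across sites**; weighting by $n_i$ is deliberately
  not applied, since the per-site sampling error is already injected
  through the bootstrap draws.
* 1000 replicates by default; the seed is an explicit argument.

The packaged 51-site calibration table (`calibration_sites()`) contains a
block of rows (36–51) whose printed precipitation means (−19 to −26 ‰ at
44–48° N) are irreconcilable with the latitudinal gradient defined by the
remaining rows and with their own small SDs — a transcription error in the
printed source. `flag_inconsistent_sites()` detects such rows from the
data alone: a least-trimmed-squares regression of the site precipitation
mean on latitude and longitude (breakdown point ~50%, so a minority block
of corrupt rows cannot mask itself), flagging absolute robust residuals
above 4 robust-scale units. On this table the screen flags exactly rows
36–51, whose residuals exceed 50 ‰ against a robust scale of ~3 ‰. The
calibration is reported on the consistent subset, with the full-table fit
computed alongside rather than silently discarded.

## 2. Error pooling

Likelihood assignment needs a per-pixel SD. `pooled_error_surface()` pools
three independent error sources in quadrature:

$$\sigma^2(c) = \sigma_{ind}^2
  + \big(b\,\sigma_p(c)\big)^2
  + \operatorname{Var}_{draws}\!\big(a + b\,\delta^2H_p(c)\big)$$

where $\sigma_{ind}$ is between-individual feather variation (default
8.4 ‰, the mean of site-level feather SDs in the calibration table),
$\sigma_p(c)$ the precipitation isoscape's own prediction SD at cell $c$
(scaled by the slope because the rescaling is applied to the predicted
value), and the last term the calibration uncertainty evaluated from the
stored bootstrap draws ($\operatorname{Var}(a) + p^2\operatorname{Var}(b)
+ 2p\operatorname{Cov}(a,b)$, floored at zero). No published formula
exists for this pooling; quadrature is the standard combination of
independent additive errors under the model, and each term is individually
interpretable. The pooled SD can never drop below $\sigma_{ind}$.

## 3. Kriged feather isoscapes and validation

For regions with dense known-origin sampling the package builds the
feather δ²H isoscape directly by **ordinary point kriging**
(`empirical_variogram()`, `fit_variogram()`, `krige()`):

* Distances are great-circle (haversine) kilometres. The original GIS
  workflows use unnamed projected coordinates; haversine is reproducible
  and accurate at the continental extents involved. Geometric anisotropy
  (azimuth + axis ratio) is supported through a local equirectangular
  projection, since an affine distance transform is not well defined on
  great circles.
* The **stable variogram model**
  $\gamma(h) = c_0 + c\,(1 - e^{-3(h/r)^\alpha})$ uses the *effective
  range* convention: the factor 3 puts $\gamma$ at ~95% of the sill at
  $h = r$. GIS packages differ here; published range parameters are
  interpreted as effective ranges. The Gaussian model is the stable model
  with $\alpha = 2$. $\gamma(0) = 0$, so kriging is exact at data
  locations.
* Fitting is weighted least squares with Cressie weights
  ($N(h)/\gamma_{model}^2$), bounded L-BFGS-B from four starting points.
  Iterative cross-validation tuning used by GIS toolchains is approximated
  by WLS fit plus leave-one-out RMSE (`loo_cross_validate()`) for model
  choice.
* One value per location: per-bird values are averaged per site before
  kriging; exact duplicate locations are averaged with a warning.
* Kriging is global (all sites in every system): with ≤ ~50 sites there
  is no need for a search neighbourhood.
* For the anisotropic Gaussian competitor, the anisotropy parameters of
  historical fits are unpublished; the package makes them explicit
  arguments with no hidden defaults (`anisotropy = c(azimuth, ratio)`),
  and examples use a ratio of 2 — a moderate stretch typical of
  continental δ²H fields, which are smoother east–west than north–south.

Candidate surfaces are compared on a holdout sample
(`compare_surfaces_by_validation()`): OLS of observed on predicted,
AICc $= n\ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)$ with $k = 3$, Akaike weights,
and 85% CIs for the validation slope and intercept (a calibrated surface
has slope ≈ 1, intercept ≈ 0).

## 4. Regression isoscape for δ¹³C

Feather δ¹³C mixes a latitudinal signal with diet (C3 vs C4 crops), so it
is modelled by regression rather than kriging. `fit_candidates()` fits
the four OLS candidates over feather δ²H and the county C4-crop
proportion — each main effect, both, both + interaction (the natural
reading of "main effects and interactions" over two predictors) — ranks
them by AICc, and picks the least-parameterized model in the ΔAICc ≤ 2
confidence set whose non-intercept 85% CIs exclude zero. A nested-model
"pretending parameter" screen drops models whose extra coefficient spans
zero while buying < 2 AICc. Residuals are averaged per site and
interpolated (`residual_surface()`; ordinary kriging under a stable
variogram, falling back to inverse-distance weighting with power 2 when
the variogram fit fails — the interpolation method for residuals is not
prescribed anywhere, and kriging keeps the machinery consistent with the
δ²H isoscape), then added to cellwise predictions (`predict_d13c()`).
Cells beyond twice the maximum pairwise site distance carry a zero
residual adjustment (no data support).

## 5. Likelihood assignment to origin

For each bird, `likelihood_surface()` evaluates
$f(y^* \mid \mu_c, \sigma_c)$, the normal density of the observed feather
δ²H at every finite cell (isoscape mean $\mu_c$, pooled SD $\sigma_c$),
and normalizes over finite cells — a flat spatial prior, so the
normalized likelihood is the posterior. The normalization domain is the
isoscape's finite cells; no range-map clipping is applied.

`odds_region()` converts the posterior into a "likely origin" region: the
smallest set of cells, in decreasing order of posterior mass, reaching
cumulative mass $odds/(odds+1)$ (2/3 at the default 2:1 odds). The region
operates on posterior *mass*, the standard odds-ratio reading. Ties at
the cut are resolved in cell-index order: an include-all-ties rule would
inflate the region to the entire grid on a flat posterior, destroying
minimality, while the index rule keeps the region minimal and the result
deterministic.

`classify_migrant()` labels a bird **resident** when its collection cell
lies inside the region; otherwise **north** when the observed value is
below the isoscape prediction at the collection site (feathers grown at
higher latitude are more depleted in ²H) and **south** when above. Exact
equality for a non-resident — measure-zero with continuous data — is
deterministically labelled south and flagged, keeping totals
reproducible. Under a correctly specified error model the resident rate
of birds sampled at their true origin equals the odds mass (2/3), a
coverage property the test suite verifies by Monte Carlo; note that as
$\sigma \to \infty$ the posterior flattens and the region tends to 2/3 of
the cells, so accuracy tends to the odds mass, not to 1.

`stack_origins()` sums the binary regions cellwise (optionally by migrant
status), giving the number of birds isotopically consistent with each
pixel.

## 6. Two-source diet mixing

The C3 and C4 photosynthetic pathways imprint distinct δ¹³C (roughly −27
and −12 ‰ in feather terms, a ~15 ‰ span, after ~1 ‰ diet-to-feather
discrimination). `estimate_endpoints()` calibrates the 100% C3 / 100% C4
endpoints at the 5th and 95th percentiles of each population's feather
δ¹³C — robust to the occasional extreme individual that would otherwise
produce negative contributions — and flags whether the observed span
conforms to the expected 15 ‰ within a tolerance (default ±3 ‰;
nonconforming populations still compute, with a warning). Percentiles use
linear interpolation between order statistics (`type = 7`, the common
software default; the definition is switchable). The ~1 ‰ discrimination
is informational only — it is absorbed by the empirical endpoints.
`percent_c4()` is the linear mixing fraction clamped to [0, 100] with a
clamp flag; `population_summary()` applies per-group endpoint estimation
and summarises, ordered by decreasing mean %C4.

## 7. Group statistics

* `lda_classification_rates()`: linear discriminant analysis per isotope
  combination (pooled covariance, equal priors), resubstitution
  classification rates as a single printed percentage per combination —
  the only reading consistent with one number per cell in published
  tables; leave-one-out rates behind `cv = TRUE`. Rates are invariant to
  affine rescaling of predictors.
* `stepwise_wilks()`: forward stepwise selection with the Wilks' Λ
  partial-F entry test at α = 0.15 (the classic SAS STEPDISC default,
  used because no level is stated anywhere), with Rao's F approximation
  for the final Λ.
* `permanova()`: one-factor permutational MANOVA on Euclidean distances,
  Anderson's partitioning ($SS_T = \frac{1}{n}\sum_{i<j} d_{ij}^2$,
  pseudo-$F = (SS_B/df_B)/(SS_W/df_W)$), unrestricted row permutation,
  $p = (\#\{F_{perm} \ge F_{obs}\} + 1)/(n_{perm}+1)$. For a univariate
  response the pseudo-F is algebraically the one-way ANOVA F (tested to
  1e-10). Designs admitting fewer distinct labelings than `n_perm` switch
  to exact enumeration.
* `state_summary()`: means ± 1.96 SE with compact letters by CI overlap:
  states sorted by mean, each maximal run of pairwise-overlapping CIs
  shares a letter, so disjoint-CI states never share one.

## 8. The synthetic-data generator

`sim_config()` + `make_precip_isoscape()` / `sample_sites()` /
`simulate_feathers()` / `simulate_crop_covariates()` generate a complete
synthetic study. The defaults are the observed magnitudes of the
North American blackbird system, chosen once:

| parameter | default | meaning |
|---|---|---|
| extent | 29.5–52° N, 109.5–88° W | the calibration transect (the northern transect end lies beyond the collection extent, so the surface spans the full ≈ −20…−101 ‰ range) |
| gradient | 172 − 2.4·lat + 1.35·lon | rounded OLS fit of the consistent calibration rows; yields ≈ −20 ‰ (SE corner) to ≈ −101 ‰ (NW corner) |
| noise_sd, noise_range_km | 3 ‰, 300 km | smooth mesoscale departure from the trend |
| calib_intercept, calib_slope | −37.45 ‰, 0.86 | published feather calibration |
| sigma_ind | 8.4 ‰ | between-individual feather SD |
| isoscape_sd_range | 9–11.3 ‰ | the per-pixel SD band of the calibration table |
| c3/c4 endpoints | −27 / −12 ‰ | feather-equivalent pure-diet values |
| diet Beta(α, β) | (2, 2) | individual C4 fraction, mean 1/2 |
| d15n_mean, d15n_sd | 10, 1.5 ‰ | feather δ¹⁵N |
| arid_shift | +2 ‰ | δ¹⁵N enrichment at arid-flagged sites; off by default (sites are non-arid unless flagged) |

The spatially correlated field is an FFT convolution of white noise with
an exponential kernel on a padded grid — approximate by design; only
smoothness and a controllable range matter to the generator's contract.
All generators are deterministic given `seed` (each generator offsets the
seed so a config reproduces the full dataset).

**What the generator does not emulate:** the true spatial detail of any
published precipitation isoscape (orography, coastal gradients),
irrigation-driven groundwater enrichment, molt-dispersal (birds molting
away from their breeding site), brackish-marsh foodweb enrichment, and
real county crop geography. Tests that pass on synthetic data therefore
establish the *statistical machinery* — calibration recovery, coverage of
odds regions, selection consistency — not the fidelity of any particular
published map.

## 9. Numerical choices and degenerate inputs

* Grids are geographic WGS84, square cells, cell-centre registration,
  north-up; the ESRI ASCII lower-left-corner convention is converted on
  read/write, values round-trip to well below 1e-6 ‰ (12 significant
  digits written). Point extraction is nearest-cell by default (the
  reproducible GIS default), bilinear behind a flag; points on the
  south/east edge belong to the last cell.
* The kriging system is solved once per data configuration and reused
  across cells; kriging variances are floored at zero against roundoff.
* Posterior normalization is done in log space (shift by the max
  log-density before exponentiation).
* `fit_rescaling_bootstrap` redraws a replicate (bounded at 20 tries)
  when the simulated predictor collapses to zero variance.
* Degenerate inputs error early and loudly: < 3 usable calibration sites,
  all-nodata grids, nonpositive SD cells, < 10 mixing values, span < 1 ‰,
  fewer than 2 states, zero-variance correlations.

## 10. Problem sizes

The shipped tests and the acceptance script run at deliberately compact
sizes chosen to exercise every code path with stable Monte Carlo margins:
1000 bootstrap replicates for calibrations, grids of roughly 40 × 45 to
113 × 108 cells, 10–40 sites with 5–20 birds per site (200-bird coverage
and mixing checks), 99–999 permutations, and 20-replicate selection
studies. All are arguments, not constants; users can scale any of them
up.

## 11. Known limitations

* Assignment uses δ²H only; a joint multi-isotope likelihood is out of
  scope (δ¹³C and δ¹⁵N enter through classification and diet analyses).
* No informative spatial priors (e.g. relative abundance) — the flat
  prior makes the posterior proportional to the likelihood.
* Anisotropy is a single azimuth + ratio; zonal or nonstationary
  anisotropy is not modelled.
* The δ¹³C isoscape inherits the weak explanatory power of its
  covariates; its published analogue failed holdout validation, and the
  package makes the same validation tooling available rather than
  claiming better.
* GeoTIFF I/O is not provided; the plain-text ESRI ASCII format is the
  interchange format.
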