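---
title: "Methods: subsoil carbon turnover times and their drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subsoil carbon turnover times and their drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(soctau)
```

## The quantity being estimated

`soctau` maps the *apparent turnover time* of soil organic carbon (SOC) in
the 0.3–1 m subsoil layer. Under a quasi-steady state — inputs balancing
outputs, no long-term directional trend — the mean residence time of carbon
in the layer is the ratio of the stock to the input flux:

$$\tau = \frac{\mathrm{SOC}_{0.3-1}}{\mathrm{BNPP}_{0.3-1}}
       = \frac{\mathrm{SOC}_{0.3-1}}
              {\mathrm{NPP} \cdot f_\mathrm{BNPP} \cdot fr_{0.3-1}} \quad
  [\mathrm{yr}],$$

treating the layer's SOC as a single homogeneous cohort. The word
*apparent* matters: few soils sit at a strict steady state, so $\tau$ is an
emergent diagnostic of relative carbon stability, not a kinetic rate
constant.

The three ingredients:

* **Stock.** $\mathrm{SOC} = \mathrm{OC}/100 \cdot D \cdot \mathrm{BD}
  \cdot (1 - G/100)$ in kg C m^-2^, with OC the organic-carbon content in
  percent of soil weight, $D = 0.7$ m the layer thickness, BD the bulk
  density and $G$ the gravel volume percent. The single likeliest
  implementation bug here is the bulk-density unit (soil databases ship
  g cm^-3^); `compute_stock()` therefore forces an explicit unit
  declaration and converts to the canonical kg m^-3^.
* **Belowground allocation.** $f_\mathrm{BNPP}$, the fraction of net
  primary production allocated belowground, is biome-specific and drawn
  from an observation table (hundreds of field records across nine biomes).
* **Depth allocation.** The fraction of belowground allocation reaching
  0.3–1 m comes from the logistic dose–response root profile
  $F(D) = 1/(1 + (D/D_{50})^c)$ with
  $c = -\log_{10} 19 / (\log_{10} D_{95} - \log_{10} D_{50})$, so that
  $F(D_{50}) = 0.5$ and $F(D_{95}) = 0.95$ by construction, and
  $fr_{0.3-1} = F(1.0) - F(0.3)$. The constant is often printed rounded to
  $-1.27875$; the package uses the exact $-\log_{10} 19$ so the 0.95 anchor
  holds to machine precision.

Croplands have no root-profile records in the source compilation; they are
treated parametrically: $D_{50} \sim N(\bar D_{50}, (0.10 \bar D_{50})^2)$
truncated positive, with a configurable $D_{95}/D_{50}$ ratio. The ratio is
genuinely unreported; the default of 5 is a round value in the range implied
by the non-crop records, and it is carried in the allocation tables so a
user can see and change it.

## Uncertainty propagation

The dominant uncertainty is the input flux, not the stock. Per pixel,
`run_ensemble()` draws a joint ensemble (default 200 members):

* NPP from a normal centred on the pixel mean with SD equal to 10% of the
  mean (truncated positive by resampling; at 10% SD the left tail is
  negligible, the guard is there for configurations that widen it);
* $f_\mathrm{BNPP}$ and the root record by bootstrap, with replacement,
  from the pixel biome's observation tables. The two resamples are
  independent, because the source compilations are unrelated; pairing them
  jointly member-by-member follows the natural reading of "200 ensembles".

The reported maps are the ensemble mean (not the point estimate at mean
inputs) and the empirical 2.5%/97.5% quantiles, computed with type-7 linear
interpolation between order statistics — the convention is a free choice
and is recorded here because alternatives shift the bounds by a fraction of
a draw spacing. The *percentage uncertainty* is
$100 (q_{97.5} - q_{2.5}) / \text{mean}$, a scale-free width.

Two numerical guards: pixels whose ensemble-median flux falls at or below a
floor (default $10^{-6}$ kg C m^-2^ yr^-1^, i.e. essentially barren pixels)
are masked and counted rather than mapped as near-infinite $\tau$; and
every pixel's draws are seeded from (master seed, row, column), which makes
results bit-reproducible and independent of pixel evaluation order.

## The synthetic world

No external rasters ship with the package. `generate_world()` builds a
domain with the statistical features the pipeline has to cope with, and —
deliberately — a *known* causal structure:

* spatially autocorrelated fields via Gaussian-filtered white noise
  (circular convolution, so the field is stationary without edge
  artifacts). This is cheaper than geostatistical simulation and creates
  the window-scale variance contrasts the local attribution needs; it does
  not reproduce long-range anisotropy or the soil-unit blocking of real
  soil databases, which underestimates local soil variability — a caveat
  the source data share;
* temperature as a latitudinal gradient plus smoothed noise; lognormal
  precipitation; productivity increasing in both and strictly positive;
* chemical soil properties sharing a latent "soil quality" factor (loading
  0.6 in the default mixed mode, 0 in the single-driver recovery modes so
  that attribution tests are not confounded by predictor correlation);
  texture closing exactly to 100;
* a log decomposition rate $\log k$ that is a linear form in standardised
  drivers with configurable coefficients (`driver_mode` presets:
  `soil_dominant`, `climate_dominant`, `mixed`, `null`) plus lognormal
  noise (SD 0.3). The organic-carbon layer is then *back-computed* from
  $\tau = 1/k$ scaled by a 200-yr baseline and the expected input flux, so
  the generator can state exactly what share of the log-rate variance each
  driver group owns. In the mixed default, warmer and wetter climates speed
  decomposition and higher-quality (higher pH, base-rich, finer) soils slow
  it — which yields the sign structure the global analyses are tested
  against: $r(\ln\tau, \ln \mathrm{SOC}) > 0$,
  $r(\ln\tau, \ln \mathrm{BNPP}) < 0$, climate$\to\tau$ negative,
  soil$\to\tau$ positive.

The allocation tables emulate the two field compilations: beta-distributed
$f_\mathrm{BNPP}$ (forests low, grasslands and tundra high) and lognormal
$(D_{50}, D_{95})$ with biome-specific depth means. Their within-biome
dispersions (relative SD ≈ 12% for $D_{50}$, 8% for the depth ratio, beta
concentration 50) were chosen so the resulting percentage uncertainty of
$\tau$ lands on the order reported for the real-data analysis (tens of
percent, higher at depth-sensitive biomes); wider dispersions inflate it
several-fold because $1/fr$ is convex in the root-profile parameters.

What passing tests on this world do *not* show: robustness to soil-unit
blocking artifacts, to misregistered layers, to the MODIS-era NPP/climate
time-frame mismatch, or to real-world confounding between climate and soil
formation. The generator is a controlled laboratory, not a re-creation.

## Driver attribution

**Local.** `run_windows()` samples up to `n_windows` distinct window
centres (centres must themselves be valid pixels) whose surrounding
`window_size`² window holds more than 50 valid pixels, truncating windows
at the domain edge rather than discarding them. In each window a boosted
regression tree model — stagewise least-squares boosting of depth-3 trees,
shrinkage 0.01, bag fraction 0.5, tree count chosen by 10-fold
cross-validation with a 50-tree floor — is fitted to $\ln\tau$ on the
twelve predictors (MAT, MAP, pH, clay, silt, sand, ECE, ESP, CaSO4, CaCO3,
TEB, BS). $\ln\tau$ is used because $\tau$ spans orders of magnitude; a
`log_tau = FALSE` switch restores the raw response. Relative influence is
Friedman's split-improvement share, normalised to 100; the climate group is
MAT + MAP, soil is the rest, and the groups aggregate across windows as the
performance-weighted average
$RI_w = \sum_i RI_i R_i^2 / \sum_i R_i^2$, alongside the $R^2$-decile
profile and the fraction of windows with climate above 50%. The boosting
engine is implemented in C++ in this package; tests cross-check its
relative influence against an independent boosting library. Desk-scale
analyses in this repository use 21-pixel windows, 50–60 windows and 500
trees at shrinkage 0.05, which recover the generator's ground truth in a
few minutes; the defaults mirror the full-scale design (101-pixel windows,
10,000 windows).

**Global.** One BRT on a random pixel sample, and a partial-least-squares
path model with latent climate (MAT, MAP) and soil (pH, TEB, ECE, BS,
CaCO3, clay, silt, sand) variables, inner paths climate→soil, climate→τ,
soil→τ, and τ as a single-indicator latent — the standard device for an
observed outcome. Estimation is the classical iterative algorithm with a
reflective outer model and the centroid inner scheme (the long-standing
default of the PLS path-modelling literature; factorial is available).
Inner coefficients are standardised OLS regressions of the converged
scores; the indirect climate effect is the product of the two legs;
significance comes from percentile intervals over 200 row-bootstrap
resamples.

Sign conventions deserve a note. Indicators with negative loadings are
sign-flipped and the model re-estimated, so all reported loadings are
positive. That rule leaves each latent's global orientation ambiguous (the
mirrored latent also has all-positive loadings on the flipped indicators);
the package resolves it by requiring that a minority of each block's
indicators be flipped, anchoring exact ties on the block's first indicator.
The orientation is therefore identifiable — and estimation invariant to
pre-flipped inputs — whenever fewer than half of a block's natural
indicators point against the latent. Composite loadings converge to
indicator–composite correlations, which exceed factor loadings when
indicator reliability is below one; recovery tests compare against that
population value, and path coefficients carry the corresponding mild
attenuation, which is why the model's explained variance is expected to sit
below the BRT's.

## Numerical and scale choices

* Grids are plain-text rasters (6-line ASCII-grid header + rows, north-up;
  pixel centres at origin + (i + 0.5)·resolution) so every artifact in the
  repository is human-readable and round-trips bit-exactly at 17
  significant digits.
* Spatial means are unweighted pixel means by default; `area_weighting`
  switches the means (not the quantiles) to cos(latitude) weights. On the
  synthetic domains the two differ by little; the option exists because at
  a fixed angular resolution pixel areas shrink poleward.
* Pixel samples for the global analyses are drawn without replacement.
* Test and analysis problem sizes — 120²–220² pixel domains, 200-member
  ensembles, 50–60 windows, 5,000–8,000-pixel global samples — were chosen
  as the smallest scales at which every recovery property is comfortably
  identifiable; all are configuration, not code.

## Known limitations

* The quasi-steady-state assumption is inherited, not tested; disturbance
  regimes that trend over time bias $\tau$ in either direction.
* Stock-side uncertainty (OC, BD, G) is deliberately not propagated; the
  ensemble covers the input flux only.
* The crop $D_{95}/D_{50}$ ratio is an assumption (default 5), flagged in
  the allocation tables.
* Latent orientation in the path model is ambiguous when exactly half of a
  block's indicators oppose the rest; the tie-break is deterministic but
  arbitrary.
* The moving-window analysis reports sampled windows, not a wall-to-wall
  influence map.
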