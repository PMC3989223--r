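---
title: "Dual-isotope isoscapes and natal-origin assignment: models and choices"
author: "dualscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-isotope isoscapes and natal-origin assignment: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualscape)
```

## The problem

Songbirds recruited into a breeding population as first-time breeders
(second-year, SY) grew their juvenile feathers near their natal site, while
experienced breeders (after-second-year, ASY) moulted near last year's
territory. Feather keratin is metabolically inert after growth, so two
isotope ratios measured in a feather — δ²H, which follows broad
precipitation gradients, and δ³⁴S, enriched near coasts by deposited marine
sulfate — record *where* the feather grew. Mapping expected feather values
over a study region ("isoscapes") and comparing each SY bird's pair of
values against that map yields a spatially explicit estimate of its natal
area, and from it residency rates and minimum natal dispersal distances.

`dualscape` implements this analysis end to end: isoscape construction by
semivariogram modelling and ordinary kriging, year/age calibration of δ²H,
bivariate-normal likelihood assignment with odds-ratio binarization, and the
dispersal summaries. A synthetic-data generator reproduces the statistical
structure the method assumes, so the whole pipeline is testable without
access to field data.

## Isoscapes: semivariograms and ordinary kriging

Per-location mean feather values $z(\mathbf{s}_i)$ at centroids
$\mathbf{s}_i$ (planar, projected km) are interpolated by ordinary kriging.
The spatial structure is summarized by the empirical semivariogram (classical
Matheron estimator over lag bins; default 12 equal-width bins up to half the
maximum pairwise distance, bins with fewer than 3 pairs dropped):

$$\hat\gamma(h) = \frac{1}{2\,|N(h)|} \sum_{(i,j) \in N(h)}
  \bigl(z_i - z_j\bigr)^2 .$$

Five isotropic families are supported — spherical, circular, exponential,
gaussian and linear — using their standard closed forms with nugget $c_0$,
partial sill $c$ and range $a$. Two conventions matter and are easy to get
wrong:

* **Range.** For the exponential and gaussian families the `range` slot is
  the *practical* range (lag at 95% of the sill); the factor 3 sits inside
  the exponent. This makes the reported range comparable across families.
* **Zero lag.** The curve evaluator returns 0 at $h = 0$ exactly and the
  nugget as the right-limit $h \to 0^+$. The kriging system uses the same
  convention, which is the classical *exact* ordinary kriging: with a zero
  nugget the surface interpolates the data at the centroids (a tested
  invariant), and weights always sum to 1.

Fitting is weighted least squares with Cressie-style weights
$N(h)/h^2$. For a fixed range every bounded family is *linear* in
$(c_0, c)$, so those are profiled out in closed form (clamped at zero) and
the range is found by a coarse log-grid scan plus golden-section polish.
This avoids gradient pathologies at the spherical kink and recovers
noiseless parameters to better than $10^{-6}$ (a tested invariant). The
linear family has one structural degree of freedom (its slope); the stored
`(psill, range)` pair is slope × reference-lag and reference-lag.

Family selection minimizes leave-one-out cross-validated RMSE: each location
is predicted from all others under the fitted model. LOOCV was chosen as the
cross-validation flavour because it is the convention of the geostatistical
tooling this workflow descends from; exact RMSE ties are broken by the
family order above. Degenerate constant data make every family tie at RMSE
0; the zero-variance kriging limit returns the plain mean with equal
weights, so the tie-break (first family in order) is well defined.

## Calibration

δ²H in precipitation varies between years, so location means sampled in
different years must be moved onto a common scale before entering one
isoscape. The benchmark is the returning-ASY series at the focal district:
`yearOffsets()` computes offset$(y) = \bar z_{\text{benchmark year}} -
\bar z_y$, added to year-$y$ values. The offset is assumed spatially
constant across the study area — a single number per year — which is the
assumption the benchmark design implies; no spatially varying correction is
attempted. Offsets display rounded to 0.1‰ but propagate at full precision.

SY feathers grown post-fledging can be systematically offset from the ASY
isoscape scale; because the magnitude (0–6‰, either sign, depending on
study) is uncertain, assignment is run as a sensitivity design over the
factor set $\{-6, -3, 0, +3, +6\}$‰ applied to SY δ²H only. δ³⁴S is never
calibrated — sulfur shows little diet–tissue discrimination and no a priori
year effect; a pooled-variance two-sample $t$ test (`sulfurYearTest()`)
checks the year effect, and mean differences within the ±2‰ assay
precision are flagged negligible regardless of significance.

## Assignment

Within-location dispersion is pooled across locations from a validation
subset: residuals $z_{ik} - \bar z_i$ give SDs $\sigma_H, \sigma_S$ and
correlation $\omega$ on $N - L$ degrees of freedom, assumed stationary over
the study area. For an individual with values $(x, y)$ and a cell $j$ with
isoscape means $(\mu_{H,j}, \mu_{S,j})$, the likelihood is the bivariate
normal density

$$f_j = \frac{1}{2\pi \sigma_H \sigma_S \sqrt{1 - \omega^2}}
 \exp\!\left[ -\frac{z_H^2 - 2\omega z_H z_S + z_S^2}{2(1 - \omega^2)}
 \right], \qquad z = \frac{\text{value} - \mu_j}{\sigma}.$$

Masses are normalized discretely (cell masses sum to 1 over the grid — the
analysis operates on raster cells, not continuous densities). The
likely-origin region at odds ratio $r$ is the highest-density region: cells
ranked by mass (descending; ties broken by ascending row-major cell index
for determinism) are included until the cumulative mass first reaches
$r/(r+1)$ — $2/3$ ("67%") for 2:1, $4/5$ for 4:1. The inclusion rule is
`>=`: a cell landing the cumulative mass exactly on the threshold is
included. On a perfectly uniform surface this includes exactly the first
$\lceil 2N/3 \rceil$ cells in index order; "not detectable within extent"
(see below) therefore signals only when the cut swallows the whole grid.
Because $2/3 \le 4/5$, every 2:1 region nests inside the matching 4:1
region — checked on every surface the tests touch. Individuals missing one
isotope are excluded from bivariate assignment rather than assigned
univariately.

## Residency and dispersal

A bird is *resident* when at least one included cell center of its binary
surface falls inside the capture-area polygon (a point capture converts to a
5 km disc, the within-location capture radius); otherwise it is an
*immigrant* with minimum dispersal distance the Euclidean distance from the
breeding point to the nearest included cell center. Distances are
point-to-cell-center: at a 2 km cell size, center-versus-edge refinements
are below the grid resolution. "Perpendicular distance" to the nearest
unlikely area is implemented as nearest-neighbour Euclidean distance, the
only well-defined reading on a raster. Regions touching the outermost grid
ring set an `edge_contact` flag — maximum dispersal distances are censored
by the isoscape extent and are deliberately not estimated.

The *minimum detectable* dispersal distance at a site is the method's
short-distance blind spot: a fictional individual is given exactly the
isoscape-predicted values at the site, assigned, and the distance to the
nearest excluded cell returned. Classification accuracy for known-origin
birds is the plain percentage whose region overlaps their origin, reported
at full precision.

## The synthetic generator

`simConfig()` fixes the study conditions the generator emulates:

| parameter | default | meaning |
|---|---|---|
| extent | 340 × 530 km | total sampling area (~180,000 km²) |
| locations | 26, ≥ 25 km apart | sampling locations (seeded uniform) |
| birds/location | 3–10 ASY | per-location sample sizes |
| σ_H, σ_S | 10.5, 3.8 ‰ | within-location SDs |
| ω | 0.29 | within-location correlation |
| year offsets | −21.1 (2011), −11.9 (2012) ‰ | δ²H shifts vs the 2010 benchmark |
| age offset | −6 ‰ | SY δ²H shift (within the 0–6‰ juvenile depletion range) |
| grid cell | 2 km | analysis resolution |

The true δ²H landscape is a linear gradient enriched toward the southeast
(`gradientH = c(0.055, -0.055)` ‰/km) and δ³⁴S a west–east coastal gradient
(`0.02` ‰/km), each plus a smooth Gaussian-process component (gaussian
covariance, default sill 8‰², range 120 km) realized once on a 10 km grid
by Cholesky factorization and interpolated bilinearly — so a field evaluated
twice at the same point always returns the same value. The minimum
location separation (25 km) keeps variogram lags non-degenerate, mimicking
surveys whose closest locations are tens of km apart. Bird values are
bivariate-normal around the field values; year and age shifts are pure
translations of δ²H, so the calibration stage can recover them exactly in
expectation. `simulateStudy()` additionally reproduces a full survey layout:
a compact benchmark district (four pooled locations in an ~80 × 25 km
footprint) with returning ASY in every year and an SY cohort, and outlying
locations with sulfur measured on a three-bird subsample per location.

What the generator does *not* emulate: elevation and seasonality effects on
δ²H, mechanistic sulfur deposition, anisotropy, non-stationary dispersion,
and habitat-age structure within locations (birds are exchangeable within a
location). Passing tests therefore demonstrate that the *machinery* is
correct under the stated model, not that the model captures every feature
of real feather data.

## Numerical choices and degenerate inputs

* Variogram range search: log-spaced 60-point scan over
  $[\min(h)/10,\, 3\max(h)]$ then two `optimize()` passes (tolerances
  $10^{-10}$, $10^{-12}$).
* Kriging systems use LAPACK `solve()` on the bordered matrix; duplicate
  coordinates are detected beforehand and reported by location pair.
  Kriging variances are clamped at 0 against round-off.
* Likelihood underflow (an individual far outside the isoscape range) falls
  back to log-density normalization, so surfaces remain proper.
* Residual correlations within $10^{-9}$ of ±1 are rejected as degenerate
  rather than propagated into a singular covariance.
* All generator randomness flows through a single integer seed; seeded
  streams are scoped so library calls never perturb the caller's RNG state.

## Problem sizes used in the checks

The shipped tests and the acceptance script run entirely on synthetic data
at sizes chosen to make sampling noise small relative to the tolerances
they assert: dispersion recovery uses 22 locations × 500 birds (residual
SE ≈ 0.7% on the SDs, ≈ 0.009 on ω); coverage calibration uses 200
known-origin birds on an 8 km grid (nominal 2:1 coverage 2/3, asserted
≥ 0.60); Monte-Carlo family comparisons use 40-point Gaussian-process
replicates. End-to-end pipeline checks use the full 26-location survey
layout at a 10 km analysis cell.

## Known limitations

* Each isoscape is built independently — no co-kriging between isotopes,
  no anisotropy; the within-location covariance enters only at assignment.
* The year correction is spatially constant by construction.
* The origin prior is implicitly uniform over the grid; no habitat or
  abundance weighting.
* Raster semantics (discrete masses, ties broken by cell index) mean
  binarized regions can differ by single boundary cells from
  continuous-density HDRs.
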