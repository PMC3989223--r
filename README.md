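# dualscape

Dual-isotope feather isoscapes and geographic assignment of natal origin.

Where did the first-time breeders in a bird population hatch? Feathers grown
near the natal site record two stable isotope ratios — δ²H, which follows
broad precipitation gradients, and δ³⁴S, enriched near coasts by deposited
marine sulfate — so an unmarked bird's feather carries a spatial fingerprint.
`dualscape` turns per-location feather means into continuous isoscapes by
semivariogram modelling and ordinary kriging (model family chosen by
leave-one-out RMSE), calibrates year and age effects in δ²H, and assigns each
individual a likely natal area through a bivariate normal likelihood over the
two isoscapes,

f(x, y | μ_j, Σ) = (2π σ_H σ_S √(1−ω²))⁻¹ ·
exp{ −[z_H² − 2ω z_H z_S + z_S²] / (2(1−ω²)) },  z = (value − μ_j)/σ,

evaluated per raster cell j, normalized, and cut into a likely/unlikely
binary surface at an odds-ratio threshold (2:1 → upper 2/3 of cumulative
probability mass, 4:1 → 4/5). Binary surfaces yield residency calls, minimum
natal dispersal distances, per-site minimum *detectable* distances (the
method's short-distance blind spot), and population-level summed origin maps.
A synthetic-data generator reproduces the statistical structure the analysis
assumes (within-location SDs 10.5 and 3.8 ‰, correlation 0.29, year shifts
of order 10–20 ‰, a 340 × 530 km extent with 26 sampling locations), so the
whole pipeline is testable without field data.

The package is aimed at spatial ecologists running isotope-based assignment
studies and at methodologists who want a fully scripted, testable
reimplementation of the workflow.

## Worked example

```r
library(dualscape)

cfg   <- simConfig(seed = 42)                  # study conditions
study <- simulateStudy(cfg)                    # full synthetic survey
district <- cbind(x = c(130, 210, 210, 130),   # focal district polygon
                  y = c(252, 252, 278, 278))
pc  <- pipelineConfig(study$records,
                      benchmarkLocs = study$benchmarkLocs,
                      benchmarkYear = 2010, cell = 4, studyArea = district,
                      ageFactors = c(-6, 0, 6), oddsRatios = c(2, 4))
res <- runPipeline(pc)
```

which logs, stage by stage:

```
[input] 225 records in: 190 ASY, 35 focal SY
[calibration] offsets: 2010 +0.0, 2011 +22.4, 2012 +13.7
[calibration] sulfur year test: t(32) = 0.91, p = 0.372 (negligible vs 2 per-mil assay error)
[summarize] 26 locations
[isoscape] d2H: gaussian (RMSE 4.92); d34S: linear (RMSE 2.24)
[covariance] sigma_H 10.82, sigma_S 4.51, omega 0.43 (df 44, 66 birds)
[assign] age +0, 2:1 -> 24/35 residents
...
[detectability] mean 92 km (SD 1) over 4 locations
```

Reading the output: the year calibration recovered the simulated ~21 and
~12 ‰ shifts (within sampling error of the 23/14/11-bird benchmark series);
a gaussian semivariogram won the δ²H cross-validation; the within-location
dispersion was re-estimated from the 66-bird validation subset; and at a 2:1
odds ratio with no age correction, 24 of 35 synthetic SY recruits have a
likely-origin region overlapping the district — the rest are immigrants:

```r
calls0 <- subset(res$calls, age_correction == 0 & odds == 2)
subset(calls0, !resident)$min_dispersal_km
#> 54, 58, 67, ... , 102   (km, nearest likely-origin cell to the district)
res$minDetectable
#> four per-site blind-spot distances, mean 92 km
```

With `outputDir` set, the run also writes the isoscapes and kriging
variances (`.asc`), variogram sidecars (`.yml`), residency calls and
location summaries (`.csv`), and per-combination summed origin rasters. The
individual stages (`summarizeLocations()`, `buildIsoscape()`,
`yearOffsets()`, `estimateCovStructure()`, `likelihoodSurface()`,
`oddsBinarize()`, `classifyResidency()`, …) are all exported and documented;
`vignettes/dualscape-methods.Rmd` explains the models, conventions and
design choices. A thin command-line driver lives at
`inst/scripts/dualscape.R` (`simulate` and `run` subcommands).

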