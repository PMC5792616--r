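---
title: "Multiscale landscape genomics with terrain-derived proxies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale landscape genomics with terrain-derived proxies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(landgea)
```

## The problem

Alpine plants adapt to conditions that change over metres: a crest is
wind-blasted and snow-free early, a hollow three metres away holds snow
into summer. Climate grids cannot resolve this, but a very high resolution
(VHR) digital elevation model can, through geomorphometric proxies —
exposure, openness, insolation, wetness. `landgea` implements an analysis
that asks, for a population of a polyploid plant genotyped with dominant
(band presence/absence) markers along a ridge: (i) what is the fine-scale
genetic structure, (ii) which terrain proxies associate with individual
loci, and (iii) **at which spatial resolution** those associations are
strongest — treating resolution itself as an analysis dimension by
degrading the DEM through a 0.5/1/2/4/8 m pyramid.

Dominant markers and recent polyploidy preclude most classical population
genetics (Hardy–Weinberg-based estimators are invalid), which drives the
method choices throughout: model-free clustering for structure, a
frequency-centred cross-product for relatedness, and binomial regressions
on raw band presence for the association scan.

## The model pipeline

### Raster model and pyramid

Grids store cell-centre values with the georeference at the outer top-left
corner; cells are half-open (a point on a shared edge belongs to the cell
with the larger index) so every in-bounds point maps to exactly one pixel
— the property the mixed models rely on when they use pixel ids as
grouping factors. Each pyramid level applies a separable cubic B-spline
low-pass filter and decimates by two, with output cell centres on the
centroids of the 2×2 input blocks (even-phase taps `(1, 23, 23, 1)/48`,
the cubic B-spline evaluated at ±0.5 and ±1.5 cells). The kernel is a
partition of unity and symmetric, so constants are preserved exactly and
linear ramps exactly away from the (half-sample-mirrored) boundary; white
noise loses variance at every level. The source only states that a
B-spline filter was used; cubic order and mirror boundaries are this
package's defaults, chosen because cubic is the geomorphometry standard
and reproduces planar terrain exactly, and both are exposed in code.

### Terrain operators

Twelve variables are computed per level (altitude itself is taken from the
field-measured sample table, not from the stack):

| var | meaning | units | key parameters |
|---|---|---|---|
| Slo | Horn 3×3 slope | degrees | flat below 0.01° |
| Nor, Eas | cos/sin of aspect | – | flat cells → 0 |
| VRM | dispersion of unit surface normals | 0–1 | 3×3 window |
| TOP, TON | mean zenith/nadir angle of the maximum-elevation line | radians | radius 50 m, 8 azimuths |
| SVF | mean cos² of horizon angles | 0–1 | radius 50 m, 16 azimuths |
| SWI | ln(specific catchment area / tan slope) | – | Freeman MFD exponent 1.1, tan floor 0.001 |
| FPL | D8 downstream path length to the grid edge | m | ε-filled surface |
| WEX | 1 + mean over azimuths of −(2/π)·atan(distance-weighted mean slope angle) | ≈1 | radius 300 m, weight 0.99^d |
| Ti6, Ti12 | monthly clear-sky irradiation | kWh/m² | lat 46.433°, transmittance 0.7, hourly steps, horizon radius 100 m |

Profile scans (openness, SVF, WEX, solar horizon) step cell-to-cell along
the eight principal azimuths (exact) and advance in cell-size steps with
bilinear sampling on intermediate azimuths. Search radii are not given in
the source material; the defaults above are configuration values recorded
in every stack's metadata. The solar model is a deliberately lumped
clear-sky scheme — direct beam `1.367 · τ^(1/sin h) · cos(incidence)`
zeroed below the DEM horizon, plus an isotropic diffuse fraction (0.3 of
the extinguished beam) weighted by the sky-view factor — validated against
analytic integrals and ordering properties (June > December; south-facing
beats north-facing in winter), not against any external package's absolute
values, which depend on unreported parameterisations.

Hydrology uses priority-flood sink filling (with ε = 0 the minimal fill,
leaving sinkless surfaces untouched; flow routing uses a 1e-6 ε to resolve
flats). Wetness takes `a = accumulated cells × cell size` as the specific
catchment area so that an isolated cell yields `ln(cs / tan_floor)`.

### Structure

K-means (per-locus mean imputation of missing genotypes, used for
clustering only) with the Calinski–Harabasz criterion selects K; fuzzy
c-means with fuzzifier m = 1.02 provides membership coefficients. At such
a small m the update `u ∝ d^(−2/(m−1))` involves 100th powers, so
memberships are computed in log space. Runs are aligned with a greedy
search over random input orders maximising the normalised-Frobenius
similarity G; at K = 2 the greedy result is tested against exhaustive
enumeration. Membership above 0.8 / below 0.2 assigns populations A / B,
the band between is "admixed" (boundaries inclusive of admixed). The
study-scale run counts (1,000 c-means runs, 10,000 alignment repeats,
m optimised at 1.02) are configuration values; defaults are desk-scale
(50 / 200) because the estimator is identical and the alignment is exact
at K = 2 regardless of repeats.

### Spatial autocorrelation

Relatedness for dominant data is the frequency-centred cross-product
normalised by `Σ p(1−p)`, restricted per pair to loci scored in both
individuals. The exact estimator used by the original tooling for
polyploid dominant data is not recoverable from the text, so this
explicit, testable form is used and documented. Distance classes hold
equal pair counts (±1; boundary ties drop to the lower class, so heavy
ties can unbalance counts). Significance permutes individual locations,
keeping genotypes fixed, with the add-one two-tailed estimate
`p = (1 + #{|null| ≥ |obs|})/(B + 1)`; classes are flagged at α/20.

### Association scan

For DEM variables the random intercept is the pixel id at the variable's
resolution — the coarser the level, the more individuals share a pixel
(the synthetic design occupies ~320/240/140/85/65 pixels across the
ladder) — while altitude, the coordinates and the membership coefficient
use the sampling plot. The marginal likelihood is maximised under the
Laplace approximation: for fixed σ the fixed effects and group modes come
from a penalized Newton solve with a Schur complement over the diagonal
random-effect block; log σ is then optimised by golden section, followed
by a finite-difference Newton polish of all parameters on the exact
Laplace objective (the profile step ignores the log-determinant's β
dependence, which otherwise biases β slightly toward zero). The σ → 0
boundary is handled by always fitting the plain logistic model and
reporting it whenever it matches or beats the random-intercept optimum —
making the reduction to fixed-effects regression exact, and keeping the
χ²(1) test of the fixed effect valid at the boundary. An adaptive
Gauss–Hermite evaluator (Golub–Welsch nodes) cross-checks the likelihood.

AIC counts fixed effects plus one variance component (constant model
k = 2, covariate model k = 3), the convention pinned by the identity
`LRT = AIC_null − AIC_full + 2` that also recovers published p-values
from published AIC pairs. Covariates are standardised per variable ×
resolution by default (the source is silent on this; it is a switch, and
no conclusion here depends on the β scale). Non-converged or degenerate
cells (constant covariate, monomorphic response) are flagged and excluded
from significance lists, never dropped silently. Multiple testing uses a
single Bonferroni family over every record attempted, matching the
printed threshold arithmetic 0.05/(233·13·5) ≈ 3.3e-6.

## The synthetic study system

The generator is first-class, tested code; its defaults *are* the study
conditions and are not tuned per analysis:

- **Landscape**: 1.2 km × 120 m ridge at 0.5 m; Gaussian cross-profile
  (σ = 22 m) carries most of the 1,864–2,043 m relief, a 15 m sinusoidal
  crest undulation (300 m wavelength) and a power-law (exponent 3)
  spectral noise field (4 m sd) provide along-ridge variation.
- **Sampling**: areas of 4 × 4 m at uniform 0–25 m gaps along the crest,
  four 2 × 2 m plots each, a plot retained with probability 0.25
  (emulating the ≥ 5-plants rule: walking the whole 1.2 km ridge at that
  spacing would otherwise yield ~1,400 plants, whereas 361 were sampled);
  retained plots hold 5–8 individuals for an exact total of 361 in ~66
  plots.
- **Genotypes**: a logistic admixture cline along the ridge axis
  (centre 600 m, width 125 m — chosen so that ~29 % of individuals fall
  in the 0.2–0.8 admixture band, the published proportion 105/361) plus
  individual logit-normal noise (sd 0.5). Neutral locus l: band
  probability `q·p_Al + (1−q)·p_Bl` with per-locus pool gaps uniform on
  (0.05, 0.20), the range of the published per-marker A/B frequency
  differences. Five adaptive loci: `plogis(β₀ + β₁ z)` with β₁ = ±1.5 per
  sd of a linked terrain variable at a linked resolution (WEX@0.5,
  TON@0.5, Nor@1, Ti12@1, SWI@2). Symmetric scoring errors at 2.93 %;
  loci failing the 0.05 minor-variant filter are redrawn so exactly 233
  polymorphic loci remain.

A deliberate design choice: the crest undulation oscillates (zero mean on
each half of the ridge), so terrain variables are nearly orthogonal to the
admixture cline. This keeps the type-I behaviour of the DEM-variable scan
interpretable — neutral loci are true nulls for terrain — at the price of
a habitat contrast between the *inferred* populations that is much weaker
than in a real hybrid zone where the pools occupy different elevations.
Habitat-comparison behaviour is therefore demonstrated on location-defined
(crest vs flank) groups. Conversely, neutral loci are *not* nulls for the
membership covariate — they are generated from the cline, and loci with
the largest pool gaps genuinely associate with membership; the scan
reports those models separately from the terrain family.

What passing tests on this generator do **not** show about real data: no
linkage or ascertainment structure among loci, no spatially autocorrelated
genotyping artefacts, no dosage variation (band presence is modelled
directly, with no Hardy–Weinberg assumption — appropriate for polyploids),
and pool gaps are independent across loci rather than genealogically
correlated.

## Numerical choices and degenerate inputs

- Fuzzy-boundary arithmetic in log space (m = 1.02); exact centroid hits
  get full membership.
- The minor-variant filter uses a 1e-12 rounding guard so that a locus at
  exactly frequency 0.95 is dropped (1 − 19/20 is a hair above 0.05 in
  doubles).
- Permutation p-values are bounded below by 1/(B+1); with B = 199 the
  α/20 class flag is unreachable — calibration checks use the p-value
  distribution, significance flags need B ≥ 999.
- Separation in a logistic fit (|β| drifting past 25) flags the record as
  non-converged.
- GLMM likelihood agreement with `lme4::glmer` is ~1e-3; the σ=0 branch
  agrees with `glm` to machine precision by construction.
- All RNG flows from explicit seeds; the pipeline derives fixed per-stage
  offsets, and resumed stages are keyed by checksums of their
  configuration and upstream results.

## Problem sizes used in the shipped checks

The test-suite and acceptance script run the full-size landscape
(2400 × 240 cells, all 12 variables at 5 levels, ~2.5 min), 10–20
replicate genotype simulations with complete scans (≈ 15,000 mixed-model
fits each), a 50-run structure inference, and permutation correlograms at
199–999 permutations; study-scale settings (9,999 permutations, 1,000
runs, 10,000 repeats) remain available through configuration.

## Known limitations

- Ray-based operators sample bilinearly off the principal azimuths;
  short-range horizon angles in sharp pits are accurate to a few hundredths
  (the 45°-pit sky-view factor reads ≈0.47 against the ideal 0.5).
- The solar model is clear-sky with a single lumped transmittance; its
  absolute totals are not comparable to full radiative-transfer schemes.
- GeoTIFF support covers single-band uncompressed IEEE-float rasters (the
  subset the package writes, bit-exact on round-trip).
- The structure module's admixture coefficients are clustering-based, not
  model-based ancestries; with Table-2-scale pool gaps the fuzzy boundary
  zone absorbs ~7–12 % of individuals as "admixed" even when the true
  cline is a step function — the price of an assumption-free estimator on
  dominant data.
- The wetness and flow-path operators treat the grid edge as an outlet;
  catchments truncated by the study window are under-accumulated.
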