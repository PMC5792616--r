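# landgea — multiscale landscape genomics with terrain-derived proxies

`landgea` is an R package for detecting signatures of selection in plant
populations genotyped with **dominant (presence/absence) markers** along
topographically complex terrain, where micro-habitat is best described not
by coarse climate layers but by variables derived from a very high
resolution digital elevation model (DEM). It is aimed at landscape
genomicists working at the scale of metres: a ridge, a slope, a single
population with restricted gene flow.

The package implements the full analysis chain:

1. **Multiscale terrain modelling.** A base DEM is degraded through a
   dyadic pyramid (0.5, 1, 2, 4, 8 m by default) with a cubic B-spline
   low-pass filter, and 12 geomorphometric proxies are computed at every
   level: slope, northness/eastness (`cos`/`sin` of aspect), vector
   ruggedness (VRM), positive and negative topographic openness (TOP/TON),
   sky-view factor (SVF), topographic wetness index (SWI, Freeman
   multiple-flow-direction), downstream flow-path length (FPL, D8), an
   isotropic wind-exposure index (WEX), and clear-sky June/December solar
   radiation (Ti6/Ti12) with DEM horizon shading.
2. **Population structure.** K-means with the Calinski–Harabasz criterion
   selects the number of gene pools; fuzzy c-means (fuzzifier m = 1.02)
   over many random starts yields admixture-like membership coefficients,
   aligned across runs by a greedy label-matching search (the CLUMPP
   statistic `G = 1 − ‖Q_a − Q_b‖_F / √(2n)`); individuals with mean
   membership in (0.2, 0.8) are called admixed.
3. **Spatial genetic autocorrelation.** A frequency-centred relationship
   coefficient for dominant data,
   `r_ij = Σ_l (x_il − p_l)(x_jl − p_l) / Σ_l p_l(1 − p_l)`,
   averaged within 20 distance classes holding equal numbers of pairs,
   with significance from permutation of spatial locations.
4. **Gene–environment association (GEA) scan.** For every locus × variable
   × resolution, a binomial mixed model
   `y ~ Bernoulli(logit⁻¹(β₀ + β₁ x + u_pixel))`, `u ~ N(0, σ_u²)`,
   with the **DEM pixel at that resolution as the random intercept**
   (individuals sharing a pixel are pseudo-replicates of one micro-site);
   measured altitude, the two coordinates and the membership coefficient
   are scanned with the sampling plot as the random effect. Each model is
   compared to its constant model by a χ²(1) likelihood-ratio test, AICs
   are reported (k = 2 for the constant model, k = 3 with a covariate),
   and a single Bonferroni family over all records controls the
   familywise error — e.g. α = 0.05 over 233 loci × 13 variables ×
   5 resolutions gives a threshold of 3.3e-06.

The mixed models are fitted by the package's own Laplace-approximation
estimator (penalized Newton inner solve, one-dimensional optimisation of
the variance, Newton polish) written in C++ for the ~15,000 fits of a full
scan; it agrees with `lme4::glmer` to ~1e-3 in log-likelihood and is
cross-checked against adaptive Gauss–Hermite quadrature.

Because the motivating field data are not redistributable, the package
ships a **synthetic-landscape generator** that reproduces the study
conditions: a 1.2 km ridge spanning 1,864–2,043 m modelled at 0.5 m, 361
individuals in a cluster design (4 × 4 m areas split into 2 × 2 m plots of
≥ 5 plants), 233 polymorphic dominant loci from two gene pools joined by
an admixture cline, a 2.93 % scoring-error rate, and a handful of planted
adaptive loci whose band probability follows a logistic function of a
terrain variable at a specific resolution. Every analysis stage is tested
against this generator's ground truth.

## Worked example

```r
library(landgea)

cfg <- scenario_config(seed = 1)                 # the default study system
out <- run_pipeline(pipeline_config(seed = 1, scenario = cfg), "run1")
make_report("run1")

head(out$scan[order(out$scan$p), c("locus", "variable", "resolution", "p",
                                   "beta1", "aic_null", "aic_full")])
```

On the default scenario (seed 1) the head of the table is dominated by
the planted loci, each far below the Bonferroni threshold (0.05/14,912 ≈
3.4e-06) and strongest at or adjacent to the resolution its effect was
generated at; correlated terrain variables (wind exposure, negative
openness, northness, December sun) pick the same loci up, as they would
in real terrain:

```
      locus variable resolution        p beta1 aic_null aic_full
10525  L040      WEX        0.5 1.45e-30  1.51      503      373
12995  L180     Ti12        0.5 1.48e-30 -1.52      503      373
10758  L040      WEX        1.0 6.58e-30  1.49      500      373
13228  L180     Ti12        1.0 1.73e-28 -1.52      496      375
180    L180      Nor        0.5 1.82e-28  1.42      503      383
5865   L040      TON        0.5 1.83e-27 -1.56      503      387
```

`p` is the likelihood-ratio p-value against the constant model; `beta1`
the effect per standard deviation of the standardised terrain variable on
the log-odds of band presence; the AIC pair satisfies
`LRT = AIC_null − AIC_full + 2`. The same run recovers the two planted
gene pools (`K = 2`, 116/106/139 individuals assigned A/B/admixed, mean
run-to-run similarity G ≈ 1.00) and an autocorrelogram whose first
distance class (pairs within ~34 m) is significantly elevated
(`mean_r = 0.011, p = 0.001`) before decaying with distance. The
`membership.csv`, `correlogram.tsv` and `habitat.tsv` outputs carry the
full structure, autocorrelation and habitat-comparison tables;
`report.md` summarises them.

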