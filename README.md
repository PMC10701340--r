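# whalemorph

Comparative morphometrics of whale populations from drone (UAS)
photogrammetry, with measurement uncertainty propagated through the whole
analysis, plus a seasonality toolkit for characterizing the oceanography of
their foraging grounds.

## Who this is for

Marine megafauna labs that measure whales from aerial images (MorphoMetriX
/ CollatriX style digitization) and want to compare populations — total
length, skull and fluke dimensions, and body condition — without
pretending photogrammetric measurements are exact; and anyone who needs to
quantify how seasonally concentrated the physical forcing of a coastal
foraging ground is.

## What it computes

**Photogrammetry.** Pixel measurements convert to metres through the
ground sampling distance `GSD = altitude × (sensor width / focal length) /
image width`. Body condition is the body area index,

```
BAI = 100 · SA / ((u − l) · TL)²
```

with `SA` the trapezoidal surface area of the perpendicular widths over a
head–tail range `(l, u)` of total length (default 20–90%). BAI is
unitless and invariant to uniform rescaling of altitude or pixels.
Quality-3 (poor) measurements, known calves, and images beyond a per-whale
cap are filtered with an audit trail.

**Measurement error.** A Bayesian per-platform error model,
`measured = true·(1+b) + ε`, `ε ~ N(0, σ²)`, is calibrated from
known-sized training objects and inverted to give each whale a posterior
predictive mean and variance per measurement; standardized measures and
BAI inherit uncertainty by transforming the joint draws.

**Inference.** A Monte Carlo ANOVA redraws every whale from
`Normal(posterior mean, posterior variance)` in each of up to 10⁶
replicates, averages the population coefficients, and reports each
pairwise contrast with its highest posterior density interval (HPDI);
contrasts whose 95% HPDI excludes zero are flagged significant.
Allometric scaling is fitted by OLS on log–log axes (slope 1 = isometry)
and small samples are screened for outliers with Dixon's Q test.

**Oceanography.** Daily forcing series are split into season years
(July-start in the Southern Hemisphere), accumulated, and averaged into a
climatological cumulative curve; seasonality is summarized by the 50% and
80% accumulation windows (the 25%→75% and 10%→90% crossings of the annual
total — 182.5 days for constant forcing, shorter for concentrated
forcing). Also included: SST-difference upwelling index, box averages of
gridded (ERDDAP-style long format) fields, monthly chlorophyll-a
climatologies, and salinity–chlorophyll Pearson correlation.

**Synthetic data.** `simulate_morphology()`, `simulate_uas_observation()`,
`simulate_forcing()` and `simulate_bundle()` generate populations,
platform errors with calibration objects, and forcing series with known
ground truth, so every stage is verifiable end to end.

## Worked example

```r
library(whalemorph)

bundle <- simulate_bundle(seed = 1)                    # synthetic field season
res <- run_morphology_pipeline(bundle$records, bundle$calibrations,
                               run_config(seed = 1, n_reps = 1e5))
res$anova$fits$BAI
#> Monte Carlo ANOVA (100,000 replicates, 95% HPDI)
#> Averaged coefficients:
#>  population estimate lower upper
#>       Chile    18.41 18.36 18.46
#>         ENP    18.41 18.38 18.44
#>          NZ    19.89 19.84 19.93
#> Pairwise contrasts:
#>       pair difference    lower   upper significant
#>  ENP-Chile  -0.002231 -0.05954 0.05662
#>   NZ-Chile   1.473908  1.40380 1.54305           *
#>     NZ-ENP   1.476139  1.42271 1.53143           *
```

The generator gave the resident "NZ" population a body-condition (BAI)
advantage of about 1.4 units over the two migratory populations, and the
pipeline — quality filter, pixel conversion, error-model calibration,
posterior prediction, Monte Carlo ANOVA — recovers it: the NZ contrasts
are significant (HPDI excludes 0), the ENP–Chile contrast is not.

```r
oce <- run_ocean_pipeline(bundle$forcing, config = run_config(seed = 1))
subset(oce$windows, fraction == 0.5)
#>     region fraction start_day end_day length_days monotone
#>   Monterey      0.5     102.8   261.4       158.6     TRUE
#>        STB      0.5      94.4   269.9       175.5     TRUE
#>  Corcovado      0.5      94.0   271.3       177.3     TRUE
```

The strongly seasonal synthetic "Monterey" region (von Mises κ = 3) has a
markedly shorter 50% accumulation window than the two weakly seasonal
regions — the same ordering a field analysis reads as differences in
upwelling seasonality.

A thin command-line wrapper lives at `inst/cli/whalemorph.R`
(subcommands `synth`, `morph`, `ocean`, `all`).

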