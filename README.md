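# swampflux

Swamp-forest flood mapping, water-table reconstruction and greenhouse-gas
upscaling — an end-to-end, fully synthetic-testable R pipeline.

## What it does, and for whom

Tropical swamp forests are both major methane sources and major carbon
stores, and their greenhouse-gas balance is governed by hydrology. This
package implements the full inference chain used to track that balance
from satellite observables:

1. **Inundation mapping** — annual dual-polarisation L-band backscatter
   scenes (HH/HV, γ⁰ in dB) are preprocessed (quality masking, cosine
   incidence-angle normalisation, 3×3 speckle filtering, DN→dB
   calibration, donor gap-filling) and classified into swamp vs
   terra-firme forest with a 500-tree random forest on
   (HH, HV, HV−HH, HAND), trained on a 70/30 stratified split of
   ground-truth points, restricted to forest with HAND ≤ 20 m.
2. **Water-table reconstruction** — per-pixel signed water-table level
   (cm): flooded depth = 100·(h₉₀ − HAND) clamped at ≥ 0, where h₉₀ is the
   90th percentile of HAND over the year's flooded pixels; below-ground
   level = −100·(HAND − h₁₀) clamped at ≤ −5 cm inside the maximum flood
   extent, where h₁₀ is the 10th percentile over non-flooded pixels.
3. **Flux upscaling** — WTL classes (≤−70, −70…−50, −50…−30, −30…−5,
   −5…40, >40 cm) × per-class flux densities (t km⁻² yr⁻¹) give annual
   CO2/CH4/N2O totals with 95% CIs, aggregated as

   CO2-eq = CO2 + 34·CH4 + 298·N2O  (100-yr horizon)
   CO2-eq = CO2 + 82.5·CH4 + 273·N2O  (20-yr horizon)

4. **Trend analysis** — OLS slopes with t-based 95% CIs, continuous
   one-breakpoint piecewise fits (exhaustive interior-year search),
   pixel-wise vegetation-index trend maps, stratum means and paired
   t-tests.

It is aimed at remote-sensing and wetland-biogeochemistry researchers who
want the statistical machinery of this analysis chain in a tested,
reproducible form. A synthetic-scene generator (terrain with HAND
structure, multi-year flood dynamics with a configurable
drying-then-wetting breakpoint, bimodal backscatter, ground-truth points,
EVI stacks, a six-class flux table) emulates all inputs, so every stage is
verifiable without satellite archives; real rasters and flux tables can be
substituted at any stage.

## Worked example

```r
library(swampflux)

co2Equivalent(0, 1, 0, gwpWeights("100yr"))
#> [1] 34

res <- runPipeline(runConfig(seed = 1), outDir = "run1")

res$extentTrend
#> TrendFit: slope 0.0191877 /yr (95% CI 0.00717607 to 0.0311992), p = 0.00454, n = 14
res$extentPiecewise
#> PiecewiseFit: breakpoint 2015 | slopes -0.0220138 -> 0.0576949 /yr | RSS 0.00164635 | n = 14
accuracyReport(res$classifier)
#> AccuracyReport: overall 0.933
#>              reference
#> mapped        swamp terra_firme
#>   swamp          57           9
#>   terra_firme    13         248
res$report
#>          quantity slopePerYear   pValue
#> 1      extent_km2    1.919e-02 4.54e-03
#> 2           CO2_t   -5.253e+01 1.24e-02
#> 3           CH4_t    1.120e+00 6.47e-03
#> 4           N2O_t   -9.896e-03 1.34e-02
#> 5   CO2eq_100yr_t   -1.742e+01 4.52e-02
#> 6    CO2eq_20yr_t    3.713e+01 3.33e-03
#> 7         EVI_all    8.179e-04 6.10e-22
#> 8       EVI_swamp    6.221e-04 1.97e-12
#> 9 EVI_terra_firme    8.966e-04 1.15e-20
res$changeCounts
#>  terra_firme stable_swamp   flood_loss   flood_gain
#>         6155         1253           10          212
```

Reading the report: on the default synthetic scenario — a 96×96-pixel
scene at 25 m, 14 observation years (2007–2010 and 2015–2024), a mild
drying trend switching to wetting at 2015 — the mapped swamp extent grows
(+0.019 km²/yr, p ≈ 0.005), the piecewise fit recovers the 2015 regime
shift, flood gain dominates loss in the change map, CH4 emissions rise
while CO2, N2O and 100-yr CO2-equivalent emissions fall, and the 20-yr
horizon (methane weighted 82.5×) turns the CO2-equivalent trend positive.
Both forest strata green (positive EVI slopes) with swamp forest less
productive than terra firme (paired t = −119, p ≪ 0.001 on this noiseless
-by-construction contrast). The `run1/` directory holds every artifact
(extents, confusion matrix, WTL class areas, emissions, trend report as
CSV; grids as ESRI ASCII; a JSON manifest with stage provenance).

A thin CLI wraps the same functions:

```sh
inst/scripts/swampflux run --seed 1 --out run1
inst/scripts/swampflux simulate --out inputs --seed 3
inst/scripts/swampflux trend --in extents.csv --out fit.csv
inst/scripts/swampflux emissions --areas areas.csv --flux flux.csv --out em.csv
```

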