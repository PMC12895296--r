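---
title: "Methods: flood mapping, water-table inversion and flux upscaling in swampflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flood mapping, water-table inversion and flux upscaling in swampflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swampflux)
```

## The problem

Tropical swamp forests — permanently inundated, often peat-forming forested
wetlands — are simultaneously large methane sources and large carbon stores.
Their greenhouse-gas balance hinges on hydrology: deep standing water favours
CH4 production, while a falling water table exposes organic soils to aerobic
decomposition and raises CO2 and N2O emissions. Mapping how inundation and
water-table levels (WTLs) change over time, and translating those changes
into gas fluxes, is therefore a chain of distinct inference steps:

1. **Inundation mapping.** L-band radar backscatter is brighter over flooded
   forest than over non-flooded (*terra firme*) forest because of the
   double-bounce mechanism (canopy-penetrating microwaves reflect off the
   water surface and then off trunks). Annual dual-polarisation (HH/HV)
   mosaics therefore separate the two classes, and a random-forest
   classifier trained on ground-truth points maps swamp forest each year.
2. **Water-table reconstruction.** Height Above Nearest Drainage (HAND) —
   a terrain metric that is 0 on watercourses and grows away from them —
   is inverted against per-year references to produce a signed per-pixel
   WTL in cm: positive standing-water depth on flooded pixels, negative
   below-ground level on non-flooded pixels inside the maximum flood
   extent.
3. **Flux upscaling.** Per-pixel WTLs are binned into six classes
   (`r paste(wtlClassLabels(), collapse = ", ")`), per-class flux densities
   for CO2, CH4 and N2O are applied to the class areas, and totals are
   aggregated to CO2-equivalents at 100-year (weights 34 and 298 for CH4
   and N2O) and 20-year (82.5 and 273) horizons.
4. **Trend analysis.** Annual extent, emissions and vegetation-index (EVI)
   series are summarised with OLS slopes (t-based 95% CIs) and continuous
   one-breakpoint piecewise fits; productivity is compared between strata
   with a paired t-test and mapped pixel-wise.

Every stage is implemented against synthetic scenes with known truth, so
the statistical machinery is verifiable without satellite archives.

## The synthetic scene generator

The generator is first-class, tested code; its defaults define the study
conditions used throughout the tests.

**Terrain.** Drainage channels are meandering random walks spanning the
grid. HAND is a monotone function of 8-connected breadth-first (BFS) grid
distance to the nearest channel — 0.5 m per step by default — plus a smooth
random relief bounded at 45% of the per-step gain. We use grid BFS distance
rather than Euclidean distance deliberately: its integer step structure
makes "strictly farther from drainage implies strictly higher HAND" an
exact, provable invariant (the relief amplitude can never bridge a full
step), and only the *ordering* of pixels relative to drainage matters
downstream. Real HAND fields carry hydrological detail (flow accumulation,
channel hierarchy) that this proxy does not attempt.

**Flood dynamics.** Each year's flooded set is the forest pixels whose HAND
falls below a cutoff that moves piecewise-linearly in time — a base value,
a pre-break trend, and an optional breakpoint with a post-break trend, so a
drying-then-wetting regime shift can be imposed exactly. Independent
Bernoulli label flips add classification-style noise.

A key design decision is the **static spatial water-level anomaly**
(`spatialAnomalySdM`, default 0 in `floodDynamics()`, 0.4 m in the default
pipeline scenario). If flooding is a deterministic threshold on HAND, then
HAND — which is also a classifier feature — *perfectly* reproduces the
training labels, the random forest collapses to a static HAND threshold,
and the annual maps carry no dynamics at all: the backscatter record
becomes irrelevant, which is the opposite of how the real system behaves.
Adding one smooth zero-mean field (drawn once per series, constant over
years) to the cutoff makes flooding correlated with, but not determined by,
HAND, exactly as in a real basin where water levels vary in space. It also
produces occasional flood patches at high HAND — the very artefact the
90th-percentile depth reference exists to mitigate. The amplitude, 0.4 m,
was chosen once as roughly half the default cutoff's dynamic range
(0.72 m); with it the classifier must, and does, lean on backscatter.

**Backscatter.** Class-conditional Gaussians in dB: HH means −6 (flooded)
and −9 (dry) dB, HV means −12/−13 dB, 1 dB noise. These values give the
clear bimodality the classification relies on and are freely configurable;
no physical scattering model is attempted, so speckle is Gaussian in dB
rather than multiplicative, and texture/incidence-angle gradients are
absent. The incidence-angle grid is constant at the 38.7° reference by
default, and a configurable gap mask sets quality flags to emulate mosaic
gaps (the default scenario flags a corner block of the 2008 scene, which
is then donor-filled from 2007).

**Ground truth, EVI, fluxes.** Reference points (default n = 1087, the
size of the GPS campaign the design is built around) are sampled with
proportional class stratification so both classes are always represented,
and labels agree with the truth grid by construction. EVI stacks impose a
stratum baseline (swamp 0.45 below terra firme 0.50), a per-stratum linear
trend (defaults 6e-4 and 9e-4 per year), Gaussian noise, and random
missingness. The default flux table is an explicitly synthetic placeholder
(per-class literature values are an input, supplied as CSV): it encodes the
qualitative structure that matters — CH4 rising and CO2/N2O falling with
rising water table, deep water the strongest CH4 source, possible CO2
sinks under standing water, and 95% bounds bracketing every mean. The
magnitudes are additionally arranged so that at the 100-year horizon every
inundated class has a lower CO2-equivalent density than every below-ground
class (so flood expansion lowers 100-yr CO2-eq), while the 20-year weights
reverse that ordering (methane amplification).

What passing tests on these scenes shows is that the *estimators* are
correct: exact recovery where noise is zero, nominal CI coverage, oracle
equivalence. It does not validate radiometric calibration against real
mosaics, real HAND derivation, transferability of a classifier across
sensors, or the magnitudes of any real flux synthesis.

## Preprocessing conventions

Digital numbers calibrate as γ⁰ = 10·log10(DN²) + CF with CF = −83 dB (the
standard L-band mosaic convention; the constant is configurable). DN = 0
pixels become invalid rather than −∞. Incidence-angle normalisation uses
the first-power cosine-ratio model γ⁰ − 10·n·log10(cosθ/cosθ_ref) with
θ_ref = 38.7° and n = 1 by default (n configurable); the correction is
exactly invertible. The speckle filter is a 3×3 square-kernel *mean* by
default — a window statistic was specified but not named, so a median is
offered as an alternative — applied in the dB domain, where it is linear
under added constants; invalid pixels are excluded from windows and stay
invalid. The operator chain is quality mask → (calibration if the input is
DN) → incidence correction → speckle filter; no operator revalidates a
pixel except explicit donor gap-filling, which records provenance in a
filled-pixel mask.

## Classification and area estimation

The classifier is a 500-tree random forest on (HH, HV, HV−HH, HAND), the
HV/HH ratio being a difference in dB. The 70/30 split is stratified by
class (per-class rounding, so 1087 points yield 760 or 761 training
points); stratification prevents degenerate single-class splits and is the
only assumption added to the stated 70/30 design. Vote ties (exactly 0.5)
go to terra firme, a conservative choice for swamp area. Accuracy is
reported on the held-out 30% as a confusion matrix with overall, user and
producer accuracies.

The flood-potential domain is forest with HAND ≤ 20 m (a pixel at exactly
20 m is retained; the rule removes values *greater than* 20 m). Mapped
areas are pixel counts × pixel area. Because mapped areas are biased by
misclassification, extent confidence intervals use the good-practice
stratified error-adjusted estimator: mapped classes are strata weighted by
their mapped area proportions, the adjusted swamp proportion is
Σᵢ Wᵢ·nᵢ_swamp/nᵢ·, and its standard error follows the stratified binomial
formula (×1.96 for the 95% interval). A bootstrap over the holdout points
reproduces this interval within Monte-Carlo error in the test suite.

The change map compares flood presence between the first-four-year and
last-ten-year periods, with presence defined as a *strict majority* of the
years in which a pixel was actually classified; "presence over a period"
was otherwise undefined, and the majority rule is robust to single-year
noise. The four classes (stable swamp, terra firme, loss, gain) partition
the assessed domain.

## Water-table reconstruction

For each year, the water-surface reference is the 90th percentile of HAND
over that year's flooded pixels (linear interpolation between order
statistics; the percentile and interpolation type are configurable).
Flooded depth is 100·(h_ref − HAND) cm, clamped below at 0 — a flooded
pixel above the reference is "at the surface", never negative. Below-ground
levels are defined only inside the maximum flood extent (the union of all
annual maps): the water-table reference is the 10th percentile of HAND over
the year's non-flooded domain pixels, and the level is −100·(HAND − h_min)
cm clamped above at −5 cm, so a classifier-dry pixel can never land in an
inundated class. The −5 cm clamp mirrors the class boundary between
"−30 to −5 cm" and "−5 to 40 cm": dry pixels occupy exactly the four
below-ground classes and flooded pixels the two inundated classes, making
the six classes a true partition of the domain. Binning is
lower-exclusive/upper-inclusive ((−∞,−70], (−70,−50], (−50,−30], (−30,−5],
(−5,40], (40,∞)), so a value exactly on a boundary goes to the
lower-labelled class, deterministically. Restricting below-ground WTLs to
the maximum flood extent understates dry-side emissions beyond it; that is
a stated limitation of the approach, not of the implementation.

## Emissions aggregation

Annual totals are linear: per gas, Σ_class area × flux density, with 95%
bounds obtained by the same sum over the lower/upper densities — flux
uncertainty dominates the emissions intervals, and area uncertainty is not
compounded into them by default (compounding products of bounds would mix
two different inferential targets; the option is deliberately left out of
the default path). Fluxes are net and may be negative (sinks). Units are
fixed at t km⁻² yr⁻¹ and km², numerically identical to g m⁻² yr⁻¹, with a
relabelling converter for tables supplied in the latter convention.
CO2-equivalents apply the horizon weights to the per-gas totals; because
the weights are positive, applying them bound-wise preserves the interval.

## Trend statistics

`olsTrend()` is the closed-form least-squares fit with t-based two-sided
95% CIs and p-values on n−2 degrees of freedom; gap years are simply
absent (no imputation) — the default year pattern has 14 observations in
2007–2010 and 2015–2024. `piecewiseTrend()` fits the continuous hinge
model y = b₀ + b₁t + b₂(t−τ)₊, with τ searched exhaustively over interior
observed years, ties broken to the earliest year; continuity and the
observed-year search grid are design choices where the design was open
(a free-knot or discontinuous model would be unidentifiable at n = 14).
The single line is nested in every candidate, so the piecewise RSS never
exceeds the line RSS. `pixelwiseTrends()` vectorises exactly the same
formulas (the test suite checks bit-level agreement with a per-pixel
loop) and reports raw p < 0.05 fractions by slope sign; a
Benjamini-Hochberg option exists but is off by default, matching the
reporting convention the summary fractions follow. The paired t-test
resolves degenerate zero-variance differences deterministically (t = ±∞,
p = 0 for a pure shift — detected up to floating-point jitter at relative
1e−12 — and t = 0, p = 1 for identical series). The AMJ compositor
averages April–June images per year after removing pixels available in
less than 80% of the AMJ record.

## Pipeline and reproducibility

`runPipeline()` chains the stages with per-stage child seeds derived from
one master seed (seed + 1000003·k mod 2³¹−19), so stage outputs are pure
functions of upstream artifacts plus configuration, and a rerun is
bit-identical. Artifacts are plain text: ESRI ASCII grids for rasters,
CSV for tables (numerics at 6 significant digits), YAML for configuration
and a JSON manifest recording each artifact's stage. The default scene is
96×96 pixels at 25 m; tests run the same machinery at 32–64 pixels per
side, and the simulation-based checks use 200–500 replicates — sizes
chosen so the full suite exercises every stage in a few seconds while
keeping Monte-Carlo error well below the tolerances being asserted.

## Known limitations

- The backscatter model is statistical (Gaussian in dB), not physical; no
  texture, seasonality, or incidence-angle structure.
- HAND is a BFS-distance proxy; no flow-routing or hydrography.
- The default flux table is a synthetic placeholder with the correct sign
  and ordering structure but arbitrary magnitudes; real syntheses must be
  supplied by the user.
- Seasonally flooded forest is out of scope: the classifier knows only
  permanently flooded and terra firme classes.
- Below-ground WTLs stop at the maximum flood extent; emissions from
  drier land beyond it are not modelled.
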