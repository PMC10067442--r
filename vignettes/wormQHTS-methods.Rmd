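---
title: "Methods: quantitative high-throughput screening analysis for C. elegans"
author: "wormQHTS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative high-throughput screening analysis for C. elegans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormQHTS)
```

# The assay and the pipeline

wormQHTS analyzes 384-well quantitative high-throughput screens (qHTS) in
which GFP-expressing *Caenorhabditis elegans* are grown in the presence of
compound titrations and read by laser-scanning cytometry (LSC).  Each well
yields object-level events (one row per detected fluorescent object, with
perimeter, area and peak intensity); the pipeline turns these into two
per-well viability readouts — total GFP area (µm²) and worm number — and
then into per-compound dose–response pharmacology:

1. **Gating** (`gateObjects`): objects are called worms when perimeter,
   area and peak intensity all fall inside the screening filters
   (100–2200, 1000–180000, 150–1500).
2. **Aggregation** (`aggregateWells`): per-well sums and counts of gated
   objects.
3. **Plate QC** (`controlStats`, `plateQuality`): signal-to-background
   S/B = µₙ/µₚ, signal-to-noise S/N = (µₙ−µₚ)/√(σₙ²+σₚ²), and the
   Z-factor Z′ = 1 − 3(σₙ+σₚ)/|µₙ−µₚ|, from the DMSO neutral controls
   (column 1) and the levamisole-type toxic controls (column 2).
4. **Normalization** (`normalizeWells`): activity% =
   100·(x−µₙ)/(µₙ−µₚ), so the neutral mean is 0% and the full-kill
   control mean −100%.
5. **Titration assembly and fitting** (`assembleSeries`, `fitHill`):
   seven-point inter-plate series (one concentration per plate, 1:5
   dilution) are fitted with the four-parameter logistic model.
6. **Curve classification** (`classifyCurve`): each fit receives a qHTS
   curve class (±1.1 … ±3, 4) and an active call; `prioritize` combines
   day-3/day-7 classes with a human-cell counter-screen.
7. **Life stages** (`classifyEvents`): COPAS flow events (TOF × EC) are
   gated into L1–adult stage counts and binned for heat-map display
   (`heatmapMatrix`).
8. **Chemotype enrichment** (`trainSom`, `clusterEnrichment`): binary
   chemotype fingerprints are clustered with a self-organizing map and
   each cluster is tested for potency enrichment.

Because no instrument data are published with screens of this kind, the
package carries a first-class synthetic-screen generator
(`makeLibrary`, `makeInterplateTitration`, `simulatePopulation`,
`emitLscEvents`, `emitCopasEvents`) that produces seeded,
ground-truth-annotated inputs for every stage.  All validation in the
test suite runs against this generator.

# The population model

`simulatePopulation` uses a discrete stage-structured stochastic model on
half-day steps.  Stage dwell times are egg 1 day and L1…L4 half a day
each, so a worm seeded as L1 becomes a reproducing adult after 2 days and
the egg-to-egg cycle takes ≈3 days — two full life cycles inside a 7-day
screen.  Adults lay `broodPerAdultPerDay` (default 40) eggs per day,
Poisson-distributed, truncated by a per-well carrying capacity.  This is
deliberately the simplest model that reproduces the observed growth
pattern; it is not a mechanistic life-history model.

Compound effect is a per-worm per-day kill hazard
(`killProbability`):

$$p_\text{day} = \min\!\left(1,\; E \cdot s_\text{stage} \cdot
\frac{c^h}{c^h + \mathrm{EC}_{50}^h}\right)$$

with efficacy $E \in [0,1]$, stage susceptibility $s$ (eggs default 0.2,
reflecting eggshell protection), concentration $c$ and Hill slope $h$.
Killing a fraction of worms each day compounds over the time course, so
the **apparent endpoint EC50 of a simulated compound sits below its
hazard EC50** (the built-in levamisole-like control, hazard EC50 8 µM,
shows an apparent day-7 EC50 of ≈3 µM).  Apparent potency tracks true
potency monotonically, which is what the recovery tests rely on; absolute
agreement between the two scales is not expected and not asserted.

Key defaults, all overridable through `dynamicsConfig()`:

* `seedWorms = 10` — the ten-worms-per-30-µl-well screening density.
* `carryingCapacity = 2000` — chosen as a plausible ceiling for a 30 µl
  384-well well.  Six-well life-stage plates (2000 worms seeded) use
  20000, which reproduces the >15000 heat-map ceiling of that assay
  format.
* `baseDeathRate = 0.01`/day — small compound-independent mortality.
* Randomness: one substream per plate, derived by stable hashing of the
  plate id with the user seed, so multi-plate simulations are
  order-independent and byte-reproducible.

# Optics and flow models

`emitLscEvents` draws one event per living worm (eggs are not emitted;
embryonic GFP is ignored) from per-stage lognormal distributions
parameterized by arithmetic mean and CV, with mean object area rising
monotonically L1 → adult (2500 → 70000 µm²).  Debris is Poisson per well
(default 20 events/read) with sub-gate feature distributions.  Under
defaults, ≥99% of worm events pass the published gate and ≥99% of debris
events fail it — so gated worm counts match simulator truth almost
exactly, which the tests exploit as an oracle.

`emitCopasEvents` draws (TOF, EC, green) triples from per-stage lognormal
clouds (CV 0.12) separated enough that the default rectangular stage
gates (`defaultStageGates`) recover mixed-population stage counts within
binomial error.  Instrument-native TOF/EC units are protocol-specific, so
the default gates are expressed in, and calibrated against, the synthetic
units; with real COPAS exports the user supplies their own `stageGates`.

What the generator does **not** emulate: spatial plate effects
(row/column gradients, edge evaporation), bacterial-food depletion,
compound degradation over the time course, merged/overlapping objects,
male/hermaphrodite genetics, and pixel-level imaging.  Passing tests
therefore demonstrate correctness of the analysis pipeline under the
stated noise model, not robustness to every artifact of real screens.

# Numerical choices

* **Gate intervals are closed on both ends**: an object with area exactly
  1000 µm² is kept.  Bare printed ranges are read inclusively.
* **Heat-map binning**: a count equal to a breakpoint falls in the lower
  bin; published scale labels are open intervals, so the tie rule is a
  convention and is stated on `heatmapMatrix`.
* **Positive controls for QC/normalization** are the toxic-control wells
  at the single full-kill concentration (41.7 µM in-well); the
  intra-plate 1:3 control titration wells are excluded from control
  statistics and instead fitted as a per-plate control curve.
* **4PL fitting** (`fitHill`): Levenberg–Marquardt with box constraints,
  weights equal to per-point replicate counts, deterministic starts
  (asymptotes from extreme-concentration medians, log EC50 from the
  half-response crossing, slope multi-start 0.5/1/3).  `bottom` is the
  zero-dose asymptote, `top` the high-dose asymptote, slope kept
  positive; a loss-of-signal curve has top < bottom.  Series with fewer
  than 4 usable points drop to a 3-parameter model with the high-dose
  plateau fixed at −100% (full kill).  Non-convergence is a reported
  state, never an exception.  Fits with EC50 outside the tested range
  are flagged `extrapolated`.
* **Outlier masking** (`maskOutliers`): a 7-point series leaves only 2
  residual degrees of freedom, so a series-internal noise estimate is
  unstable and a least-squares fit absorbs much of a spike into its
  parameters.  Masking therefore studentizes each candidate's
  *leave-one-out prediction error*, leverage-corrected via the fit
  Jacobian, against the plate-control activity SD that the pipeline
  supplies (`noiseSd`); without it the threshold rises to the matching
  t-quantile and masking is deliberately conservative.  Mid-transition
  points have held-out leverage of ~10 — a spike there is statistically
  indistinguishable from an EC50 shift and is intentionally left alone.
  At most 2 points of a 7-point series are ever masked.
* **Curve classes**: thresholds live in `classThresholds()` — efficacy
  floor 30%, high-efficacy split 80%, r² floor 0.9, plateau support
  within 15% of the fitted span.  These reconstruct the standard qHTS
  scheme; the exact thresholds of the original in-house software are not
  published, so all of them are configuration, not constants.
* **SOM** (`trainSom`): standard batch algorithm, Euclidean distance on
  raw 0/1 bits, Gaussian neighborhood with radius decaying geometrically
  from max(rows, cols)/2 to 0.5, codebook initialized from seeded random
  data rows.  Default grid side ⌈√(5√N)⌉ (the ~5√N-unit heuristic).
  Rectangular topology; hexagonal rendering is presentation-only.
* **Enrichment**: inactive compounds are imputed at log10(2 × top tested
  concentration).  The Welch t-test compares members against the
  *rest* of the library: including the members in the reference (the
  library-average reading) distorts the test size for small clusters
  (measured false-positive rates 0.03–0.08 instead of 0.05), while the
  leave-cluster-out form is calibrated.  `excludeSelf = FALSE` restores
  the library-average variant.  Clusters with fewer than 2 members are
  reported untestable rather than dropped.

# Validation strategy and problem sizes

The test suite checks every stage against an independent oracle:
hand-computed control statistics and normalization identities; noiseless
4PL identity recovery (≤0.1% relative error) and stochastic recovery
(median |Δlog EC50| ≤ 0.1 at 5% noise, 100 seeds; bias ≤ 0.05 on an EC50
grid kept ≥1.5 decades inside the tested range, where both plateaus are
sampled); simulator ground truth for gating and life-stage recovery
(within 3 binomial SDs); a 10⁴-draw permutation oracle and a 200-replicate
null calibration for cluster enrichment; and an end-to-end screen of 643
compounds with 83 planted actives, which must be recovered with ≥90%
sensitivity and ≥98% specificity from the day-7 GFP-area readout.  The
demo pipeline (`runScreen`) uses a 60-compound, 7-plate screen; these
sizes keep the full suite and the acceptance script comfortably
reproducible on a laptop while exercising every code path at full plate
geometry.

# Known limitations

* The population model is phenomenological; brood size, dwell times and
  carrying capacity are tuned for realism of scale, not fitted to data.
* Apparent EC50s include the hazard-compounding shift described above.
* COPAS gates are only meaningful relative to the flow model's units.
* The SOM gives no uncertainty on cluster membership, and enrichment
  p-values are not multiplicity-adjusted (the screen-level claim is about
  the *pattern* of enrichment; adjust with `p.adjust` if individual
  clusters must be called).
* Spatial plate-effect correction is out of scope.
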