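---
title: "Methods: edaphoclimatic suitability and climate-adaptation zoning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: edaphoclimatic suitability and climate-adaptation zoning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocoazone)
```

## The problem

Cocoa (*Theobroma cacao* L.) is a perennial crop sensitive to heat and to dry
spells. Under warming-and-drying climate projections for the Amazon basin, the
question for territorial planning is not just *where suitability is lost* but
*what to do where*: keep intensifying production, expand into newly viable
land, diversify toward hardier crops, progressively convert away from cocoa,
or not plant at all. `cocoazone` implements that full chain — habitat
suitability modelling under current and future climates, soil-by-infrastructure
suitability rules, and a decision-table zoning with area accounting — as
reusable, tested R functions, together with a synthetic-world generator that
provides a known ground truth for every stage.

## The suitability model

Presence-only occurrences are combined with *pseudo-absences* placed by the
Surface Range Envelope (SRE) strategy: the envelope of a presence set is the
per-variable interval between the $q$ and $1-q$ empirical quantiles of the
presence-cell values (default $q = 0.025$), and pseudo-absences are drawn
uniformly, without replacement, from cells falling *outside* the envelope on at
least one variable (presence cells are never eligible, avoiding contradictory
labels). The default of 300 pseudo-absences mirrors the reference study
design.

A small registry of heterogeneous learners is fitted to a stratified 75/25
train/test split:

* `sre` — envelope membership scored 1/0;
* `linear` — additive logistic regression on standardized predictors;
* `flexible` — a random-forest tree committee;
* `smooth` — a spline additive logistic model (GAM).

The registry defines a learner *contract* (fit on a labelled table, score new
rows in $[0,1]$, deterministic given a seed); four learners are enough to
exercise gating, averaging and projection, and more can be added behind the
same contract.

Each learner is evaluated on the held-out quarter by the True Skill Statistic,

$$\mathrm{TSS} = \max_{\tau}\;(\mathrm{sensitivity}(\tau) +
\mathrm{specificity}(\tau) - 1),$$

maximized exactly over all candidate thresholds — the midpoints of the sorted
unique scores plus one cut beyond each extreme, so the no-skill classifiers
are always candidates and TSS is never negative. AUC is the tie-corrected
rank statistic (the probability that a random presence outscores a random
pseudo-absence, ties counted half). Learners with test TSS above 0.7 enter
the ensemble; projected suitability is their unweighted arithmetic mean per
cell, which is bounded by the member scores and stays in $[0,1]$.

Future climates come as one stack per general circulation model (GCM). A
per-scenario *consensus* — the per-cell, per-variable arithmetic mean across
GCMs — is computed **before** projection, and the ensemble is then projected
onto the consensus stack. Nodata propagates pessimistically everywhere: a
cell is nodata in any product whenever any input is nodata there.

Predictor collinearity is reduced by a greedy filter: Pearson correlations
are computed over all complete raster cells; while any pair exceeds
$|r| = 0.7$, the member of the worst pair with the larger mean $|r|$ against
the remaining layers is dropped (ties drop the later name in canonical
`bio1..bio19` order), so the outcome is deterministic and independent of
layer insertion order. Constant layers are excluded up front. Because which
survivors emerge is a property of the data, the modelling pipeline accepts a
forced predictor set; its default is the six-variable set fixed in the
reference study design (mean diurnal range bio2, isothermality bio3, mean
temperatures of the wettest and driest quarters bio8/bio9, precipitation of
the driest month bio14, precipitation seasonality bio15). The filter is still
computed and recorded on every run, and its contract is tested independently.

## Soil and infrastructure rules

A cell's soil is suitable for cocoa iff

* its reference group is Acrisol, Fluvisol, Nitosol or Ferralsol;
* stoniness is low (a binary input attribute; the underlying gravel
  measurement is not modelled);
* it is eutrophic (≥ 50 % of cation-exchange capacity occupied by nutrient
  cations), or dystrophic **and** located in the *network* territory, the
  consolidated high-mobility part of the macro-zoning where infrastructure
  keeps fertilizer and transport costs viable;
* it is outside protected areas (indigenous lands and conservation units are
  merged into a single boolean layer, as the exclusion treats them
  identically).

The conjunction is order-independent, so the sequence in which criteria are
applied does not affect the mask. Soil groups beyond the four named ones are
unsuitable.

## Zoning

Continuous suitability is discretized at 20 % and 50 %: very low (VL) below
0.20, low-to-medium (LM) from 0.20 to 0.50 inclusive, medium-to-high (MH)
above 0.50. The published class wording ("> 50 %", "20 to 50 %", "< 20 %")
places both boundary values in LM, and that convention is implemented
literally.

Cocoa *prevalence* is a municipality attribute broadcast to cells: crops are
ranked within each municipality by production value (descending, ties sharing
the better rank); cocoa ranked first or second with positive production is
*dominant*, third or lower is *present*, zero production or no cocoa row is
*absent*.

The zoning decision table maps (current class, future class, prevalence) to a
zone, in order: MH→MH with dominance is *intensification*; MH→MH otherwise is
*expansion*; a future LM over a current LM/MH base with the crop present is
*diversification*; a future VL over that base is *conversion*; future VL with
the crop absent is *not recommended*. The published table leaves 13 of the 27
triples open; a completion rule resolves them conservatively — a future MH is
*expansion* only over an established (non-VL) current base and otherwise not
recommended, and a future LM or VL not matched above is not recommended (this
covers, in particular, cells that are VL in both periods regardless of
prevalence). Every firing of the completion rule is counted and reported so
its footprint stays auditable.

The current-conditions map uses a distinct single-column table
(`current_zoning()`) rather than substituting "future := current" into the
two-column table: under substitution the conversion zone could never be
non-empty under current conditions, yet the published current-column
accounting reports a non-zero conversion area, so the single-column reading
is the only consistent one. In it, a VL cell where cocoa is grown is a
*conversion* cell (the crop is present but the climate no longer supports
it), and VL/LM cells without cocoa are not recommended.

## Area accounting and change statistics

Zone areas are cell counts times the constant per-cell area. All synthetic
worlds use an equal-area projected grid, which keeps area arithmetic exact;
geodesic cell areas of geographic grids are out of scope. Percentages are
shares of the common suitable-soil mask, rounded **half away from zero** to
two decimals (`round_half_up()`), matching how the published table prints
them; `base::round()`'s half-to-even rule cannot reproduce those figures.

Derived change statistics are *percentage-point differences of shares*, never
relative percent changes. Combined shares (intensification + expansion,
diversification + conversion) are computed from summed areas *before*
rounding, then rounded; differences are taken between the rounded shares.
This composition reproduces every derived figure of the published accounting
simultaneously (e.g. an 81.48 % combined current share falling to 44.73 %
and 20.27 % under the two scenarios — drops of 36.75 and 61.21 points); the
alternative, summing already-rounded per-zone shares, disagrees with the
printed combined shares by a cent.

The analysis of variance over territories and scenarios is the classical
two-way fixed-effects decomposition without interaction (only the two main
effects are reported), delegated to `stats::aov`. The sampling unit is the
per-cell ensemble suitability on the suitable-soil mask (1 000 cells by
default), tagged with the cell's territory and the scenario. A factor with a
single level degenerates to the one-way analysis, and an all-constant
response reports $F = 0$, $p = 1$ for both factors, since a constant sample
carries no evidence of either effect.

## The synthetic world

The generator emulates the *structure* of the real inputs, not their
geography:

* **Climate.** 19 bioclimatic layers on a 120×120 equal-area grid of 25 km²
  cells are linear mixtures of 6 independent latent fields; smoothness comes
  from low-pass filtering white noise with a separable Gaussian kernel of
  width one tenth of the grid, giving the spatial autocorrelation that makes
  envelopes and suitability surfaces plausible. The six study variables are
  near-pure latents (mutually $|r| \le 0.7$), every other layer loads 0.9 on
  one latent, so the collinearity filter always has genuine work: some pairs
  exceed $|r| = 0.7$ by construction. Layers are scaled to plausible
  climatological means and spreads (e.g. bio9 ≈ 25 ± 2 °C, bio14 ≈ 30 ±
  15 mm).
* **Truth and occurrences.** True suitability is
  $\mathrm{plogis}(\beta_0 + \beta^\top z)$ in the standardized study
  variables. The default intercept $\beta_0 = -4$ and coefficient magnitudes
  (1.5–3.6) make high suitability a minority feature — roughly a quarter of
  the landscape above 0.5 — the way a crop with a well-defined niche looks;
  a diffuse surface would make presence samples nearly indistinguishable
  from background, which is neither realistic nor informative. Signs encode
  cocoa ecology (suitability falls with hotter dry seasons, rises with a
  wetter driest month), so warming/drying shifts reduce suitability. The 300
  occurrences are cells sampled without replacement with probability
  proportional to the truth.
* **Future scenarios.** Each of 5 pseudo-GCMs equals the current stack plus
  per-variable additive deltas plus zero-mean cell noise (default sd 0.25
  native units). The default deltas are the reported 2050 climate shifts for
  the region: bio2 +0.25/+0.31 °C, bio8 +1.45/+2.94 °C, bio9 +2.00/+2.67 °C,
  bio14 −9.0/−19.6 mm, bio15 +4.0/+7.7 CV units for the moderate (RCP4.5)
  and high (RCP8.5) forcing scenarios.
* **Context.** Soil attributes are thresholded smooth fields (reference
  groups 25/20/15/15/25 %, 40 % eutrophic, 70 % low-stony); territories are
  three contiguous longitudinal bands with smoothly wavering boundaries
  (network | border | zone); municipalities are the Voronoi cells of 30
  random seeds; each municipality gets cocoa plus four other perennial crops
  with production values engineered so all three prevalence classes occur;
  the protected mask covers the top decile of a smooth field (~10 % of
  cells).

Everything is bit-reproducible given (config, seed).

What passing tests on this world do **not** show: real occurrence data carry
sampling bias, spatial clustering and taxonomic error that the generator does
not emulate; real soils and territories are not smooth-field partitions; and
the real study's reported performance (TSS 0.82–0.88, AUC 0.91–0.99) and its
specific six surviving variables are data outcomes of the real rasters, not
reproducible synthetically. The synthetic world demonstrates that the
machinery recovers known structure under its stated assumptions, nothing
more.

## Numerical choices and degenerate inputs

* Suitability thresholds, the TSS gate (0.7), the collinearity bound (0.7),
  the train fraction (0.75), pseudo-absence count (300) and SRE trim
  (q = 0.025) are all exposed as arguments with those defaults.
* TSS threshold search is exact over midpoints plus the two beyond-extreme
  cuts; ties in the maximum keep the first (lowest) threshold.
* Fewer eligible cells than requested pseudo-absences returns all of them
  with an explicit shortfall flag; zero eligible cells is a hard error
  suggesting a smaller q.
* A train/test split that would empty either label in either half is an
  error, as is a single-class training set.
* Scoring rows with missing predictors yields NA rather than an error, and
  projection masks follow the pessimistic nodata rule.
* Rasters are exchanged as single-band ESRI ASCII grids with a JSON sidecar
  for category dictionaries; write∘read is the identity on values, grid
  geometry, nodata and categories. The working convention is row 1 =
  northernmost row, half-open cell intervals for point-in-cell lookup, and a
  lower-left grid origin in the files.

## Problem sizes

Unit tests run on 10–60 cell-wide grids; pipeline-level properties (ensemble
recovery, delta response, ANOVA) use the full default 120×120 world across
three seeds, which completes in well under a minute per seed on one core.
The acceptance script runs one full default world plus the published-table
replay.

## Known limitations

* The learner registry intentionally ships 4 of the 10 algorithm families
  used in the reference study; the ensemble contract, not the roster, is the
  tested surface.
* A single seeded split evaluates each learner; an optional replicated-split
  protocol would tighten TSS estimates but is not part of the published
  design.
* Prevalence is a municipality-level label broadcast to cells; sub-municipal
  production heterogeneity is not represented.
* No reprojection: all layers must already share one grid.
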