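---
title: "Methods: assessing marginal-land restoration for wild-bee pollination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assessing marginal-land restoration for wild-bee pollination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`beescape` implements a complete assessment chain for the question: *how
much can restoring only marginal agricultural land improve wild-bee
pollination provision and natural-habitat coverage?* This vignette is the
package's own account of the models it implements, the parameters that
matter, the numerical choices taken where the design was genuinely open,
and what the synthetic test bed does and does not demonstrate.

## The spatial data model

All computation happens on a regular 30-m grid in a projected metric
coordinate system, with row 1 as the northernmost row and a cell area of
0.09 ha that anchors all raster area accounting. Maps carry a 2-km
analysis buffer: a border ring that participates in every kernel and
focal computation (so that bees forage across the territory edge and
windows near the border are not artificially habitat-poor) but is
excluded from every reported statistic. The buffer is carried as extra
rows and columns flagged by a core mask rather than as geometry, so focal
and kernel operators need no special casing.

Field polygons are vector objects; rasterization assigns a cell to the
field containing its center. Cell centers sit at half-resolution offsets,
so for fields whose boundaries follow cell edges (as all generated fields
do) center containment is exact and an independent point-in-polygon count
reproduces it cell for cell. Area bookkeeping is deliberately two-track:
raster cell counts drive the supply model, while all reported restored
areas come from vector geometry. This matters most for flower strips: a
5-m strip cannot be represented at 30-m cells, so strip cells are burned
to the strip class for the supply model (over-representing their floral
contribution — a known bias, see Limitations) while ledgers carry the
exact strip polygons' areas.

Because no full-featured geospatial stack is assumed, the package carries
its own small geometry kernel (shoelace areas, ray-casting containment,
Sutherland–Hodgman clipping, segment distances) and reads and writes
plain-text formats: ESRI ASCII grids for rasters, GeoJSON for field
polygons, CSV for class, guild, history and dependency tables. Round
trips preserve codes, flags and coordinates.

## Detecting marginal land

**Abandonment.** A field is abandoned when it was cultivated in none of
the final `window = 5` consecutive history years. Five years is long
enough that routine fallow does not trigger a false positive. The rule is
deliberately insensitive to anything before the terminal window. Fields
whose raster cells are already dominated (majority) by a natural class
are excluded: regrown old-field vegetation is habitat already, and
"restoring" it would double-count.

**Degradation.** Annual NDVI is regressed on year per pixel (ordinary
least squares; two-sided p from the t statistic on n − 2 df; at least 3
years required). Three filters follow, in order:

1. *Edge erosion*: one full cell ring (the 25-m default rounded up to
   whole cells at 30-m resolution) is eroded inward from each field
   boundary, because edge pixels mix in roads, hedges and bare margins.
2. *Significance*: slope < 0 and p ≤ 0.05, boundary inclusive.
3. *Patch filter*: 8-connected components under 0.15 ha are dropped —
   restoring scattered single pixels inside a working field is
   impractical for machinery. Connectivity is configurable;
   8-connectivity is the conservative choice (retains more patches).

A field is degraded when surviving patches cover ≥ 30% of its *full*
(pre-erosion) area; the whole field is then treated as potentially
degraded, otherwise its flagged pixels contribute nothing downstream.
Lowering the p-threshold or raising the minimum patch size can only
shrink the degraded set (tested as a monotonicity property).

Two numerical conventions are worth stating. A zero-variance
(numerically constant) NDVI series gets p = 1 — a pristine field is never
declared degraded by a division-by-zero accident — while a residual-free
sloped line gets p = 0. The guard is scale-aware (residual SD below
1e-10 of the mean absolute level), because an analytically constant
series accumulates floating-point residuals that would otherwise produce
an arbitrary t statistic. No multiple-testing correction is applied to
the per-pixel p-values; the patch-size and 30%-of-field rules are the
de-facto guards against isolated false positives, and users comparing
individual pixels should be aware of this.

## The pollination-supply model

Supply is a Lonsdorf-type source–sink kernel model, computed per taxon
and season directly from the class table:

* *Nesting*: `HN(x) = max_j class_nest_j(x) × pref_j` over substrates
  (ground, cavity, wood in the shipped tables). The max, not the sum: a
  bee needs one suitable substrate.
* *Floral*: `HF(x, season)` is a class lookup; seasonal activity weights
  are applied at the end, not here.
* *Foraging*: every average is a distance-weighted mean with exponential
  kernel `w(d) = exp(−d/α)`, truncated where the relative weight falls
  below 1e-3 (radius ≈ 6.9 α; configurable — the truncation error is
  below the 1e-9 tolerance at which the implementation is tested against
  a brute-force double loop). Weighted means are normalized per cell over
  in-extent cells only, so border cells average over what actually
  exists.
* *Two passes*: a nest cell's source strength is `P = HN × favg(HF)`;
  the abundance visiting a cell is `A = favg(P)`, scaled by the taxon's
  seasonal activity. The landscape index is the unweighted mean over the
  guild — whether the original software weighted taxa is not documented,
  so equal weights are the default and the guild table is the knob.

Convolutions are zero-padded FFTs (`stats::fft`), with the denominator
(kernel mass over in-extent cells) computed once per kernel and cached.
On grids up to 21 × 21 the FFT path agrees with an explicit double loop
to better than 1e-9; the same code path runs the full landscapes.

The shipped ten-genus guild table (Bombus, Lasioglossum, Andrena,
Halictus, Megachile, Ceratina, Hylaeus, Osmia, Agapostemon, Melissodes;
foraging distances 100–1500 m) and the class suitability table are
explicitly illustrative: values follow the literature's relative
{0, 0.25, 0.5, 0.75, 1} convention but are not an expert-elicited
parameterization for any specific region. Both are CSV data, not code.
Only the summer abundance map feeds the assessment; spring machinery
exists but is untested beyond unit level.

## Demand, mismatch and the S/D comparison

Field demand is `area_ha × mean-over-years(weight(main crop))`, with
uncultivated years contributing zero (a fallow field demands no
pollination that year — a convention, exposed through the history table)
and marginal fields zeroed outright. The Klein-style class weights
(essential 0.95, great 0.65, modest 0.25, little 0.05, none 0) are class
midpoints shipped as an editable table; because the assessment min–max
scales demand, every headline metric is invariant to positive rescaling
of these weights (tested).

The bivariate classification computes tertiles of per-field supply and
demand independently (sample quantiles with linear interpolation,
`type = 7`; values ≤ q1 are low, ≤ q2 intermediate; ties therefore fall
toward the lower class; degenerate inputs with fewer than three distinct
values all land in "low" with a warning). Being rank-based, the hotspot
set — low supply with intermediate-to-high demand — is invariant under
any strictly monotone transform of either axis.

The S/D ratio divides min–max-scaled supply by min–max-scaled demand
where raw demand is positive, and is averaged on a 1-km² grid anchored at
the territory's north-west corner (the anchor is a convention; nothing
downstream depends on sub-kilometer alignment). Blocks with < 25%
agricultural overlap are dropped, as are retained blocks containing no
demand-positive cell (they have no defined ratio; their count is
reported). Scaling is per scenario map. That choice follows the original
procedure, but it means the percentage of blocks with mean S/D ≥ 1 is a
*relative* comparison device, not an absolute provision measure, and it
is not mathematically guaranteed to rise when supply rises everywhere
(the scenario's own maximum rescales the map). The tested invariant is
the honest one: adding floral resources raises *raw* supply pointwise.

Natural cover is a two-stage statistic, faithful to the original
sequence: first the per-pixel percentage of natural cells within a 1-km
circular window (buffer cells count as neighbours), then the mean of
that raster within 1 km of each field centroid. Priority classes cut at
5, 10 and 20% with left-closed intervals ("5% or more" is intermediate —
where the source material's Methods and figure caption disagree on the
boundary, the Methods wording is used).

## Restoration scenarios

All five scenarios are pure LULC transformations — same grid, same class
table, only codes change — plus a ledger. Strips use the longest
exterior-ring edge (ties broken by ring order), buffered 5 m toward the
interior and clipped to the field (exact for convex fields; non-convex
fields keep the unclipped rectangle with a warning — generated fields
are rectangles, so this path never triggers there). Reforested cells take
the forest class's suitabilities immediately; no succession lag is
modeled.

The mixed strategy is the one algorithmic scenario: priority fields are
baseline hotspots with < 5% surrounding natural cover; candidates are the
marginal fields and potential strips intersecting the union of 1-km
buffers around priority-field centroids; all candidate marginal fields
are reforested; and candidate strips are removed one at a time — *closest
to a marginal field first*, on the rationale that a strip beside a future
forest patch is redundant — until the vector-accounted total fits the 3%
-of-territory cap. The sweep direction was an open reading; closest-first
is implemented and tested with a hand-traced three-strip case. If the
candidate reforested area alone exceeds the cap, all strips are removed
and a warning is raised rather than silently dropping fields the
selection rule says to restore. The 3% target applies to the territory
(buffer excluded).

## The synthetic landscape and what it shows

The generator emulates an intensive corn/soy county of the St. Lawrence
lowland type, and its defaults are the study conditions under which the
package is tested:

* ~60% of the territory agricultural, ~20% forest, 2% wetland, 15%
  built-up, remainder old field; cover types are assigned to parcels by
  smooth random "nature" and "urban" blob scores, so natural area is
  spatially clustered and open crop plains with very low surrounding
  cover exist — the situation the priority ranking is about. Assignment
  is stratified between territory and buffer, so realized core fractions
  track the targets to within one parcel (tested at ±5 points).
* Fields come from a two-phase partition: chunky blocks (~10 field
  areas) cut recursively, then sliced into parallel long lots spanning
  the block's short side, with lot areas drawn log-normally at
  6.2 ± 7.1 ha. The resulting elongated fields (median aspect ratio ≈ 5)
  reproduce the long-lot ("rang") cadastre of the emulated region — and
  that elongation is load-bearing: total potential strip area scales
  with summed longest-edge length, and near-square fields would
  understate it by half.
* Cultivation histories draw one main crop per field-year from a mix
  dominated by corn and soy (~76%) with a pollinator-dependent minority.
  Abandonment is planted as a spatial cluster seeded at the field with
  the highest nature score — land abandonment concentrates on marginal
  soils near existing natural areas, not mid-plain — with the terminal
  5 years uncultivated. Degraded fields are planted in moderately sized
  fields (whole very large fields rarely degrade wholesale) as a
  contiguous block covering 60% of cells with a linear NDVI decline of
  −0.01/yr over 22 years under Gaussian noise (SD 0.02), sized so ≥ 30%
  of the full field area still shows the trend after edge erosion.
* NDVI is generated annually; the upstream satellite compositing
  (June–September medians, cloud masking) is out of scope, so the annual
  value stands in for "median NDVI across a growing season".
* Randomness is staged: one seed drives parcel/cover/history draws and a
  fixed offset of it drives the NDVI noise, making bundles byte-identical
  per seed. (A per-cell keyed stream would make partial regeneration
  order-independent, but base R lacks a counter-based RNG; whole-bundle
  determinism is the property the tests rely on.)

What passing tests show: the detection stages recover planted truth
(abandonment exactly; degradation with ≥ 90% sensitivity and ≤ 5% false
positives under the stated noise), the supply model equals its
brute-force definition, ledgers are arithmetically exact, and the
assessment invariants hold end to end. What they do not show: anything
about a real region. Real cultivation records carry reporting noise the
generator omits; real NDVI declines are neither linear nor spatially
crisp; real land-cover suitabilities require expert parameterization;
and rectangular fields sidestep every polygon pathology (slivers,
holes, shared multi-part parcels).

## Problem sizes and runtime

The reference configuration is a 6 × 6-km territory (200 × 200 core
cells plus a 67-cell buffer ring, ~330 fields) — large enough for ~26
retained 1-km² blocks and populated priority classes, small enough that
the full five-scenario pipeline with a ten-taxon guild runs in well under
a minute on one CPU. Oracle-equivalence tests run on ≤ 21 × 21 grids
where double loops are exact and fast; detection-recovery tests use a
~3-km landscape with ~100 fields. These sizes are choices about test
economy, not model limits; the FFT path scales to county-size rasters.

## Known limitations

* Burned strip cells over-represent 5-m strips in the 30-m supply
  raster (a 30-m cell of flower-strip class where 5 m exist). Ledgers
  are unaffected; supply gains from strip scenarios should be read as
  optimistic. A finer grid is the remedy when it matters.
* Per-scenario min–max scaling makes S/D comparisons relative (see
  above); compare trajectories, not absolute percentages.
* Relative abundance only: the model cannot say whether supply *meets*
  demand, only whether a scenario raises supply relative to demand more
  than another.
* Causes of NDVI decline (drought, pests, management) are not
  attributed; "degraded" means "persistently declining vigor".
* Managed honey-bee colonies, pesticide effects, succession lags,
  economics and stakeholder constraints are all out of scope.
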