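---
title: "Assessing prairie pothole wetland condition with the IPCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing prairie pothole wetland condition with the IPCI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipci)
```

## The assessment problem

Prairie pothole wetlands are small depressional wetlands embedded in
grassland, either never-tilled native prairie or former cropland reseeded
to grass. Their plant communities integrate the disturbance history of
the wetland and its catchment: undisturbed potholes support diverse
communities of conservative native perennials, while disturbed ones lose
species and become dominated by short-lived, introduced, and invasive
perennial plants (smooth brome, Kentucky bluegrass, reed canarygrass,
hybrid cattail). A multi-metric index over the plant species list
therefore serves as a practical condition measure that a field crew can
collect in a single visit, and a spatially balanced probability sample of
wetlands lets a monitoring program report the share of its resource in
each condition class.

This package implements the whole chain: site selection, the survey data
model, the Index of Plant Community Integrity (IPCI), and the unweighted
summaries — plus a synthetic-data generator rich enough to exercise every
stage.

## The index

Two hydrologic classes are assessed: *temporarily ponded* wetlands with
two concentric vegetation zones (low prairie outside, wet meadow in the
center) and *seasonally ponded* wetlands with a third, central
shallow-marsh zone. Surveys place 8 quadrats of 1 m² in the low-prairie
zone, 7 in the wet meadow, and 5 in the shallow marsh; species seen
between quadrats are recorded with their zone and count fully toward the
index. Quadrats are centered in the interior/exterior zones (equal
angular spacing on the zone's mid-radius) and spiral inward through the
central zone; when open water occupies part of the central zone its five
quadrats are split between open-water and emergent placements by
largest-remainder rounding. The layout geometry is a planning and
visualization convenience — no metric uses it, and quadrat spacing is
irrelevant to scoring.

Nine presence/absence metrics are computed from the wetland species list
(all zones, in- and between-quadrat records pooled) and the wet-meadow
species list:

1. species richness of native perennials,
2. genera of native perennials,
3. native grass and grass-like (sedge/rush) species,
4. percent of annual, biennial, and introduced species (one decimal),
5. native perennial species in the wet-meadow zone,
6. species with C-value ≥ 5,
7. wet-meadow species with C-value ≥ 4,
8. average C-value (two decimals),
9. Floristic Quality Index, FQI = C̄·√N (two decimals), with C̄ the mean
   C over natives carrying a C-value and N the count of *all* native
   species.

Each metric maps to an ordinal score of 0, 4, 7, or 11 through
class-specific value ranges, and the nine scores sum to a 0–99 total.
Seasonally ponded totals fall into five categories (Very poor 0–19, Poor
20–39, Fair 40–59, Good 60–79, Very good 80–99); temporarily ponded
wetlands use three (Poor 0–33, Fair 34–66, Good 67–99) with no Very
poor/Very good classes. Both tables ship as a versioned YAML file
(`system.file("extdata", "ipci_scoring.yaml", package = "ipci")`) so that
regional re-calibration is a config edit.

### Scoring and rounding policy

The published value ranges are printed at fixed precision, which leaves
apparent gaps (35.0 vs 35.1; 22.99 vs 23.00). `score_metric()` therefore
rounds the metric value **half away from zero** to the metric's printed
precision before range lookup; after rounding, every achievable value
lands in exactly one range, and the test suite verifies this by
exhaustive grid scan against an independently hand-encoded copy of the
tables. The FQI is computed from the *unrounded* mean C, rounding only
the final value, to avoid double-rounding drift at the 23.00 boundary.

### Edge-case policies

* **Unknown species** (not in the trait table) count in the total-species
  denominator of metric 4 and nowhere else, with a warning. Field lists
  routinely contain unresolvable taxa; dropping them silently would bias
  the percentage metric downward.
* **Natives without a C-value** count in the richness metrics (1, 2, 3,
  5, and the √N of the FQI) but not in the C-threshold counts or the
  mean C.
* **The annual/biennial/introduced set is a union**: an introduced annual
  counts once.
* **Empty surveys** score 0 on all nine metrics and fall in the lowest
  category for their class. Without this rule a species-free wetland
  would take the top score on metric 4 (0% of nothing), which inverts
  the metric's meaning.
* **Between-quadrat records carry a zone label**, so the two wet-meadow
  metrics include them; without zone attribution those metrics would be
  undefined for species found outside quadrats.

## Site selection

`grts_draw()` implements equal-probability generalized random
tessellation stratified (GRTS) sampling over a point frame, stratified
(as in a two-year, two-class design) with independent draws per stratum.
Each point receives a hierarchical address: the bounding box is split
recursively into quadrants, one base-4 digit per level, and each cell's
digits are remapped through a random permutation drawn from a
counter-based generator keyed by `(seed, level, cell)` — draws are
reproducible and independent of evaluation order, and no global RNG
state is touched. Address depth starts at 8 levels and deepens (to at
most 12) until addresses are unique, with `site_id` breaking residual
ties.

Selection takes a systematic sample with a seeded random start along the
randomized address order; it is this order that spreads the sample
evenly over space. The selected sites are then arranged in *reverse
hierarchical order* (reversed address digits, lexicographic), whose
defining property is that every prefix of the ordered sample is itself
spatially balanced: the first `n_primary` sites form the designed
sample, the following `n_alternate` are spares, and `replace_site()`
promotes the next unused alternate from the same stratum, so the active
sample stays balanced as unsampleable sites (misclassified, inaccessible)
are swapped out. Taking the systematic sample directly along the
*reversed* order — a tempting shortcut — destroys the balance: in our
Voronoi diagnostic it performs no better than simple random sampling,
while the construction used here cuts the Voronoi cell-count variance
to roughly a third of the simple-random-sampling value.

`spatial_balance_variance()` is the diagnostic: each frame point is
assigned to its nearest sampled point and the variance of the resulting
cell counts is reported; lower is more even. Design-based variance
estimation and unequal inclusion probabilities are out of scope — the
reporting is unweighted category counts by design.

## The synthetic-data model

The generator exists so that every stage — file I/O, metric logic,
scoring, sampling, summaries — can be exercised on data with the
statistical structure the analysis assumes.

**Species pool** (`generate_species_pool()`): by default 120 native
perennials, 25 short-lived (annual/biennial) natives, and 35 introduced
species, from a genus pool sized at 0.65 genera per species so congeners
exist. C-values are drawn as 1 + Binomial(9, p) with mean 5.0 for native
perennials and 2.4 for short-lived natives (weedy natives are
disturbance-tolerant, low-C); introduced species carry none. Growth
forms make natives mostly forbs with a ~35% grass/sedge contingent;
introduced species are grass-heavy, mirroring the region's invasive
brome/bluegrass/canarygrass problem. Each species gets zone-affinity
weights concentrated on a preferred zone, with introduced perennials
leaning toward the wetter interior zones the way cattail and
canarygrass do.

**Disturbance gradient** (`gradient_config()`): a single disturbance
level $d \in [0,1]$ drives Bernoulli occupancy per species per wetland.
Native-perennial occupancy decays from 0.45 at $d=0$ toward 0.04 at
$d=1$, with an exponent increasing in C/10 so conservative species
disappear first; short-lived natives rise 0.25→0.50, non-invasive
introduced species 0.10→0.65, and introduced perennials (the invasive
mimics) 0.25→0.95. A per-site log-normal multiplier (SD 0.15 on the log
scale) adds between-wetland heterogeneity, and reseeded-grassland sites
experience the gradient at $d + 0.30$, encoding the legacy of
cultivation. These values were fixed once, from the qualitative pattern
the index is built on: at $d=0$ a seasonal wetland supports ≈55–60
native perennials across ≈40 genera with mean C ≈ 5 (comfortably in the
top scoring classes), and at $d=1$ it holds a handful of natives among
a mostly short-lived/introduced flora (bottom classes). The test suite
confirms the calibration behaviorally: pristine seasonal replicates
classify Good/Very good and fully degraded ones Poor/Very poor in well
over 80% of runs, mean totals decrease monotonically in $d$, and the
native/reseeded strata order correctly.

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: species inclusion is independent
Bernoulli (no co-occurrence or nestedness structure), there is no
hydrologic or interannual dynamics, no seed-bank memory, no observer
error or misidentification, and synthetic names carry none of the
taxonomic ambiguity of real field lists beyond the unknown-species code
path. The generator demonstrates that the pipeline recovers a gradient
it was given; it cannot validate the index against real degradation.

## Numerical and design choices

* Rounding is half-away-from-zero everywhere a value meets a printed
  range (`round_half_up()`), with a 10⁻⁹-scale guard against binary
  representation error.
* Largest-remainder (Hamilton) apportionment is used wherever an integer
  total is split proportionally (open-water quadrats, stratum sizes);
  remainder ties resolve to the earlier category, i.e. the emergent
  placement and the first-listed stratum.
* Scoring-range containment uses an epsilon of half the metric's
  precision step × 10⁻⁶, so grid values sitting exactly on printed
  boundaries resolve deterministically.
* Hash-based uniform deviates drive the GRTS random start and layout
  start angles, keeping those functions pure; the synthetic generators
  use R's RNG under a save/restore wrapper (`with_seed()`), so calling
  them never perturbs the session's random stream.
* Simulation sizes in the checks — 100-replicate balance comparisons on
  1000-point frames, 200 replicates at the gradient endpoints, 100 at
  interior points — were chosen so that the asserted orderings hold with
  wide margins under the fixed seeds while the whole suite stays quick
  to run.

## Limitations

The index here is the established prairie-pothole formulation; its
metrics and ranges are not expected to transfer to other wetland types
without re-calibration (edit the YAML, refit categories). Metrics are
presence/absence only — abundance-weighted variants are deliberately out
of scope, as is design-based variance estimation for the category
percentages. The synthetic-data caveats above apply to any conclusion
drawn from simulated studies.
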