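# ipci

Condition assessment of prairie pothole wetlands from vegetation surveys.

Prairie pothole wetlands — the small, shallow depressional wetlands of the
northern Great Plains — are assessed in the field by surveying the plant
community of each concentric vegetation zone (an exterior low-prairie zone,
a wet-meadow zone, and, in seasonally ponded wetlands, a central
shallow-marsh zone) with 1-m² quadrats, and scoring the species list with a
multi-metric biotic index. This package implements that workflow end to
end for wetland scientists and monitoring programs:

* **Index of Plant Community Integrity (IPCI)** — nine presence/absence
  plant-community metrics, each scored on an ordinal 0/4/7/11 scale from
  class-specific value ranges and summed to a 0–99 total, which maps to a
  condition category (*Very poor* … *Very good*; temporarily ponded
  wetlands use only *Poor*/*Fair*/*Good*).
* **Floristic quality** — native species carry a coefficient of
  conservatism C ∈ {0..10}; three metrics use C directly and one uses the
  Floristic Quality Index, FQI = C̄ · √N, where C̄ is the mean C-value of
  the natives carrying one and N the number of native species.
* **GRTS site selection** — stratified, spatially balanced sampling of a
  wetland point frame by generalized random tessellation stratified
  sampling, with primary/alternate designation and logged replacement of
  unsampleable sites.
* **Survey data model** — zoned quadrat layouts (8 low-prairie / 7
  wet-meadow / 5 shallow-marsh quadrats), between-quadrat species records,
  delimited-text readers and writers for trait tables, surveys, frames,
  and draws.
* **Unweighted condition summaries** — number and percent of wetlands per
  category, mean ± SD of total scores, overall or by stratum.
* **Synthetic data** — a disturbance-gradient community generator that
  emulates degradation from diverse, high-C native-perennial communities
  toward short-lived, introduced, and invasive-perennial dominance, so the
  whole pipeline is testable without field data.

The nine metrics: native-perennial species richness; native-perennial
genera; native grass and grass-like species; percent annual, biennial, and
introduced species; wet-meadow native perennials; species with C ≥ 5;
wet-meadow species with C ≥ 4; average C-value; and FQI. Scoring ranges
and category boundaries ship as an editable YAML config
(`inst/extdata/ipci_scoring.yaml`), so adapting the index to another
region is a config edit.

## Worked example

Four species in a seasonally ponded wetland — two native perennials
(C = 8 and 5), one introduced perennial grass, and one native annual
observed between quadrats:

```r
library(ipci)

traits <- trait_table(data.frame(
  name        = c("Andropogon gerardii", "Symphyotrichum ericoides",
                  "Bromus inermis", "Chenopodium album"),
  genus       = "",
  nativity    = c("native", "native", "introduced", "native"),
  lifespan    = c("perennial", "perennial", "perennial", "annual"),
  growth_form = c("grass", "forb", "grass", "forb"),
  c_value     = c(8L, 5L, NA, 1L)))

survey <- wetland_survey("pothole-17", "seasonally_ponded",
  observations = data.frame(
    species = c("Andropogon gerardii", "Symphyotrichum ericoides",
                "Bromus inermis", "Chenopodium album"),
    zone    = c("wet_meadow", "low_prairie", "low_prairie", "wet_meadow"),
    quadrat = c("1", "2", "3", "BETWEEN")))

assess(survey, traits)
#> IPCI assessment for pothole-17 (seasonally_ponded)
#>                          metric value score
#>       richness_native_perennial  2.00     0
#>         genera_native_perennial  2.00     0
#>          native_grass_grasslike  1.00     0
#>  pct_annual_biennial_introduced 50.00     0
#>      wetmeadow_native_perennial  1.00     0
#>                    count_c_ge_5  2.00     0
#>          wetmeadow_count_c_ge_4  1.00     0
#>                           avg_c  4.67    11
#>                             fqi  8.08     0
#> Total: 11 / 99  ->  Very poor
```

Reading the output: the wetland supports only two native perennials, half
its flora is short-lived or introduced, and its FQI of 8.08
(= 4.6667 · √3) sits in the lowest scoring class — every metric scores 0
except the average C-value of 4.67, which exceeds the 3.53 floor of the
top class for seasonal wetlands. The total of 11 falls in the 0–19 range:
*Very poor* condition.

A full pipeline is three more calls:

```r
frame <- generate_site_frame(400, c(seasonal_y1 = 0.5, seasonal_y2 = 0.5), seed = 1)
draw  <- grts_draw(frame, n_primary = 100, n_alternate = 25, seed = 1)
pool  <- generate_species_pool(species_pool_config(seed = 1))
surveys <- lapply(active_sites(draw)$site_id[1:50], function(id)
  generate_survey(pool, id, "seasonally_ponded", gradient = gradient_config(d = 0.3),
                  seed = match(id, frame$site_id)))
results <- assess_all(surveys, pool)
summarize_condition(results, group_by = "grassland_type")
```

## Documentation

The methods vignette (`vignettes/wetland-condition-assessment.Rmd`)
describes the index, the scoring and rounding policies, the sampling
design, the synthetic-data model and its limitations.
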