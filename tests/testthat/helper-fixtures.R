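# Shared fixtures: a small trait table, the four-species worked-example
# survey, and an independently hand-encoded scoring oracle used to
# cross-check the packaged YAML scoring configuration.

make_test_traits <- function() {
  trait_table(data.frame(
    name = c("Alpha uno", "Beta duo", "Gamma tres", "Delta quattro",
             "Poa pratensis", "Cirsium arvense", "Typha × glauca"),
    genus = "",
    nativity = c("native", "native", "introduced", "native",
                 "introduced", "introduced", "introduced"),
    lifespan = c("perennial", "perennial", "perennial", "annual",
                 "perennial", "perennial", "perennial"),
    growth_form = c("grass", "forb", "grass", "forb",
                    "grass", "forb", "grass_like"),
    c_value = c(8L, 5L, NA, 1L, NA, NA, NA)),
    provenance = "test fixture")
}

# seasonal survey: A(native perennial grass C=8, wet meadow),
# B(native perennial forb C=5, low prairie), C(introduced perennial
# grass, low prairie), D(native annual forb C=1, wet meadow, between
# quadrats). Hand enumeration gives metrics
# (2, 2, 1, 50.0, 1, 2, 1, 4.67, 8.08): avg C = (8+5+1)/3 = 4.6667,
# FQI = 4.6667 * sqrt(3) = 8.0829.
make_example_survey <- function() {
  wetland_survey("EX1", "seasonally_ponded", "native", 2020L,
                 observations = data.frame(
                   species = c("Alpha uno", "Beta duo", "Gamma tres", "Delta quattro"),
                   zone = c("wet_meadow", "low_prairie", "low_prairie", "wet_meadow"),
                   quadrat = c("1", "2", "3", "BETWEEN")))
}

EXAMPLE_METRICS <- c(richness_native_perennial = 2, genera_native_perennial = 2,
                     native_grass_grasslike = 1, pct_annual_biennial_introduced = 50.0,
                     wetmeadow_native_perennial = 1, count_c_ge_5 = 2,
                     wetmeadow_count_c_ge_4 = 1, avg_c = 4.67, fqi = 8.08)

# ---------------------------------------------------------------------
# Independent scoring oracle: the printed value ranges re-encoded by
# hand in a different representation (lower bounds of the 4/7/11
# classes, plus a reversed flag for the percentage metric, which scores
# high when the value is low). Scores come from a brute-force scan.
ORACLE <- list(
  temporarily_ponded = list(
    richness_native_perennial      = list(lb = c(17, 24, 41),          rev = FALSE, prec = 0),
    genera_native_perennial        = list(lb = c(12, 20, 27),          rev = FALSE, prec = 0),
    native_grass_grasslike         = list(lb = c(9, 11, 16),           rev = FALSE, prec = 0),
    pct_annual_biennial_introduced = list(lb = c(41.0, 35.0, 27.0),    rev = TRUE,  prec = 1),
    wetmeadow_native_perennial     = list(lb = c(8, 11, 14),           rev = FALSE, prec = 0),
    count_c_ge_5                   = list(lb = c(5, 12, 17),           rev = FALSE, prec = 0),
    wetmeadow_count_c_ge_4         = list(lb = c(4, 10, 13),           rev = FALSE, prec = 0),
    avg_c                          = list(lb = c(2.51, 3.58, 4.59),    rev = FALSE, prec = 2),
    fqi                            = list(lb = c(13.61, 21.71, 27.21), rev = FALSE, prec = 2)),
  seasonally_ponded = list(
    richness_native_perennial      = list(lb = c(20, 32, 42),          rev = FALSE, prec = 0),
    genera_native_perennial        = list(lb = c(15, 25, 33),          rev = FALSE, prec = 0),
    native_grass_grasslike         = list(lb = c(7, 11, 18),           rev = FALSE, prec = 0),
    pct_annual_biennial_introduced = list(lb = c(41.0, 30.7, 21.0),    rev = TRUE,  prec = 1),
    wetmeadow_native_perennial     = list(lb = c(9, 17, 25),           rev = FALSE, prec = 0),
    count_c_ge_5                   = list(lb = c(8, 18, 27),           rev = FALSE, prec = 0),
    wetmeadow_count_c_ge_4         = list(lb = c(5, 10, 17),           rev = FALSE, prec = 0),
    avg_c                          = list(lb = c(2.61, 3.13, 3.53),    rev = FALSE, prec = 2),
    fqi                            = list(lb = c(10.01, 16.12, 23.00), rev = FALSE, prec = 2))
)

# for rev = FALSE, lb are the inclusive floors of scores 4, 7, 11;
# for rev = TRUE, lb are the inclusive ceilings of scores 4, 7, 11
# (value <= 27.0 scores 11, <= 35.0 scores 7, <= 41.0 scores 4, else 0)
oracle_score <- function(metric_id, value, hydro_class) {
  o <- ORACLE[[hydro_class]][[metric_id]]
  v <- round_half_up(value, o$prec)
  eps <- 1e-9
  if (o$rev) {
    if (v <= o$lb[3] + eps) 11L
    else if (v <= o$lb[2] + eps) 7L
    else if (v <= o$lb[1] + eps) 4L
    else 0L
  } else {
    if (v >= o$lb[3] - eps) 11L
    else if (v >= o$lb[2] - eps) 7L
    else if (v >= o$lb[1] - eps) 4L
    else 0L
  }
}

# hand-encoded category boundaries (worst first)
ORACLE_CATEGORIES <- list(
  temporarily_ponded = data.frame(
    category = c("Poor", "Fair", "Good"),
    min = c(0, 34, 67), max = c(33, 66, 99)),
  seasonally_ponded = data.frame(
    category = c("Very poor", "Poor", "Fair", "Good", "Very good"),
    min = c(0, 20, 40, 60, 80), max = c(19, 39, 59, 79, 99))
)

# value grids spanning each metric's achievable domain at its printed
# precision
oracle_grid <- function(metric_id) {
  switch(metric_id,
         pct_annual_biennial_introduced = seq(0, 100, by = 0.1),
         avg_c = seq(0, 10, by = 0.01),
         fqi = seq(0, 40, by = 0.01),
         0:100)
}

# simple random sample drawn reproducibly, for balance comparisons
srs_ids <- function(frame, n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample(frame$site_id, n)
}
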