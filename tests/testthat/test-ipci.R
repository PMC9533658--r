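cfg <- load_scoring_config()

test_that("the four-species worked example reproduces the hand enumeration", {
  s <- make_example_survey()
  m <- compute_metrics(s, make_test_traits())
  expect_equal(m, EXAMPLE_METRICS)
  r <- assess(s, make_test_traits(), cfg)
  expect_equal(unname(r$scores), c(0, 0, 0, 0, 0, 0, 0, 11, 0))
  expect_equal(r$total, 11L)
  expect_equal(r$category, "Very poor")
})

test_that("degenerate surveys score sensibly", {
  tr <- make_test_traits()
  empty_s <- wetland_survey("E1", "seasonally_ponded")
  m <- compute_metrics(empty_s, tr)
  expect_equal(unname(m), rep(0, 9))
  expect_equal(assess(empty_s, tr, cfg)$category, "Very poor")
  empty_t <- wetland_survey("E2", "temporarily_ponded")
  rt <- assess(empty_t, tr, cfg)
  expect_equal(rt$total, 0L)
  expect_equal(rt$category, "Poor") # the temporary class has no Very poor

  # one native perennial grass with C = 10 in the wet meadow
  tr1 <- trait_table(data.frame(name = "Solus optimus", genus = "Solus",
                                nativity = "native", lifespan = "perennial",
                                growth_form = "grass", c_value = 10L))
  s1 <- wetland_survey("E3", "seasonally_ponded", observations = data.frame(
    species = "Solus optimus", zone = "wet_meadow", quadrat = "1"))
  expect_equal(unname(compute_metrics(s1, tr1)),
               c(1, 1, 1, 0, 1, 1, 1, 10, 10))
})

test_that("fqi multiplies mean C by the square root of native richness", {
  expect_equal(fqi(4.0, 16), 16)
  expect_equal(fqi(3.7, 0), 0)
  expect_equal(fqi(5.75, 16), 23.00)
  expect_equal(score_metric("fqi", fqi(5.75, 16), "seasonally_ponded", cfg), 11)
  expect_error(fqi(-1, 4), "non-negative")
})

test_that("unknown species count only in the percentage denominator", {
  tr <- make_test_traits()
  s <- wetland_survey("U1", "seasonally_ponded", observations = data.frame(
    species = c("Alpha uno", "Beta duo", "Ignotus planta"),
    zone = "wet_meadow", quadrat = c("1", "2", "3")))
  expect_warning(m <- compute_metrics(s, tr), "not in trait table")
  expect_equal(m[["richness_native_perennial"]], 2)
  # 0 of 3 known ABI species, but the unknown is in the denominator
  expect_equal(m[["pct_annual_biennial_introduced"]], 0)
  s2 <- wetland_survey("U2", "seasonally_ponded", observations = data.frame(
    species = c("Alpha uno", "Cirsium arvense", "Ignotus planta"),
    zone = "wet_meadow", quadrat = c("1", "2", "3")))
  expect_warning(m2 <- compute_metrics(s2, tr))
  expect_equal(m2[["pct_annual_biennial_introduced"]], 33.3) # 1 of 3
})

test_that("scoring agrees with the hand-encoded oracle over dense grids", {
  for (cls in c("temporarily_ponded", "seasonally_ponded")) {
    for (m in names(ORACLE[[cls]])) {
      grid <- oracle_grid(m)
      got <- vapply(grid, function(v) score_metric(m, v, cls, cfg), integer(1))
      want <- vapply(grid, function(v) oracle_score(m, v, cls), integer(1))
      expect_identical(got, want, label = paste(cls, m))
      expect_true(all(got %in% c(0L, 4L, 7L, 11L)))
    }
  }
})

test_that("rounding-then-lookup closes the printed-range gaps", {
  # values falling between printed ranges land in the nearer one
  expect_equal(score_metric("pct_annual_biennial_introduced", 35.04,
                            "temporarily_ponded", cfg), 7)
  expect_equal(score_metric("pct_annual_biennial_introduced", 35.05,
                            "temporarily_ponded", cfg), 4)
  expect_equal(score_metric("fqi", 22.994, "seasonally_ponded", cfg), 7)
  expect_equal(score_metric("fqi", 22.995, "seasonally_ponded", cfg), 11)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(4.665, 2), 4.67)
})

test_that("totals sum nine ordinal scores into [0, 99]", {
  expect_equal(total_score(rep(11, 9)), 99L)
  expect_equal(total_score(rep(0, 9)), 0L)
  expect_equal(total_score(c(11, 0, 0, 0, 0, 0, 0, 11, 0)), 22L)
  expect_error(total_score(rep(11, 8)), "nine")
  expect_error(total_score(c(rep(11, 8), 5)), "0, 4, 7, or 11")
})

test_that("categories partition 0-99 exactly and match the hand-encoded table", {
  for (cls in c("temporarily_ponded", "seasonally_ponded")) {
    oc <- ORACLE_CATEGORIES[[cls]]
    for (t in 0:99) {
      want <- oc$category[t >= oc$min & t <= oc$max]
      expect_length(want, 1)
      expect_equal(categorize(t, cls, cfg), want)
    }
    expect_equal(category_levels(cls, cfg), oc$category)
  }
  expect_error(categorize(100, "seasonally_ponded", cfg), "\\[0, 99\\]")
  expect_error(categorize(-1, "seasonally_ponded", cfg), "\\[0, 99\\]")
})

test_that("adding native species moves richness metrics the right way", {
  tr <- generate_species_pool(species_pool_config(seed = 21L))
  np <- tr$name[tr$nativity == "native" & tr$lifespan == "perennial"]
  grasses <- tr$name[tr$nativity == "native" &
                       tr$growth_form %in% c("grass", "grass_like")]
  base_obs <- data.frame(species = np[1:10], zone = "wet_meadow",
                         quadrat = as.character(rep(1:5, 2)))
  s0 <- wetland_survey("M0", "seasonally_ponded", observations = base_obs)
  m0 <- compute_metrics(s0, tr)
  for (extra in setdiff(np, np[1:10])[1:25]) {
    s1 <- wetland_survey("M1", "seasonally_ponded",
                         observations = rbind(base_obs,
                                              data.frame(species = extra,
                                                         zone = "low_prairie",
                                                         quadrat = "1")))
    m1 <- compute_metrics(s1, tr)
    expect_gte(m1[["richness_native_perennial"]], m0[["richness_native_perennial"]])
    expect_gte(m1[["genera_native_perennial"]], m0[["genera_native_perennial"]])
    # a native perennial can only dilute the short-lived/introduced share
    expect_lte(m1[["pct_annual_biennial_introduced"]],
               m0[["pct_annual_biennial_introduced"]])
  }
  for (extra in setdiff(grasses, np[1:10])[1:10]) {
    s1 <- wetland_survey("M2", "seasonally_ponded",
                         observations = rbind(base_obs,
                                              data.frame(species = extra,
                                                         zone = "low_prairie",
                                                         quadrat = "1")))
    expect_gte(compute_metrics(s1, tr)[["native_grass_grasslike"]],
               m0[["native_grass_grasslike"]])
  }
})

test_that("assess_all tabulates one row per wetland with consistent totals", {
  pool <- generate_species_pool(species_pool_config(seed = 6L))
  surveys <- lapply(1:4, function(i) {
    generate_survey(pool, paste0("W", i),
                    if (i %% 2) "seasonally_ponded" else "temporarily_ponded",
                    gradient = gradient_config(d = 0.4), seed = 40L + i)
  })
  res <- assess_all(surveys, pool, cfg)
  expect_equal(nrow(res), 4)
  score_cols <- paste0("score_", names(EXAMPLE_METRICS))
  expect_equal(res$total, as.integer(rowSums(res[score_cols])))
  expect_true(all(unlist(res[score_cols]) %in% c(0, 4, 7, 11)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_assessments(res, f)
  expect_equal(nrow(utils::read.csv(f)), 4)
})
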