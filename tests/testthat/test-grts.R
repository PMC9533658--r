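test_that("hierarchical addresses reflect quadrant membership", {
  bbox <- c(0, 0, 1, 1)
  # identity permutations: digit = (x-half) + 2*(y-half)
  expect_equal(hierarchical_address(0.1, 0.1, bbox, depth = 3, seed = NULL), "000")
  expect_equal(hierarchical_address(0.9, 0.9, bbox, depth = 3, seed = NULL), "333")
  # a point offset into quadrant 1 at every level
  expect_equal(hierarchical_address(0.5 + 0.25 + 0.125 + 0.0625, 0.01,
                                    bbox, depth = 3, seed = NULL), "111")
  # different level-1 quadrants differ in the first digit (any seed)
  a <- hierarchical_address(c(0.2, 0.8), c(0.2, 0.2), bbox, depth = 4, seed = 7L)
  expect_true(substr(a[1], 1, 1) != substr(a[2], 1, 1))
  expect_error(hierarchical_address(1.5, 0.5, bbox), "outside")
})

test_that("a full grid at matching depth gets unique addresses", {
  g <- expand.grid(x = (0:15 + 0.5) / 16, y = (0:15 + 0.5) / 16)
  addr <- hierarchical_address(g$x, g$y, c(0, 0, 1, 1), depth = 4, seed = 11L)
  expect_equal(length(unique(addr)), 256)
  expect_true(all(nchar(addr) == 4))
})

test_that("draws are deterministic, stratified, and exhaustive when asked", {
  fr <- generate_site_frame(400, c(s1 = 0.25, s2 = 0.25, s3 = 0.25, s4 = 0.25),
                            seed = 2L)
  expect_equal(unname(table(fr$stratum)[paste0("s", 1:4)]), rep(100L, 4),
               ignore_attr = TRUE)
  d1 <- grts_draw(fr, n_primary = 50, n_alternate = 12, seed = 9L)
  d2 <- grts_draw(fr, n_primary = 50, n_alternate = 12, seed = 9L)
  expect_identical(d1$sites, d2$sites)
  expect_equal(nrow(d1$sites), 4 * 62)
  expect_false(anyDuplicated(d1$sites$site_id) > 0)
  # exhaustive draw: every point of a stratum, all primary
  small <- site_frame(data.frame(site_id = paste0("p", 1:8),
                                 x = runif(8), y = runif(8), stratum = "only"))
  dall <- grts_draw(small, n_primary = 8, seed = 1L)
  expect_setequal(dall$sites$site_id, small$site_id)
  expect_true(all(dall$sites$role == "primary"))
  expect_error(grts_draw(small, n_primary = 9, seed = 1L), "stratum 'only'")
})

test_that("a 250-site stratified draw supports the study's 24 replacements", {
  fr <- generate_site_frame(400, c(temp_y1 = 0.25, temp_y2 = 0.25,
                                   seas_y1 = 0.25, seas_y2 = 0.25), seed = 3L)
  draw <- grts_draw(fr,
                    n_primary = c(temp_y1 = 50, temp_y2 = 50,
                                  seas_y1 = 50, seas_y2 = 50),
                    n_alternate = c(temp_y1 = 12, temp_y2 = 13,
                                    seas_y1 = 12, seas_y2 = 13),
                    seed = 17L)
  expect_equal(nrow(draw$sites), 250)
  expect_equal(sum(draw$sites$role == "primary"), 200)
  expect_equal(sum(draw$sites$role == "alternate"), 50)

  # replace 6 primaries in each stratum (24 total, 12-13 alternates apiece)
  to_replace <- unlist(lapply(split(draw$sites, draw$sites$stratum), function(s) {
    s$site_id[s$role == "primary"][1:6]
  }))
  for (id in to_replace) {
    draw <- replace_site(draw, id, reason = "misclassified")
  }
  expect_equal(nrow(draw$replacements), 24)
  act <- active_sites(draw)
  expect_equal(nrow(act), 200) # conservation of the designed sample size
  expect_equal(sum(draw$sites$role == "alternate" & !draw$sites$active), 26)
  # replacements never cross strata
  expect_equal(draw$replacements$stratum,
               draw$sites$stratum[match(draw$replacements$replacement,
                                        draw$sites$site_id)])
  # errors: double replacement, non-primary, exhausted alternates
  expect_error(replace_site(draw, to_replace[1]), "already replaced")
  alt1 <- draw$sites$site_id[draw$sites$role == "alternate"][1]
  expect_error(replace_site(draw, alt1), "not a primary")
  one <- site_frame(data.frame(site_id = c("a", "b"), x = c(0.2, 0.8),
                               y = c(0.5, 0.5), stratum = "z"))
  d0 <- grts_draw(one, n_primary = 2, n_alternate = 0, seed = 1L)
  expect_error(replace_site(d0, "a"), "no unused alternate")
})

test_that("prefixes of the draw order spread over space at least as well as random order", {
  fr <- generate_site_frame(256, c(a = 1), seed = 8L)
  bbox <- attr(fr, "bbox")
  # occupied level-2 cells (16 cells) among the first 16 sites of the order
  occupied <- function(ids) {
    i <- match(ids, fr$site_id)
    cx <- pmin(floor(4 * (fr$x[i] - bbox[1]) / (bbox[3] - bbox[1])), 3)
    cy <- pmin(floor(4 * (fr$y[i] - bbox[2]) / (bbox[4] - bbox[2])), 3)
    length(unique(cx + 4 * cy))
  }
  grts_occ <- rand_occ <- numeric(20)
  for (r in 1:20) {
    d <- grts_draw(fr, n_primary = 64, seed = 100L + r)
    ids <- d$sites$site_id[order(d$sites$order_rank)]
    grts_occ[r] <- occupied(ids[1:16])
    rand_occ[r] <- occupied(srs_ids(fr, 16, 500L + r))
  }
  expect_gte(mean(grts_occ), mean(rand_occ))
})

test_that("frames and draws round-trip through delimited text", {
  fr <- generate_site_frame(40, c(a = 0.5, b = 0.5), seed = 12L)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(as.data.frame(fr), f, sep = ",", quote = FALSE, row.names = FALSE)
  fr2 <- read_site_frame(f)
  expect_equal(as.data.frame(fr2), as.data.frame(fr), tolerance = 1e-12)
  d <- grts_draw(fr, n_primary = 5, n_alternate = 2, seed = 4L)
  out <- withr::local_tempfile(fileext = ".csv")
  write_draw(d, out)
  back <- utils::read.csv(out)
  expect_equal(nrow(back), 14)
  expect_named(back, c("site_id", "stratum", "order_rank", "role", "replaced_by"))
})
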