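#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's
#' RNG state, so generators are deterministic without disturbing the
#' session's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration of a synthetic regional species pool
#'
#' Defines the flora the generator draws communities from: counts of
#' native perennials, short-lived (annual/biennial) natives, and
#' introduced species; the C-value distributions; growth-form mixes;
#' and zone-affinity concentration. Defaults emulate a prairie-pothole
#' regional flora rich enough that an undisturbed seasonal wetland can
#' support the diverse native-perennial community the top condition
#' scores describe, with a contingent of introduced perennials standing
#' in for the region's invasive grasses and cattails.
#'
#' C-values (0-10 conservatism) are drawn as `1 + Binomial(9, p)` with
#' `p` set from the target mean: native perennials center on
#' `c_mean_perennial` and short-lived natives on `c_mean_annual` (weedy,
#' disturbance-tolerant species carry low C). Introduced species carry
#' none.
#'
#' @param n_native_perennial Native perennial species in the pool.
#' @param n_native_annual_biennial Short-lived native species.
#' @param n_introduced Introduced species (about half modeled as
#'   perennial invasives).
#' @param c_mean_perennial Target mean C-value of native perennials.
#' @param c_mean_annual Target mean C-value of short-lived natives.
#' @param genus_ratio Genera per species (< 1 creates congeners).
#' @param seed Integer seed.
#' @return A `species_pool_config` list.
#' @export
species_pool_config <- function(n_native_perennial = 120L,
                                n_native_annual_biennial = 25L,
                                n_introduced = 35L,
                                c_mean_perennial = 5.0,
                                c_mean_annual = 2.4,
                                genus_ratio = 0.65,
                                seed = 1L) {
  stopifnot(n_native_perennial >= 0, n_native_annual_biennial >= 0,
            n_introduced >= 0,
            c_mean_perennial >= 1, c_mean_perennial <= 10,
            c_mean_annual >= 1, c_mean_annual <= 10,
            genus_ratio > 0, genus_ratio <= 1)
  structure(list(n_native_perennial = as.integer(n_native_perennial),
                 n_native_annual_biennial = as.integer(n_native_annual_biennial),
                 n_introduced = as.integer(n_introduced),
                 c_mean_perennial = c_mean_perennial,
                 c_mean_annual = c_mean_annual,
                 genus_ratio = genus_ratio, seed = as.integer(seed)),
            class = "species_pool_config")
}

# pseudo-Latin binomials: enough syllable combinations for thousands of
# unique names, deterministic under the config seed
make_binomials <- function(n_genera, n_species) {
  syl1 <- c("Ast", "Bor", "Cal", "Del", "Eri", "Fal", "Gly", "Hel", "Jun",
            "Kal", "Lim", "Mon", "Nup", "Ost", "Pol", "Quer", "Ran", "Sal",
            "Tri", "Ver")
  syl2 <- c("ago", "antha", "aria", "ella", "ensis", "ica", "ina", "iola",
            "ista", "oides", "opsis", "ula", "um", "usa", "ix")
  ep1 <- c("alb", "bore", "camp", "dens", "elat", "falc", "grac", "hirt",
           "lanc", "macr", "nan", "obtus", "pall", "ripar", "seros", "tenu",
           "vill", "glauc", "prat", "palustr")
  ep2 <- c("a", "ula", "ata", "escens", "iflora", "oides", "alis", "ica",
           "ensis", "osa")
  genera <- unique(as.vector(outer(syl1, syl2, paste0)))
  stopifnot(n_genera <= length(genera))
  genera <- sample(genera, n_genera)
  epithets <- as.vector(outer(ep1, ep2, paste0))
  names_out <- character(n_species)
  used <- character(0)
  gi <- sample(rep_len(seq_len(n_genera), n_species))
  for (i in seq_len(n_species)) {
    repeat {
      nm <- paste(genera[gi[i]], sample(epithets, 1))
      if (!nm %in% used) break
    }
    used <- c(used, nm)
    names_out[i] <- nm
  }
  names_out
}

rc_values <- function(n, target_mean) {
  1L + stats::rbinom(n, 9L, (target_mean - 1) / 9)
}

#' Generate a synthetic species pool as a trait table
#'
#' Draws a regional flora per the configuration: binomial-shaped
#' synthetic names, growth forms (natives: mostly forbs with a strong
#' grass/sedge contingent; introduced: grass-heavy), lifespans, and
#' C-values on natives only. Each species also receives zone-affinity
#' weights over the three vegetation zones (attribute `zone_affinity`,
#' rows summing to 1), used by [generate_survey()] to place species in
#' zones; introduced perennials lean toward the wetter interior zones
#' the way invasive cattails and canarygrass do.
#'
#' @param config A [species_pool_config()].
#' @return A [trait_table()] with a `zone_affinity` matrix attribute.
#' @export
generate_species_pool <- function(config = species_pool_config()) {
  stopifnot(inherits(config, "species_pool_config"))
  with_seed(config$seed, {
    n_np <- config$n_native_perennial
    n_na <- config$n_native_annual_biennial
    n_in <- config$n_introduced
    n <- n_np + n_na + n_in
    if (n == 0L) {
      return(trait_table(data.frame(name = character(0), genus = character(0),
                                    nativity = character(0), lifespan = character(0),
                                    growth_form = character(0), c_value = integer(0)),
                         provenance = "synthetic pool (empty)"))
    }
    n_genera <- max(1L, ceiling(n * config$genus_ratio))
    name <- make_binomials(n_genera, n)
    nativity <- rep(c("native", "native", "introduced"), c(n_np, n_na, n_in))
    lifespan <- c(rep("perennial", n_np),
                  sample(c("annual", "biennial"), n_na, TRUE, prob = c(0.7, 0.3)),
                  sample(c("perennial", "annual", "biennial"), n_in, TRUE,
                         prob = c(0.5, 0.4, 0.1)))
    growth_form <- character(n)
    nat <- nativity == "native"
    growth_form[nat] <- sample(GROWTH_FORM, sum(nat), TRUE,
                               prob = c(0.18, 0.17, 0.55, 0.05, 0.05))
    growth_form[!nat] <- sample(GROWTH_FORM, sum(!nat), TRUE,
                                prob = c(0.35, 0.05, 0.50, 0.02, 0.08))
    c_value <- rep(NA_integer_, n)
    c_value[seq_len(n_np)] <- rc_values(n_np, config$c_mean_perennial)
    if (n_na > 0) c_value[n_np + seq_len(n_na)] <- rc_values(n_na, config$c_mean_annual)

    tab <- trait_table(data.frame(name = name, genus = genus_of(name),
                                  nativity = nativity, lifespan = lifespan,
                                  growth_form = growth_form, c_value = c_value),
                       provenance = sprintf("synthetic pool (seed %d)", config$seed))
    # zone affinity: a preferred zone gets ~60-75% of the weight
    pref_prob <- matrix(rep(c(0.40, 0.35, 0.25), each = n), nrow = n)
    invasive <- tab$nativity == "introduced" & tab$lifespan == "perennial"
    pref_prob[invasive, ] <- rep(c(0.15, 0.40, 0.45), each = sum(invasive))
    aff <- matrix(0, nrow = n, ncol = 3, dimnames = list(tab$name, ZONES))
    for (i in seq_len(n)) {
      z <- sample(3L, 1L, prob = pref_prob[i, ])
      w <- stats::runif(3, 0.05, 0.25)
      w[z] <- stats::runif(1, 0.6, 0.75)
      aff[i, ] <- w / sum(w)
    }
    attr(tab, "zone_affinity") <- aff
    tab
  })
}

#' Configuration of the disturbance gradient
#'
#' Controls how community composition responds to the disturbance level
#' `d` in `[0, 1]`. Occupancy of native species declines from
#' `native_occ_pristine` toward `native_occ_degraded` as `d` grows,
#' faster for high-C (conservative) species; short-lived natives,
#' introduced species, and introduced-perennial invasives become more
#' likely instead, so degraded wetlands end up species-poor and
#' dominated by short-lived and introduced plants. Reseeded-grassland
#' sites experience the gradient at `d + reseeded_offset`, encoding the
#' legacy of cultivation.
#'
#' @param d Disturbance level in `[0, 1]`.
#' @param native_occ_pristine Occupancy probability of a native
#'   perennial at `d = 0`.
#' @param native_occ_degraded Occupancy of a mid-C native perennial at
#'   `d = 1`.
#' @param c_sensitivity Extra decline per unit C/10 (high-C species
#'   disappear first).
#' @param annual_occ_range Occupancy of short-lived natives at
#'   `d = 0` and `d = 1`.
#' @param introduced_occ_range Occupancy of non-invasive introduced
#'   species at `d = 0` and `d = 1`.
#' @param invasive_occ_range Occupancy of introduced perennials
#'   (invasive mimics) at `d = 0` and `d = 1`.
#' @param zone_spread Multiplier converting zone affinity into per-zone
#'   occupancy for a species present at a site.
#' @param site_noise_sd SD of the per-site log-normal occupancy
#'   multiplier (between-wetland heterogeneity).
#' @param reseeded_offset Added to `d` (capped at 1) on reseeded sites.
#' @param between_quadrat_rate Probability a species-zone record is a
#'   between-quadrat observation rather than an in-quadrat one.
#' @param seed Integer seed.
#' @return A `gradient_config` list.
#' @export
gradient_config <- function(d = 0,
                            native_occ_pristine = 0.45,
                            native_occ_degraded = 0.04,
                            c_sensitivity = 0.8,
                            annual_occ_range = c(0.25, 0.50),
                            introduced_occ_range = c(0.10, 0.65),
                            invasive_occ_range = c(0.25, 0.95),
                            zone_spread = 1.5,
                            site_noise_sd = 0.15,
                            reseeded_offset = 0.30,
                            between_quadrat_rate = 0.12,
                            seed = 1L) {
  stopifnot(d >= 0, d <= 1, native_occ_pristine > native_occ_degraded,
            length(annual_occ_range) == 2, length(introduced_occ_range) == 2,
            length(invasive_occ_range) == 2,
            reseeded_offset >= 0, between_quadrat_rate >= 0,
            between_quadrat_rate <= 1)
  structure(as.list(environment()), class = "gradient_config")
}

# vectorized occupancy probabilities at effective disturbance d_eff:
# conservative native perennials fade first; short-lived natives,
# introduced species, and introduced-perennial invasives move in
species_occupancy <- function(traits, d_eff, g) {
  nat <- traits$nativity == "native"
  per <- traits$lifespan == "perennial"
  cc <- ifelse(is.na(traits$c_value), 5, traits$c_value)
  lerp <- function(range) range[1] + d_eff * (range[2] - range[1])
  ratio <- g$native_occ_degraded / g$native_occ_pristine
  p <- numeric(nrow(traits))
  p[nat & per] <- g$native_occ_pristine *
    ratio^(d_eff * (0.6 + g$c_sensitivity * cc[nat & per] / 10))
  p[nat & !per] <- lerp(g$annual_occ_range)
  p[!nat & per] <- lerp(g$invasive_occ_range)
  p[!nat & !per] <- lerp(g$introduced_occ_range)
  p
}

#' Generate one synthetic zoned quadrat survey
#'
#' Draws a community for one wetland from the species pool under the
#' disturbance gradient, places each present species into vegetation
#' zones by its zone affinity, and emits quadrat-level and
#' between-quadrat observations consistent with the class layout (8
#' low-prairie / 7 wet-meadow / 5 shallow-marsh quadrats for seasonal
#' wetlands; no shallow marsh for temporary ones). Species inclusion is
#' independent Bernoulli per species — no co-occurrence structure.
#'
#' @param pool A [generate_species_pool()] trait table (with the
#'   `zone_affinity` attribute).
#' @param site_id Site identifier for the survey.
#' @param hydro_class Wetland hydrologic class.
#' @param grassland_type `"native"` or `"reseeded"` (reseeded sites get
#'   the configured disturbance offset).
#' @param gradient A [gradient_config()].
#' @param sample_year Year label.
#' @param seed Integer seed for this survey; defaults to the gradient
#'   seed.
#' @return A [wetland_survey()].
#' @export
generate_survey <- function(pool, site_id, hydro_class,
                            grassland_type = "native",
                            gradient = gradient_config(),
                            sample_year = 2020L, seed = gradient$seed) {
  stopifnot(inherits(pool, "trait_table"), nrow(pool) > 0,
            inherits(gradient, "gradient_config"))
  hydro_class <- match.arg(hydro_class, HYDRO_CLASSES)
  aff <- attr(pool, "zone_affinity")
  if (is.null(aff)) stop("pool lacks the zone_affinity attribute; use generate_species_pool()")
  zones <- zones_for_class(hydro_class)
  layout <- generate_layout(hydro_class,
                            zone_radii = if (length(zones) == 3) c(10, 20, 30) else c(15, 30),
                            seed = seed)
  with_seed(seed, {
    d_eff <- min(1, gradient$d +
                   if (grassland_type == "reseeded") gradient$reseeded_offset else 0)
    site_mult <- exp(stats::rnorm(1, 0, gradient$site_noise_sd))
    tab <- as.data.frame(pool)
    p <- pmin(1, species_occupancy(tab, d_eff, gradient) * site_mult)
    present <- which(stats::runif(nrow(tab)) < p)
    obs_rows <- lapply(present, function(i) {
      a <- aff[tab$name[i], zones]
      a <- a / sum(a)
      pz <- pmin(1, a * gradient$zone_spread)
      occ <- stats::runif(length(zones)) < pz
      if (!any(occ)) occ[sample(length(zones), 1, prob = a)] <- TRUE
      z_occ <- zones[occ]
      quad <- vapply(z_occ, function(z) {
        if (stats::runif(1) < gradient$between_quadrat_rate) BETWEEN
        else as.character(sample(QUADRAT_COUNTS[[hydro_class]][[z]], 1))
      }, character(1))
      data.frame(species = tab$name[i], zone = z_occ, quadrat = quad)
    })
    obs <- do.call(rbind, obs_rows)
    if (!is.null(obs) && nrow(obs)) {
      inq <- obs$quadrat != BETWEEN
      obs$pct_standing_dead <- ifelse(inq, round(stats::runif(nrow(obs), 0, 40), 0), NA)
      obs$pct_open_water <- ifelse(inq & obs$zone == "shallow_marsh",
                                   round(stats::runif(nrow(obs), 0, 60), 0), NA)
      obs$pct_bare_ground <- ifelse(inq, round(stats::runif(nrow(obs), 0, 20), 0), NA)
      obs$litter_cm <- ifelse(inq, round(stats::runif(nrow(obs), 0, 8), 1), NA)
      obs$water_depth_cm <- ifelse(inq & obs$zone != "low_prairie",
                                   round(stats::runif(nrow(obs), 0, 30), 1), NA)
    }
    wetland_survey(site_id, hydro_class, grassland_type, sample_year,
                   observations = obs, layout = layout)
  })
}

#' Generate a synthetic site frame
#'
#' Lays `n` candidate wetland points in a bounding box, either as a
#' uniform Poisson-like scatter or as a clustered (Thomas-style
#' parent-offspring) pattern, and assigns stratum labels by
#' largest-remainder apportionment of the given proportions.
#'
#' @param n Number of points.
#' @param strata Named numeric vector of stratum proportions (sums to 1).
#' @param bbox Numeric `c(xmin, ymin, xmax, ymax)`.
#' @param mode `"uniform"` or `"clustered"`.
#' @param n_clusters Parent count for clustered mode.
#' @param cluster_sd Gaussian offspring SD (in bbox units).
#' @param seed Integer seed.
#' @return A [site_frame()].
#' @export
generate_site_frame <- function(n, strata = c(stratum_1 = 1),
                                bbox = c(0, 0, 100, 100),
                                mode = c("uniform", "clustered"),
                                n_clusters = 15L, cluster_sd = 3,
                                seed = 1L) {
  mode <- match.arg(mode)
  if (abs(sum(strata) - 1) > 1e-8) stop("stratum proportions must sum to 1")
  with_seed(seed, {
    if (mode == "uniform") {
      x <- stats::runif(n, bbox[1], bbox[3])
      y <- stats::runif(n, bbox[2], bbox[4])
    } else {
      px <- stats::runif(n_clusters, bbox[1], bbox[3])
      py <- stats::runif(n_clusters, bbox[2], bbox[4])
      parent <- sample(n_clusters, n, TRUE)
      x <- pmin(pmax(px[parent] + stats::rnorm(n, 0, cluster_sd), bbox[1]), bbox[3])
      y <- pmin(pmax(py[parent] + stats::rnorm(n, 0, cluster_sd), bbox[2]), bbox[4])
    }
    counts <- largest_remainder(n, strata)
    lab <- sample(rep(names(strata), counts))
    site_frame(data.frame(site_id = sprintf("W%04d", seq_len(n)),
                          x = x, y = y, stratum = lab))
  })
}
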