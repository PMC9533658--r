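#' Zoned quadrat vegetation surveys
#'
#' A survey records every species found in a wetland, attributed to a
#' vegetation zone and either to a numbered 1-m^2 quadrat or to a
#' between-quadrat record (sentinel `"BETWEEN"`): species seen inside the
#' wetland but outside all quadrats are recorded too and enter the
#' condition index on equal footing. Optional cover descriptors
#' (percent standing dead, open water, bare ground, litter thickness,
#' water depth) are stored and round-tripped but feed no metric —
#' scoring is presence/absence only.
#'
#' @param site_id Site identifier.
#' @param hydro_class `"temporarily_ponded"` or `"seasonally_ponded"`.
#' @param grassland_type `"native"` or `"reseeded"` upland stratum.
#' @param sample_year Integer year.
#' @param observations Data frame with columns `species`, `zone`,
#'   `quadrat` (integer as character, or `"BETWEEN"`), and optionally
#'   `pct_standing_dead`, `pct_open_water`, `pct_bare_ground`,
#'   `litter_cm`, `water_depth_cm`.
#' @param location Numeric `c(x, y)` planar coordinates (arbitrary units).
#' @param layout Optional [generate_layout()] plan the survey used.
#' @return A `wetland_survey` object.
#' @export
wetland_survey <- function(site_id, hydro_class, grassland_type = "native",
                           sample_year = NA_integer_, observations = NULL,
                           location = c(NA_real_, NA_real_), layout = NULL) {
  hydro_class <- match.arg(hydro_class, HYDRO_CLASSES)
  grassland_type <- match.arg(grassland_type, c("native", "reseeded"))
  obs_cols <- c("species", "zone", "quadrat", "pct_standing_dead",
                "pct_open_water", "pct_bare_ground", "litter_cm", "water_depth_cm")
  if (is.null(observations) || nrow(observations) == 0L) {
    observations <- as.data.frame(
      stats::setNames(rep(list(character(0)), 3), obs_cols[1:3]))
  }
  observations <- as.data.frame(observations)
  for (col in obs_cols) {
    if (!col %in% names(observations)) {
      observations[[col]] <- rep(NA, nrow(observations))
    }
  }
  observations <- observations[obs_cols]
  observations$species <- canonical_name(as.character(observations$species))
  observations$zone <- as.character(observations$zone)
  q <- trimws(as.character(observations$quadrat))
  q[is.na(q) | !nzchar(q)] <- BETWEEN
  observations$quadrat <- q
  for (col in c("pct_standing_dead", "pct_open_water", "pct_bare_ground",
                "litter_cm", "water_depth_cm")) {
    observations[[col]] <- suppressWarnings(as.numeric(observations[[col]]))
  }

  legal <- zones_for_class(hydro_class)
  bad <- which(!observations$zone %in% legal)
  if (length(bad)) {
    stop(sprintf("site %s: zone '%s' (observation row %d) is not legal for %s wetlands",
                 site_id, observations$zone[bad[1]], bad[1], hydro_class))
  }
  for (col in c("pct_standing_dead", "pct_open_water", "pct_bare_ground")) {
    v <- observations[[col]]
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      stop(sprintf("site %s: %s outside [0, 100]", site_id, col))
    }
  }
  if (!is.null(layout)) {
    per_zone <- layout$counts
    for (i in which(observations$quadrat != BETWEEN)) {
      z <- observations$zone[i]
      qi <- suppressWarnings(as.integer(observations$quadrat[i]))
      if (is.na(qi) || qi < 1L || qi > per_zone[[z]]) {
        stop(sprintf("site %s: quadrat '%s' not in layout for zone %s",
                     site_id, observations$quadrat[i], z))
      }
    }
  }
  rownames(observations) <- NULL
  structure(list(site_id = as.character(site_id), hydro_class = hydro_class,
                 grassland_type = grassland_type,
                 sample_year = as.integer(sample_year),
                 location = as.numeric(location),
                 observations = observations, layout = layout),
            class = "wetland_survey")
}

#' @export
print.wetland_survey <- function(x, ...) {
  cat(sprintf("Wetland survey %s (%s, %s grassland, year %s): %d records, %d species\n",
              x$site_id, x$hydro_class, x$grassland_type, x$sample_year,
              nrow(x$observations), length(wetland_species_list(x))))
  invisible(x)
}

#' All species recorded at a wetland
#'
#' Union over every observation, quadrat and between-quadrat alike —
#' condition is assessed from all species identified, including those
#' not located within the sample quadrats.
#'
#' @param survey A `wetland_survey`.
#' @return Sorted character vector of canonical species names.
#' @export
wetland_species_list <- function(survey) {
  stopifnot(inherits(survey, "wetland_survey"))
  sort(unique(survey$observations$species))
}

#' Species recorded in one vegetation zone
#'
#' Union of observations whose zone matches, including between-quadrat
#' records attributed to that zone. Zone-restricted metrics (wet-meadow
#' native perennials; wet-meadow species with C-value >= 4) are computed
#' over these sets.
#'
#' @param survey A `wetland_survey`.
#' @param zone Zone name; must be legal for the survey's hydrologic class.
#' @return Sorted character vector of canonical species names.
#' @export
zone_species_list <- function(survey, zone) {
  stopifnot(inherits(survey, "wetland_survey"))
  legal <- zones_for_class(survey$hydro_class)
  if (!zone %in% legal) {
    stop(sprintf("zone '%s' is not legal for %s wetlands (legal: %s)",
                 zone, survey$hydro_class, paste(legal, collapse = ", ")))
  }
  obs <- survey$observations
  sort(unique(obs$species[obs$zone == zone]))
}

SURVEY_HEADER <- c("site_id", "hydro_class", "grassland_type", "sample_year",
                   "zone", "quadrat_id", "species", "pct_standing_dead",
                   "pct_open_water", "pct_bare_ground", "litter_cm",
                   "water_depth_cm")

#' Read zoned quadrat surveys from delimited text
#'
#' One row per species occurrence; header
#' `site_id,hydro_class,grassland_type,sample_year,zone,quadrat_id,species,pct_standing_dead,pct_open_water,pct_bare_ground,litter_cm,water_depth_cm`.
#' `quadrat_id` blank or `BETWEEN` marks a between-quadrat record. Zone
#' legality is enforced per site; species unknown to `traits` pass
#' through with a warning (they count in total richness but feed no
#' native or C-value metric).
#'
#' @param path Path to the survey file.
#' @param traits Optional `trait_table` used to warn about unknown species.
#' @param sep Field separator.
#' @return Named list of `wetland_survey` objects, one per `site_id`, in
#'   first-appearance order.
#' @export
read_surveys <- function(path, traits = NULL, sep = ",") {
  if (!file.exists(path)) stop("survey file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", strip.white = TRUE,
                          fileEncoding = "UTF-8")
  missing_cols <- setdiff(SURVEY_HEADER, names(df))
  if (length(missing_cols)) {
    stop("survey file is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!is.null(traits)) {
    unknown <- setdiff(canonical_name(df$species), traits$name)
    if (length(unknown)) {
      warning("species not in trait table (counted in richness only): ",
              paste(unknown, collapse = ", "))
    }
  }
  ids <- unique(df$site_id)
  surveys <- lapply(ids, function(id) {
    rows <- df[df$site_id == id, , drop = FALSE]
    hc <- unique(rows$hydro_class)
    gt <- unique(rows$grassland_type)
    yr <- unique(rows$sample_year)
    if (length(hc) != 1L || length(gt) != 1L || length(yr) != 1L) {
      stop(sprintf("site %s: inconsistent class/stratum/year labels across rows", id))
    }
    obs <- data.frame(species = rows$species, zone = rows$zone,
                      quadrat = rows$quadrat_id,
                      pct_standing_dead = rows$pct_standing_dead,
                      pct_open_water = rows$pct_open_water,
                      pct_bare_ground = rows$pct_bare_ground,
                      litter_cm = rows$litter_cm,
                      water_depth_cm = rows$water_depth_cm)
    wetland_survey(id, hc, gt, as.integer(yr), obs)
  })
  names(surveys) <- ids
  surveys
}

#' Write surveys to delimited text
#'
#' Inverse of [read_surveys()]; a write-read round trip reproduces the
#' surveys (canonical names, `BETWEEN` sentinels, cover descriptors).
#'
#' @param surveys A `wetland_survey` or list of them.
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_surveys <- function(surveys, path, sep = ",") {
  if (inherits(surveys, "wetland_survey")) surveys <- list(surveys)
  rows <- lapply(surveys, function(s) {
    o <- s$observations
    n <- nrow(o)
    data.frame(site_id = rep(s$site_id, n),
               hydro_class = rep(s$hydro_class, n),
               grassland_type = rep(s$grassland_type, n),
               sample_year = rep(s$sample_year, n),
               zone = o$zone, quadrat_id = o$quadrat, species = o$species,
               pct_standing_dead = o$pct_standing_dead,
               pct_open_water = o$pct_open_water,
               pct_bare_ground = o$pct_bare_ground,
               litter_cm = o$litter_cm, water_depth_cm = o$water_depth_cm)
  })
  out <- do.call(rbind, rows)
  for (col in names(out)) {
    v <- out[[col]]
    if (is.numeric(v)) out[[col]] <- ifelse(is.na(v), "", as.character(v))
  }
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
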