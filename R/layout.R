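#' Generate a quadrat layout plan
#'
#' Places the fixed quadrat complement for a wetland class on an
#' idealized wetland of concentric circular zones: 8 quadrats in the
#' exterior low-prairie zone and 7 in the wet-meadow zone for both
#' classes, plus 5 in the central shallow-marsh zone of seasonally
#' ponded wetlands. Interior and exterior zone quadrats are centered in
#' their zone — equally spaced in angle on the zone's mid-radius ring,
#' starting at a seeded random angle. Central-zone quadrats follow an
#' inward Archimedean spiral at equal arc-length steps. When open water
#' occupies part of the central zone, its 5 quadrats are split between
#' open-water and emergent-vegetation placements proportionally to area,
#' by largest-remainder rounding, so the central count is always
#' conserved.
#'
#' Real pothole wetlands are irregular; the circular geometry is a
#' layout/visualization convenience only — no condition metric uses it.
#'
#' @param hydro_class `"temporarily_ponded"` or `"seasonally_ponded"`.
#' @param zone_radii Strictly increasing outer radii, one per zone,
#'   interior zone first (2 radii for temporary, 3 for seasonal).
#' @param open_water_fraction Fraction of the central zone under open
#'   water, in `[0, 1]`; only meaningful for seasonally ponded wetlands.
#' @param seed Integer seed for the random start angle.
#' @return A `layout_plan`: list with `hydro_class`, `counts` (named
#'   integer vector of quadrats per zone), `arrangement` (`"spiral"` for
#'   the central zone), `central_split` (named integer vector
#'   `c(open_water=, emergent=)`), and `quadrats`, a data frame of
#'   per-quadrat planar placements (`zone`, `quadrat`, `x`, `y`,
#'   `placement`).
#' @examples
#' plan <- generate_layout("seasonally_ponded", c(10, 20, 30), 0.4)
#' plan$counts
#' plan$central_split
#' @export
generate_layout <- function(hydro_class, zone_radii,
                            open_water_fraction = 0, seed = 1L) {
  hydro_class <- match.arg(hydro_class, HYDRO_CLASSES)
  zones <- rev(zones_for_class(hydro_class)) # interior first
  if (length(zone_radii) != length(zones)) {
    stop(sprintf("%s wetlands need %d zone radii (interior first), got %d",
                 hydro_class, length(zones), length(zone_radii)))
  }
  if (any(diff(zone_radii) <= 0) || any(zone_radii <= 0)) {
    stop("zone_radii must be positive and strictly increasing")
  }
  if (open_water_fraction < 0 || open_water_fraction > 1) {
    stop("open_water_fraction must be in [0, 1]")
  }
  counts <- QUADRAT_COUNTS[[hydro_class]]
  inner <- c(0, zone_radii[-length(zone_radii)])
  names(inner) <- names(zone_radii) <- zones
  central <- zones[1L]

  placements <- list()
  for (z in rev(zones)) { # exterior outward-in for readable output
    n <- counts[[z]]
    if (z == central) {
      # inward spiral: equal arc-length steps from the zone's outer edge
      r1 <- zone_radii[[z]]
      theta0 <- 2 * pi * hash_unif(seed, 7L)
      s <- seq(0.9, 0.15, length.out = n)
      r <- r1 * s
      theta <- theta0 + 4 * pi * (1 - s) # ~2 turns edge to center
      placement <- rep("emergent", n)
      if (central == "shallow_marsh" && open_water_fraction > 0) {
        split <- largest_remainder(n, c(open_water_fraction, 1 - open_water_fraction))
        # open water pools at the wetland center: innermost spiral steps
        placement <- c(rep("emergent", split[2]), rep("open_water", split[1]))
      }
      placements[[z]] <- data.frame(zone = z, quadrat = seq_len(n),
                                    x = r * cos(theta), y = r * sin(theta),
                                    placement = placement)
    } else {
      mid <- (inner[[z]] + zone_radii[[z]]) / 2
      theta0 <- 2 * pi * hash_unif(seed, match(z, ZONES))
      theta <- theta0 + 2 * pi * (seq_len(n) - 1) / n
      placements[[z]] <- data.frame(zone = z, quadrat = seq_len(n),
                                    x = mid * cos(theta), y = mid * sin(theta),
                                    placement = "zone_center")
    }
  }
  quadrats <- do.call(rbind, placements)
  rownames(quadrats) <- NULL
  split <- c(open_water = sum(quadrats$placement == "open_water"),
             emergent = sum(quadrats$placement == "emergent"))
  structure(list(hydro_class = hydro_class, counts = counts,
                 arrangement = "spiral", central_split = split,
                 zone_radii = zone_radii, quadrats = quadrats),
            class = "layout_plan")
}

#' @export
print.layout_plan <- function(x, ...) {
  cat(sprintf("Quadrat layout (%s): %s; total %d quadrats of 1 m^2\n",
              x$hydro_class,
              paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
              sum(x$counts)))
  invisible(x)
}
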