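#' Site frames for probability sampling
#'
#' A site frame is the list of candidate wetland points a sample is
#' drawn from: planar coordinates plus a stratum label (here, the
#' hydrologic class x sample year combinations). Frame construction
#' from wetland polygons or map projections is out of scope — the frame
#' is the abstraction the design operates on.
#'
#' @param df Data frame with columns `site_id`, `x`, `y`, `stratum`.
#' @return A `site_frame` (data frame subclass) with a `bbox` attribute
#'   `c(xmin, ymin, xmax, ymax)`.
#' @export
site_frame <- function(df) {
  req <- c("site_id", "x", "y", "stratum")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("site frame is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$site_id <- as.character(df$site_id)
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  df$stratum <- as.character(df$stratum)
  if (anyDuplicated(df$site_id)) {
    stop("duplicate site_id in frame: ",
         paste(unique(df$site_id[duplicated(df$site_id)]), collapse = ", "))
  }
  bbox <- c(xmin = min(df$x), ymin = min(df$y), xmax = max(df$x), ymax = max(df$y))
  rownames(df) <- NULL
  structure(df, bbox = bbox, class = c("site_frame", "data.frame"))
}

#' Read a site frame from delimited text (`site_id,x,y,stratum`)
#'
#' @param path Path to the frame file.
#' @param sep Field separator.
#' @return A [site_frame()].
#' @export
read_site_frame <- function(path, sep = ",") {
  if (!file.exists(path)) stop("site frame file not found: ", path)
  site_frame(utils::read.table(path, header = TRUE, sep = sep,
                               strip.white = TRUE, fileEncoding = "UTF-8"))
}

# one base-4 digit per level by quadrant membership; digits 0..3 are
# (x-half) + 2*(y-half) before the per-cell random remap
PERMS4 <- {
  p <- expand.grid(a = 0:3, b = 0:3, c = 0:3, d = 0:3)
  p <- p[apply(p, 1, function(r) length(unique(r)) == 4L), ]
  unname(as.matrix(p))
}

#' Hierarchical randomized quadrant address of a point
#'
#' The engine of GRTS ordering: the bounding box is split recursively
#' into quadrants, one base-4 digit per level. At each level the four
#' digits of each cell are remapped through a random permutation drawn
#' from a counter-based generator keyed by `(seed, level, cell)`, so
#' addresses are reproducible and independent of evaluation order.
#' Points close in space share long address prefixes; the randomized
#' digits make the induced order a random one among spatially
#' structured orders.
#'
#' @param x,y Point coordinates (vectorized).
#' @param bbox Numeric `c(xmin, ymin, xmax, ymax)`; all points must lie
#'   inside.
#' @param depth Number of levels (address length), >= 1.
#' @param seed Integer seed keying the per-cell digit permutations;
#'   `NULL` means identity permutations (no randomization).
#' @return Character vector of base-4 address strings of length `depth`.
#' @export
hierarchical_address <- function(x, y, bbox, depth = 8L, seed = 1L) {
  stopifnot(length(x) == length(y), depth >= 1L)
  if (any(x < bbox[1] | x > bbox[3] | y < bbox[2] | y > bbox[4])) {
    stop("point(s) outside the bounding box")
  }
  # normalize into [0, 1); points on the top/right edge belong to the last cell
  u <- pmin((x - bbox[1]) / max(bbox[3] - bbox[1], .Machine$double.eps), 1 - 1e-12)
  v <- pmin((y - bbox[2]) / max(bbox[4] - bbox[2], .Machine$double.eps), 1 - 1e-12)
  n <- length(x)
  cell <- integer(n) # raw (unpermuted) cell index at the current level
  digits <- matrix(0L, nrow = n, ncol = depth)
  for (lev in seq_len(depth)) {
    u2 <- u * 2; v2 <- v * 2
    qx <- as.integer(u2 >= 1); qy <- as.integer(v2 >= 1)
    q <- qx + 2L * qy
    if (is.null(seed)) {
      digits[, lev] <- q
    } else {
      for (cl in unique(cell)) {
        sel <- cell == cl
        perm <- PERMS4[int_hash(seed, lev, cl) %% 24L + 1L, ]
        digits[sel, lev] <- perm[q[sel] + 1L]
      }
    }
    cell <- cell * 4L + q
    u <- u2 - qx; v <- v2 - qy
  }
  apply(digits, 1, paste, collapse = "")
}

# reverse hierarchical rank: lexicographic order of reversed addresses,
# site_id breaking ties
reverse_hierarchical_order <- function(addresses, site_ids) {
  rev_addr <- vapply(strsplit(addresses, ""), function(d) paste(rev(d), collapse = ""),
                     character(1))
  order(rev_addr, site_ids)
}

#' Draw a stratified, spatially balanced GRTS sample
#'
#' Within each stratum: points receive hierarchical randomized quadrant
#' addresses ([hierarchical_address()]); a systematic sample with a
#' seeded random start is taken along the randomized address order
#' (which is what spreads the sample evenly over space); and the
#' selected sites are then arranged in reverse hierarchical order
#' (reversed address digits, lexicographic, ties by `site_id`), whose
#' defining property is that every prefix of the sample is itself
#' spatially balanced. The first `n_primary` sites in that order are
#' the designed sample; the next `n_alternate` are spatially balanced
#' spares promoted by [replace_site()] when a primary proves
#' unsampleable (misclassified, inaccessible). The draw is fully
#' deterministic given the frame, configuration, and seed.
#'
#' Address depth starts at `depth` and deepens until addresses are
#' unique within every stratum (ties, if the cap of 12 levels is hit,
#' are broken by `site_id`).
#'
#' @param frame A [site_frame()].
#' @param n_primary,n_alternate Named integer vectors (one entry per
#'   stratum), or scalars recycled to all strata.
#' @param seed Integer seed.
#' @param depth Starting address depth.
#' @return A `grts_draw`: list with `sites` (data frame `site_id`,
#'   `stratum`, `order_rank`, `role`, `active`, `replaced_by`),
#'   `replacements` (log data frame), `seed`, and `config`.
#' @export
grts_draw <- function(frame, n_primary, n_alternate = 0L, seed = 1L, depth = 8L) {
  stopifnot(inherits(frame, "site_frame"))
  strata <- sort(unique(frame$stratum))
  expand <- function(v, what) {
    if (length(v) == 1L && is.null(names(v))) {
      stats::setNames(rep(as.integer(v), length(strata)), strata)
    } else {
      miss <- setdiff(strata, names(v))
      if (length(miss)) stop(what, " missing for stratum: ", paste(miss, collapse = ", "))
      stats::setNames(as.integer(v[strata]), strata)
    }
  }
  n_primary <- expand(n_primary, "n_primary")
  n_alternate <- expand(n_alternate, "n_alternate")
  bbox <- attr(frame, "bbox")

  out <- list()
  for (si in seq_along(strata)) {
    st <- strata[si]
    pts <- frame[frame$stratum == st, , drop = FALSE]
    n_take <- n_primary[[st]] + n_alternate[[st]]
    if (n_take > nrow(pts)) {
      stop(sprintf("stratum '%s': requested %d sites but frame holds %d",
                   st, n_take, nrow(pts)))
    }
    if (n_take == 0L) next
    d <- depth
    repeat {
      addr <- hierarchical_address(pts$x, pts$y, bbox, depth = d,
                                   seed = int_hash(seed, 11L, si))
      if (!anyDuplicated(addr) || d >= 12L) break
      d <- d + 1L
    }
    fwd <- order(addr, pts$site_id)
    pts <- pts[fwd, , drop = FALSE]
    addr <- addr[fwd]
    N <- nrow(pts)
    k <- N / n_take
    u <- hash_unif(seed, 13L, si) * k # seeded random start in [0, k)
    take <- ceiling(u + (seq_len(n_take) - 1) * k)
    take[take < 1L] <- 1L
    sel <- pts[take, , drop = FALSE]
    # reverse hierarchical ordering of the sample: any prefix stays balanced
    rho <- reverse_hierarchical_order(addr[take], sel$site_id)
    sel <- sel[rho, , drop = FALSE]
    out[[st]] <- data.frame(
      site_id = sel$site_id, stratum = st, order_rank = seq_len(n_take),
      role = rep(c("primary", "alternate"),
                 c(n_primary[[st]], n_alternate[[st]])),
      active = rep(c(TRUE, FALSE), c(n_primary[[st]], n_alternate[[st]])),
      replaced_by = NA_character_)
  }
  sites <- do.call(rbind, out)
  rownames(sites) <- NULL
  structure(list(sites = sites,
                 replacements = data.frame(site_id = character(0),
                                           replacement = character(0),
                                           stratum = character(0),
                                           reason = character(0)),
                 seed = seed,
                 config = list(n_primary = n_primary, n_alternate = n_alternate)),
            class = "grts_draw")
}

#' @export
print.grts_draw <- function(x, ...) {
  s <- x$sites
  cat(sprintf("GRTS draw: %d sites (%d primary, %d alternate) in %d strata; %d replacement(s)\n",
              nrow(s), sum(s$role == "primary"), sum(s$role == "alternate"),
              length(unique(s$stratum)), nrow(x$replacements)))
  invisible(x)
}

#' Replace an unsampleable primary site with the next alternate
#'
#' Marks the primary inactive and promotes the first unused alternate
#' from the same stratum, in reverse hierarchical order, preserving the
#' spatial balance of the active sample. The replacement is logged.
#'
#' @param draw A [grts_draw()].
#' @param site_id Primary site to replace.
#' @param reason Free-text reason recorded in the log.
#' @return The updated `grts_draw`.
#' @export
replace_site <- function(draw, site_id, reason = "") {
  stopifnot(inherits(draw, "grts_draw"))
  s <- draw$sites
  i <- which(s$site_id == site_id)
  if (!length(i)) stop("site not in draw: ", site_id)
  if (s$role[i] != "primary") stop("site is not a primary: ", site_id)
  if (!s$active[i]) stop("site already replaced: ", site_id)
  st <- s$stratum[i]
  alt <- which(s$stratum == st & s$role == "alternate" & !s$active &
                 !s$site_id %in% draw$replacements$replacement)
  if (!length(alt)) stop(sprintf("stratum '%s' has no unused alternate left", st))
  j <- alt[which.min(s$order_rank[alt])]
  s$active[i] <- FALSE
  s$active[j] <- TRUE
  s$replaced_by[i] <- s$site_id[j]
  draw$sites <- s
  draw$replacements <- rbind(draw$replacements,
                             data.frame(site_id = site_id,
                                        replacement = s$site_id[j],
                                        stratum = st, reason = reason))
  draw
}

#' The currently active sample of a draw
#'
#' Primaries not yet replaced plus promoted alternates; size equals the
#' configured primary total as long as alternates remain.
#'
#' @param draw A [grts_draw()].
#' @return Data frame of active sites.
#' @export
active_sites <- function(draw) {
  stopifnot(inherits(draw, "grts_draw"))
  draw$sites[draw$sites$active, , drop = FALSE]
}

#' Write a draw to delimited text
#'
#' Columns `site_id,stratum,order_rank,role,replaced_by`.
#'
#' @param draw A [grts_draw()].
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_draw <- function(draw, path, sep = ",") {
  stopifnot(inherits(draw, "grts_draw"))
  s <- draw$sites[c("site_id", "stratum", "order_rank", "role", "replaced_by")]
  s$replaced_by[is.na(s$replaced_by)] <- ""
  utils::write.table(s, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Voronoi spatial-balance statistic
#'
#' Diagnostic for how evenly a sample spreads over its frame: each frame
#' point is assigned to its nearest sampled point (the sample's Voronoi
#' cells), and the variance of the resulting cell counts is returned.
#' Spatially balanced designs give more even cells — lower variance —
#' than simple random sampling of equal size.
#'
#' @param frame A [site_frame()] (or data frame with `x`, `y`, `site_id`).
#' @param sample_ids Site ids of the sampled points.
#' @return Variance of per-sample-point frame counts.
#' @export
spatial_balance_variance <- function(frame, sample_ids) {
  idx <- match(sample_ids, frame$site_id)
  if (anyNA(idx)) stop("sample id(s) not in frame")
  sx <- frame$x[idx]; sy <- frame$y[idx]
  d2 <- outer(frame$x, sx, "-")^2 + outer(frame$y, sy, "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  counts <- tabulate(nearest, nbins = length(idx))
  stats::var(counts)
}
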