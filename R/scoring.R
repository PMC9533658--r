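METRIC_IDS <- c("richness_native_perennial", "genera_native_perennial",
                "native_grass_grasslike", "pct_annual_biennial_introduced",
                "wetmeadow_native_perennial", "count_c_ge_5",
                "wetmeadow_count_c_ge_4", "avg_c", "fqi")

#' Load the IPCI scoring configuration
#'
#' Reads the versioned YAML file that encodes, cell for cell, the metric
#' value ranges for scores 0/4/7/11 by hydrologic class and the
#' total-score ranges for the condition categories. The packaged default
#' carries the established prairie-pothole ranges; adapting the index to
#' another region or wetland class is a config edit, not a code change.
#'
#' @param path Path to a scoring YAML; default is the packaged table.
#' @return A `scoring_config`: list with `version`, `scores`,
#'   `metric_precision`, `metrics` (class -> metric -> range table) and
#'   `categories` (class -> category table).
#' @export
load_scoring_config <- function(path = system.file("extdata", "ipci_scoring.yaml",
                                                   package = "ipci")) {
  if (!nzchar(path) || !file.exists(path)) stop("scoring config not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (need in c("scores", "metric_precision", "metrics", "categories")) {
    if (is.null(cfg[[need]])) stop("scoring config lacks '", need, "'")
  }
  for (cls in HYDRO_CLASSES) {
    miss <- setdiff(METRIC_IDS, names(cfg$metrics[[cls]]))
    if (length(miss)) {
      stop(sprintf("scoring config: class %s lacks metric(s) %s",
                   cls, paste(miss, collapse = ", ")))
    }
  }
  structure(cfg, class = "scoring_config")
}

# range table for one metric+class as a data.frame(score, min, max)
metric_ranges <- function(config, metric_id, hydro_class) {
  rr <- config$metrics[[hydro_class]][[metric_id]]
  data.frame(score = vapply(rr, `[[`, numeric(1), "score"),
             min = vapply(rr, function(r) as.numeric(r$min), numeric(1)),
             max = vapply(rr, function(r) as.numeric(r$max), numeric(1)))
}

#' Score one metric value on the ordinal 0/4/7/11 scale
#'
#' The value is first rounded half away from zero to the metric's
#' printed precision (counts: integer; percentage: 1 decimal; average C
#' and FQI: 2 decimals); rounding closes the gaps between consecutive
#' printed ranges (35.0 vs 35.1, 22.99 vs 23.00), so every achievable
#' value lands in exactly one range.
#'
#' @param metric_id One of the nine metric identifiers (see
#'   [compute_metrics()]).
#' @param value Metric value.
#' @param hydro_class Wetland hydrologic class.
#' @param config A [load_scoring_config()] result.
#' @return Integer score: 0, 4, 7, or 11.
#' @examples
#' cfg <- load_scoring_config()
#' score_metric("pct_annual_biennial_introduced", 41.1, "temporarily_ponded", cfg)
#' score_metric("avg_c", 3.53, "seasonally_ponded", cfg)
#' @export
score_metric <- function(metric_id, value, hydro_class,
                         config = load_scoring_config()) {
  metric_id <- match.arg(metric_id, METRIC_IDS)
  hydro_class <- match.arg(hydro_class, HYDRO_CLASSES)
  stopifnot(is.numeric(value), length(value) == 1L, !is.na(value))
  prec <- config$metric_precision[[metric_id]]
  v <- round_half_up(value, prec)
  rr <- metric_ranges(config, metric_id, hydro_class)
  eps <- 10^(-prec) / 2 * 1e-6
  hit <- which(v >= rr$min - eps & v <= rr$max + eps)
  if (length(hit) != 1L) {
    stop(sprintf("mis-encoded scoring table: %s=%s (%s) falls in %d ranges",
                 metric_id, format(v), hydro_class, length(hit)))
  }
  as.integer(rr$score[hit])
}

#' Sum nine ordinal metric scores
#'
#' @param scores Numeric vector of exactly nine scores, each 0, 4, 7 or 11.
#' @return Integer total in `[0, 99]`.
#' @export
total_score <- function(scores) {
  if (length(scores) != 9L) stop("exactly nine metric scores are required")
  if (!all(scores %in% c(0, 4, 7, 11))) stop("scores must each be 0, 4, 7, or 11")
  as.integer(sum(scores))
}

#' Assign the condition category for a total score
#'
#' Categories partition the total range 0-99 per hydrologic class.
#' Seasonally ponded wetlands use five categories (Very poor through
#' Very good); temporarily ponded wetlands use three (Poor, Fair, Good —
#' no Very poor or Very good class exists for them).
#'
#' @param total Integer total score in `[0, 99]`.
#' @param hydro_class Wetland hydrologic class.
#' @param config A [load_scoring_config()] result.
#' @return Category label as a character scalar.
#' @examples
#' cfg <- load_scoring_config()
#' categorize(99, "seasonally_ponded", cfg)
#' categorize(0, "temporarily_ponded", cfg)
#' @export
categorize <- function(total, hydro_class, config = load_scoring_config()) {
  hydro_class <- match.arg(hydro_class, HYDRO_CLASSES)
  stopifnot(is.numeric(total), length(total) == 1L)
  if (is.na(total) || total < 0 || total > 99) {
    stop("total score must be in [0, 99], got ", total)
  }
  cats <- config$categories[[hydro_class]]
  for (c_ in cats) {
    if (total >= c_$min && total <= c_$max) return(c_$category)
  }
  stop("mis-encoded category table: no category for total ", total)
}

#' Condition category labels for a hydrologic class
#'
#' @param hydro_class Wetland hydrologic class.
#' @param config A [load_scoring_config()] result.
#' @return Character vector of category labels, worst first.
#' @export
category_levels <- function(hydro_class, config = load_scoring_config()) {
  hydro_class <- match.arg(hydro_class, HYDRO_CLASSES)
  vapply(config$categories[[hydro_class]], `[[`, character(1), "category")
}
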