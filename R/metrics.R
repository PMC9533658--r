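#' Floristic Quality Index
#'
#' The FQI is the average coefficient of conservatism multiplied by the
#' square root of the total number of native plant species. The mean is
#' taken over natives that carry a C-value; the richness term counts all
#' natives regardless of lifespan.
#'
#' @param mean_c Non-negative mean C-value.
#' @param n_native Non-negative count of native species.
#' @return `mean_c * sqrt(n_native)`.
#' @examples
#' fqi(4.0, 16)  # 16
#' fqi(5.75, 16) # 23
#' @export
fqi <- function(mean_c, n_native) {
  stopifnot(is.numeric(mean_c), is.numeric(n_native))
  if (mean_c < 0 || n_native < 0) stop("fqi() inputs must be non-negative")
  mean_c * sqrt(n_native)
}

#' Compute the nine IPCI metrics for one wetland
#'
#' Metrics are computed over the wetland-level species union (quadrat
#' and between-quadrat records alike); the two wet-meadow metrics use
#' the species attributed to the wet-meadow zone. The nine metrics, in
#' order:
#'
#' \describe{
#'   \item{`richness_native_perennial`}{species richness of native perennials}
#'   \item{`genera_native_perennial`}{number of genera of native perennials}
#'   \item{`native_grass_grasslike`}{number of native grass and
#'     grass-like (sedge/rush) species, any lifespan}
#'   \item{`pct_annual_biennial_introduced`}{percentage of annual,
#'     biennial, and introduced species among all species recorded
#'     (a species in the union counts once; unknown-trait species
#'     inflate only the denominator); 1 decimal}
#'   \item{`wetmeadow_native_perennial`}{native perennial species in the
#'     wet-meadow zone}
#'   \item{`count_c_ge_5`}{species with C-value >= 5}
#'   \item{`wetmeadow_count_c_ge_4`}{wet-meadow species with C-value >= 4}
#'   \item{`avg_c`}{mean C-value over natives carrying one; 2 decimals}
#'   \item{`fqi`}{[fqi()] of the unrounded mean C and the count of all
#'     native species; 2 decimals}
#' }
#'
#' Species absent from the trait table count in the percentage
#' denominator and nowhere else (a warning is issued); natives lacking a
#' C-value count in the richness metrics but not in `count_c_ge_5`,
#' `wetmeadow_count_c_ge_4`, `avg_c`, or the mean-C factor of the FQI.
#' An empty survey yields the all-zero vector.
#'
#' @param survey A [wetland_survey()].
#' @param traits A [trait_table()].
#' @return Named numeric vector of the nine metric values.
#' @export
compute_metrics <- function(survey, traits) {
  stopifnot(inherits(survey, "wetland_survey"), inherits(traits, "trait_table"))
  all_sp <- wetland_species_list(survey)
  wm_sp <- zone_species_list(survey, "wet_meadow")

  idx <- match(all_sp, traits$name)
  unknown <- all_sp[is.na(idx)]
  if (length(unknown)) {
    warning(sprintf("site %s: %d species not in trait table (%s); counted in total richness only",
                    survey$site_id, length(unknown),
                    paste(unknown, collapse = ", ")))
  }
  tr <- as.data.frame(traits)[idx[!is.na(idx)], , drop = FALSE]

  native <- tr$nativity == "native"
  perennial <- tr$lifespan == "perennial"
  has_c <- !is.na(tr$c_value)
  np <- tr[native & perennial, , drop = FALSE]

  m1 <- nrow(np)
  m2 <- length(unique(np$genus))
  m3 <- sum(native & tr$growth_form %in% c("grass", "grass_like"))
  abi <- sum(tr$lifespan %in% c("annual", "biennial") | tr$nativity == "introduced")
  m4 <- if (length(all_sp)) round_half_up(100 * abi / length(all_sp), 1) else 0
  wm <- tr[tr$name %in% wm_sp, , drop = FALSE]
  m5 <- sum(wm$nativity == "native" & wm$lifespan == "perennial")
  m6 <- sum(has_c & tr$c_value >= 5)
  m7 <- sum(!is.na(wm$c_value) & wm$c_value >= 4)
  mean_c <- if (any(native & has_c)) mean(tr$c_value[native & has_c]) else 0
  m8 <- round_half_up(mean_c, 2)
  m9 <- round_half_up(fqi(mean_c, sum(native)), 2)

  stats::setNames(as.numeric(c(m1, m2, m3, m4, m5, m6, m7, m8, m9)), METRIC_IDS)
}

#' Assess one wetland: metrics, scores, total, condition category
#'
#' Runs the full index for one survey: computes the nine metrics, scores
#' each on the 0/4/7/11 scale for the wetland's hydrologic class, sums
#' to the 0-99 total, and assigns the condition category. All
#' intermediate values are retained in the result.
#'
#' @param survey A [wetland_survey()].
#' @param traits A [trait_table()].
#' @param config A [load_scoring_config()] result.
#' @return An `ipci_result`: list with `site_id`, `hydro_class`,
#'   `grassland_type`, `sample_year`, `metrics` (named numeric, 9),
#'   `scores` (named integer, 9), `total` (integer), `category`.
#' @export
assess <- function(survey, traits, config = load_scoring_config()) {
  metrics <- compute_metrics(survey, traits)
  scores <- if (length(wetland_species_list(survey)) == 0L) {
    # no community to score: all nine scores are 0 (otherwise the
    # 0% short-lived/introduced share would spuriously hit the top class)
    stats::setNames(rep(0L, 9), METRIC_IDS)
  } else {
    vapply(METRIC_IDS, function(m) {
      score_metric(m, metrics[[m]], survey$hydro_class, config)
    }, integer(1))
  }
  total <- total_score(scores)
  structure(list(site_id = survey$site_id, hydro_class = survey$hydro_class,
                 grassland_type = survey$grassland_type,
                 sample_year = survey$sample_year,
                 metrics = metrics, scores = scores, total = total,
                 category = categorize(total, survey$hydro_class, config)),
            class = "ipci_result")
}

#' @export
print.ipci_result <- function(x, ...) {
  cat(sprintf("IPCI assessment for %s (%s)\n", x$site_id, x$hydro_class))
  tab <- data.frame(metric = METRIC_IDS, value = unname(x$metrics),
                    score = unname(x$scores))
  print(tab, row.names = FALSE)
  cat(sprintf("Total: %d / 99  ->  %s\n", x$total, x$category))
  invisible(x)
}

#' Assess many wetlands into one table
#'
#' @param surveys List of [wetland_survey()] objects.
#' @param traits A [trait_table()].
#' @param config A [load_scoring_config()] result.
#' @return Data frame, one row per wetland: identifiers, the nine metric
#'   values, the nine scores (columns prefixed `score_`), `total`, and
#'   `category`.
#' @export
assess_all <- function(surveys, traits, config = load_scoring_config()) {
  stopifnot(length(surveys) > 0)
  rows <- lapply(surveys, function(s) {
    r <- assess(s, traits, config)
    out <- data.frame(site_id = r$site_id, hydro_class = r$hydro_class,
                      grassland_type = r$grassland_type,
                      sample_year = r$sample_year)
    for (m in METRIC_IDS) out[[m]] <- r$metrics[[m]]
    for (m in METRIC_IDS) out[[paste0("score_", m)]] <- r$scores[[m]]
    out$total <- r$total
    out$category <- r$category
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write an assessment table to delimited text
#'
#' @param results Data frame from [assess_all()].
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(results, path, sep = ",") {
  utils::write.table(results, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
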