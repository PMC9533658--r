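CATEGORY_ORDER <- c("Very poor", "Poor", "Fair", "Good", "Very good")

#' Summarize assessed wetlands into unweighted condition tables
#'
#' Aggregates an [assess_all()] table the way a probability-sample
#' condition report does: number and percent of wetlands in each
#' condition category per group, plus the mean and standard deviation
#' of the total score. Counts are unweighted (every assessed wetland
#' counts once) and no confidence intervals are attached — the
#' summaries are category counts, not design-based estimates.
#' Percentages are reported to 1 decimal (half away from zero); the SD
#' uses the n-1 denominator.
#'
#' @param results Data frame from [assess_all()] (needs `total`,
#'   `category`, and any grouping columns).
#' @param group_by Character vector of column names to group by
#'   (e.g. `"grassland_type"`, `"hydro_class"`); `NULL` for one overall
#'   row.
#' @return Data frame with the grouping columns, `n`, one `pct_*`
#'   column per condition category (ordered worst to best), `mean_total`
#'   and `sd_total`.
#' @examples
#' \dontrun{
#' summarize_condition(results, group_by = "grassland_type")
#' }
#' @export
summarize_condition <- function(results, group_by = NULL) {
  if (is.null(results) || nrow(results) == 0L) stop("no assessment results to summarize")
  miss <- setdiff(group_by, names(results))
  if (length(miss)) stop("grouping column(s) not present: ", paste(miss, collapse = ", "))
  if (any(is.na(results[group_by]))) stop("missing grouping label(s) in results")

  key <- if (length(group_by)) {
    interaction(results[group_by], drop = TRUE, lex.order = TRUE, sep = "\r")
  } else {
    factor(rep("all", nrow(results)))
  }
  rows <- lapply(levels(key), function(k) {
    grp <- results[key == k, , drop = FALSE]
    out <- if (length(group_by)) {
      stats::setNames(as.data.frame(as.list(strsplit(k, "\r", fixed = TRUE)[[1]])),
                      group_by)
    } else {
      data.frame(group = "all")
    }
    out$n <- nrow(grp)
    for (cat in CATEGORY_ORDER) {
      col <- paste0("pct_", gsub(" ", "_", tolower(cat)))
      out[[col]] <- round_half_up(100 * sum(grp$category == cat) / nrow(grp), 1)
    }
    out$mean_total <- mean(grp$total)
    out$sd_total <- if (nrow(grp) > 1) stats::sd(grp$total) else 0
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Format a condition summary as a plain-text table
#'
#' @param summary Data frame from [summarize_condition()].
#' @return Character vector of formatted lines (also printed with
#'   `cat()` when at top level via [print()]).
#' @export
format_summary <- function(summary) {
  df <- summary
  df$mean_total <- sprintf("%.1f", df$mean_total)
  df$sd_total <- sprintf("%.1f", df$sd_total)
  widths <- vapply(names(df), function(cn) {
    max(nchar(cn), max(nchar(as.character(df[[cn]]))))
  }, numeric(1))
  fmt_row <- function(vals) {
    paste(mapply(formatC, as.character(vals), width = widths), collapse = "  ")
  }
  c(fmt_row(names(df)),
    paste(rep("-", sum(widths) + 2 * (ncol(df) - 1)), collapse = ""),
    apply(df, 1, fmt_row))
}

#' Write a condition summary to delimited text
#'
#' @param summary Data frame from [summarize_condition()].
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path, sep = ",") {
  utils::write.table(summary, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
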