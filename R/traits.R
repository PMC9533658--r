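#' Species trait tables
#'
#' A trait table supplies, for every species that can appear in a survey,
#' the attributes the condition metrics count over: nativity, lifespan,
#' growth form, genus, and — for native species only — a coefficient of
#' conservatism (C-value), an expert-assigned integer from 0 to 10
#' expressing fidelity to undisturbed habitat. Introduced species carry
#' no C-value.
#'
#' A `trait_table` is a data frame with columns `name`, `genus`,
#' `nativity`, `lifespan`, `growth_form`, `c_value` (integer, `NA` =
#' absent), one row per canonical species name, plus a `provenance`
#' attribute describing the source.
#'
#' @param df Data frame with the six trait columns (names need not be
#'   canonical yet).
#' @param provenance Free-text source label.
#' @return A validated `trait_table`.
#' @seealso [load_trait_table()], [trait_lookup()]
#' @export
trait_table <- function(df, provenance = "unspecified") {
  required <- c("name", "genus", "nativity", "lifespan", "growth_form", "c_value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("trait table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  df$name <- canonical_name(as.character(df$name))
  df$genus <- genus_of(df$name)
  df$nativity <- tolower(trimws(as.character(df$nativity)))
  df$lifespan <- tolower(trimws(as.character(df$lifespan)))
  df$growth_form <- tolower(trimws(as.character(df$growth_form)))
  cv <- df$c_value
  if (is.character(cv)) cv[!nzchar(trimws(cv))] <- NA
  df$c_value <- suppressWarnings(as.integer(cv))

  problems <- character(0)
  row_problem <- function(rows, what) {
    sprintf("row %d: %s", rows, what)
  }
  bad <- which(!nzchar(df$name))
  if (length(bad)) problems <- c(problems, row_problem(bad, "empty species name"))
  bad <- which(!df$nativity %in% NATIVITY)
  if (length(bad)) {
    problems <- c(problems, row_problem(bad, sprintf(
      "nativity '%s' not one of {%s}", df$nativity[bad], paste(NATIVITY, collapse = ", "))))
  }
  bad <- which(!df$lifespan %in% LIFESPAN)
  if (length(bad)) {
    problems <- c(problems, row_problem(bad, sprintf(
      "lifespan '%s' not one of {%s}", df$lifespan[bad], paste(LIFESPAN, collapse = ", "))))
  }
  bad <- which(!df$growth_form %in% GROWTH_FORM)
  if (length(bad)) {
    problems <- c(problems, row_problem(bad, sprintf(
      "growth_form '%s' not one of {%s}", df$growth_form[bad], paste(GROWTH_FORM, collapse = ", "))))
  }
  bad <- which(!is.na(df$c_value) & (df$c_value < 0 | df$c_value > 10))
  if (length(bad)) {
    problems <- c(problems, row_problem(bad, sprintf(
      "c_value %d outside [0, 10]", df$c_value[bad])))
  }
  # C-values express conservatism of the native flora; an introduced
  # species with one is a data error, not a convention difference
  bad <- which(!is.na(df$c_value) & df$nativity == "introduced")
  if (length(bad)) {
    problems <- c(problems, row_problem(bad, sprintf(
      "introduced species '%s' has a c_value", df$name[bad])))
  }
  dup <- df$name[duplicated(df$name) & nzchar(df$name)]
  for (nm in unique(dup)) {
    rows <- which(df$name == nm)
    problems <- c(problems, sprintf(
      "duplicate canonical name '%s' at rows %s", nm, paste(rows, collapse = ", ")))
  }
  if (length(problems)) {
    stop("invalid trait table:\n  ", paste(problems, collapse = "\n  "))
  }
  rownames(df) <- NULL
  structure(df, provenance = provenance, class = c("trait_table", "data.frame"))
}

#' Read a species trait table from delimited text
#'
#' The file must carry the header
#' `name,genus,nativity,lifespan,growth_form,c_value` (comma by default,
#' tab accepted via `sep`). Enum columns are matched case-insensitively;
#' an empty `c_value` field means the species has no assigned C-value.
#' Rows violating any invariant (out-of-range C-value, C-value on an
#' introduced species, duplicate canonical name) abort the load with
#' row-numbered diagnostics.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @param provenance Source label stored on the table; defaults to `path`.
#' @return A `trait_table`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("name,genus,nativity,lifespan,growth_form,c_value",
#'              "Poa pratensis,Poa,introduced,perennial,grass,",
#'              "Carex praegracilis,Carex,native,perennial,grass_like,4"), f)
#' tr <- load_trait_table(f)
#' nrow(tr)
#' @export
load_trait_table <- function(path, sep = ",", provenance = path) {
  if (!file.exists(path)) stop("trait table file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", strip.white = TRUE,
                          fileEncoding = "UTF-8", check.names = TRUE)
  trait_table(df, provenance = provenance)
}

#' Write a trait table back to delimited text
#'
#' Inverse of [load_trait_table()]: loading the written file reproduces a
#' canonically equal table.
#'
#' @param table A `trait_table`.
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "trait_table"))
  df <- as.data.frame(table)
  df$c_value <- ifelse(is.na(df$c_value), "", as.character(df$c_value))
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Look up one species in a trait table
#'
#' Lookup is case- and whitespace-insensitive: the query is canonicalized
#' first. An unknown species is a typed outcome (`NULL`), not an error,
#' so callers can apply the unknown-species policy (count in the total
#' richness denominator, contribute to no native or C-value metric).
#'
#' @param table A `trait_table`.
#' @param name Scientific name (any capitalization/spacing).
#' @return A one-row data frame of the trait record, or `NULL` if the
#'   species is not in the table.
#' @export
trait_lookup <- function(table, name) {
  stopifnot(inherits(table, "trait_table"))
  nm <- canonical_name(name)
  i <- match(nm, table$name)
  if (is.na(i)) return(NULL)
  as.data.frame(table)[i, , drop = FALSE]
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("Species trait table: %d species (%d native), source: %s\n",
              nrow(x), sum(x$nativity == "native"), attr(x, "provenance")))
  NextMethod()
}
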