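#' Round half away from zero
#'
#' Deterministic commercial rounding used everywhere a value is compared
#' against a printed scoring range: exact halves move away from zero,
#' unlike [base::round()]'s round-half-to-even. A tiny guard absorbs
#' binary floating-point representation error (e.g. `4.665 * 100` being
#' stored just under `466.5`).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (>= 0).
#' @return `x` rounded to `digits` places.
#' @examples
#' round_half_up(2.5, 0)   # 3, not 2
#' round_half_up(4.665, 2) # 4.67
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Canonicalize a scientific name
#'
#' Trims and collapses whitespace, capitalizes the genus, lowercases the
#' epithet and any trailing tokens, and preserves hybrid markers
#' (`x` / `×` between tokens is kept as `×`). All species
#' lookups and set operations run on canonical names, so
#' `"  poa PRATENSIS "` and `"Poa pratensis"` are the same species.
#'
#' @param name Character vector of scientific names.
#' @return Character vector of canonical binomials.
#' @examples
#' canonical_name("  poa PRATENSIS ")
#' canonical_name("TYPHA x GLAUCA")
#' @export
canonical_name <- function(name) {
  stopifnot(is.character(name))
  vapply(name, function(nm) {
    nm <- gsub("\\s+", " ", trimws(nm))
    if (!nzchar(nm)) return("")
    toks <- strsplit(nm, " ", fixed = TRUE)[[1]]
    out <- character(length(toks))
    for (i in seq_along(toks)) {
      tk <- toks[i]
      if (tk %in% c("x", "X", "×") && i > 1L) {
        out[i] <- "×"
      } else if (i == 1L) {
        out[i] <- paste0(toupper(substr(tk, 1, 1)), tolower(substr(tk, 2, nchar(tk))))
      } else {
        out[i] <- tolower(tk)
      }
    }
    paste(out, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# genus = first whitespace-delimited token of the canonical name
genus_of <- function(canonical) {
  vapply(strsplit(canonical, " ", fixed = TRUE),
         function(t) if (length(t)) t[[1]] else "", character(1))
}

#' Largest-remainder apportionment
#'
#' Splits an integer `total` across categories in proportion to
#' `weights`, rounding by the largest-remainder (Hamilton) rule so the
#' parts always sum to `total`. Remainder ties are broken in favor of
#' the earlier category.
#'
#' @param total Non-negative integer to apportion.
#' @param weights Non-negative weights, at least one positive.
#' @return Integer vector of the same length as `weights` summing to `total`.
#' @examples
#' largest_remainder(5, c(0.4, 0.6)) # 2 3
#' @export
largest_remainder <- function(total, weights) {
  stopifnot(total >= 0, all(weights >= 0), sum(weights) > 0)
  total <- as.integer(total)
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- quota - base
    # order(-frac) ranks by decreasing remainder; ties keep input order
    take <- order(-frac)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# deterministic 31-bit integer hash of small non-negative integer keys;
# used for counter-based randomization that never touches R's RNG stream
int_hash <- function(...) {
  keys <- c(...)
  h <- 2166136261
  for (k in keys) {
    h <- (h + (k %% 2147483647) + 1) %% 2147483647
    h <- (h * 48271) %% 2147483647
    h <- (h * 69621 + 1013904223) %% 2147483647
  }
  h
}

# uniform deviate in [0, 1) derived from a hash
hash_unif <- function(...) int_hash(...) / 2147483647
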