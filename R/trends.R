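#' Yearly record and richness table by source
#'
#' Aggregates cleaned records into the table that temporal trend models
#' consume: for every year and source category, the number of records and the
#' species richness (distinct species recorded that year by that source).
#' Year-source combinations without records are emitted with zeros across the
#' global year range, so downstream smoothers see a complete design.
#'
#' @param records Cleaned occurrence table.
#' @param complete Emit zero rows for empty year-source combinations
#'   (default `TRUE`).
#' @return Tibble with `year`, `source`, `n_records`, `n_species`.
#' @export
yearly_table <- function(records, complete = TRUE) {
  records <- validate_occurrences(records)
  if (any(is.na(records$year))) {
    abort("Yearly tables need cleaned records (no missing years).")
  }
  out <- records %>%
    group_by(.data$year, .data$source) %>%
    summarise(n_records = n(), n_species = n_distinct(.data$species),
              .groups = "drop")
  if (complete && nrow(out) > 0) {
    out <- out %>%
      complete(year = seq(min(.data$year), max(.data$year)),
               source = occ_sources(),
               fill = list(n_records = 0L, n_species = 0L))
  }
  arrange(out, .data$year, .data$source)
}

#' Species-level yearly record counts
#'
#' One row per (species, year, source) with at least one record — the
#' finest-grained aggregation, i.e. the observation response of
#' records-per-species-year-source models.
#'
#' @param records Cleaned occurrence table.
#' @return Tibble with `species`, `year`, `source`, `n_records`.
#' @export
yearly_species_table <- function(records) {
  records <- validate_occurrences(records)
  if (any(is.na(records$year))) {
    abort("Yearly tables need cleaned records (no missing years).")
  }
  records %>%
    count(.data$species, .data$year, .data$source, name = "n_records") %>%
    arrange(.data$species, .data$year, .data$source)
}

#' Split records into periods around a pivot year
#'
#' Counts records (and their per-source composition) before and after a split
#' year. By default the boundary year counts as "after" (before means
#' strictly earlier); set `boundary = "inclusive"` to place the boundary year
#' in "before" instead. Year-assigned sub-counts are reported per source and
#' period.
#'
#' @param records Cleaned occurrence table.
#' @param split_year Pivot year (default 2005).
#' @param boundary `"strict"` (before = year < split) or `"inclusive"`
#'   (before = year <= split).
#' @return A `period_split` list: `split_year`, `n_before`, `n_after`,
#'   `pct_before`, `pct_after`, and tibbles `before_by_source` /
#'   `after_by_source` (`source`, `n`, `pct` within the period,
#'   `n_year_assigned`).
#' @export
period_split <- function(records, split_year = 2005, boundary = c("strict", "inclusive")) {
  boundary <- match.arg(boundary)
  records <- validate_occurrences(records)
  if (any(is.na(records$year))) {
    abort("Period splits need cleaned records (no missing years).")
  }
  before <- if (boundary == "strict") records$year < split_year else records$year <= split_year
  tally <- function(sub) {
    sub %>%
      group_by(.data$source) %>%
      summarise(n = n(), n_year_assigned = sum(.data$year_assigned),
                .groups = "drop") %>%
      complete(source = occ_sources(), fill = list(n = 0L, n_year_assigned = 0L)) %>%
      mutate(pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else 0) %>%
      select(all_of(c("source", "n", "pct", "n_year_assigned")))
  }
  n_total <- nrow(records)
  structure(list(
    split_year = split_year,
    boundary = boundary,
    n_before = sum(before),
    n_after = sum(!before),
    pct_before = if (n_total > 0) 100 * sum(before) / n_total else NA_real_,
    pct_after = if (n_total > 0) 100 * sum(!before) / n_total else NA_real_,
    before_by_source = tally(records[before, , drop = FALSE]),
    after_by_source = tally(records[!before, , drop = FALSE])
  ), class = "period_split")
}

#' @export
print.period_split <- function(x, ...) {
  rel <- if (x$boundary == "strict") "<" else "<="
  cat("Period split at ", x$split_year, " (before means year ", rel, " ",
      x$split_year, ")\n", sep = "")
  cat(sprintf("  before: %d (%.1f%%)   after: %d (%.1f%%)\n",
              x$n_before, x$pct_before, x$n_after, x$pct_after))
  cat("  after-period composition:\n")
  ab <- x$after_by_source
  for (i in seq_len(nrow(ab))) {
    cat(sprintf("    %-24s %6d (%.1f%%, %d year-assigned)\n",
                ab$source[i], ab$n[i], ab$pct[i], ab$n_year_assigned[i]))
  }
  invisible(x)
}
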