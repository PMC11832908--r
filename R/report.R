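#' One-call summary of a multi-source occurrence dataset
#'
#' Runs the whole pipeline on an occurrence table and gathers the headline
#' quantities in one object: the cleaning tallies, per-source species
#' inventories, community extinction potential with all sources and with
#' citizen science excluded, the "last seen before cutoff" and "not recorded
#' in the final year" species screens, grid occupancy by source, and the
#' period split around a pivot year.
#'
#' @param records Occurrence table (raw, possibly with missing years; cleaning
#'   is applied first).
#' @param end_year Final survey year.
#' @param cutoff Last-seen screening year (default 1996).
#' @param split_year Period-split pivot (default 2005).
#' @param grid A [grid_spec()] for the occupancy computation.
#' @return A `dataset_report` list with elements `cleaning`, `inventory`,
#'   `pets_all`, `pets_no_citizen_science`, `last_seen_before`,
#'   `not_in_end_year`, `occupancy`, `period` and `end_year`.
#' @export
dataset_report <- function(records, end_year = NULL, cutoff = 1996,
                           split_year = 2005, grid = grid_spec()) {
  cleaned <- clean_records(records, end_year = end_year)
  recs <- cleaned$records
  end_year <- cleaned$report$end_year

  tl_all <- build_timelines(recs, end_year = end_year)
  tl_ncs <- build_timelines(recs, end_year = end_year,
                            exclude_sources = "citizen_science")

  structure(list(
    cleaning = cleaned$report,
    inventory = species_inventory(recs),
    pets_all = pets_community(tl_all),
    pets_no_citizen_science = pets_community(tl_ncs),
    last_seen_before = species_last_seen_before(tl_all, cutoff),
    cutoff = cutoff,
    not_in_end_year = species_last_seen_before(tl_all, end_year),
    occupancy = occupancy_by_source(recs, grid),
    period = period_split(recs, split_year = split_year),
    end_year = end_year,
    records = recs
  ), class = "dataset_report")
}

#' @export
print.dataset_report <- function(x, ...) {
  print(x$cleaning)
  cat("\nSpecies: ", x$inventory$n_species, " overall; missing per source: ",
      paste(names(x$inventory$missing_by_source),
            x$inventory$missing_by_source, sep = "=", collapse = ", "),
      "\n\n", sep = "")
  cat(sprintf("Community extinction potential: %.2f%% (all sources), %.2f%% (no citizen science)\n",
              x$pets_all$pooled_ratio, x$pets_no_citizen_science$pooled_ratio))
  cat("Species last seen before ", x$cutoff, ": ", nrow(x$last_seen_before),
      "; not recorded in ", x$end_year, ": ", nrow(x$not_in_end_year), "\n\n",
      sep = "")
  occ <- x$occupancy$occupancy
  for (i in seq_len(nrow(occ))) {
    cat(sprintf("  %-24s occupies %d / %d cells (%.0f%%)\n", occ$source[i],
                occ$n_cells[i], occ$total_cells[i], occ$pct[i]))
  }
  cat("\n")
  print(x$period)
  invisible(x)
}
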