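#' Read a multi-source occurrence table
#'
#' Reads a delimited text file (comma or tab separated, UTF-8, header row) into
#' a tidy occurrence table. Column names and category tokens are resolved
#' through an [occ_dialect()], so differently-labelled tables parse without
#' code changes. Unparseable or blank years become missing values rather than
#' errors; row order is preserved. Rows whose coordinates are only half present
#' have both coordinates blanked (with a warning), since a record is either
#' georeferenced or not.
#'
#' @param path Path to the delimited file.
#' @param dialect An [occ_dialect()]; defaults to the canonical column names.
#' @return A tibble with columns `species`, `year` (integer, `NA` allowed),
#'   `source`, `lat`, `lon`, `resolution`, `year_assigned`.
#' @seealso [clean_records()], [write_occurrences()]
#' @export
read_occurrences <- function(path, dialect = occ_dialect()) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0 || !nzchar(trimws(header[1]))) {
    abort(paste0("Empty occurrence file: ", path))
  }
  delim <- dialect$delim
  if (is.null(delim)) delim <- if (grepl("\t", header[1])) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE,
                           na = c("", "NA"))
  if (nrow(raw) == 0) abort(paste0("Occurrence file has a header but no rows: ", path))

  cols <- dialect$columns
  for (field in c("species", "source")) {
    if (!(cols[[field]] %in% names(raw))) {
      abort(paste0("Mandatory column '", cols[[field]], "' (field '", field,
                   "') is missing from ", path))
    }
  }
  grab <- function(field) {
    cn <- cols[[field]]
    if (is.na(cn) || !(cn %in% names(raw))) rep(NA_character_, nrow(raw)) else raw[[cn]]
  }

  species <- canonical_species(grab("species"))
  if (any(is.na(species))) {
    abort("Occurrence file contains rows with an empty species name.")
  }

  year <- suppressWarnings(as.integer(grab("year")))

  src_tokens <- tolower(trimws(grab("source")))
  src_lookup <- setNames(unname(dialect$source_map), tolower(trimws(names(dialect$source_map))))
  source <- unname(src_lookup[src_tokens])
  if (any(is.na(source))) {
    bad <- unique(src_tokens[is.na(source)])
    abort(paste0("Source token(s) not covered by the dialect: ",
                 paste(bad, collapse = ", ")))
  }

  res_tokens <- tolower(trimws(grab("resolution")))
  res_lookup <- setNames(unname(dialect$resolution_map),
                         tolower(trimws(names(dialect$resolution_map))))
  resolution <- unname(res_lookup[res_tokens])
  resolution[is.na(resolution)] <- "unknown"

  lat <- suppressWarnings(as.numeric(grab("lat")))
  lon <- suppressWarnings(as.numeric(grab("lon")))
  one_sided <- xor(is.na(lat), is.na(lon))
  if (any(one_sided)) {
    warn(paste0(sum(one_sided), " record(s) had only one coordinate; both were",
                " set to missing."))
    lat[one_sided] <- NA_real_
    lon[one_sided] <- NA_real_
  }

  ya_tokens <- tolower(trimws(grab("year_assigned")))
  year_assigned <- ya_tokens %in% c("true", "t", "1", "yes", "y")

  validate_occurrences(tibble(
    species = species, year = year, source = source,
    lat = lat, lon = lon, resolution = resolution,
    year_assigned = year_assigned
  ))
}

#' Write an occurrence table back to delimited text
#'
#' Emits records in the same dialect that [read_occurrences()] accepts, so a
#' read-write-read round trip preserves every field. Canonical column names
#' and category tokens are used.
#'
#' @param records Validated occurrence table.
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(records, path, delim = ",") {
  records <- validate_occurrences(records)
  readr::write_delim(records, path, delim = delim, na = "")
  invisible(path)
}

#' Clean an occurrence table and tally what was dropped
#'
#' Applies the record-exclusion rules: records without a year are dropped (they
#' cannot enter any time-based analysis), and records whose year falls outside
#' the plausible bounds are rejected with their own counter. Cleaning never
#' hard-fails: every pathology is counted in the report. Records with a year
#' but no coordinates are retained (they participate in the extinction
#' statistic and the yearly tables, and are excluded only from gridding).
#'
#' @param records Occurrence table from [read_occurrences()] or
#'   [generate_occurrences()].
#' @param end_year Final survey year; must be at least the maximum year present.
#' @param year_bounds Length-2 integer vector of acceptable years, default
#'   `c(1700, end_year)`; the upper bound is always capped at `end_year`, so
#'   no retained record can postdate the final survey year.
#' @return A list with elements `records` (the retained rows, all with a year)
#'   and `report` (a `cleaning_report`).
#' @export
clean_records <- function(records, end_year = NULL, year_bounds = NULL) {
  records <- validate_occurrences(records)
  if (is.null(end_year)) {
    if (all(is.na(records$year))) abort("No record has a year; supply end_year.")
    end_year <- max(records$year, na.rm = TRUE)
  }
  end_year <- as.integer(end_year)
  if (is.null(year_bounds)) year_bounds <- c(1700L, end_year)
  year_bounds[2] <- min(year_bounds[2], end_year)

  no_year <- is.na(records$year)
  oob <- !no_year & (records$year < year_bounds[1] | records$year > year_bounds[2])
  kept <- records[!no_year & !oob, , drop = FALSE]

  by_source <- kept %>%
    count(.data$source, name = "n") %>%
    complete(source = occ_sources(), fill = list(n = 0L)) %>%
    mutate(pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else 0)

  by_res <- kept %>%
    count(.data$resolution, name = "n") %>%
    complete(resolution = occ_resolutions(), fill = list(n = 0L))

  report <- structure(list(
    n_input = nrow(records),
    n_retained = nrow(kept),
    n_dropped_no_year = sum(no_year),
    n_dropped_year_out_of_bounds = sum(oob),
    n_year_assigned = sum(kept$year_assigned),
    n_georeferenced = sum(!is.na(kept$lat)),
    counts_by_resolution = setNames(by_res$n, by_res$resolution),
    counts_by_source = by_source,
    n_distinct_years = n_distinct(kept$year),
    year_range = if (nrow(kept) > 0) range(kept$year) else c(NA_integer_, NA_integer_),
    end_year = end_year,
    year_bounds = as.integer(year_bounds)
  ), class = "cleaning_report")

  list(records = kept, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Occurrence cleaning report\n")
  cat("  input records:     ", x$n_input, "\n")
  cat("  retained:          ", x$n_retained, "\n")
  cat("  dropped (no year): ", x$n_dropped_no_year, "\n")
  if (x$n_dropped_year_out_of_bounds > 0) {
    cat("  dropped (year out of bounds):", x$n_dropped_year_out_of_bounds, "\n")
  }
  cat("  year-assigned:     ", x$n_year_assigned, "\n")
  cat("  georeferenced:     ", x$n_georeferenced, "\n")
  if (x$n_retained > 0) {
    cat("  years: ", x$year_range[1], "-", x$year_range[2], " (",
        x$n_distinct_years, " distinct record years)\n", sep = "")
  }
  src <- x$counts_by_source
  for (i in seq_len(nrow(src))) {
    cat(sprintf("  %-24s %6d (%.1f%%)\n", src$source[i], src$n[i], src$pct[i]))
  }
  invisible(x)
}

#' Serialise a cleaning report to JSON
#'
#' @param report A `cleaning_report` from [clean_records()].
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
cleaning_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "cleaning_report"))
  payload <- unclass(report)
  payload$counts_by_resolution <- as.list(payload$counts_by_resolution)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Per-source species inventories
#'
#' Species sets recorded by each source category, their union, and how many
#' species of the union each source misses — the "which source sees which
#' species" comparison.
#'
#' @param records Cleaned occurrence table.
#' @return A list with `by_source` (named list of sorted species vectors),
#'   `all_species` (sorted union), `n_species`, `missing_by_source` (named
#'   integer) and `missing_pct` (named numeric, percentage of the union).
#' @export
species_inventory <- function(records) {
  records <- validate_occurrences(records)
  by_source <- lapply(setNames(occ_sources(), occ_sources()), function(s) {
    sort(unique(records$species[records$source == s]))
  })
  all_species <- sort(unique(records$species))
  missing <- vapply(by_source, function(sp) length(setdiff(all_species, sp)), integer(1))
  pct <- if (length(all_species) > 0) 100 * missing / length(all_species) else missing * 0
  list(by_source = by_source,
       all_species = all_species,
       n_species = length(all_species),
       missing_by_source = missing,
       missing_pct = pct)
}
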