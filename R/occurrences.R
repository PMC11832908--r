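#' Source categories of an occurrence record
#'
#' Occurrence records carry exactly one of three provenance classes:
#' `literature_collections` (semi-structured historical data from faunistic
#' literature and museum collections), `citizen_science` (opportunistic,
#' validated public records) and `sampling` (structured expert surveys).
#'
#' @return Character vector of the three canonical source labels.
#' @export
occ_sources <- function() {
  c("literature_collections", "citizen_science", "sampling")
}

#' Spatial resolution classes of an occurrence record
#'
#' @return Character vector of the canonical resolution labels: 1 km, 3 km and
#'   10 km representative resolutions plus `unknown` for records reported only
#'   at region level.
#' @export
occ_resolutions <- function() {
  c("res_1km", "res_3km", "res_10km", "unknown")
}

#' Canonicalise species names
#'
#' Matching of species names across sources is an exact string match after
#' whitespace trimming/squishing and case normalisation to standard binomial
#' form (genus capitalised, epithets lower case). No fuzzy synonymy is
#' attempted: the intended use is data already on a single regional checklist
#' nomenclature.
#'
#' @param x Character vector of raw species names.
#' @return Character vector of canonical names.
#' @export
canonical_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  out <- tolower(x)
  substr(out, 1, 1) <- toupper(substr(out, 1, 1))
  out[is.na(x) | x == ""] <- NA_character_
  out
}

#' Column dialect for occurrence tables
#'
#' Describes how a delimited occurrence table maps onto the semantic fields of
#' an occurrence record, so that differently-labelled tables parse without code
#' changes. The default dialect expects columns `species`, `year`, `source`,
#' `lat`, `lon`, `resolution`, `year_assigned` with the canonical tokens of
#' [occ_sources()] and [occ_resolutions()].
#'
#' @param columns Named character vector mapping semantic field names
#'   (`species`, `year`, `source`, `lat`, `lon`, `resolution`, `year_assigned`)
#'   to column names in the file. `species` and `source` are mandatory; any
#'   other field may be mapped to `NA` if the file lacks it.
#' @param source_map Named character vector mapping file tokens to canonical
#'   source labels, e.g. `c(CS = "citizen_science")`. Tokens are matched
#'   case-insensitively after trimming.
#' @param resolution_map Named character vector mapping file tokens to
#'   canonical resolution labels.
#' @param delim Field delimiter; `NULL` auto-detects tab vs comma from the
#'   header line.
#' @return An object of class `occ_dialect`.
#' @export
occ_dialect <- function(columns = c(species = "species", year = "year",
                                    source = "source", lat = "lat", lon = "lon",
                                    resolution = "resolution",
                                    year_assigned = "year_assigned"),
                        source_map = setNames(occ_sources(), occ_sources()),
                        resolution_map = setNames(occ_resolutions(), occ_resolutions()),
                        delim = NULL) {
  defaults <- c(species = "species", year = "year", source = "source",
                lat = "lat", lon = "lon", resolution = "resolution",
                year_assigned = "year_assigned")
  cols <- defaults
  cols[names(columns)] <- columns
  unknown <- setdiff(names(columns), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown dialect field(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.na(cols["species"]) || is.na(cols["source"])) {
    abort("Dialect must map the mandatory fields 'species' and 'source'.")
  }
  bad_src <- setdiff(unname(source_map), occ_sources())
  if (length(bad_src) > 0) {
    abort(paste0("source_map targets outside the canonical categories: ",
                 paste(bad_src, collapse = ", ")))
  }
  bad_res <- setdiff(unname(resolution_map), occ_resolutions())
  if (length(bad_res) > 0) {
    abort(paste0("resolution_map targets outside the canonical classes: ",
                 paste(bad_res, collapse = ", ")))
  }
  structure(list(columns = cols, source_map = source_map,
                 resolution_map = resolution_map, delim = delim),
            class = "occ_dialect")
}

#' @export
print.occ_dialect <- function(x, ...) {
  cat("<occ_dialect>\n")
  cat("  columns: ",
      paste(names(x$columns), unname(x$columns), sep = "=", collapse = ", "),
      "\n", sep = "")
  cat("  source tokens: ",
      paste(names(x$source_map), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Validate an occurrence table
#'
#' Checks the structural invariants of a table of occurrence records: required
#' columns, source and resolution labels drawn from the canonical sets, years
#' integer or missing, and coordinates either both present or both absent on
#' every row.
#'
#' @param records A data frame of occurrence records.
#' @return The validated records as a tibble (invisibly usable in pipes).
#' @export
validate_occurrences <- function(records) {
  records <- as_tibble(records)
  needed <- c("species", "year", "source", "lat", "lon", "resolution",
              "year_assigned")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Occurrence table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(records$species) | records$species == "")) {
    abort("Occurrence table contains records without a species name.")
  }
  bad_source <- setdiff(unique(records$source), occ_sources())
  if (length(bad_source) > 0) {
    abort(paste0("Unknown source categor",
                 if (length(bad_source) > 1) "ies: " else "y: ",
                 paste(bad_source, collapse = ", ")))
  }
  bad_res <- setdiff(unique(records$resolution), occ_resolutions())
  if (length(bad_res) > 0) {
    abort(paste0("Unknown resolution class(es): ",
                 paste(bad_res, collapse = ", ")))
  }
  one_sided <- xor(is.na(records$lat), is.na(records$lon))
  if (any(one_sided)) {
    abort(paste0(sum(one_sided),
                 " record(s) carry exactly one of lat/lon; coordinates must be",
                 " both present or both absent."))
  }
  records$year <- as.integer(records$year)
  records$year_assigned <- as.logical(records$year_assigned)
  records
}
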