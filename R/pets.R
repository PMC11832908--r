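#' Build per-species record timelines
#'
#' Collapses a cleaned occurrence table into one timeline per species: the
#' sorted record years split by source, the first record year and the last
#' occasion year, relative to a final survey year. Records from excluded
#' sources are removed first; species left with no records at all are omitted
#' from the timelines and reported in the `dropped_species` attribute, since
#' the extinction statistic needs a first record within the retained data.
#'
#' @param records Cleaned occurrence table (every record has a year).
#' @param end_year Final survey year; defaults to the maximum year present in
#'   `records`. Must not precede any record year.
#' @param exclude_sources Character vector of source categories to drop before
#'   building timelines (subset of [occ_sources()]).
#' @return A `pets_timelines` tibble with columns `species`, `first_record`,
#'   `last_occasion`, `n_records`, `n_years` and the list-column
#'   `years_by_source`; attributes `end_year`, `excluded_sources`,
#'   `dropped_species`.
#' @export
build_timelines <- function(records, end_year = NULL, exclude_sources = character()) {
  records <- validate_occurrences(records)
  if (any(is.na(records$year))) {
    abort("Timelines need cleaned records: some records lack a year (run clean_records()).")
  }
  bad <- setdiff(exclude_sources, occ_sources())
  if (length(bad) > 0) {
    abort(paste0("exclude_sources contains unknown categor",
                 if (length(bad) > 1) "ies: " else "y: ",
                 paste(bad, collapse = ", ")))
  }
  if (is.null(end_year)) end_year <- max(records$year)
  end_year <- as.integer(end_year)

  all_species <- sort(unique(records$species))
  kept <- records[!(records$source %in% exclude_sources), , drop = FALSE]
  if (nrow(kept) > 0 && end_year < max(kept$year)) {
    abort(paste0("end_year (", end_year, ") is earlier than the latest record year (",
                 max(kept$year), ")."))
  }

  tl <- kept %>%
    group_by(.data$species) %>%
    summarise(first_record = min(.data$year),
              last_occasion = max(.data$year),
              n_records = n(),
              n_years = n_distinct(.data$year),
              years_by_source = list(split(.data$year, .data$source) |>
                                       lapply(function(v) sort(unique(v)))),
              .groups = "drop") %>%
    arrange(.data$species)

  structure(tl,
            class = c("pets_timelines", class(tl)),
            end_year = end_year,
            excluded_sources = exclude_sources,
            dropped_species = setdiff(all_species, tl$species))
}

#' @export
print.pets_timelines <- function(x, ...) {
  cat("Species timelines: ", nrow(x), " species, end year ",
      attr(x, "end_year"), "\n", sep = "")
  excl <- attr(x, "excluded_sources")
  if (length(excl) > 0) cat("  excluded sources:", paste(excl, collapse = ", "), "\n")
  dropped <- attr(x, "dropped_species")
  if (length(dropped) > 0) {
    cat("  species dropped (no record left):", length(dropped), "\n")
  }
  NextMethod()
}

#' Per-species extinction potential (PETS)
#'
#' The PETS statistic for a species is the fraction of its known regional
#' history during which it has gone unobserved:
#' \deqn{(Y_{end} - y_{last}) / (Y_{end} - y_{first})}
#' where \eqn{Y_{end}} is the final survey year, \eqn{y_{last}} the last
#' occasion and \eqn{y_{first}} the first record. It is 0 exactly when the
#' species was recorded in the final year. A species whose only record year is
#' historical (first = last, before the final year) takes the value 1 under
#' the literal formula, so the range is \[0, 1\]; such species are flagged
#' with a warning. A species whose only record year *is* the final year
#' (presence span 0) takes the value 0.
#'
#' @param timelines A `pets_timelines` object from [build_timelines()].
#' @return A tibble sorted by `last_occasion` descending (ties alphabetical)
#'   with columns `species`, `first_record`, `last_occasion`, `absence_years`,
#'   `presence_span`, `absence_fraction`.
#' @export
pets_species <- function(timelines) {
  stopifnot(inherits(timelines, "pets_timelines"))
  end_year <- attr(timelines, "end_year")
  out <- timelines %>%
    as_tibble() %>%
    mutate(absence_years = .env$end_year - .data$last_occasion,
           presence_span = .env$end_year - .data$first_record,
           absence_fraction = ifelse(.data$presence_span > 0,
                                     .data$absence_years / .data$presence_span,
                                     0)) %>%
    select(all_of(c("species", "first_record", "last_occasion",
                    "absence_years", "presence_span", "absence_fraction"))) %>%
    arrange(desc(.data$last_occasion), .data$species)
  n_one <- sum(out$absence_fraction == 1)
  if (n_one > 0) {
    warn(paste0(n_one, " species with a single historical record year take the",
                " maximal absence fraction 1."))
  }
  attr(out, "end_year") <- end_year
  out
}

#' Community extinction potential
#'
#' Aggregates per-species absence fractions into the community-level
#' extinction potential, expressed as a percentage. The default pooled ratio
#' divides the summed absence spans (time since each species' last record) by
#' the summed presence spans (time since each species' first record) — the
#' ratio of total "red" to total "red + green" bar length on the persistence
#' timeline. The unweighted mean of per-species fractions is also computed as
#' a sensitivity; the two coincide whenever all species share the same first
#' record year.
#'
#' @param timelines A `pets_timelines` object.
#' @param aggregation `"pooled_ratio"` (default) or `"mean_of_ratios"`; selects
#'   which value is reported as `community_extinction_potential` (both are
#'   always returned).
#' @return A `pets_community` list with elements
#'   `community_extinction_potential` (percentage under the chosen
#'   aggregation), `aggregation`, `pooled_ratio`, `mean_of_ratios`,
#'   `n_species`, `end_year`, `excluded_sources`, `dropped_species` and the
#'   per-species table `species_results` sorted by last occasion (most recent
#'   first).
#' @export
pets_community <- function(timelines, aggregation = c("pooled_ratio", "mean_of_ratios")) {
  aggregation <- match.arg(aggregation)
  sp <- suppressWarnings(pets_species(timelines))
  if (nrow(sp) == 0) abort("No species timeline to aggregate.")
  spanned <- sp[sp$presence_span > 0, , drop = FALSE]
  if (nrow(spanned) == 0) {
    abort("Degenerate community: every species has presence span 0.")
  }
  pooled <- 100 * sum(spanned$absence_years) / sum(spanned$presence_span)
  mean_r <- 100 * mean(sp$absence_fraction)
  structure(list(
    community_extinction_potential = if (aggregation == "pooled_ratio") pooled else mean_r,
    aggregation = aggregation,
    pooled_ratio = pooled,
    mean_of_ratios = mean_r,
    n_species = nrow(sp),
    end_year = attr(timelines, "end_year"),
    excluded_sources = attr(timelines, "excluded_sources"),
    dropped_species = attr(timelines, "dropped_species"),
    species_results = sp
  ), class = "pets_community")
}

#' @export
print.pets_community <- function(x, ...) {
  cat("Community extinction potential (PETS)\n")
  cat(sprintf("  %-18s %.2f%%\n", "pooled ratio:", x$pooled_ratio))
  cat(sprintf("  %-18s %.2f%%\n", "mean of ratios:", x$mean_of_ratios))
  cat("  species:", x$n_species, " end year:", x$end_year, "\n")
  if (length(x$excluded_sources) > 0) {
    cat("  excluded sources:", paste(x$excluded_sources, collapse = ", "), "\n")
  }
  if (length(x$dropped_species) > 0) {
    cat("  species dropped by exclusion:", length(x$dropped_species), "\n")
  }
  invisible(x)
}

#' Serialise a community PETS result to JSON
#'
#' @param x A `pets_community` object.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
pets_community_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "pets_community"))
  payload <- unclass(x)
  payload$species_results <- as.data.frame(payload$species_results)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Species whose last record precedes a cutoff year
#'
#' The "no longer reported" screen: species whose last occasion is strictly
#' before `cutoff`, sorted by last occasion ascending (oldest disappearances
#' first), ties broken alphabetically.
#'
#' @param timelines A `pets_timelines` object (usually built on all sources).
#' @param cutoff Cutoff year (exclusive).
#' @return Tibble with `species`, `first_record`, `last_occasion`, `n_records`.
#' @export
species_last_seen_before <- function(timelines, cutoff) {
  stopifnot(inherits(timelines, "pets_timelines"))
  timelines %>%
    as_tibble() %>%
    filter(.data$last_occasion < cutoff) %>%
    arrange(.data$last_occasion, .data$species) %>%
    select(all_of(c("species", "first_record", "last_occasion", "n_records")))
}

#' Per-species PETS computed within each source category
#'
#' Rebuilds timelines from each source alone and evaluates the per-species
#' absence fraction on that source's records only; this is the per-source
#' extinction-potential table that trait regressions consume. Species never
#' recorded by a source have `NA` in that column.
#'
#' @param records Cleaned occurrence table.
#' @param end_year Final survey year (shared across sources).
#' @return Tibble with `species`, one absence-fraction column per source
#'   (`pets_literature_collections`, `pets_citizen_science`, `pets_sampling`)
#'   and `pets_all_sources`.
#' @export
pets_by_source <- function(records, end_year = NULL) {
  records <- validate_occurrences(records)
  if (is.null(end_year)) end_year <- max(records$year)
  all_tl <- build_timelines(records, end_year = end_year)
  out <- suppressWarnings(pets_species(all_tl)) %>%
    select(all_of(c("species", "absence_fraction"))) %>%
    rename(pets_all_sources = "absence_fraction")
  for (s in occ_sources()) {
    sub <- records[records$source == s, , drop = FALSE]
    col <- paste0("pets_", s)
    if (nrow(sub) == 0) {
      out[[col]] <- NA_real_
      next
    }
    tab <- suppressWarnings(pets_species(build_timelines(sub, end_year = end_year))) %>%
      select(all_of(c("species", "absence_fraction"))) %>%
      rename(!!col := "absence_fraction")
    out <- left_join(out, tab, by = "species")
  }
  arrange(out, .data$species)
}

#' Assemble the model-input table for trait analyses
#'
#' Joins per-species record counts (overall and per source) and per-source
#' PETS absence fractions with a user-supplied trait table, producing the
#' deterministic input table that downstream mixed models (out of scope here)
#' consume.
#'
#' @param records Cleaned occurrence table.
#' @param traits Optional data frame with a `species` column plus trait
#'   columns (e.g. voltinism, altitudinal range, wingspan, host-plant genera).
#' @param end_year Final survey year.
#' @return Tibble, one row per species, sorted by species name.
#' @export
model_input_table <- function(records, traits = NULL, end_year = NULL) {
  records <- validate_occurrences(records)
  counts <- records %>%
    count(.data$species, .data$source, name = "n") %>%
    pivot_wider(names_from = "source", values_from = "n", values_fill = 0L,
                names_prefix = "n_records_") %>%
    mutate(n_records_total = rowSums(across(dplyr::starts_with("n_records_"))))
  out <- left_join(pets_by_source(records, end_year = end_year), counts,
                   by = "species")
  if (!is.null(traits)) {
    traits <- as_tibble(traits)
    if (!("species" %in% names(traits))) {
      abort("Trait table must contain a 'species' column.")
    }
    traits$species <- canonical_species(traits$species)
    out <- left_join(out, traits, by = "species")
  }
  arrange(out, .data$species)
}
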