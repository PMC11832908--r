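#' Species-by-year persistence/absence matrix
#'
#' Builds the raster behind the persistence plot: one row per species (ordered
#' by last occasion, most recent first, ties alphabetical), one column per
#' year from the earliest first record to the final survey year. Each cell
#' holds one state: `no_record`, the single source that recorded the species
#' that year, `multiple_sources` when more than one source did, or
#' `year_assigned` when every record in the cell carries the year-assigned
#' flag. Per-species persistence (first to last record) and absence (last
#' record to final year) spans are attached; together they partition each
#' species' row from its first record to the final year.
#'
#' @param records Cleaned occurrence table.
#' @param end_year Final survey year; defaults to the maximum record year.
#' @return A `pets_timeline_matrix`: list with `states` (character matrix,
#'   species x years), `years`, `species`, `spans` (tibble of per-species
#'   first/last/absence spans) and `end_year`.
#' @export
timeline_matrix <- function(records, end_year = NULL) {
  records <- validate_occurrences(records)
  if (any(is.na(records$year))) {
    abort("Timeline matrix needs cleaned records (no missing years).")
  }
  if (is.null(end_year)) end_year <- max(records$year)
  end_year <- as.integer(end_year)
  tl <- build_timelines(records, end_year = end_year)
  ord <- order(-tl$last_occasion, tl$species)
  species <- tl$species[ord]
  years <- seq(min(tl$first_record), end_year)

  states <- matrix("no_record", nrow = length(species), ncol = length(years),
                   dimnames = list(species, as.character(years)))
  cells <- records %>%
    group_by(.data$species, .data$year) %>%
    summarise(n_sources = n_distinct(.data$source),
              the_source = .data$source[1],
              all_assigned = all(.data$year_assigned),
              .groups = "drop")
  state <- ifelse(cells$all_assigned, "year_assigned",
                  ifelse(cells$n_sources > 1, "multiple_sources", cells$the_source))
  states[cbind(match(cells$species, species), match(cells$year, years))] <- state

  spans <- tibble(species = species,
                  first_record = tl$first_record[ord],
                  last_occasion = tl$last_occasion[ord],
                  end_year = end_year)

  structure(list(states = states, years = years, species = species,
                 spans = spans, end_year = end_year),
            class = "pets_timeline_matrix")
}

#' @export
print.pets_timeline_matrix <- function(x, ...) {
  cat("Persistence/absence timeline: ", length(x$species), " species x ",
      length(x$years), " years (", min(x$years), "-", x$end_year, ")\n", sep = "")
  tab <- table(x$states)
  for (s in names(tab)) cat(sprintf("  %-22s %d\n", s, tab[[s]]))
  invisible(x)
}

#' Long (tidy) form of a timeline matrix
#'
#' @param x A `pets_timeline_matrix`.
#' @param keep_empty Keep `no_record` cells (default `FALSE`).
#' @return Tibble with `species`, `year`, `state`.
#' @export
timeline_long <- function(x, keep_empty = FALSE) {
  stopifnot(inherits(x, "pets_timeline_matrix"))
  out <- tibble(species = rep(x$species, times = length(x$years)),
                year = rep(x$years, each = length(x$species)),
                state = as.vector(x$states))
  if (!keep_empty) out <- out[out$state != "no_record", , drop = FALSE]
  out
}

#' Plot a persistence/absence timeline
#'
#' Renders the species-by-year raster: coloured squares for record years
#' (by source, grey for year-assigned, purple for plural sources), a green
#' persistence bar from first to last record and a pink absence bar from the
#' last record to the final survey year. Species with recent last records sit
#' at the top.
#'
#' @param x A `pets_timeline_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.pets_timeline_matrix <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("Plotting the timeline needs the 'ggplot2' package.")
  }
  spans <- x$spans
  spans$species <- factor(spans$species, levels = rev(x$species))
  cells <- timeline_long(x)
  cells$species <- factor(cells$species, levels = rev(x$species))
  palette <- c(citizen_science = "#d73027", literature_collections = "#1a9850",
               sampling = "#4575b4", year_assigned = "grey55",
               multiple_sources = "#7b3294")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = spans,
                          ggplot2::aes(x = .data$first_record, xend = .data$last_occasion,
                                       y = .data$species, yend = .data$species),
                          colour = "#a6dba0", linewidth = 0.6) +
    ggplot2::geom_segment(data = spans[spans$last_occasion < spans$end_year, ],
                          ggplot2::aes(x = .data$last_occasion, xend = .data$end_year,
                                       y = .data$species, yend = .data$species),
                          colour = "#fbb4b9", linewidth = 0.6) +
    ggplot2::geom_tile(data = cells,
                       ggplot2::aes(x = .data$year, y = .data$species,
                                    fill = .data$state),
                       width = 1, height = 0.8) +
    ggplot2::scale_fill_manual(values = palette, name = "record source") +
    ggplot2::labs(x = "year", y = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 4))
}
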