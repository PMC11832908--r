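test_that("timelines carry first record, last occasion and per-source years", {
  recs <- make_records(species = "A", year = c(2000L, 2022L),
                       source = c("literature_collections", "citizen_science"))
  tl <- build_timelines(recs, end_year = 2022)
  expect_equal(tl$first_record, 2000L)
  expect_equal(tl$last_occasion, 2022L)
  expect_equal(tl$years_by_source[[1]]$literature_collections, 2000L)
  expect_equal(tl$years_by_source[[1]]$citizen_science, 2022L)
  expect_error(build_timelines(recs, end_year = 2010), "end_year")
  expect_error(build_timelines(recs, exclude_sources = "museum"), "museum")
})

test_that("source exclusion removes records first and reports species left empty", {
  recs <- dplyr::bind_rows(
    make_records("Only cs", c(2010L, 2015L), "citizen_science"),
    make_records("Both", c(1990L, 2020L),
                 c("literature_collections", "citizen_science")))
  tl <- build_timelines(recs, end_year = 2022,
                        exclude_sources = "citizen_science")
  expect_equal(tl$species, "Both")
  expect_equal(tl$last_occasion, 1990L)
  expect_equal(attr(tl, "dropped_species"), "Only cs")
})

test_that("the absence fraction follows (end - last) / (end - first)", {
  cases <- ten_species_years()
  recs <- make_records(species = rep(cases$species, 2),
                       year = c(cases$first, cases$last))
  tl <- build_timelines(recs, end_year = 2022)
  res <- suppressWarnings(pets_species(tl))
  res <- res[match(cases$species, res$species), ]
  expect_equal(res$absence_fraction,
               (2022 - cases$last) / (2022 - cases$first))
  # spot values implied by the printed years
  expect_identical(res$absence_fraction[cases$species == "Erebia eriphyle"], 36 / 54)
  expect_identical(res$absence_fraction[cases$species == "Argynnis pandora"], 26 / 197)
  # a single historical record year gives the maximal value 1 and a warning
  expect_identical(res$absence_fraction[cases$species == "Polygonia egea"], 1)
  expect_warning(pets_species(tl), "single historical record")
})

test_that("a species recorded in the final year has absence fraction exactly zero", {
  recs <- dplyr::bind_rows(make_records("Recent", c(1980L, 2022L)),
                           make_records("Only end", 2022L))
  res <- pets_species(build_timelines(recs, end_year = 2022))
  expect_equal(res$absence_fraction, c(0, 0))
  expect_equal(res$presence_span[res$species == "Only end"], 0)
})

test_that("pets_species agrees with a brute-force min/max oracle on random communities", {
  for (seed in 1:50) {
    recs <- random_community(seed)
    res <- suppressWarnings(pets_species(build_timelines(recs, end_year = 2022)))
    oracle <- pets_oracle(recs, 2022)
    expect_equal(setNames(res$absence_fraction, res$species)[names(oracle)],
                 oracle, tolerance = 0)
  }
})

test_that("community aggregation pools spans and sorts species by last occasion", {
  recs <- dplyr::bind_rows(make_records("A", c(2000L, 2022L)),
                           make_records("B", c(2000L, 2011L)))
  com <- pets_community(build_timelines(recs, end_year = 2022))
  expect_equal(com$pooled_ratio, 100 * (0 + 11) / (22 + 22))
  expect_equal(com$mean_of_ratios, 25) # equal spans: aggregations coincide
  expect_equal(com$community_extinction_potential, com$pooled_ratio)
  expect_equal(com$species_results$species, c("A", "B"))

  mean_first <- pets_community(build_timelines(recs, end_year = 2022),
                               aggregation = "mean_of_ratios")
  expect_equal(mean_first$community_extinction_potential, mean_first$mean_of_ratios)

  # community value bounded by the per-species extremes, both aggregations
  fr <- com$species_results$absence_fraction * 100
  expect_gte(com$pooled_ratio, min(fr))
  expect_lte(com$pooled_ratio, max(fr))

  # zero-absence community
  zero <- pets_community(build_timelines(
    make_records(c("A", "A", "B", "B"), c(2000L, 2022L, 2010L, 2022L)),
    end_year = 2022))
  expect_equal(zero$pooled_ratio, 0)

  # degenerate community: every species seen only in the end year
  degen <- build_timelines(make_records(c("A", "B"), c(2022L, 2022L)),
                           end_year = 2022)
  expect_error(pets_community(degen), "[Dd]egenerate")
})

test_that("community JSON round-trips the headline values", {
  recs <- dplyr::bind_rows(make_records("A", c(2000L, 2022L)),
                           make_records("B", c(2000L, 2011L)))
  com <- pets_community(build_timelines(recs, end_year = 2022))
  parsed <- jsonlite::fromJSON(pets_community_json(com))
  expect_equal(parsed$pooled_ratio, com$pooled_ratio)
  expect_equal(nrow(parsed$species_results), 2)
})

test_that("the last-seen screen filters strictly before the cutoff and sorts ascending", {
  cases <- ten_species_years()
  recs <- dplyr::bind_rows(
    make_records(species = rep(cases$species, 2), year = c(cases$first, cases$last)),
    make_records("Still here", c(1990L, 2022L)))
  tl <- build_timelines(recs, end_year = 2022)

  expect_equal(nrow(species_last_seen_before(tl, 1800)), 0)

  before96 <- species_last_seen_before(tl, 1996)
  expect_equal(before96$species[1:3],
               c("Polygonia egea", "Coenonympha glycerion", "Araschnia levana"))
  expect_equal(before96$last_occasion[1:3], c(1909L, 1950L, 1956L))
  expect_false("Still here" %in% before96$species)
  expect_false(is.unsorted(before96$last_occasion))

  # cutoff at the end year counts every species not recorded in that year
  expect_equal(nrow(species_last_seen_before(tl, 2022L)), 10)
})

test_that("the timeline matrix encodes source states and orders rows by last occasion", {
  recs <- dplyr::bind_rows(
    make_records("Solo", c(2010L, 2012L), "sampling"),
    make_records("Plural", c(2015L, 2015L),
                 c("sampling", "citizen_science")),
    make_records("Assigned", 2011L, "literature_collections",
                 year_assigned = TRUE))
  m <- timeline_matrix(recs, end_year = 2022)

  expect_equal(m$species, c("Plural", "Solo", "Assigned"))
  expect_equal(m$states["Solo", "2010"], "sampling")
  expect_equal(m$states["Solo", "2012"], "sampling")
  expect_equal(m$states["Plural", "2015"], "multiple_sources")
  expect_equal(m$states["Assigned", "2011"], "year_assigned")
  expect_equal(sum(m$states != "no_record"), 4)

  # each species' record years map to exactly its non-empty cells
  long <- timeline_long(m)
  expect_equal(nrow(long), 4)

  # persistence + absence spans partition [first_record, end_year]
  expect_equal(m$spans$end_year - m$spans$first_record,
               (m$spans$last_occasion - m$spans$first_record) +
                 (m$spans$end_year - m$spans$last_occasion))
})

test_that("per-source PETS and the model-input table line up by species", {
  recs <- dplyr::bind_rows(
    make_records("A", c(1990L, 2020L),
                 c("literature_collections", "citizen_science")),
    make_records("B", 2000L, "literature_collections"))
  tab <- pets_by_source(recs, end_year = 2022)
  expect_equal(tab$pets_all_sources[tab$species == "A"], 2 / 32)
  expect_equal(tab$pets_literature_collections[tab$species == "A"], 1)
  expect_true(is.na(tab$pets_sampling[tab$species == "A"]))

  traits <- tibble::tibble(species = c("A", "B"), wingspan = c(40, 28))
  mit <- model_input_table(recs, traits, end_year = 2022)
  expect_equal(mit$n_records_total, c(2L, 1L))
  expect_equal(mit$wingspan, c(40, 28))
})
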