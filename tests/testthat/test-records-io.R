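test_that("reading a delimited table preserves rows and blanks unparseable years", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,year,source,lat,lon,resolution,year_assigned",
               "Pieris napi,2001,citizen_science,45.7,7.2,res_1km,FALSE",
               "Pieris napi,,literature_collections,,,res_10km,TRUE",
               "Erebia eriphyle,not-a-year,sampling,45.6,7.1,res_3km,FALSE"),
             path)
  recs <- read_occurrences(path)
  expect_equal(nrow(recs), 3)
  expect_equal(recs$year, c(2001L, NA, NA))
  expect_equal(recs$source,
               c("citizen_science", "literature_collections", "sampling"))
  expect_true(recs$year_assigned[2])
  expect_true(is.na(recs$lat[2]) && is.na(recs$lon[2]))
})

test_that("a column dialect remaps names and source tokens", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("taxon\tanno\tsrc",
               "Lysandra coridon\t1999\tCS",
               "Lysandra coridon\t1950\tLIT",
               "Parnassius apollo\t2010\tSAMP"),
             path)
  dia <- occ_dialect(
    columns = c(species = "taxon", year = "anno", source = "src",
                lat = NA, lon = NA, resolution = NA, year_assigned = NA),
    source_map = c(CS = "citizen_science", LIT = "literature_collections",
                   SAMP = "sampling"))
  recs <- read_occurrences(path, dia)
  expect_equal(recs$source,
               c("citizen_science", "literature_collections", "sampling"))
  expect_equal(recs$resolution, rep("unknown", 3))
})

test_that("missing mandatory columns and empty files are hard errors naming the problem", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,year", "Pieris napi,2001"), path)
  expect_error(read_occurrences(path), "source")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(), empty)
  expect_error(read_occurrences(empty), "[Ee]mpty")

  header_only <- withr::local_tempfile(fileext = ".csv")
  writeLines("species,year,source", header_only)
  expect_error(read_occurrences(header_only), "no rows")

  bad_token <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,year,source", "Pieris napi,2001,telepathy"), bad_token)
  expect_error(read_occurrences(bad_token), "telepathy")
})

test_that("read-write-read round trip is lossless", {
  recs <- make_records(
    species = c("Pieris napi", "Erebia eriphyle", "Erebia eriphyle"),
    year = c(2001L, NA, 1968L),
    source = c("citizen_science", "literature_collections", "sampling"),
    lat = c(45.71234, NA, 45.601),
    lon = c(7.23456, NA, 7.109),
    resolution = c("res_1km", "res_10km", "res_3km"),
    year_assigned = c(FALSE, TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(recs, path)
  back <- read_occurrences(path)
  expect_equal(as.data.frame(back), as.data.frame(recs))
})

test_that("cleaning drops yearless records, tallies everything, and is idempotent", {
  recs <- make_records(
    species = sprintf("Sp %d", 1:10),
    year = c(1990L, NA, 2000L, 2010L, NA, 1825L, 2022L, 1950L, 1999L, 2005L),
    source = rep(occ_sources(), length.out = 10),
    lat = c(45.5, NA, 45.6, NA, NA, 45.7, 45.8, NA, 45.9, 45.55),
    lon = c(7.1, NA, 7.2, NA, NA, 7.3, 7.4, NA, 7.5, 7.15),
    year_assigned = c(rep(FALSE, 9), TRUE))
  out <- clean_records(recs, end_year = 2022)
  rep1 <- out$report

  expect_equal(rep1$n_input, 10)
  expect_equal(rep1$n_retained, 8)
  expect_equal(rep1$n_dropped_no_year, 2)
  expect_true(all(!is.na(out$records$year)))
  expect_equal(rep1$n_georeferenced, 6)
  expect_equal(rep1$n_year_assigned, 1)

  # accounting invariants
  expect_equal(rep1$n_retained + rep1$n_dropped_no_year +
                 rep1$n_dropped_year_out_of_bounds, rep1$n_input)
  expect_equal(sum(rep1$counts_by_source$n), rep1$n_retained)
  expect_equal(sum(rep1$counts_by_source$pct), 100, tolerance = 1e-9)
  expect_equal(sum(rep1$counts_by_resolution), rep1$n_retained)

  # idempotence: cleaning the cleaned set changes nothing
  again <- clean_records(out$records, end_year = 2022)
  expect_equal(as.data.frame(again$records), as.data.frame(out$records))
  expect_equal(again$report$n_dropped_no_year, 0)
  expect_equal(again$report$n_retained, rep1$n_retained)

  # both readings of "years in total" are exposed
  expect_equal(rep1$n_distinct_years, length(unique(out$records$year)))
  expect_equal(rep1$year_range, c(1825L, 2022L))
})

test_that("years outside the plausible bounds are rejected with their own counter", {
  recs <- make_records(species = c("A", "B", "C"),
                       year = c(1650L, 2001L, 2200L))
  out <- clean_records(recs, end_year = 2022, year_bounds = c(1700, 2022))
  expect_equal(out$report$n_dropped_year_out_of_bounds, 2)
  expect_equal(out$report$n_retained, 1)
  # cleaning never hard-fails: years beyond the survey end are dropped too
  early <- clean_records(recs, end_year = 1990)
  expect_equal(early$report$n_dropped_year_out_of_bounds, 3)
  expect_equal(early$report$n_retained, 0)
})

test_that("cleaning reports serialise to JSON", {
  out <- clean_records(make_records("A", 2000L), end_year = 2022)
  json <- cleaning_report_json(out$report)
  parsed <- jsonlite::fromJSON(json)
  expect_equal(parsed$n_retained, 1)
  expect_equal(parsed$counts_by_resolution$unknown, 1)
})

test_that("species inventories report per-source missing species against the union", {
  recs <- make_records(
    species = c("A", "A", "B"),
    year = c(2000L, 2001L, 2002L),
    source = c("literature_collections", "citizen_science", "sampling"))
  inv <- species_inventory(recs)
  expect_equal(inv$n_species, 2)
  expect_equal(unname(inv$missing_by_source["sampling"]), 1L)
  expect_equal(unname(inv$missing_by_source["citizen_science"]), 1L)
  expect_equal(unname(inv$missing_by_source["literature_collections"]), 1L)
  expect_equal(unname(inv$missing_pct["sampling"]), 50)

  empty <- species_inventory(make_records(character(), integer()))
  expect_equal(empty$n_species, 0)
  expect_equal(length(empty$all_species), 0)
})

test_that("species names are canonicalised by trimming and case, never fuzzily", {
  expect_equal(canonical_species(c(" Pieris  napi", "PIERIS NAPI")),
               rep("Pieris napi", 2))
  expect_false(canonical_species("Pieris napii") == canonical_species("Pieris napi"))
})
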