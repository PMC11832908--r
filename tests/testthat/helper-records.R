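# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk except files the tests write themselves.

make_records <- function(species, year, source = "literature_collections",
                         lat = NA_real_, lon = NA_real_,
                         resolution = "unknown", year_assigned = FALSE) {
  tibble::tibble(species = species, year = as.integer(year), source = source,
                 lat = lat, lon = lon, resolution = resolution,
                 year_assigned = year_assigned)
}

# A small random multi-source community: a few species, each with record
# years scattered over 1900-2022 across randomly chosen sources.
random_community <- function(seed, end_year = 2022) {
  set.seed(seed)
  n_species <- sample(2:8, 1)
  rows <- lapply(seq_len(n_species), function(i) {
    n_rec <- sample(1:12, 1)
    make_records(species = sprintf("Sp %02d", i),
                 year = sample(1900:end_year, n_rec, replace = TRUE),
                 source = sample(occ_sources(), n_rec, replace = TRUE))
  })
  dplyr::bind_rows(rows)
}

# Independent brute-force oracle for the per-species absence fraction: plain
# min/max arithmetic on the raw record list, no timeline machinery.
pets_oracle <- function(records, end_year) {
  sapply(split(records$year, records$species), function(yrs) {
    first <- min(yrs); last <- max(yrs)
    if (end_year - first > 0) (end_year - last) / (end_year - first) else 0
  })
}

# Ground-truth first/last observation years of the ten species recorded only
# before 1996 in the worked example, used as desk fixtures for the formula.
ten_species_years <- function() {
  tibble::tribble(
    ~species,                  ~first, ~last,
    "Polygonia egea",            1909L, 1909L,
    "Coenonympha glycerion",     1950L, 1950L,
    "Araschnia levana",          1956L, 1956L,
    "Erebia eriphyle",           1968L, 1986L,
    "Argynnis pandora",          1825L, 1996L,
    "Leptidea juvernica",        1984L, 1996L,
    "Limenitis camilla",         1898L, 1996L,
    "Lycaeides argyrognomon",    1908L, 1996L,
    "Pyronia tithonus",          1950L, 1996L,
    "Thecla betulae",            1921L, 1996L
  )
}

# Tiny deterministic synthetic configuration for generator tests.
tiny_config <- function(seed = 1, n_species = 3, detectability = 0.8,
                        effort_level = 2, years = c(1990L, 2022L),
                        extinction = NA_integer_) {
  sp <- tibble::tibble(
    species = sprintf("Sim %02d", seq_len(n_species)),
    detectability = detectability,
    colonization = years[1],
    extinction = rep_len(as.integer(extinction), n_species),
    centre_lon = seq(7.0, 7.5, length.out = n_species),
    centre_lat = seq(45.5, 45.9, length.out = n_species)
  )
  synthetic_config(
    species_params = sp, years = years,
    effort = list(
      literature_collections = list(type = "constant", onset = years[1],
                                    level = effort_level),
      citizen_science = list(type = "growth", onset = 2000, base = 0.5,
                             rate = 1.1),
      sampling = list(type = "zero")
    ),
    region = c(6.8, 7.95, 45.47, 46.05),
    sampling_window = c(6.95, 7.40, 45.47, 45.75),
    seed = seed
  )
}
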