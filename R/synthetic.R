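#' Evaluate a source effort curve over years
#'
#' Effort curves give the expected number of records per species of unit
#' detectability, per year, for one source category. Supported parametric
#' shapes:
#' \describe{
#'   \item{`oscillating`}{`base * (1 + amplitude * sin(2*pi*(y - y0)/period))`,
#'     multiplied after `decline_from` by a linear ramp from 1 down to
#'     `end_frac` at the last year — the historical literature/collections
#'     regime: fluctuating effort that fades in recent decades.}
#'   \item{`growth`}{0 before `onset`, then `base * rate^(y - onset)` —
#'     the citizen-science regime: nothing before an onset year, then
#'     geometric growth.}
#'   \item{`constant`}{0 before `onset`, then `level` — the structured
#'     sampling regime: a monitoring programme switched on at some year.}
#'   \item{`zero`}{No effort at all.}
#' }
#'
#' @param spec A list with a `type` element and the shape's parameters, or a
#'   numeric vector of per-year intensities of the same length as `years`.
#' @param years Integer vector of years to evaluate at.
#' @return Numeric vector of non-negative intensities, one per year.
#' @export
effort_curve <- function(spec, years) {
  if (is.numeric(spec)) {
    if (length(spec) != length(years)) {
      abort("A numeric effort curve must have one intensity per year.")
    }
    return(pmax(spec, 0))
  }
  out <- switch(spec$type,
    zero = rep(0, length(years)),
    constant = ifelse(years >= spec$onset, spec$level, 0),
    growth = ifelse(years >= spec$onset, spec$base * spec$rate^(years - spec$onset), 0),
    oscillating = {
      y0 <- min(years)
      base <- spec$base * (1 + spec$amplitude * sin(2 * pi * (years - y0) / spec$period))
      ramp <- rep(1, length(years))
      late <- years > spec$decline_from
      span <- max(years) - spec$decline_from
      if (span > 0) {
        ramp[late] <- 1 - (1 - spec$end_frac) * (years[late] - spec$decline_from) / span
      }
      base * ramp
    },
    abort(paste0("Unknown effort curve type: ", spec$type))
  )
  pmax(out, 0)
}

#' Assemble and validate a synthetic recording configuration
#'
#' Bundles everything the generator needs: the species pool with its ground
#' truth (colonization years, scheduled true extinction years, per-species
#' detectability, spatial centres), the three source effort regimes, the
#' study-region rectangle and the spatial sub-window that structured sampling
#' is confined to. All invariants are checked here, before any random draw.
#'
#' @param species_params Tibble with columns `species`, `detectability`
#'   (in \[0, 1\]; 0 means the species is never recorded), `colonization`,
#'   `extinction` (year or `NA` for extant),
#'   `centre_lon`, `centre_lat`.
#' @param years Length-2 integer vector `c(first, end)` of the simulated
#'   period.
#' @param effort Named list of effort-curve specs, one per source category
#'   (see [effort_curve()]).
#' @param region Length-4 numeric `c(lon_min, lon_max, lat_min, lat_max)`
#'   rectangle in decimal degrees.
#' @param sampling_window Rectangle (same format) that sampling-source records
#'   are confined to; sampling only detects species whose centre lies inside
#'   it.
#' @param coord_sd_km Isotropic spread (km) of record coordinates around a
#'   species' centre.
#' @param prop_year_assigned Probability that a historical (pre-1991)
#'   literature record carries the year-assigned flag.
#' @param seed Integer seed making [generate_occurrences()] deterministic.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(species_params, years = c(1825L, 2022L),
                             effort, region, sampling_window = region,
                             coord_sd_km = 3, prop_year_assigned = 0.1,
                             seed = 1L) {
  species_params <- as_tibble(species_params)
  needed <- c("species", "detectability", "colonization", "extinction",
              "centre_lon", "centre_lat")
  missing_cols <- setdiff(needed, names(species_params))
  if (length(missing_cols) > 0) {
    abort(paste0("species_params lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(species_params$species)) {
    abort("species_params has duplicated species names.")
  }
  if (any(species_params$detectability < 0 | species_params$detectability > 1)) {
    abort("Detectabilities must lie in [0, 1].")
  }
  years <- as.integer(years)
  if (length(years) != 2 || years[1] >= years[2]) {
    abort("years must be c(first, end) with first < end.")
  }
  ext <- species_params$extinction
  if (any(species_params$colonization > ifelse(is.na(ext), years[2], ext))) {
    abort("Every colonization year must precede the (scheduled) extinction year.")
  }
  if (any(!is.na(ext) & ext > years[2])) {
    abort("Scheduled extinction years must not exceed the end year.")
  }
  if (any(species_params$colonization < years[1])) {
    abort("Colonization years must not precede the first simulated year.")
  }
  missing_eff <- setdiff(occ_sources(), names(effort))
  if (length(missing_eff) > 0) {
    abort(paste0("Effort curves missing for: ", paste(missing_eff, collapse = ", ")))
  }
  yr <- seq(years[1], years[2])
  for (s in occ_sources()) {
    vals <- effort_curve(effort[[s]], yr)
    if (any(!is.finite(vals)) || any(vals < 0)) {
      abort(paste0("Effort curve for ", s, " yields negative or non-finite intensity."))
    }
  }
  chk_rect <- function(r, what) {
    if (length(r) != 4 || r[1] >= r[2] || r[3] >= r[4]) {
      abort(paste0(what, " must be c(lon_min, lon_max, lat_min, lat_max) with min < max."))
    }
  }
  chk_rect(region, "region")
  chk_rect(sampling_window, "sampling_window")
  structure(list(species_params = species_params, years = years,
                 effort = effort, region = as.numeric(region),
                 sampling_window = as.numeric(sampling_window),
                 coord_sd_km = coord_sd_km,
                 prop_year_assigned = prop_year_assigned,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", nrow(x$species_params), " species, ",
      x$years[1], "-", x$years[2], ", seed ", x$seed, "\n", sep = "")
  cat("  scheduled extinctions:", sum(!is.na(x$species_params$extinction)), "\n")
  invisible(x)
}

#' Study-like synthetic preset
#'
#' A ready-made configuration emulating an alpine regional butterfly dataset
#' accumulated over two centuries by three source regimes: oscillating
#' literature/collections effort that declines after 1990, citizen science
#' absent before 2000 and then growing geometrically, and structured sampling
#' switched on around 2000 and confined to a south-western sub-window of the
#' region. The pool holds 170 species with first-record years spread across
#' the period and ten species scheduled to go truly extinct between 1900 and
#' 1995 (so their record series stop before 1996). Detectabilities,
#' colonization years and range centres are drawn once, deterministically
#' from `seed`.
#'
#' @param n_species Size of the species pool (default 170).
#' @param n_extinct Number of scheduled pre-1996 extinctions (default 10).
#' @param seed Integer seed; drives both the pool draw and record generation.
#' @return A `synthetic_config`.
#' @export
alpine_preset <- function(n_species = 170, n_extinct = 10, seed = 1L) {
  stopifnot(n_extinct <= n_species)
  region <- c(6.80, 7.95, 45.47, 46.05)
  window <- c(6.95, 7.40, 45.47, 45.75)
  set.seed(as.integer(seed))
  n_extant <- n_species - n_extinct
  extinction <- c(as.integer(round(seq(1900, 1995, length.out = n_extinct))),
                  rep(NA_integer_, n_extant))
  colonization <- c(as.integer(round(runif(n_extinct, 1825, 1880))),
                    as.integer(round(runif(n_extant, 1825, 2000))))
  detectability <- c(runif(n_extinct, 0.3, 1), runif(n_extant, 0.1, 1))
  sp <- tibble(
    species = sprintf("Species %03d", seq_len(n_species)),
    detectability = detectability,
    colonization = colonization,
    extinction = extinction,
    centre_lon = runif(n_species, region[1], region[2]),
    centre_lat = runif(n_species, region[3], region[4])
  )
  synthetic_config(
    species_params = sp,
    years = c(1825L, 2022L),
    effort = list(
      literature_collections = list(type = "oscillating", base = 0.45,
                                    amplitude = 0.5, period = 40,
                                    decline_from = 1990, end_frac = 0.2),
      citizen_science = list(type = "growth", onset = 2000, base = 0.55,
                             rate = 1.2),
      sampling = list(type = "constant", onset = 2000, level = 6)
    ),
    region = region, sampling_window = window,
    coord_sd_km = 3, prop_year_assigned = 0.1,
    seed = as.integer(seed) + 1000L
  )
}

#' Generate a synthetic multi-source occurrence dataset
#'
#' The virtual-ecologist step: for every species, every year it is truly
#' present (from colonization to its scheduled extinction or the end year)
#' and every source, the number of records is Poisson with mean
#' `effort(source, year) * detectability(species)`. Record coordinates are
#' drawn isotropically around the species' centre and clipped to the region;
#' sampling records exist only for species whose centre lies inside the
#' sampling window and are clipped to it. Resolution classes coarsen with
#' age (10 km before 1980, 3 km to 2004, 1 km after) and a fraction of
#' historical literature records carry the year-assigned flag. Output is
#' byte-identical for identical configurations (the seed lives in the
#' config).
#'
#' @param config A [synthetic_config()].
#' @return A list with `records` (a valid occurrence tibble in the
#'   [read_occurrences()] layout), `truth` (a `pets_truth` list: `species`
#'   ground-truth table and realized per-source `detections`), and `config`.
#' @export
generate_occurrences <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  years <- seq(config$years[1], config$years[2])
  end_year <- config$years[2]
  sp <- config$species_params
  in_window <- sp$centre_lon >= config$sampling_window[1] &
    sp$centre_lon <= config$sampling_window[2] &
    sp$centre_lat >= config$sampling_window[3] &
    sp$centre_lat <= config$sampling_window[4]

  pieces <- vector("list", length(occ_sources()))
  names(pieces) <- occ_sources()
  for (src in occ_sources()) {
    eff <- effort_curve(config$effort[[src]], years)
    grid <- tidyr::expand_grid(si = seq_len(nrow(sp)), yi = seq_along(years))
    grid$year <- years[grid$yi]
    last_alive <- ifelse(is.na(sp$extinction[grid$si]), end_year,
                         sp$extinction[grid$si])
    active <- grid$year >= sp$colonization[grid$si] & grid$year <= last_alive
    if (src == "sampling") active <- active & in_window[grid$si]
    mu <- eff[grid$yi] * sp$detectability[grid$si]
    grid <- grid[active & mu > 0, , drop = FALSE]
    if (nrow(grid) == 0) next
    mu <- eff[grid$yi] * sp$detectability[grid$si]
    n <- rpois(nrow(grid), mu)
    keep <- n > 0
    grid <- grid[keep, , drop = FALSE]
    n <- n[keep]
    if (nrow(grid) == 0) next
    si <- rep(grid$si, n)
    pieces[[src]] <- tibble(species = sp$species[si],
                            year = rep(grid$year, n),
                            source = src,
                            si = si)
  }
  recs <- bind_rows(pieces)
  if (nrow(recs) == 0) {
    records <- tibble(species = character(), year = integer(),
                      source = character(), lat = numeric(), lon = numeric(),
                      resolution = character(), year_assigned = logical())
  } else {
    sd_lat <- config$coord_sd_km / 110.574
    sd_lon <- config$coord_sd_km /
      (111.320 * cos(sp$centre_lat[recs$si] * pi / 180))
    lon <- rnorm(nrow(recs), sp$centre_lon[recs$si], sd_lon)
    lat <- rnorm(nrow(recs), sp$centre_lat[recs$si], sd_lat)
    lon <- pmin(pmax(lon, config$region[1]), config$region[2])
    lat <- pmin(pmax(lat, config$region[3]), config$region[4])
    is_samp <- recs$source == "sampling"
    lon[is_samp] <- pmin(pmax(lon[is_samp], config$sampling_window[1]),
                         config$sampling_window[2])
    lat[is_samp] <- pmin(pmax(lat[is_samp], config$sampling_window[3]),
                         config$sampling_window[4])
    resolution <- ifelse(recs$year < 1980, "res_10km",
                         ifelse(recs$year < 2005, "res_3km", "res_1km"))
    year_assigned <- recs$source == "literature_collections" &
      recs$year <= 1990 &
      runif(nrow(recs)) < config$prop_year_assigned
    records <- tibble(species = recs$species, year = as.integer(recs$year),
                      source = recs$source, lat = lat, lon = lon,
                      resolution = resolution, year_assigned = year_assigned) %>%
      arrange(.data$source, .data$species, .data$year)
  }

  detections <- records %>%
    count(.data$species, .data$source, .data$year, name = "n")
  truth <- structure(list(
    species = sp %>%
      mutate(extant = is.na(.data$extinction)) %>%
      select(all_of(c("species", "colonization", "extinction", "extant",
                      "detectability", "centre_lon", "centre_lat"))),
    detections = detections,
    end_year = end_year
  ), class = "pets_truth")

  list(records = validate_occurrences(records), truth = truth, config = config)
}

#' Compare estimated extinction potential against generator ground truth
#'
#' For every species with at least one record, sets the PETS absence fraction
#' estimated from the records against the value implied by the ground truth:
#' `(end - min(true extinction, end)) / (end - first record)` — the fraction
#' obtained if the species had been detected right up to its true last year
#' of presence. The summary also checks the qualitative expectation that
#' truly extinct species carry larger absence fractions than extant ones.
#'
#' @param records Records from [generate_occurrences()].
#' @param truth The matching `pets_truth` object.
#' @param end_year Final survey year (defaults to the truth's end year).
#' @return A list with `table` (per-species tibble: estimated
#'   `absence_fraction`, `true_absence_fraction`, `extant`) and `summary`
#'   (mean fractions by true status and their difference).
#' @export
recovery_report <- function(records, truth, end_year = NULL) {
  stopifnot(inherits(truth, "pets_truth"))
  if (is.null(end_year)) end_year <- truth$end_year
  tl <- build_timelines(records, end_year = end_year)
  est <- suppressWarnings(pets_species(tl))
  tab <- est %>%
    left_join(truth$species, by = "species") %>%
    mutate(true_last = ifelse(is.na(.data$extinction), end_year, .data$extinction),
           true_absence_fraction = ifelse(.data$presence_span > 0,
                                          (end_year - .data$true_last) / .data$presence_span,
                                          0)) %>%
    select(all_of(c("species", "first_record", "last_occasion",
                    "absence_fraction", "true_absence_fraction", "extant")))
  mean_ext <- mean(tab$absence_fraction[!tab$extant])
  mean_sur <- mean(tab$absence_fraction[tab$extant])
  list(table = tab,
       summary = list(n_species = nrow(tab),
                      n_extinct_detected = sum(!tab$extant),
                      mean_pets_extinct = mean_ext,
                      mean_pets_extant = mean_sur,
                      separation = mean_ext - mean_sur))
}

#' Read / write a synthetic configuration as YAML
#'
#' @param path File path.
#' @return For `read_synthetic_config()`, a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Reading YAML configs needs the 'yaml' package.")
  }
  raw <- yaml::read_yaml(path)
  sp <- as_tibble(raw$species_params)
  sp$extinction <- as.integer(sp$extinction)
  synthetic_config(species_params = sp,
                   years = unlist(raw$years),
                   effort = raw$effort,
                   region = unlist(raw$region),
                   sampling_window = unlist(raw$sampling_window),
                   coord_sd_km = raw$coord_sd_km,
                   prop_year_assigned = raw$prop_year_assigned,
                   seed = raw$seed)
}

#' @rdname read_synthetic_config
#' @param config A `synthetic_config`.
#' @export
write_synthetic_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Writing YAML configs needs the 'yaml' package.")
  }
  stopifnot(inherits(config, "synthetic_config"))
  payload <- unclass(config)
  payload$species_params <- as.data.frame(payload$species_params)
  yaml::write_yaml(payload, path)
  invisible(path)
}
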