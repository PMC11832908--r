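#' Forward UTM projection (WGS84)
#'
#' Projects geographic coordinates (decimal degrees, WGS84) to Universal
#' Transverse Mercator easting/northing in metres, using the standard
#' truncated Krueger series for the transverse Mercator mapping (scale factor
#' 0.9996, 500 km false easting, 10,000 km false northing in the southern
#' hemisphere). Accuracy is sub-millimetre within a zone and ample for
#' kilometre-scale gridding a few degrees either side of the central
#' meridian. Latitudes must lie within the UTM validity band (84 deg N to
#' 80 deg S); points outside it, or farther than 45 degrees of longitude from
#' the central meridian, are returned as `NA` so callers can flag them.
#'
#' @param lon,lat Numeric vectors of decimal degrees (recycled together).
#' @param zone UTM zone number (1-60). `NULL` picks the zone of the mean
#'   longitude of the finite inputs.
#' @param hemisphere `"N"` or `"S"` (controls the false northing).
#' @return Tibble with columns `easting`, `northing` (metres), `zone`,
#'   `in_domain` (logical).
#' @export
utm_project <- function(lon, lat, zone = NULL, hemisphere = c("N", "S")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(length(lon) == length(lat))
  if (is.null(zone)) {
    m <- mean(lon[is.finite(lon)])
    if (!is.finite(m)) abort("Cannot infer a UTM zone: no finite longitude.")
    zone <- floor((m + 180) / 6) + 1
  }
  zone <- as.integer(zone)
  if (zone < 1 || zone > 60) abort("UTM zone must be in 1..60.")
  lon0 <- zone * 6 - 183

  # WGS84 ellipsoid
  a <- 6378137
  f <- 1 / 298.257223563
  e2 <- f * (2 - f)
  ep2 <- e2 / (1 - e2)
  k0 <- 0.9996

  in_domain <- is.finite(lon) & is.finite(lat) &
    lat >= -80 & lat <= 84 & abs(lon - lon0) <= 45

  phi <- lat * pi / 180
  dlam <- (lon - lon0) * pi / 180
  sinp <- sin(phi); cosp <- cos(phi); tanp <- tan(phi)

  N <- a / sqrt(1 - e2 * sinp^2)
  Tt <- tanp^2
  C <- ep2 * cosp^2
  A <- dlam * cosp
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
              (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
              (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
              (35 * e2^3 / 3072) * sin(6 * phi))

  easting <- k0 * N * (A + (1 - Tt + C) * A^3 / 6 +
                         (5 - 18 * Tt + Tt^2 + 72 * C - 58 * ep2) * A^5 / 120) + 500000
  northing <- k0 * (M + N * tanp * (A^2 / 2 +
                                      (5 - Tt + 9 * C + 4 * C^2) * A^4 / 24 +
                                      (61 - 58 * Tt + Tt^2 + 600 * C - 330 * ep2) * A^6 / 720))
  if (hemisphere == "S") northing <- northing + 1e7

  easting[!in_domain] <- NA_real_
  northing[!in_domain] <- NA_real_
  tibble(easting = easting, northing = northing, zone = zone,
         in_domain = in_domain)
}

#' Define a square analysis grid on a metric projection
#'
#' The grid lives in projected (UTM) coordinates: half-open square cells
#' `[x0 + i*s, x0 + (i+1)*s) x [y0 + j*s, y0 + (j+1)*s)`, so every point maps
#' to exactly one cell and a point on a shared edge belongs to the cell whose
#' lower/left boundary it sits on. The default origin (0, 0) aligns cells
#' with the UTM kilometre grid.
#'
#' @param cell_size Cell side in metres (default 10,000 for a 10 km grid).
#' @param zone UTM zone number; `NULL` infers it from the data at assignment
#'   time. The study-region default for north-west Italy is zone 32.
#' @param hemisphere `"N"` or `"S"`.
#' @param origin Projected coordinates `c(x0, y0)` of the grid's lower-left
#'   corner, metres.
#' @param mask Optional region mask: a data frame with integer columns
#'   `cell_x`, `cell_y` listing the valid cells of the region. When present
#'   it fixes the total cell count that occupancy percentages refer to.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(cell_size = 10000, zone = 32L, hemisphere = "N",
                      origin = c(0, 0), mask = NULL) {
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    abort("cell_size must be a single positive number of metres.")
  }
  if (!is.null(mask)) {
    mask <- as_tibble(mask)
    if (!all(c("cell_x", "cell_y") %in% names(mask))) {
      abort("A grid mask needs integer columns cell_x and cell_y.")
    }
    mask <- distinct(mask, .data$cell_x, .data$cell_y)
  }
  structure(list(cell_size = cell_size, zone = zone, hemisphere = hemisphere,
                 origin = as.numeric(origin), mask = mask),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", x$cell_size / 1000, " km cells, UTM zone ",
      if (is.null(x$zone)) "(from data)" else x$zone, x$hemisphere,
      ", origin (", x$origin[1], ", ", x$origin[2], ")",
      if (!is.null(x$mask)) paste0(", mask of ", nrow(x$mask), " cells"),
      "\n", sep = "")
  invisible(x)
}

#' Assign occurrence records to grid cells
#'
#' Projects every georeferenced record and computes its half-open cell index
#' by floor division of the projected offsets from the grid origin. Records
#' without coordinates get `NA` cells; records outside the projection's
#' validity domain are flagged (`in_domain = FALSE`) and excluded from grid
#' outputs.
#'
#' @param records Occurrence table.
#' @param grid A [grid_spec()].
#' @return The records tibble with added columns `easting`, `northing`,
#'   `cell_x`, `cell_y`, `in_domain`; attributes `n_no_coords` and
#'   `n_out_of_domain`.
#' @export
assign_cells <- function(records, grid = grid_spec()) {
  records <- validate_occurrences(records)
  stopifnot(inherits(grid, "grid_spec"))
  prj <- utm_project(records$lon, records$lat, zone = grid$zone,
                     hemisphere = grid$hemisphere)
  out <- records
  out$easting <- prj$easting
  out$northing <- prj$northing
  out$in_domain <- prj$in_domain
  out$cell_x <- as.integer(floor((prj$easting - grid$origin[1]) / grid$cell_size))
  out$cell_y <- as.integer(floor((prj$northing - grid$origin[2]) / grid$cell_size))
  has_coords <- !is.na(records$lon)
  attr(out, "n_no_coords") <- sum(!has_coords)
  attr(out, "n_out_of_domain") <- sum(has_coords & !prj$in_domain)
  out
}

#' Per-cell, per-source record counts
#'
#' @param records Occurrence table.
#' @param grid A [grid_spec()].
#' @return Tibble with `cell_x`, `cell_y`, one count column per source
#'   (`n_literature_collections`, `n_citizen_science`, `n_sampling`) and
#'   `total`.
#' @export
cell_counts <- function(records, grid = grid_spec()) {
  assigned <- assign_cells(records, grid)
  assigned <- assigned[assigned$in_domain, , drop = FALSE]
  if (nrow(assigned) == 0) {
    warn("No georeferenced record falls in the projection domain; empty grid table.")
    return(tibble(cell_x = integer(), cell_y = integer(),
                  n_literature_collections = integer(),
                  n_citizen_science = integer(), n_sampling = integer(),
                  total = integer()))
  }
  out <- assigned %>%
    count(.data$cell_x, .data$cell_y, .data$source, name = "n") %>%
    pivot_wider(names_from = "source", values_from = "n", values_fill = 0L,
                names_prefix = "n_")
  for (s in paste0("n_", occ_sources())) if (!(s %in% names(out))) out[[s]] <- 0L
  out$total <- rowSums(out[paste0("n_", occ_sources())])
  out %>%
    select(all_of(c("cell_x", "cell_y", paste0("n_", occ_sources()), "total"))) %>%
    arrange(.data$cell_x, .data$cell_y)
}

#' Grid occupancy by source category
#'
#' A cell is occupied for a source when at least one in-domain georeferenced
#' record of that source falls in it. Percentages are relative to the total
#' number of region cells: the mask size when the grid carries one (cells
#' outside the mask are then not counted as occupied), otherwise the union of
#' cells occupied by any source.
#'
#' @param records Occurrence table.
#' @param grid A [grid_spec()].
#' @return A list with `occupancy` (tibble: `source`, `n_cells`,
#'   `total_cells`, `pct`, `area_km2`), `cells` (the [cell_counts()] table),
#'   `total_cells`, and the no-coordinate / out-of-domain tallies.
#' @export
occupancy_by_source <- function(records, grid = grid_spec()) {
  assigned <- assign_cells(records, grid)
  cells <- cell_counts(records, grid)
  if (!is.null(grid$mask)) {
    total_cells <- nrow(grid$mask)
    in_mask <- paste(cells$cell_x, cells$cell_y) %in%
      paste(grid$mask$cell_x, grid$mask$cell_y)
  } else {
    total_cells <- nrow(cells)
    in_mask <- rep(TRUE, nrow(cells))
  }
  occ <- tibble(source = occ_sources(),
                n_cells = unname(vapply(occ_sources(), function(s) {
                  sum(cells[[paste0("n_", s)]] > 0 & in_mask)
                }, integer(1))))
  occ$total_cells <- total_cells
  occ$pct <- if (total_cells > 0) 100 * occ$n_cells / total_cells else NA_real_
  occ$area_km2 <- occ$n_cells * (grid$cell_size / 1000)^2
  list(occupancy = occ, cells = cells, total_cells = total_cells,
       n_no_coords = attr(assigned, "n_no_coords"),
       n_out_of_domain = attr(assigned, "n_out_of_domain"))
}
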