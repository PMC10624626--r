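#' Generate a synthetic world: grid, bathymetry, EEZs and socioeconomics
#'
#' Builds the spatial scaffold every other stage consumes: a regular
#' latitude-longitude grid with cell areas and bathymetry, a set of
#' Exclusive Economic Zones (EEZs) laid out as contiguous rectangular
#' cell blocks, and per-EEZ socioeconomic attributes (centroid latitude,
#' tropical flag, GDP per capita in year-2010 currency units, and a
#' coastal population trajectory for 2010-2100).
#'
#' The default 18 x 36 grid (10 degree cells) is a desk-scale stand-in
#' for a 0.5 degree global grid: it preserves the latitudinal structure
#' (thermal gradient, tropics at |lat| < 23.5) that the downstream
#' models actually use, at minute-scale runtimes. Tropical EEZs draw
#' GDP per capita from a lower lognormal than extra-tropical ones,
#' emulating the real-world correlation between latitude and income
#' that the income-disparity analyses rely on.
#'
#' @param n_eez number of EEZs (>= 2).
#' @param grid_shape integer vector `c(n_lat_rows, n_lon_cols)`.
#' @param seed integer seed; identical seeds give identical worlds.
#' @param pop_years years covered by the coastal population trajectories.
#' @param eez_block cell extent `c(rows, cols)` of each rectangular EEZ.
#' @return An object of class `fc_world`: list with `lat`, `lon` (cell
#'   center coordinates), `area` (km^2 matrix), `depth` (m matrix,
#'   positive down), `eez` (integer matrix, `NA` = open ocean),
#'   `eez_table` (one row per EEZ: `eez_id`, `centroid_lat`, `tropical`,
#'   `gdp_pc`, `area_km2`), and `population` (long data.frame
#'   `eez_id`, `year`, `population`).
#' @export
generate_world <- function(n_eez = 14,
                           grid_shape = c(18, 36),
                           seed = 1,
                           pop_years = 2010:2100,
                           eez_block = c(2, 3)) {
  if (!is_count(n_eez) || n_eez < 2) stopf("n_eez must be an integer >= 2")
  nlat <- grid_shape[1]; nlon <- grid_shape[2]
  if (nlat < 2) stopf("grid must have >= 2 latitude rows")
  lat_step <- 180 / nlat
  lon_step <- 360 / nlon
  lat <- seq(-90 + lat_step / 2, 90 - lat_step / 2, by = lat_step)
  lon <- seq(-180 + lon_step / 2, 180 - lon_step / 2, by = lon_step)
  if (max(lat) <= 23.5 || min(lat) >= -23.5) {
    stopf("grid must span both hemispheres and the tropics")
  }

  br <- eez_block[1]; bc <- eez_block[2]
  n_block_rows <- nlat %/% br
  n_block_cols <- nlon %/% bc
  if (n_block_rows * n_block_cols < n_eez) {
    stopf("grid too small to host %d EEZs of %dx%d cells", n_eez, br, bc,
          class = "fc_sizing_error")
  }

  set.seed(child_seed(seed, 1))

  ## candidate blocks with their centroid latitude
  blocks <- expand.grid(brow = seq_len(n_block_rows), bcol = seq_len(n_block_cols))
  blocks$rows0 <- (blocks$brow - 1) * br
  blocks$cols0 <- (blocks$bcol - 1) * bc
  blocks$clat <- vapply(seq_len(nrow(blocks)), function(i) {
    mean(lat[blocks$rows0[i] + seq_len(br)])
  }, numeric(1))

  tropical_blocks <- which(abs(blocks$clat) < 23.5)
  extrat_blocks <- which(abs(blocks$clat) >= 23.5)
  if (!length(tropical_blocks) || !length(extrat_blocks)) {
    stopf("grid cannot host both a tropical and an extra-tropical EEZ",
          class = "fc_sizing_error")
  }
  ## force one of each, fill the rest at random; prefer a mid-latitude
  ## extra-tropical seat (23.5-55 deg) so exploited ranges can reach it
  mid_extrat <- extrat_blocks[abs(blocks$clat[extrat_blocks]) <= 55]
  pick <- c(sample(tropical_blocks, 1),
            if (length(mid_extrat)) sample(mid_extrat, 1)
            else sample(extrat_blocks, 1))
  remaining <- setdiff(seq_len(nrow(blocks)), pick)
  if (n_eez > 2) pick <- c(pick, sample(remaining, n_eez - 2))

  eez <- matrix(NA_integer_, nlat, nlon)
  for (k in seq_len(n_eez)) {
    b <- blocks[pick[k], ]
    eez[b$rows0 + seq_len(br), b$cols0 + seq_len(bc)] <- k
  }

  ## areas: equirectangular cell area, floored away from zero at the poles
  km_per_deg <- 111.32
  area <- outer(pmax(cos(lat * pi / 180), 0.02) * km_per_deg^2 * lat_step * lon_step,
                rep(1, nlon))

  ## bathymetry: shelf depths inside EEZ blocks, abyssal open ocean
  depth <- matrix(stats::runif(nlat * nlon, 800, 5000), nlat, nlon)
  shelf <- !is.na(eez)
  depth[shelf] <- stats::runif(sum(shelf), 30, 250)

  centroid_lat <- vapply(seq_len(n_eez), function(k) {
    mean(outer(lat, rep(1, nlon))[which(eez == k)])
  }, numeric(1))
  tropical <- abs(centroid_lat) < 23.5
  gdp_pc <- stats::rlnorm(n_eez,
                          meanlog = ifelse(tropical, log(4500), log(24000)),
                          sdlog = 0.45)
  area_km2 <- vapply(seq_len(n_eez), function(k) sum(area[which(eez == k)]), numeric(1))

  pop0 <- stats::rlnorm(n_eez, meanlog = log(2e6), sdlog = 1)
  growth <- stats::runif(n_eez, 0.002, 0.015)  # some EEZs exceed +50% by 2050
  population <- do.call(rbind, lapply(seq_len(n_eez), function(k) {
    data.frame(eez_id = k, year = pop_years,
               population = pop0[k] * (1 + growth[k])^(pop_years - pop_years[1]))
  }))

  structure(list(
    lat = lat, lon = lon, lat_step = lat_step, lon_step = lon_step,
    area = area, depth = depth, eez = eez,
    eez_table = data.frame(eez_id = seq_len(n_eez), centroid_lat = centroid_lat,
                           tropical = tropical, gdp_pc = gdp_pc,
                           area_km2 = area_km2),
    population = population,
    n_eez = n_eez, seed = seed
  ), class = "fc_world")
}

#' @export
print.fc_world <- function(x, ...) {
  cat(sprintf("<fc_world> %d x %d grid (%.1f deg), %d EEZs (%d tropical)\n",
              length(x$lat), length(x$lon), x$lat_step, x$n_eez,
              sum(x$eez_table$tropical)))
  invisible(x)
}

## latitude of every cell as a matrix (row-constant)
cell_lat_matrix <- function(world) outer(world$lat, rep(1, length(world$lon)))
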