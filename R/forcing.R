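#' Default configuration for the synthetic climate forcing generator
#'
#' All tunable constants of the forcing generator in one place. Warming
#' trajectories are anchored to the two headline scenario outcomes:
#' global surface air temperature anomaly (vs the 1850-1900
#' pre-industrial mean) limited to below 2 degC by 2100 under strong
#' mitigation, and exceeding 4 degC by 2100 under no mitigation.
#'
#' @param sst_eq,sst_pole equatorial / polar baseline sea surface
#'   temperature (degC).
#' @param sbt_offset how much colder the bottom is than the surface (degC).
#' @param amplification local ocean warming per degC of global
#'   atmospheric anomaly (dimensionless).
#' @param npp_sensitivity fractional change in net primary production
#'   per degC of local warming (default -5% / degC).
#' @param sst_noise_sd per-cell SST noise sd (degC); noise is centered
#'   within each latitude row so zonal means keep the exact gradient.
#' @param dt_noise_sd interannual noise sd on the global anomaly (degC).
#' @param ice_edge_lat latitude (deg) of the 50% sea-ice fraction under
#'   no warming; the edge migrates poleward with local warming.
#' @param current_speed peak magnitude of the stationary surface current
#'   field (grid cells per year).
#' @return named list of generator constants.
#' @export
forcing_config <- function(sst_eq = 29, sst_pole = -1.5, sbt_offset = 4,
                           amplification = 0.85, npp_sensitivity = -0.05,
                           sst_noise_sd = 0.3, dt_noise_sd = 0.02,
                           ice_edge_lat = 66, current_speed = 0.3) {
  list(sst_eq = sst_eq, sst_pole = sst_pole, sbt_offset = sbt_offset,
       amplification = amplification, npp_sensitivity = npp_sensitivity,
       sst_noise_sd = sst_noise_sd, dt_noise_sd = dt_noise_sd,
       ice_edge_lat = ice_edge_lat, current_speed = current_speed)
}

## deterministic global-anomaly trajectory (degC vs 1850-1900), no noise
delta_t_ramp <- function(years, scenario) {
  hist_ramp <- function(y) 1.2 * pmax(0, (y - 1930) / 85)^1.5
  clim_ref <- mean(hist_ramp(1971:2000))
  switch(scenario,
    climatology = rep(clim_ref, length(years)),
    strong_mitigation = ifelse(years < 2015, hist_ramp(years),
                               1.8 - 0.6 * exp(-(years - 2015) / 25)),
    no_mitigation = ifelse(years < 2015, hist_ramp(years),
                           1.2 + 3.2 * ((years - 2015) / 85)^1.3),
    stopf("unknown scenario '%s'", scenario, class = "fc_config_error")
  )
}

## zonal baseline SST (degC): monotone non-increasing from equator to pole
base_sst <- function(lat, cfg = forcing_config()) {
  cfg$sst_pole + (cfg$sst_eq - cfg$sst_pole) * cos(lat * pi / 180)^1.5
}

#' Generate gridded climate forcing under a scenario
#'
#' Produces annual gridded fields (sea surface and bottom temperature,
#' net primary production, salinity, sea-ice fraction, surface current
#' components) plus the yearly global surface air temperature anomaly
#' vs pre-industrial, for one scenario:
#' \describe{
#'   \item{strong_mitigation}{warming saturates below 2 degC by 2100 (an
#'     SSP1-2.6-like pathway);}
#'   \item{no_mitigation}{warming exceeds 4 degC by 2100 (SSP5-8.5-like);}
#'   \item{climatology}{stationary in expectation at the 1971-2000 mean
#'     state, for spin-up and null tests.}
#' }
#' Temperatures are a latitudinal baseline plus `amplification` times the
#' anomaly (relative to the 1971-2000 climatological anomaly) plus
#' row-centered noise, so the zonal-mean SST gradient is exactly
#' monotone from equator to pole at every time step. NPP responds to
#' local warming with the configured sensitivity; the sea-ice edge
#' retreats poleward with warming.
#'
#' @param world an `fc_world`.
#' @param scenario one of `"strong_mitigation"`, `"no_mitigation"`,
#'   `"climatology"`.
#' @param years integer vector of forcing years (contiguous).
#' @param seed integer seed.
#' @param config list from [forcing_config()].
#' @return `fc_forcing`: list with `years`, `delta_t` (named numeric,
#'   degC anomaly per year), `fields` (list of `[lat, lon, year]` arrays:
#'   `sst`, `sbt`, `npp`, `sal`, `ice`, `u`, `v`), `scenario`, `seed`,
#'   `config`.
#' @export
generate_forcing <- function(world, scenario, years = 1991:2100, seed = 1,
                             config = forcing_config()) {
  if (!scenario %in% c("strong_mitigation", "no_mitigation", "climatology")) {
    stopf("unknown scenario '%s'", scenario, class = "fc_config_error")
  }
  set.seed(child_seed(seed, match(scenario, c("climatology", "strong_mitigation",
                                              "no_mitigation")) * 11 + 2))
  nlat <- length(world$lat); nlon <- length(world$lon); ny <- length(years)
  cfg <- config

  dt_det <- delta_t_ramp(years, scenario)
  delta_t <- dt_det + stats::rnorm(ny, 0, cfg$dt_noise_sd)
  if (scenario == "climatology") delta_t <- pmax(delta_t, 0)
  names(delta_t) <- years
  clim_ref <- mean(delta_t_ramp(1971:2000, "climatology"))

  bsst <- base_sst(world$lat, cfg)
  latm <- cell_lat_matrix(world)
  alat <- abs(latm)

  dims <- c(nlat, nlon, ny)
  f <- list(sst = array(NA_real_, dims), sbt = array(NA_real_, dims),
            npp = array(NA_real_, dims), sal = array(NA_real_, dims),
            ice = array(NA_real_, dims), u = array(NA_real_, dims),
            v = array(NA_real_, dims))

  ## stationary gyre-like current field, cells / yr
  u0 <- cfg$current_speed * sin(2 * latm * pi / 180) * -1
  v0 <- 0.3 * cfg$current_speed * sin(outer(rep(1, nlat), world$lon) * pi / 180)

  base_npp <- 0.5 + cos(latm * pi / 180)        # higher NPP at low latitudes
  base_sal <- 34 + 1.5 * cos(2 * latm * pi / 180)

  for (t in seq_len(ny)) {
    warm <- cfg$amplification * (delta_t[t] - clim_ref)
    noise <- matrix(stats::rnorm(nlat * nlon, 0, cfg$sst_noise_sd), nlat, nlon)
    noise <- noise - rowMeans(noise)            # keep zonal means exact
    sst <- outer(bsst, rep(1, nlon)) + warm + noise
    noise2 <- matrix(stats::rnorm(nlat * nlon, 0, cfg$sst_noise_sd), nlat, nlon)
    noise2 <- noise2 - rowMeans(noise2)
    sbt <- outer(bsst, rep(1, nlon)) - cfg$sbt_offset + 0.6 * warm + noise2
    npp <- base_npp * pmax(0, 1 + cfg$npp_sensitivity * warm) *
      exp(stats::rnorm(nlat * nlon, 0, 0.05))
    sal <- base_sal + matrix(stats::rnorm(nlat * nlon, 0, 0.2), nlat, nlon)
    edge <- cfg$ice_edge_lat + 3 * warm         # ice edge retreats poleward
    ice <- clamp(stats::plogis((alat - edge) / 2.5), 0, 1)
    f$sst[, , t] <- sst
    f$sbt[, , t] <- sbt
    f$npp[, , t] <- pmax(npp, 0)
    f$sal[, , t] <- sal
    f$ice[, , t] <- ice
    f$u[, , t] <- u0
    f$v[, , t] <- v0
  }
  for (nm in names(f)) dimnames(f[[nm]]) <- list(NULL, NULL, years)

  structure(list(years = years, delta_t = delta_t, fields = f,
                 scenario = scenario, seed = seed, config = cfg),
            class = "fc_forcing")
}

#' Extract one year's fields from a forcing object
#'
#' @param forcing an `fc_forcing`.
#' @param year a year present in `forcing$years`.
#' @return list of matrices (`sst`, `sbt`, `npp`, `sal`, `ice`, `u`, `v`)
#'   plus scalars `year` and `delta_t`.
#' @export
forcing_slice <- function(forcing, year) {
  t <- match(year, forcing$years)
  if (is.na(t)) stopf("year %s outside forcing span", year, class = "fc_span_error")
  sl <- lapply(forcing$fields, function(a) a[, , t])
  sl$year <- year
  sl$delta_t <- unname(forcing$delta_t[t])
  sl
}

#' Average forcing fields over a climatological window
#'
#' @param forcing an `fc_forcing`.
#' @param years window to average over (default: all forcing years).
#' @return a slice (list of matrices) of time-mean fields.
#' @export
climatology_slice <- function(forcing, years = forcing$years) {
  idx <- match(intersect(years, forcing$years), forcing$years)
  if (!length(idx)) stopf("window outside forcing span", class = "fc_span_error")
  sl <- lapply(forcing$fields, function(a) {
    apply(a[, , idx, drop = FALSE], c(1, 2), mean)
  })
  sl$year <- NA_integer_
  sl$delta_t <- mean(forcing$delta_t[idx])
  sl
}

#' @export
print.fc_forcing <- function(x, ...) {
  cat(sprintf("<fc_forcing> %s, %d-%d, dT(end) = %.2f degC\n",
              x$scenario, min(x$years), max(x$years),
              unname(x$delta_t[length(x$delta_t)])))
  invisible(x)
}
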