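#' Numerical parameters for the dynamic bioclimate envelope model
#'
#' @param D adult diffusion coefficient (grid cells^2 / yr).
#' @param larval_D larval dispersal coefficient (cells^2 / yr), applied
#'   as one extra diffusion pass on the reaction increment only.
#' @param dt nominal time step (yr); drivers halve it as needed to meet
#'   the explicit-scheme stability bounds (`dt * D <= 0.25`,
#'   `dt * larval_D <= 0.25`, `dt * max|u| <= 1`).
#' @param kappa carrying-capacity scaling constant; total capacity is
#'   `kappa * B0`.
#' @param b_exp generalized von Bertalanffy shape exponent (weight ~
#'   length^b), default 3.
#' @param spinup_years spin-up length under climatological forcing.
#' @param wasy_sens fractional change in the realized asymptotic weight
#'   per degC above the species' preferred maximum (default -2%/degC).
#' @param init_frac spin-up starting biomass as a fraction of capacity.
#' @return named list of class `fc_dbem_params`.
#' @export
dbem_params <- function(D = 1.0, larval_D = 0.5, dt = 0.25, kappa = 1,
                        b_exp = 3, spinup_years = 100, wasy_sens = -0.02,
                        init_frac = 0.1) {
  stopifnot(D >= 0, larval_D >= 0, dt > 0, spinup_years >= 1)
  structure(list(D = D, larval_D = larval_D, dt = dt, kappa = kappa,
                 b_exp = b_exp, spinup_years = spinup_years,
                 wasy_sens = wasy_sens, init_frac = init_frac),
            class = "fc_dbem_params")
}

## trapezoidal membership: 0 at [a, d] boundaries, 1 across [b, c]
trapezoid_membership <- function(x, a, b, c, d) {
  m <- numeric(length(x))
  m[x >= b & x <= c] <- 1
  ramp_up <- x > a & x < b
  m[ramp_up] <- (x[ramp_up] - a) / (b - a)
  ramp_dn <- x > c & x < d
  m[ramp_dn] <- (d - x[ramp_dn]) / (d - c)
  m
}

#' Habitat suitability index for one species and one forcing slice
#'
#' Per-cell suitability in `[0, 1]`: the geometric mean of the active
#' per-variable memberships — a trapezoidal thermal membership (0 at the
#' tolerance bounds, 1 across the preferred range) on surface
#' temperature for pelagic species and bottom temperature for demersal
#' ones, and an open-water membership `1 - ice fraction` when the slice
#' carries sea ice — masked to zero outside the species' latitudinal
#' range and where the bathymetry cannot host its depth range (bottom
#' within the depth range for demersal species; at least `depth_min` of
#' water for pelagic ones).
#'
#' @param species one species row.
#' @param forcing_slice list of field matrices (from [forcing_slice()]
#'   or built directly); must carry the temperature field the species'
#'   habitat association requires (`sst` or `sbt`).
#' @param world an `fc_world`.
#' @return matrix of class `fc_hsi` (`[lat, lon]`, values in `[0, 1]`).
#' @export
compute_hsi <- function(species, forcing_slice, world) {
  sp <- as.list(species[1, ])
  temp_field <- if (sp$habitat == "pelagic") "sst" else "sbt"
  if (is.null(forcing_slice[[temp_field]])) {
    stopf("forcing slice missing required field '%s'", temp_field,
          class = "fc_forcing_error")
  }
  temp <- forcing_slice[[temp_field]]
  m <- trapezoid_membership(temp, sp$tol_min, sp$pref_min, sp$pref_max, sp$tol_max)
  n_active <- 1
  if (!is.null(forcing_slice$ice)) {
    m <- m * clamp(1 - forcing_slice$ice, 0, 1)
    n_active <- n_active + 1
  }
  hsi <- matrix(m, nrow(temp), ncol(temp))^(1 / n_active)

  latm <- cell_lat_matrix(world)
  hsi[latm < sp$lat_min | latm > sp$lat_max] <- 0
  if (sp$habitat == "pelagic") {
    hsi[world$depth < sp$depth_min] <- 0
  } else {
    hsi[world$depth < sp$depth_min | world$depth > sp$depth_max] <- 0
  }
  structure(hsi, class = c("fc_hsi", "matrix", "array"),
            species_id = sp$species_id)
}

#' Per-cell carrying capacity from habitat suitability and productivity
#'
#' Distributes the unfished biomass `B0` over cells proportionally to
#' `HSI * NPP`, so total capacity is exactly `kappa * B0` whenever any
#' habitat exists. With no habitat at all (`sum(HSI * NPP) = 0`) the
#' capacity is all zero, flagged with attribute `no_habitat` and a
#' warning.
#'
#' In transient projections the normalizer is not recomputed every
#' year: passing `norm` (the climatological reference `sum(HSI * NPP)`)
#' anchors per-unit-suitability capacity at the reference state, so
#' total capacity — and with it catch potential — declines when warming
#' erodes suitability or primary production, instead of being silently
#' renormalized back to `B0`.
#'
#' @param species one species row (uses `b0_t`).
#' @param hsi `fc_hsi` matrix.
#' @param npp_grid NPP matrix on the same grid.
#' @param kappa scaling constant (default 1).
#' @param norm optional fixed normalizer (reference-period
#'   `sum(HSI * NPP)`); default: this slice's own sum.
#' @return capacity matrix (t per cell).
#' @export
carrying_capacity <- function(species, hsi, npp_grid, kappa = 1, norm = NULL) {
  stopifnot(all(dim(hsi) == dim(npp_grid)))
  w <- unclass(hsi) * npp_grid
  s <- norm %||% sum(w)
  if (s <= 0) {
    warnf("species %s has no habitat (sum(HSI*NPP) = 0)", species$species_id)
    return(structure(w * 0, no_habitat = TRUE))
  }
  structure(kappa * species$b0_t * w / s, no_habitat = sum(w) <= 0)
}

## conservative flux-form diffusion increment, no-flux boundaries.
## `mask` (logical) marks habitable cells: edges touching uninhabitable
## cells carry no flux, so populations do not pour into lethal habitat
## (they can still colonize cells that become suitable).
diffuse_increment <- function(B, Ddt, mask = NULL) {
  nr <- nrow(B); nc <- ncol(B)
  dB <- matrix(0, nr, nc)
  if (Ddt == 0 || (nr == 1 && nc == 1)) return(dB)
  if (nc > 1) {
    fx <- Ddt * (B[, -1, drop = FALSE] - B[, -nc, drop = FALSE])
    if (!is.null(mask)) {
      fx <- fx * (mask[, -1, drop = FALSE] & mask[, -nc, drop = FALSE])
    }
    dB[, -nc] <- dB[, -nc] + fx
    dB[, -1] <- dB[, -1] - fx
  }
  if (nr > 1) {
    fy <- Ddt * (B[-1, , drop = FALSE] - B[-nr, , drop = FALSE])
    if (!is.null(mask)) {
      fy <- fy * (mask[-1, , drop = FALSE] & mask[-nr, , drop = FALSE])
    }
    dB[-nr, ] <- dB[-nr, ] + fy
    dB[-1, ] <- dB[-1, ] - fy
  }
  dB
}

## conservative first-order upwind advection increment, closed boundaries
advect_increment <- function(B, u, v, dt, mask = NULL) {
  nr <- nrow(B); nc <- ncol(B)
  dB <- matrix(0, nr, nc)
  if (nc > 1) {
    ue <- 0.5 * (u[, -nc, drop = FALSE] + u[, -1, drop = FALSE])
    fl <- dt * ifelse(ue > 0, ue * B[, -nc, drop = FALSE], ue * B[, -1, drop = FALSE])
    if (!is.null(mask)) {
      fl <- fl * (mask[, -1, drop = FALSE] & mask[, -nc, drop = FALSE])
    }
    dB[, -nc] <- dB[, -nc] - fl
    dB[, -1] <- dB[, -1] + fl
  }
  if (nr > 1) {
    ve <- 0.5 * (v[-nr, , drop = FALSE] + v[-1, , drop = FALSE])
    fl <- dt * ifelse(ve > 0, ve * B[-nr, , drop = FALSE], ve * B[-1, , drop = FALSE])
    if (!is.null(mask)) {
      fl <- fl * (mask[-1, , drop = FALSE] & mask[-nr, , drop = FALSE])
    }
    dB[-nr, ] <- dB[-nr, ] - fl
    dB[-1, ] <- dB[-1, ] + fl
  }
  dB
}

check_stability <- function(params, dt, umax) {
  if (dt * params$D > 0.25 + 1e-12) {
    stopf("stability bound violated: dt * D = %.3g > 0.25", dt * params$D,
          class = "fc_step_error")
  }
  if (dt * params$larval_D > 0.25 + 1e-12) {
    stopf("stability bound violated: dt * larval_D = %.3g > 0.25",
          dt * params$larval_D, class = "fc_step_error")
  }
  if (dt * umax > 1 + 1e-12) {
    stopf("stability bound violated: CFL dt * max|u| = %.3g > 1", dt * umax,
          class = "fc_step_error")
  }
}

## steps per year honouring all stability bounds
n_substeps <- function(params, umax) {
  n <- max(1L, ceiling(1 / params$dt))
  while (TRUE) {
    dt <- 1 / n
    ok <- dt * params$D <= 0.25 && dt * params$larval_D <= 0.25 && dt * umax <= 1
    if (ok) return(n)
    n <- n * 2L
  }
}

#' One time step of the advection-diffusion-reaction population model
#'
#' Operator order: logistic reaction toward carrying capacity at rate
#' `r` (decay where capacity is zero) minus catch `F * B`, with the
#' reaction increment given one extra larval-dispersal diffusion pass;
#' then conservative explicit diffusion and first-order upwind advection
#' with no-flux domain boundaries. The mean body weight relaxes toward a
#' temperature-adjusted von Bertalanffy asymptote. Biomass is clipped at
#' zero (clip count in the diagnostics attribute).
#'
#' @param state list with `biomass` and `weight` matrices and `time`.
#' @param species one species row.
#' @param forcing_slice field list; needs `u`/`v` when `advect = TRUE`
#'   and the species' temperature field for the weight sub-model.
#' @param params `fc_dbem_params`; `params$dt` is the step length and
#'   must satisfy the stability bounds (error naming the bound if not).
#' @param fishing_mortality instantaneous fishing mortality F (1/yr).
#' @param kc optional precomputed carrying-capacity matrix (computed
#'   from the slice if omitted).
#' @param world required when `kc` is omitted.
#' @return updated state; attributes `catch` (matrix of catch removed
#'   this step, t) and `clipped` (number of negative-biomass clips).
#' @export
step_population <- function(state, species, forcing_slice, params,
                            fishing_mortality = 0, kc = NULL, world = NULL) {
  dt <- params$dt
  u <- forcing_slice$u
  v <- forcing_slice$v
  umax <- max(abs(c(u %||% 0, v %||% 0)))
  check_stability(params, dt, umax)

  if (is.null(kc)) {
    if (is.null(world)) stopf("need world or a precomputed kc")
    hsi <- compute_hsi(species, forcing_slice, world)
    kc <- carrying_capacity(species, hsi, forcing_slice$npp, params$kappa)
  }

  B <- state$biomass
  r <- species$r_intr
  growth <- matrix(0, nrow(B), ncol(B))
  pos <- kc > 0
  growth[pos] <- dt * r * B[pos] * (1 - B[pos] / kc[pos])
  growth[!pos] <- -dt * r * B[!pos]

  ## larval dispersal: extra diffusion pass on the reaction increment only
  mask <- kc > 0
  if (params$larval_D > 0) {
    growth <- growth + diffuse_increment(growth, params$larval_D * dt, mask)
  }
  catch <- dt * fishing_mortality * B
  B <- B + growth - catch

  ## transport (habitat-masked: no flux into lethal cells)
  B <- B + diffuse_increment(B, params$D * dt, mask)
  if (!is.null(u) && !is.null(v)) B <- B + advect_increment(B, u, v, dt, mask)

  clipped <- sum(B < 0)
  B[B < 0] <- 0

  ## body-weight sub-model: relax toward temperature-adjusted asymptote
  W <- state$weight
  temp_field <- if (species$habitat == "pelagic") "sst" else "sbt"
  temp <- forcing_slice[[temp_field]]
  if (!is.null(W) && !is.null(temp)) {
    weff <- species$winf_g *
      pmax(0.05, 1 + params$wasy_sens * pmax(0, temp - species$pref_max))
    W <- W + dt * params$b_exp * species$k_growth * W * ((weff / W)^(1 / 3) - 1)
    W <- clamp(W, 1e-6, species$winf_g)
  }

  structure(list(biomass = B, weight = W, time = (state$time %||% 0) + dt),
            catch = catch, clipped = clipped)
}

#' Spin up a species to equilibrium under climatological forcing
#'
#' Runs `spinup_years` of unfished dynamics under a stationary
#' climatological slice, starting from `init_frac` of carrying capacity,
#' so the population reaches (near-)equilibrium before being perturbed
#' by transient forcing. The default spin-up length is 100 years.
#'
#' @param species one species row.
#' @param world an `fc_world`.
#' @param climatology_forcing an `fc_forcing` (its time mean is used) or
#'   a single slice list.
#' @param params `fc_dbem_params`.
#' @return state list (`biomass`, `weight`, `time`) with attribute
#'   `diagnostics`: `converged`, `max_rel_change` (final-year per-cell
#'   relative change), `spinup_years`, `kc`.
#' @export
initialize_distribution <- function(species, world, climatology_forcing,
                                    params = dbem_params()) {
  sl <- if (inherits(climatology_forcing, "fc_forcing")) {
    climatology_slice(climatology_forcing)
  } else climatology_forcing
  hsi <- compute_hsi(species, sl, world)
  kc <- carrying_capacity(species, hsi, sl$npp, params$kappa)

  state <- list(biomass = params$init_frac * kc,
                weight = matrix(0.5 * species$winf_g, nrow(kc), ncol(kc)),
                time = 0)
  umax <- max(abs(c(sl$u %||% 0, sl$v %||% 0)))
  n_sub <- n_substeps(params, umax)
  p_sub <- params; p_sub$dt <- 1 / n_sub

  prev <- state$biomass
  max_rel <- Inf
  for (yr in seq_len(params$spinup_years)) {
    for (s in seq_len(n_sub)) {
      state <- step_population(state, species, sl, p_sub,
                               fishing_mortality = 0, kc = kc)
    }
    if (yr == params$spinup_years) {
      active <- prev > 1e-9 * max(species$b0_t, 1)
      max_rel <- if (any(active)) {
        max(abs(state$biomass[active] - prev[active]) / prev[active])
      } else 0
    }
    prev <- state$biomass
  }
  attr(state, "diagnostics") <- list(converged = max_rel < 1e-3,
                                     max_rel_change = max_rel,
                                     spinup_years = params$spinup_years,
                                     kc = kc)
  state
}

#' Project maximum catch potential under F = M
#'
#' Runs the population forward over the forcing years with fishing
#' mortality set equal to natural mortality (the maximum-catch-potential
#' rule), recomputing habitat suitability and carrying capacity from
#' each year's forcing with the capacity normalizer anchored at the
#' climatological reference state (see [carrying_capacity()]), so
#' habitat erosion translates into lost capacity rather than being
#' renormalized away. Annual catch per cell is `F * B` integrated over
#' the year's sub-steps; the maximum sustainable yield summary is the
#' mean of the ten largest annual aggregate catches.
#'
#' @param species one species row.
#' @param forcing an `fc_forcing`.
#' @param params `fc_dbem_params`.
#' @param world an `fc_world`.
#' @param years projection years (default: all forcing years); must lie
#'   within the forcing span.
#' @param state optional initial state (default: spin-up under the
#'   climatological mean of `climatology_years`).
#' @param climatology_years window for the spin-up climatology (default:
#'   the first up-to-30 forcing years).
#' @param fishing_mortality F (1/yr), default `species$m_nat`.
#' @param burn_in_years fished burn-in under climatological conditions
#'   before catch accounting starts (default 20; 0 disables).
#' @return `fc_mcp`: list with `species_id`, `years`, `annual_catch`
#'   (t/yr, named), `catch_by_eez` (year, eez_id, tonnes), `msy`
#'   (mean of top-ten annual catches), `centroid_lat` (biomass-weighted,
#'   per year), `biomass_total`, `final_state`, `diagnostics`.
#' @export
project_catch_potential <- function(species, forcing, params = dbem_params(),
                                    world, years = forcing$years, state = NULL,
                                    climatology_years = NULL,
                                    fishing_mortality = NULL,
                                    burn_in_years = 20) {
  if (!all(years %in% forcing$years)) {
    stopf("forcing (%d-%d) shorter than requested projection (%d-%d)",
          min(forcing$years), max(forcing$years), min(years), max(years),
          class = "fc_span_error")
  }
  f_mort <- fishing_mortality %||% species$m_nat
  cy <- climatology_years %||% forcing$years[seq_len(min(30, length(forcing$years)))]
  if (is.null(state)) {
    state <- initialize_distribution(species, world,
                                     climatology_slice(forcing, cy), params)
  }
  init_diag <- attr(state, "diagnostics")

  ## reference normalizer: per-unit-suitability capacity is anchored at
  ## the climatological state for the whole projection
  sl0 <- climatology_slice(forcing, cy)
  hsi0 <- compute_hsi(species, sl0, world)
  kc_norm <- sum(unclass(hsi0) * sl0$npp)

  ## fished burn-in: approach the F = M equilibrium under climatological
  ## conditions so the accounted years carry the climate signal, not the
  ## unfished-to-fished transient
  if (burn_in_years > 0 && kc_norm > 0) {
    kc0 <- carrying_capacity(species, hsi0, sl0$npp, params$kappa)
    umax0 <- max(abs(c(sl0$u %||% 0, sl0$v %||% 0)))
    n_sub0 <- n_substeps(params, umax0)
    p_sub0 <- params; p_sub0$dt <- 1 / n_sub0
    for (i in seq_len(burn_in_years * n_sub0)) {
      state <- step_population(state, species, sl0, p_sub0,
                               fishing_mortality = f_mort, kc = kc0)
    }
  }

  latm <- cell_lat_matrix(world)
  ny <- length(years)
  annual_catch <- stats::setNames(numeric(ny), years)
  centroid <- stats::setNames(rep(NA_real_, ny), years)
  biomass_total <- stats::setNames(numeric(ny), years)
  eez_rows <- vector("list", ny)

  for (t in seq_len(ny)) {
    sl <- forcing_slice(forcing, years[t])
    hsi <- compute_hsi(species, sl, world)
    kc <- suppressWarnings(
      carrying_capacity(species, hsi, sl$npp, params$kappa,
                        norm = if (kc_norm > 0) kc_norm else NULL))
    umax <- max(abs(c(sl$u %||% 0, sl$v %||% 0)))
    n_sub <- n_substeps(params, umax)
    p_sub <- params; p_sub$dt <- 1 / n_sub
    catch_cells <- matrix(0, length(world$lat), length(world$lon))
    for (s in seq_len(n_sub)) {
      state <- step_population(state, species, sl, p_sub,
                               fishing_mortality = f_mort, kc = kc)
      catch_cells <- catch_cells + attr(state, "catch")
    }
    annual_catch[t] <- sum(catch_cells)
    bt <- sum(state$biomass)
    biomass_total[t] <- bt
    centroid[t] <- if (bt > 0) sum(state$biomass * latm) / bt else NA_real_
    in_eez <- !is.na(world$eez)
    agg <- tapply(catch_cells[in_eez], world$eez[in_eez], sum)
    eez_rows[[t]] <- data.frame(year = years[t],
                                eez_id = as.integer(names(agg)),
                                tonnes = unname(agg))
  }

  catch_by_eez <- do.call(rbind, eez_rows)
  msy <- msy_top_ten(annual_catch)

  structure(list(species_id = species$species_id, years = years,
                 annual_catch = annual_catch, catch_by_eez = catch_by_eez,
                 msy = msy, centroid_lat = centroid,
                 biomass_total = biomass_total, final_state = state,
                 diagnostics = list(spinup = init_diag,
                                    fishing_mortality = f_mort)),
            class = "fc_mcp")
}

#' Mean of the ten largest annual catches (MSY proxy)
#'
#' @param annual_catch numeric vector of annual catches.
#' @return mean of the ten largest values (all values if fewer than ten).
#' @export
msy_top_ten <- function(annual_catch) {
  mean(sort(annual_catch, decreasing = TRUE)[seq_len(min(10, length(annual_catch)))])
}
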