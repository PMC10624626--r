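#' Default run configuration
#'
#' Central registry of every tunable the pipeline uses; all unstated
#' constants live here (and in the per-module `*_config()` /
#' `*_params()` helpers) so they are visible and overridable in one
#' place. The defaults describe the standard desk-scale experiment:
#' a 18 x 36 (10 degree) world, 8 EEZs, 30 warm-affiliated species, two
#' emission scenarios over 1991-2100, reference period 1991-2010 and
#' 1,000 Monte Carlo draws.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    out_dir = "fishcast_out",
    world = list(n_eez = 14, grid_rows = 18, grid_cols = 36),
    years = list(history = c(1991, 2014), projection = c(1991, 2100),
                 reference = c(1991, 2010)),
    scenarios = c("strong_mitigation", "no_mitigation"),
    species = list(n_species = 30, invert_frac = 0.3, farmed_frac = 0.4,
                   warm_affiliated = TRUE),
    nutrients = list(missingness = 0.2, n_obs = 3),
    monte_carlo = list(draws = 1000),
    dbem = list(D = 1.0, larval_D = 0.5, dt = 0.25, spinup_years = 100),
    gomap = list(fcr = 1.5, inclusion = 0.3, max_depth = 200, max_ice = 0.5,
                 hsi_cutoff = 0.5),
    trends = list(baseline_year = 2000, horizons = c(2050, 2100),
                  reference_year = 2010)
  )
}

## strict merge: user keys must exist in the defaults (recursively)
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  for (k in names(user)) {
    if (!k %in% names(defaults)) {
      stopf("unknown config key '%s%s'", path, k, class = "fc_config_error")
    }
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path,
                                class = "fc_config_error")
  merge_config(default_config(), yaml::read_yaml(path))
}

#' Run the integrated projection pipeline
#'
#' Executes, in order: synthetic-data generation (world, climate
#' forcing per scenario, species pool, nutrient observations,
#' production history), nutrient-model fitting and profile prediction,
#' catch-potential projection (DBEM, F = M), mariculture-potential
#' projection (GOMAP surrogate), availability accounting with relative
#' changes against the reference period, and the trend / warming-scaling
#' / disparity statistics. `through` stops the pipeline early for
#' stage-wise runs.
#'
#' @param config list as from [default_config()] / [read_config()].
#' @param through last stage to execute: `"synth"`, `"dbem"`, `"gomap"`,
#'   `"availability"` or `"trends"`.
#' @param mc_draws Monte Carlo draws for the availability envelope
#'   (default from config; 0 disables the envelope).
#' @param quiet suppress progress messages.
#' @return named list of all stage products (see vignette).
#' @export
run_pipeline <- function(config = default_config(), through = "trends",
                         mc_draws = NULL, quiet = TRUE) {
  stages <- c("synth", "dbem", "gomap", "availability", "trends")
  depth <- match(through, stages)
  if (is.na(depth)) stopf("unknown stage '%s'", through, class = "fc_config_error")
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed
  res <- list(config = config)

  ## --- synth ---------------------------------------------------------
  say("stage synth")
  world <- generate_world(n_eez = config$world$n_eez,
                          grid_shape = c(config$world$grid_rows,
                                         config$world$grid_cols),
                          seed = seed)
  proj_years <- seq(config$years$projection[1], config$years$projection[2])
  hist_years <- seq(config$years$history[1], config$years$history[2])
  forcing <- lapply(stats::setNames(config$scenarios, config$scenarios),
                    function(sc) generate_forcing(world, sc, proj_years, seed))
  sp_cfg <- species_config(invert_frac = config$species$invert_frac,
                           farmed_frac = config$species$farmed_frac,
                           warm_affiliated = config$species$warm_affiliated)
  pool <- generate_species_pool(config$species$n_species, world, seed, sp_cfg)
  nut <- generate_nutrient_observations(pool,
                                        missingness = config$nutrients$missingness,
                                        n_obs_per_species = config$nutrients$n_obs,
                                        seed = seed)
  production <- generate_production_history(pool, world, hist_years, seed)
  res <- c(res, list(world = world, forcing = forcing, pool = pool,
                     nutrient_data = nut, production = production))

  ## nutrient model + profiles (needed by everything downstream)
  model <- fit_hierarchical_nutrients(nut$observations, pool$species)
  profiles <- predict_nutrient_profiles(model, pool$species)
  portions <- default_edible_portions()
  groups <- pool$species[, c("species_id", "functional_group")]
  res <- c(res, list(nutrient_model = model, profiles = profiles,
                     portions = portions))
  if (depth < 2) return(res)

  ## --- dbem ----------------------------------------------------------
  say("stage dbem")
  params <- dbem_params(D = config$dbem$D, larval_D = config$dbem$larval_D,
                        dt = config$dbem$dt,
                        spinup_years = config$dbem$spinup_years)
  ref <- config$years$reference
  ref_years <- seq(ref[1], ref[2])
  mcp <- list(); mcp_rel_rows <- list(); mcp_excluded <- character(0)
  for (si in seq_len(nrow(pool$species))) {
    sp <- pool$species[si, ]
    ## shared spin-up on the first scenario's reference-period climatology
    ## (scenarios share the historical ramp)
    init <- tryCatch(
      suppressWarnings(initialize_distribution(
        sp, world, climatology_slice(forcing[[1]], ref_years), params)),
      error = function(e) NULL)
    if (is.null(init) || sum(init$biomass) <= 0) {
      mcp_excluded <- c(mcp_excluded, sp$species_id)
      next
    }
    for (sc in config$scenarios) {
      run <- project_catch_potential(sp, forcing[[sc]], params, world,
                                     state = init)
      mcp[[paste(sp$species_id, sc, sep = ".")]] <- run
      for (ez in unique(run$catch_by_eez$eez_id)) {
        ser <- run$catch_by_eez[run$catch_by_eez$eez_id == ez, ]
        rel <- tryCatch(relative_change(
          data.frame(year = ser$year, value = ser$tonnes), ref),
          error = function(e) NULL)
        if (is.null(rel)) next
        mcp_rel_rows[[length(mcp_rel_rows) + 1]] <-
          data.frame(scenario = sc, species_id = sp$species_id, eez_id = ez,
                     year = rel$year, rel = rel$rel)
      }
    }
  }
  mcp_rel <- do.call(rbind, mcp_rel_rows)
  res <- c(res, list(dbem_params = params, mcp = mcp, mcp_rel = mcp_rel,
                     mcp_excluded = mcp_excluded))
  if (depth < 3) return(res)

  ## --- gomap ---------------------------------------------------------
  say("stage gomap")
  filters <- farm_filters(max_depth = config$gomap$max_depth,
                          max_ice = config$gomap$max_ice,
                          hsi_cutoff = config$gomap$hsi_cutoff)
  ## forage supply history from the generator's reduction records
  fish_tot <- stats::aggregate(tonnes ~ year,
                               data = production[production$sector == "fisheries", ],
                               FUN = sum)
  red_tot <- stats::aggregate(tonnes ~ year,
    data = production[production$end_use == "reduction", , drop = FALSE],
    FUN = sum)
  forage_hist <- merge(fish_tot, red_tot, by = "year",
                       suffixes = c("_all", "_red"), all.x = TRUE)
  forage_hist <- data.frame(year = forage_hist$year,
                            tonnes = ifelse(is.na(forage_hist$tonnes_red), 0,
                                            forage_hist$tonnes_red),
                            usage_fraction = ifelse(is.na(forage_hist$tonnes_red),
                                                    0, forage_hist$tonnes_red /
                                                      forage_hist$tonnes_all))

  mar <- production[production$sector == "mariculture" &
                    production$year >= ref[1] & production$year <= ref[2], ]
  mar_base <- stats::aggregate(tonnes ~ species_id + eez_id, data = mar,
                               FUN = function(x) sum(x) / length(ref_years))
  clim_sl <- climatology_slice(forcing[[1]], ref_years)

  training <- NULL; mpp_model <- NULL; mpp <- list(); mpp_rel <- NULL
  gomap_diag <- list()
  farmed <- pool$species[pool$species$farmed, , drop = FALSE]
  if (nrow(farmed) && nrow(mar_base)) {
    rows <- list()
    for (si in seq_len(nrow(farmed))) {
      sp <- farmed[si, ]
      mb <- mar_base[mar_base$species_id == sp$species_id, ]
      if (!nrow(mb)) next
      suit <- tryCatch(suppressWarnings(farm_suitability(sp, clim_sl, world,
                                                         filters)),
                       error = function(e) NULL)
      if (is.null(suit)) next
      ph <- pool$prices[pool$prices$species_id == sp$species_id, ]
      price_now <- mean(utils::tail(ph$price[order(ph$year)], 5))
      feed <- feed_requirements(sp, sum(mb$tonnes), forage_hist,
                                fcr = config$gomap$fcr,
                                inclusion = config$gomap$inclusion)
      for (j in seq_len(nrow(mb))) {
        ez <- as.character(mb$eez_id[j])
        rows[[length(rows) + 1]] <- data.frame(
          species_id = sp$species_id, eez_id = mb$eez_id[j],
          area = unname(suit$area_by_eez[ez]),
          price = price_now, hsi = unname(suit$mean_hsi_by_eez[ez]),
          protein_index = feed$crude_protein_index,
          production = mb$tonnes[j])
      }
    }
    training <- do.call(rbind, rows)
  }
  if (!is.null(training) && nrow(training) >= 20) {
    mpp_model <- withCallingHandlers(fit_mpp_model(training),
                                     warning = function(w) invokeRestart("muffleWarning"))
    mpp_rel_rows <- list()
    for (si in seq_len(nrow(farmed))) {
      sp <- farmed[si, ]
      est_eez <- mar_base$eez_id[mar_base$species_id == sp$species_id]
      if (!length(est_eez)) next  # established producers only
      ph <- pool$prices[pool$prices$species_id == sp$species_id, ]
      pf <- forecast_price(ph$price[order(ph$year)], length(proj_years))
      feed <- feed_requirements(sp, sum(mar_base$tonnes[
        mar_base$species_id == sp$species_id]), forage_hist,
        fcr = config$gomap$fcr, inclusion = config$gomap$inclusion)
      for (sc in config$scenarios) {
        proj <- project_mpp(mpp_model, sp, forcing[[sc]], world, pf$forecast,
                            feed$crude_protein_index, proj_years, filters,
                            eez_ids = est_eez)
        mpp[[paste(sp$species_id, sc, sep = ".")]] <- proj
        for (ez in est_eez) {
          ser <- proj[proj$eez_id == ez, ]
          rel <- tryCatch(relative_change(
            data.frame(year = ser$year, value = ser$mpp_t), ref),
            error = function(e) NULL)
          if (is.null(rel)) next
          mpp_rel_rows[[length(mpp_rel_rows) + 1]] <-
            data.frame(scenario = sc, species_id = sp$species_id, eez_id = ez,
                       year = rel$year, rel = rel$rel)
        }
      }
    }
    mpp_rel <- do.call(rbind, mpp_rel_rows)
  } else {
    gomap_diag$skipped <- sprintf(
      "mariculture model skipped: %d training rows (< 20)",
      if (is.null(training)) 0L else nrow(training))
  }
  res <- c(res, list(gomap_training = training, mpp_model = mpp_model,
                     mpp = mpp, mpp_rel = mpp_rel, gomap_diag = gomap_diag,
                     forage_history = forage_hist))
  if (depth < 4) return(res)

  ## --- availability --------------------------------------------------
  say("stage availability")
  hist_avail <- compute_availability(production, profiles, portions, groups,
                                     exclude_reduction = TRUE)
  availability <- list(); envelopes <- list()
  draws <- mc_draws %||% config$monte_carlo$draws
  for (sc in config$scenarios) {
    mr <- mcp_rel[mcp_rel$scenario == sc, c("species_id", "eez_id", "year", "rel")]
    pr <- if (!is.null(mpp_rel)) {
      mpp_rel[mpp_rel$scenario == sc, c("species_id", "eez_id", "year", "rel")]
    } else NULL
    availability[[sc]] <- project_availability(production, mr, pr, profiles,
                                               portions, groups, ref)
    if (draws >= 2) {
      envelopes[[sc]] <- monte_carlo_bands(
        function(prof_d, port_d) {
          project_availability(production, mr, pr, prof_d, port_d, groups, ref)
        }, profiles, portions, draws = draws, seed = seed)
    }
  }
  res <- c(res, list(hist_availability = hist_avail,
                     availability = availability, envelopes = envelopes))
  if (depth < 5) return(res)

  ## --- trends --------------------------------------------------------
  say("stage trends")
  global_hist <- stats::aggregate(available_t ~ nutrient + year,
                                  data = hist_avail, FUN = sum)
  trend_fits <- lapply(stats::setNames(nm = unique(global_hist$nutrient)),
                       function(nut) {
    g <- global_hist[global_hist$nutrient == nut, ]
    fit_trend(data.frame(year = g$year, value = g$available_t))
  })

  scaling <- list(); scaling_rows <- list()
  for (scope in c("global", "lower_income")) {
    for (nutx in unique(profiles$nutrient)) {
      pts <- NULL
      for (sc in config$scenarios) {
        agg <- if (scope == "global") {
          aggregate_availability(availability[[sc]], world, "global")
        } else {
          a <- aggregate_availability(availability[[sc]], world, "income")
          a[a$region == "lower_income", ]
        }
        a2 <- stats::aggregate(available_t ~ year,
                               data = agg[agg$nutrient == nutx, ], FUN = sum)
        p <- tryCatch(scaling_points(a2, forcing[[sc]]$delta_t,
                                     config$trends$baseline_year),
                      error = function(e) NULL)
        if (!is.null(p)) pts <- rbind(pts, p)
      }
      if (is.null(pts) || nrow(pts) < 3) next
      f <- fit_warming_scaling(pts, scope, nutx)
      scaling[[paste(scope, nutx, sep = ".")]] <- f
      scaling_rows[[length(scaling_rows) + 1]] <- data.frame(
        scope = scope, nutrient = nutx, slope = f$slope,
        intercept = f$intercept, se = f$se, p = f$p, n = f$n)
    }
  }

  disparity <- lapply(availability, function(av) {
    disparity_summary(av, world, config$trends$horizons,
                      config$trends$reference_year)
  })

  res <- c(res, list(trend_fits = trend_fits, scaling = scaling,
                     scaling_table = do.call(rbind, scaling_rows),
                     disparity = disparity))
  res
}
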