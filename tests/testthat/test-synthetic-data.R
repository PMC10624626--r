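test_that("generate_world honours its invariants and the tropics rule", {
  for (seed in 1:3) {
    w <- tiny_world(n_eez = 6, seed = seed)
    et <- w$eez_table
    expect_equal(et$tropical, abs(et$centroid_lat) < 23.5)
    expect_true(any(et$tropical) && any(!et$tropical))
    ## every EEZ has cells, positive areas, positive population
    counts <- table(w$eez[!is.na(w$eez)])
    expect_setequal(as.integer(names(counts)), et$eez_id)
    expect_true(all(counts >= 1))
    expect_true(all(w$area > 0))
    expect_true(all(w$population$population > 0))
  }
})

test_that("generate_world is deterministic and GDP median split is balanced", {
  w1 <- tiny_world(n_eez = 6, seed = 11)
  w2 <- tiny_world(n_eez = 6, seed = 11)
  expect_identical(w1, w2)
  ## sort-and-count oracle: exactly half strictly below the median of 6
  gdp <- sort(w1$eez_table$gdp_pc)
  med <- stats::median(gdp)
  expect_identical(sum(w1$eez_table$gdp_pc < med), 3L)
})

test_that("generate_world rejects grids too small for the EEZ count", {
  expect_error(generate_world(40, c(6, 6), seed = 1), class = "fc_sizing_error")
})

test_that("forcing scenarios hit their warming anchors", {
  w <- tiny_world()
  f_no <- generate_forcing(w, "no_mitigation", 1991:2100, seed = 2)
  f_sm <- generate_forcing(w, "strong_mitigation", 1991:2100, seed = 2)
  f_cl <- generate_forcing(w, "climatology", 1991:2100, seed = 2)
  expect_gt(f_no$delta_t[["2100"]], 4.0)
  expect_lte(f_sm$delta_t[["2100"]], 2.0)
  ## climatology: regression slope of dT on year indistinguishable from 0
  sl <- stats::coef(stats::lm(f_cl$delta_t ~ seq_along(f_cl$delta_t)))[2]
  expect_lt(abs(sl), 1e-3)
  ## scenario ordering from 2040 on
  late <- as.character(2040:2100)
  expect_true(all(f_no$delta_t[late] >= f_sm$delta_t[late]))
  expect_error(generate_forcing(w, "rcp85", 1991:2000), class = "fc_config_error")
})

test_that("forcing fields satisfy their physical invariants", {
  w <- tiny_world()
  f <- generate_forcing(w, "no_mitigation", 1991:2020, seed = 3)
  expect_true(all(f$fields$ice >= 0 & f$fields$ice <= 1))
  expect_true(all(f$fields$npp >= 0))
  ## zonal-mean SST non-increasing from equator to pole in every year
  i10 <- which.min(abs(abs(w$lat) - 10))
  i60 <- which.min(abs(abs(w$lat) - 60))
  for (t in seq_along(f$years)) {
    zm <- rowMeans(f$fields$sst[, , t])
    expect_gte(zm[i10], zm[i60])
    sorted_north <- zm[w$lat >= 0][order(w$lat[w$lat >= 0])]
    expect_true(all(diff(sorted_north) <= 1e-9))
  }
})

test_that("species pool nests taxonomy and honours envelope invariants", {
  w <- tiny_world()
  pool <- generate_species_pool(30, w, seed = 4)
  sp <- pool$species
  expect_true(all(sp$tol_min < sp$pref_min & sp$pref_max < sp$tol_max))
  expect_true(all(sp$m_nat > 0 & sp$r_intr > 0 & sp$winf_g > 0))
  ## species sharing a genus share family and order
  for (g in unique(sp$genus)) {
    sub <- sp[sp$genus == g, ]
    expect_length(unique(sub$family), 1)
    expect_length(unique(sub$order), 1)
  }
  ## invertebrate count exact under the configured fraction
  n_inv <- sum(sp$class %in% c("Bivalvia", "Cephalopoda", "Malacostraca",
                               "Gastropoda"))
  expect_identical(n_inv, 9L)  # round-half-up of 30 x 0.3
  ## pelagic/demersal assignment consistent with functional group
  expect_true(all(sp$habitat[sp$functional_group %in%
                               c("small_pelagic", "large_pelagic")] == "pelagic"))
  expect_identical(pool, generate_species_pool(30, w, seed = 4))
})

test_that("nutrient observation generator controls missingness exactly", {
  w <- tiny_world()
  pool <- generate_species_pool(50, w, seed = 5)
  nd <- generate_nutrient_observations(pool, missingness = 0.4, seed = 5)
  expect_length(nd$unobserved, 20)
  obs_sp <- unique(nd$observations$species_id)
  expect_setequal(obs_sp, setdiff(pool$species$species_id, nd$unobserved))

  nd0 <- generate_nutrient_observations(pool, missingness = 0, seed = 5)
  tab <- table(nd0$observations$species_id, nd0$observations$nutrient)
  expect_true(all(tab >= 1))

  ## zero observation noise: observed value equals hidden truth
  cfgq <- nutrient_truth_config(sd_obs = 0)
  ndq <- generate_nutrient_observations(pool, cfgq, missingness = 0, seed = 6)
  m <- merge(ndq$observations, ndq$truth, by = c("species_id", "nutrient"))
  expect_equal(m$concentration, m$true_conc, tolerance = 1e-12)

  expect_error(generate_nutrient_observations(pool, missingness = 1.0, seed = 1))
  small <- list(species = pool$species[1:10, ])
  expect_error(generate_nutrient_observations(small, missingness = 0.97, seed = 1),
               class = "fc_degenerate_design")
})

test_that("production history keeps reduction near one-third of catches", {
  w <- tiny_world(n_eez = 6)
  pool <- generate_species_pool(30, w, seed = 7)
  prod <- generate_production_history(pool, w, 1991:2014, seed = 7)
  fish <- prod[prod$sector == "fisheries", ]
  for (yr in unique(fish$year)) {
    fy <- fish[fish$year == yr, ]
    share <- sum(fy$tonnes[fy$end_use == "reduction"]) / sum(fy$tonnes)
    expect_gte(share, 0.28)
    expect_lte(share, 0.38)
  }
  ## reduction never appears outside fisheries
  expect_true(all(prod$sector[prod$end_use == "reduction"] == "fisheries"))
  ## non-farmed species have no mariculture records
  nf <- pool$species$species_id[!pool$species$farmed]
  expect_identical(
    nrow(prod[prod$sector == "mariculture" & prod$species_id %in% nf, ]), 0L)
  ## summation oracle against the generator's own per-year summary
  yt <- attr(prod, "yearly_totals")
  recompute <- stats::aggregate(tonnes ~ year + sector, data = prod, FUN = sum)
  m <- merge(yt, recompute, by = c("year", "sector"))
  expect_equal(m$tonnes.x, m$tonnes.y, tolerance = 1e-12)
  expect_error(generate_production_history(pool, w, 2001:2010, seed = 1))
})
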