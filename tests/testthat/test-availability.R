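## small hand-built accounting fixtures
mini_profiles <- function(conc = c(sp_a = 10, sp_b = 40), width = 0) {
  do.call(rbind, lapply(names(conc), function(sp) {
    data.frame(species_id = sp, nutrient = "calcium", point = conc[[sp]],
               lower = max(conc[[sp]] - width / 2, 0),
               upper = conc[[sp]] + width / 2, provenance = "species")
  }))
}

mini_portions <- function(means = c(small_pelagic = 0.5, demersal = 0.25),
                          spread = 0) {
  data.frame(functional_group = names(means), mean = unname(means),
             min = pmax(unname(means) - spread / 2, 0),
             max = unname(means) + spread / 2)
}

mini_groups <- data.frame(species_id = c("sp_a", "sp_b"),
                          functional_group = c("small_pelagic", "demersal"))

mini_production <- function() {
  data.frame(year = 2000, species_id = c("sp_a", "sp_b"), eez_id = 1L,
             sector = "fisheries", tonnes = c(1000, 500), end_use = "direct")
}

test_that("relative change follows the reference-mean rule", {
  s <- data.frame(year = 1:3, value = c(10, 10, 20))
  rc <- relative_change(s, reference = c(1, 2))
  expect_equal(rc$rel, c(0, 0, 1))
  expect_equal(relative_change(data.frame(year = 1:3, value = c(5, 5, 5)),
                               c(1, 3))$rel, rep(0, 3))
  expect_error(relative_change(data.frame(year = 1:3, value = c(0, 0, 1)),
                               c(1, 2)),
               class = "fc_undefined_change")
})

test_that("availability unit arithmetic is exact", {
  ## 1000 t x 0.5 edible x 10 mg/100g = 0.05 t of calcium
  av <- compute_availability(mini_production()[1, ], mini_profiles(),
                             mini_portions(), mini_groups)
  expect_equal(av$available_t, 0.05, tolerance = 1e-15)

  ## two-species hand summation: 0.05 + 500*0.25*40*1e-5 = 0.10
  av2 <- compute_availability(mini_production(), mini_profiles(),
                              mini_portions(), mini_groups)
  expect_equal(sum(av2$available_t), 0.10, tolerance = 1e-15)

  ## omega-3 uses the g/100g factor
  pr <- mini_profiles(); pr$nutrient <- "omega3"
  av3 <- compute_availability(mini_production()[1, ], pr, mini_portions(),
                              mini_groups)
  expect_equal(av3$available_t, 1000 * 0.5 * 10 * 1e-2)
})

test_that("reduction exclusion is exact and consistent", {
  prod <- rbind(mini_production(),
                data.frame(year = 2000, species_id = "sp_a", eez_id = 1L,
                           sector = "fisheries", tonnes = 600,
                           end_use = "reduction"))
  on <- compute_availability(prod, mini_profiles(), mini_portions(), mini_groups,
                             exclude_reduction = TRUE)
  off <- compute_availability(prod, mini_profiles(), mini_portions(), mini_groups,
                              exclude_reduction = FALSE)
  red_only <- compute_availability(prod[prod$end_use == "reduction", ],
                                   mini_profiles(), mini_portions(), mini_groups,
                                   exclude_reduction = FALSE)
  expect_equal(sum(on$available_t) + sum(red_only$available_t),
               sum(off$available_t), tolerance = 1e-15)

  all_red <- prod[prod$end_use == "reduction", ]
  expect_equal(nrow(compute_availability(all_red, mini_profiles(),
                                         mini_portions(), mini_groups)), 0L)
})

test_that("missing profiles or portions are reported by species id", {
  prod <- mini_production()
  err <- tryCatch(
    compute_availability(prod, mini_profiles(c(sp_a = 10)), mini_portions(),
                         mini_groups),
    error = identity)
  expect_s3_class(err, "fc_accounting_error")
  expect_match(conditionMessage(err), "sp_b")
})

test_that("availability is linear in tonnage", {
  prod <- mini_production()
  a1 <- compute_availability(prod, mini_profiles(), mini_portions(), mini_groups)
  prod2 <- prod; prod2$tonnes <- prod2$tonnes * 2
  a2 <- compute_availability(prod2, mini_profiles(), mini_portions(), mini_groups)
  expect_equal(a2$available_t, 2 * a1$available_t, tolerance = 1e-15)
})

test_that("projection applies (1 + relative change) to the reference baseline", {
  ## constant 1000 t/yr over 1991-2010 baseline
  base <- do.call(rbind, lapply(1991:2010, function(y) {
    data.frame(year = y, species_id = "sp_a", eez_id = 1L,
               sector = "fisheries", tonnes = 1000, end_use = "direct")
  }))
  prof <- mini_profiles(c(sp_a = 10))
  port <- mini_portions(c(small_pelagic = 0.5))
  grp <- mini_groups[1, ]
  ref_av <- compute_availability(base[base$year == 2000, ], prof, port, grp)

  rel <- data.frame(species_id = "sp_a", year = c(2050, 2051, 2052),
                    rel = c(0, -1, 0.5))
  proj <- project_availability(base, rel, NULL, prof, port, grp)
  expect_equal(proj$available_t[proj$year == 2050], ref_av$available_t,
               tolerance = 1e-12)
  expect_equal(proj$available_t[proj$year == 2051], 0)
  expect_equal(proj$available_t[proj$year == 2052], 1.5 * ref_av$available_t,
               tolerance = 1e-12)
  expect_identical(attr(proj, "diagnostics")$excluded_species, character(0))

  ## unknown species excluded with diagnostic
  rel2 <- rbind(rel, data.frame(species_id = "ghost", year = 2050, rel = 0))
  proj2 <- project_availability(base, rel2, NULL, prof, port, grp)
  expect_identical(attr(proj2, "diagnostics")$excluded_species, "ghost")
})

test_that("EEZ aggregation closes to the global total", {
  w <- tiny_world(n_eez = 6)
  pool <- generate_species_pool(20, w, seed = 12)
  prod <- generate_production_history(pool, w, 1991:2012, seed = 12)
  nd <- generate_nutrient_observations(pool, missingness = 0.2, seed = 12)
  model <- fit_hierarchical_nutrients(nd$observations, pool$species)
  prof <- predict_nutrient_profiles(model, pool$species)
  av <- compute_availability(prod, prof, default_edible_portions(),
                             pool$species[, c("species_id", "functional_group")])
  glob <- aggregate_availability(av, w, "global")
  for (grouping in c("tropics", "income")) {
    g <- aggregate_availability(av, w, grouping)
    for (nut in unique(glob$nutrient)) {
      a <- sum(g$available_t[g$nutrient == nut])
      b <- sum(glob$available_t[glob$nutrient == nut])
      expect_equal(a, b, tolerance = 1e-9)
    }
  }
})

test_that("Monte Carlo degenerates to zero-width bands and rejects draws < 2", {
  prof <- mini_profiles(width = 0)
  port <- mini_portions(spread = 0)
  pipeline <- function(p, q) {
    compute_availability(mini_production(), p, q, mini_groups,
                         portion_col = "mean")
  }
  env <- monte_carlo_bands(pipeline, prof, port, draws = 10, seed = 1)
  expect_equal(env$lo95, env$median, tolerance = 1e-15)
  expect_equal(env$hi95, env$median, tolerance = 1e-15)
  expect_equal(sum(env$median), 0.10, tolerance = 1e-12)
  expect_error(monte_carlo_bands(pipeline, prof, port, draws = 1),
               class = "fc_config_error")
  ## spec'd default draw count
  expect_equal(eval(formals(monte_carlo_bands)$draws), 1000)
})

test_that("widening an input interval never narrows the envelope", {
  pipeline <- function(p, q) {
    compute_availability(mini_production(), p, q, mini_groups,
                         portion_col = "mean")
  }
  port <- mini_portions(spread = 0.1)
  widths <- vapply(c(1, 4, 10), function(wd) {
    env <- monte_carlo_bands(pipeline, mini_profiles(width = wd), port,
                             draws = 400, seed = 99)
    sum(env$hi95 - env$lo95)
  }, numeric(1))
  expect_true(all(diff(widths) >= 0))
})

test_that("per-capita series and the population-race comparison behave", {
  w <- tiny_world()
  av <- data.frame(nutrient = "calcium", region = "1",
                   year = c(2010, 2050), sector = "fisheries",
                   available_t = c(100, 100))
  pc <- per_capita(av, w, compare_years = c(2010, 2050))
  p10 <- w$population$population[w$population$eez_id == 1 &
                                 w$population$year == 2010]
  p50 <- w$population$population[w$population$eez_id == 1 &
                                 w$population$year == 2050]
  expect_equal(pc$per_capita$per_capita_t, c(100 / p10, 100 / p50))
  ## flat availability, growing population -> above the parity line
  cmp <- pc$comparison
  expect_equal(cmp$avail_change, 0)
  expect_gt(cmp$pop_change, 0)
  expect_true(cmp$above_line)

  ## equal % changes sit exactly on the line
  av2 <- av; av2$available_t <- c(100, 100 * p50 / p10)
  cmp2 <- per_capita(av2, w, c(2010, 2050))$comparison
  expect_equal(cmp2$comparison, 0, tolerance = 1e-12)
  expect_false(cmp2$above_line)

  av3 <- av; av3$year <- c(1900, 1901)
  expect_error(per_capita(av3, w), class = "fc_span_error")
})
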