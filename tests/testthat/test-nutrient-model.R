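test_that("degenerate fit: identical observations give exact means and zero variance", {
  obs <- toy_observations(list(a1 = c(7, 7), a2 = c(7, 7), b1 = 7, c1 = 7))
  m <- fit_hierarchical_nutrients(obs, toy_taxonomy())
  f <- m$fits$calcium
  expect_equal(unname(f$means$genus), rep(7, length(f$means$genus)))
  expect_equal(unname(f$means$family), rep(7, length(f$means$family)))
  expect_equal(f$means$pooled, 7)
  expect_equal(unname(f$varcomp), rep(0, length(f$varcomp)))
  pred <- predict_nutrient_content(m, toy_taxonomy()[1, ])
  expect_equal(pred$point, 7, tolerance = 1e-6)
})

test_that("balanced design: family mean is the mean of genus means", {
  ## GenA species at 10, GenB species at 20, equal n -> Fam1 mean 15
  obs <- toy_observations(list(a1 = c(10, 10), a2 = c(10, 10),
                               b1 = c(20, 20), b2 = c(20, 20)))
  m <- fit_hierarchical_nutrients(obs, toy_taxonomy())
  f <- m$fits$calcium
  expect_equal(unname(f$means$genus[c("GenA", "GenB")]), c(10, 20))
  expect_equal(unname(f$means$family[["Fam1"]]), 15)
})

test_that("fit rejects an empty table and flags the single-observation case", {
  expect_error(fit_hierarchical_nutrients(data.frame(), toy_taxonomy()),
               class = "fc_fit_error")
  one <- toy_observations(list(a1 = 12))
  m <- fit_hierarchical_nutrients(one, toy_taxonomy())
  expect_true(m$fits$calcium$single_observation)
  pred <- predict_nutrient_content(m, toy_taxonomy()[3, ])  # no own data
  expect_gt(pred$upper, pred$lower)  # interval not collapsed to zero width
})

test_that("provenance follows the descending-priority fallback", {
  tax <- toy_taxonomy()
  obs <- rbind(toy_observations(list(a1 = c(10, 12))),
               data.frame(species_id = "inv1", nutrient = "calcium",
                          concentration = 80, study_id = 1))
  m <- fit_hierarchical_nutrients(obs, tax)

  p_self <- predict_nutrient_content(m, tax[tax$species_id == "a1", ])
  expect_identical(p_self$provenance, "species")
  ## a2 shares GenA with a1 -> genus
  p_gen <- predict_nutrient_content(m, tax[tax$species_id == "a2", ])
  expect_identical(p_gen$provenance, "genus")
  ## b1 (GenB, Fam1) has no species/genus data -> family
  p_fam <- predict_nutrient_content(m, tax[tax$species_id == "b1", ])
  expect_identical(p_fam$provenance, "family")
  ## c1 (Fam2, Ord1) -> order
  p_ord <- predict_nutrient_content(m, tax[tax$species_id == "c1", ])
  expect_identical(p_ord$provenance, "order")
  ## an invertebrate with only class-level data -> class
  inv2 <- data.frame(species_id = "inv2", class = "Bivalvia", order = "OrdB2",
                     family = "FamB2", genus = "GenInv2")
  p_cls <- predict_nutrient_content(m, inv2)
  expect_identical(p_cls$provenance, "class")
  expect_equal(p_cls$point, 80, tolerance = 1e-9)
  ## a species in an unobserved class -> pooled
  alien <- data.frame(species_id = "x", class = "Cephalopoda", order = "OrdX",
                      family = "FamX", genus = "GenX")
  expect_identical(predict_nutrient_content(m, alien)$provenance, "pooled")
})

test_that("interval width never narrows as provenance coarsens", {
  set.seed(42)
  w <- tiny_world()
  pool <- generate_species_pool(60, w, seed = 8)
  nd <- generate_nutrient_observations(pool, missingness = 0.3, seed = 8)
  m <- fit_hierarchical_nutrients(nd$observations, pool$species)
  sp1 <- pool$species[1, ]
  lineages <- list(
    species = sp1,
    genus = transform(sp1, species_id = "ghost"),
    family = transform(sp1, species_id = "ghost", genus = "GhostGen"),
    order = transform(sp1, species_id = "ghost", genus = "GhostGen",
                      family = "GhostFam"),
    class = transform(sp1, species_id = "ghost", genus = "GhostGen",
                      family = "GhostFam", order = "GhostOrd"))
  for (nut in m$nutrients) {
    widths <- vapply(lineages, function(sp) {
      p <- predict_nutrient_content(m, sp)
      p$upper[p$nutrient == nut] - p$lower[p$nutrient == nut]
    }, numeric(1))
    expect_true(all(diff(widths) >= -1e-9),
                info = sprintf("nutrient %s widths: %s", nut,
                               paste(signif(widths, 4), collapse = ", ")))
  }
})

test_that("shrinkage keeps predictions in the hull and pooling is exact", {
  obs <- toy_observations(list(a1 = 10, a2 = c(19, 21), b1 = c(30, 32),
                               b2 = c(28, 31)))
  tax <- toy_taxonomy()
  m <- fit_hierarchical_nutrients(obs, tax)
  g <- unname(m$fits$calcium$means$genus[["GenA"]])
  p <- predict_nutrient_content(m, tax[tax$species_id == "a1", ])
  ## strictly between own observation (10) and the genus mean
  expect_gt(p$point, 10)
  expect_lt(p$point, g)

  ## monotone pooling: drop a1's own observations -> prediction = genus mean
  m2 <- fit_hierarchical_nutrients(obs[obs$species_id != "a1", ], tax)
  p2 <- predict_nutrient_content(m2, tax[tax$species_id == "a1", ])
  expect_identical(p2$provenance, "genus")
  expect_equal(p2$point, unname(m2$fits$calcium$means$genus[["GenA"]]),
               tolerance = 1e-12)
})

test_that("prediction RMSE against hidden truth falls as observations grow", {
  w <- tiny_world()
  pool <- generate_species_pool(40, w, seed = 9)
  rmse <- vapply(c(1, 5, 25), function(nobs) {
    nd <- generate_nutrient_observations(pool, missingness = 0,
                                         n_obs_per_species = nobs, seed = 9)
    m <- fit_hierarchical_nutrients(nd$observations, pool$species)
    pr <- predict_nutrient_profiles(m, pool$species)
    j <- merge(pr, nd$truth, by = c("species_id", "nutrient"))
    jc <- j[j$nutrient == "calcium", ]
    sqrt(mean((jc$point - jc$true_conc)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("farmed species inherit wild nutrient values exactly", {
  obs <- toy_observations(list(a1 = c(10, 12)))
  tax <- toy_taxonomy()
  m <- fit_hierarchical_nutrients(obs, tax)
  wild <- tax[1, ]
  farmed <- transform(wild, farmed = TRUE)
  expect_equal(predict_nutrient_content(m, wild)[c("point", "lower", "upper")],
               predict_nutrient_content(m, farmed)[c("point", "lower", "upper")])
})

test_that("nutrient model survives a JSON round trip", {
  w <- tiny_world()
  pool <- generate_species_pool(20, w, seed = 10)
  nd <- generate_nutrient_observations(pool, missingness = 0.2, seed = 10)
  m <- fit_hierarchical_nutrients(nd$observations, pool$species)
  path <- tempfile(fileext = ".json")
  nutrient_model_to_json(m, path)
  m2 <- nutrient_model_from_json(path)
  p1 <- predict_nutrient_profiles(m, pool$species[1:5, ])
  p2 <- predict_nutrient_profiles(m2, pool$species[1:5, ])
  expect_equal(p1$point, p2$point, tolerance = 1e-12)
  expect_equal(p1$provenance, p2$provenance)
})

test_that("edible portion table matches its anchors and invariants", {
  expect_equal(lookup_edible_portion("crustacean")$mean, 0.56)
  fin <- lookup_edible_portion("finfish_demersal")
  expect_equal(c(fin$min, fin$max), c(0.33, 0.92))
  tab <- default_edible_portions()
  expect_true(all(tab$min > 0 & tab$min <= tab$mean &
                  tab$mean <= tab$max & tab$max <= 1))
  ## molluscs (excluding cephalopods) anchored at 0.28
  expect_equal(lookup_edible_portion("bivalve")$mean, 0.28)
  err <- tryCatch(lookup_edible_portion("sea_cucumber"), error = identity)
  expect_s3_class(err, "fc_lookup_error")
  expect_match(conditionMessage(err), "sea_cucumber")
})
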