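#' Truth configuration for the synthetic nutrient-observation generator
#'
#' Per-species true concentrations are drawn from a taxonomically nested
#' random-effects structure on the `log(1 + concentration)` scale:
#' grand mean per nutrient plus independent class, order, family, genus
#' and species effects with the configured standard deviations, plus
#' observation noise on each measurement. Units follow seafood
#' composition conventions: calcium and iron in mg/100 g, omega-3 in
#' g/100 g, protein in % of edible mass (capped at 100).
#'
#' @param mu named grand means on the concentration scale; defaults are
#'   field-typical values (calcium 50 mg/100 g, iron 1.5 mg/100 g,
#'   omega-3 0.5 g/100 g, protein 19%).
#' @param sd_class,sd_order,sd_family,sd_genus,sd_species level effect
#'   sds on the log1p scale.
#' @param sd_obs observation (study) noise sd on the log1p scale.
#' @return named list.
#' @export
nutrient_truth_config <- function(mu = c(calcium = 50, iron = 1.5,
                                         omega3 = 0.5, protein = 19),
                                  sd_class = 0.4, sd_order = 0.3,
                                  sd_family = 0.25, sd_genus = 0.2,
                                  sd_species = 0.15, sd_obs = 0.1) {
  list(mu = mu, sd_class = sd_class, sd_order = sd_order, sd_family = sd_family,
       sd_genus = sd_genus, sd_species = sd_species, sd_obs = sd_obs)
}

fc_nutrients <- c("calcium", "iron", "omega3", "protein")

#' Generate synthetic nutrient-composition observations with hidden truth
#'
#' Emulates a database of published nutrient composition studies: each
#' species has a true concentration per nutrient drawn from the nested
#' taxonomic random-effects structure in [nutrient_truth_config()], and
#' observed measurements equal truth plus study noise. A fraction of
#' species ("missingness") has no observations at all for any nutrient —
#' the out-of-sample prediction case the hierarchical model must handle.
#' The hidden truth is returned alongside for recovery tests.
#'
#' The number of unobserved species is `round_half_up(missingness * n)`.
#'
#' @param pool output of [generate_species_pool()] (or its `species`
#'   data.frame).
#' @param truth_config list from [nutrient_truth_config()].
#' @param missingness fraction in `[0, 1)` of species with no observations.
#' @param n_obs_per_species observations per observed species per nutrient.
#' @param seed integer seed.
#' @return list with `observations` (`species_id`, `nutrient`,
#'   `concentration`, `study_id`), `truth` (`species_id`, `nutrient`,
#'   `true_z` on log1p scale, `true_conc`), `effects` (per-level effect
#'   draws), `unobserved` (species ids), `config`.
#' @export
generate_nutrient_observations <- function(pool,
                                           truth_config = nutrient_truth_config(),
                                           missingness = 0.2,
                                           n_obs_per_species = 3,
                                           seed = 1) {
  species <- if (is.data.frame(pool)) pool else pool$species
  if (missingness < 0 || missingness >= 1) stopf("missingness must be in [0, 1)")
  set.seed(child_seed(seed, 29))
  cfg <- truth_config
  n <- nrow(species)

  levels_tab <- list(class = species$class, order = species$order,
                     family = species$family, genus = species$genus,
                     species = species$species_id)
  sds <- c(class = cfg$sd_class, order = cfg$sd_order, family = cfg$sd_family,
           genus = cfg$sd_genus, species = cfg$sd_species)

  effects <- list()
  truth <- NULL
  for (nut in fc_nutrients) {
    z <- rep(log1p(cfg$mu[[nut]]), n)
    for (lv in names(levels_tab)) {
      taxa <- unique(levels_tab[[lv]])
      e <- stats::rnorm(length(taxa), 0, sds[[lv]])
      names(e) <- taxa
      effects[[paste(nut, lv, sep = ".")]] <-
        data.frame(nutrient = nut, level = lv, taxon = taxa, effect = unname(e))
      z <- z + e[levels_tab[[lv]]]
    }
    conc <- pmax(expm1(z), 0)
    if (nut == "protein") conc <- pmin(conc, 100)
    z <- log1p(conc)
    truth <- rbind(truth, data.frame(species_id = species$species_id,
                                     nutrient = nut, true_z = unname(z),
                                     true_conc = unname(conc)))
  }

  n_miss <- round_half_up(missingness * n)
  if (n_miss >= n) {
    stopf("all species unobserved: degenerate design", class = "fc_degenerate_design")
  }
  unobserved <- if (n_miss > 0) sample(species$species_id, n_miss) else character(0)
  observed <- setdiff(species$species_id, unobserved)

  obs <- do.call(rbind, lapply(fc_nutrients, function(nut) {
    tz <- truth$true_z[truth$nutrient == nut]
    names(tz) <- truth$species_id[truth$nutrient == nut]
    zz <- rep(tz[observed], each = n_obs_per_species) +
      stats::rnorm(length(observed) * n_obs_per_species, 0, cfg$sd_obs)
    y <- expm1(zz)
    if (nut == "protein") y <- pmin(y, 100)
    data.frame(species_id = rep(observed, each = n_obs_per_species),
               nutrient = nut, concentration = pmax(y, 0),
               study_id = rep(seq_len(n_obs_per_species), length(observed)))
  }))
  rownames(obs) <- NULL

  list(observations = obs, truth = truth,
       effects = do.call(rbind, effects), unobserved = unobserved, config = cfg)
}
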