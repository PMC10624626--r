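#' Configuration for the synthetic species-pool generator
#'
#' @param invert_frac fraction of the pool drawn from invertebrate
#'   classes (exact count by half-up rounding).
#' @param farmed_frac target fraction of non-bivalve species flagged as
#'   farmed (bivalves are always farmed).
#' @param warm_affiliated if `TRUE`, 70% of range centers fall in the
#'   tropics (|lat| < 20) and the rest at mid-latitudes (25-45 deg), the
#'   configuration used for climate-impact ordering experiments.
#' @param finfish_groups,invert_groups functional groups drawn for each
#'   branch, with sampling weights.
#' @param finfish_weights sampling weights for `finfish_groups`; small
#'   pelagics are over-represented, mirroring the dominance of forage
#'   fish in world catches.
#' @return named list of generator constants.
#' @export
species_config <- function(invert_frac = 0.3, farmed_frac = 0.4,
                           warm_affiliated = FALSE,
                           finfish_groups = c("small_pelagic", "large_pelagic",
                                              "demersal", "benthopelagic"),
                           finfish_weights = c(0.4, 0.2, 0.25, 0.15),
                           invert_groups = c("bivalve", "cephalopod",
                                             "crustacean", "gastropod")) {
  list(invert_frac = invert_frac, farmed_frac = farmed_frac,
       warm_affiliated = warm_affiliated, finfish_groups = finfish_groups,
       finfish_weights = finfish_weights, invert_groups = invert_groups)
}

## class for each functional group
group_class <- c(small_pelagic = "Actinopterygii", large_pelagic = "Actinopterygii",
                 demersal = "Actinopterygii", benthopelagic = "Actinopterygii",
                 bivalve = "Bivalvia", cephalopod = "Cephalopoda",
                 crustacean = "Malacostraca", gastropod = "Gastropoda")

## temperature field each group's envelope is scored against
group_habitat <- c(small_pelagic = "pelagic", large_pelagic = "pelagic",
                   demersal = "demersal", benthopelagic = "demersal",
                   bivalve = "demersal", cephalopod = "demersal",
                   crustacean = "demersal", gastropod = "demersal")

finfish_group_names <- c("small_pelagic", "large_pelagic", "demersal", "benthopelagic")

#' Generate a synthetic species pool
#'
#' Draws `n_species` exploited marine species with a properly nested
#' taxonomy (class > order > family > genus > species), functional
#' groups spanning finfish and invertebrate classes, thermal envelopes
#' anchored to the climatological temperature at each species' range
#' center (so every species is viable somewhere in its range), depth and
#' latitudinal ranges, von Bertalanffy growth parameters, population
#' parameters (natural mortality M, intrinsic rate r, unfished biomass
#' B0) and mariculture flags. Pelagic groups are scored against surface
#' temperature, all others against bottom temperature.
#'
#' The number of invertebrate species equals
#' `round_half_up(n_species * invert_frac)` exactly.
#'
#' @param n_species pool size (>= 1).
#' @param world an `fc_world` (used to anchor thermal envelopes).
#' @param seed integer seed.
#' @param config list from [species_config()].
#' @return list with `species` (one row per species; traits and
#'   taxonomy), and `prices` (long data.frame `species_id`, `year`,
#'   `price` farm-gate currency/t for 1991-2014).
#' @export
generate_species_pool <- function(n_species, world, seed = 1,
                                  config = species_config()) {
  if (!is_count(n_species) || n_species < 1) stopf("n_species must be >= 1")
  set.seed(child_seed(seed, 17))
  cfg <- config

  n_inv <- round_half_up(n_species * cfg$invert_frac)
  n_fin <- n_species - n_inv
  grp <- c(
    sample(cfg$finfish_groups, n_fin, replace = TRUE, prob = cfg$finfish_weights),
    sample(cfg$invert_groups, n_inv, replace = TRUE)
  )
  cls <- unname(group_class[grp])

  ## nested taxonomy: orders within class, 2 families/order, 2 genera/family
  make_taxa <- function(class_vec) {
    out <- data.frame(order = character(length(class_vec)),
                      family = character(length(class_vec)),
                      genus = character(length(class_vec)))
    for (cl in unique(class_vec)) {
      i <- which(class_vec == cl)
      n_ord <- max(1, ceiling(length(i) / 6))
      ord <- sample(paste0("Ord_", cl, "_", seq_len(n_ord)), length(i), replace = TRUE)
      fam <- paste0(sub("Ord_", "Fam_", ord), letters[sample(1:2, length(i), TRUE)])
      gen <- paste0(sub("Fam_", "Gen_", fam), sample(1:2, length(i), TRUE))
      out$order[i] <- ord; out$family[i] <- fam; out$genus[i] <- gen
    }
    out
  }
  taxa <- make_taxa(cls)

  habitat <- unname(group_habitat[grp])
  ## warm-affiliated pools concentrate in the tropics but keep a
  ## temperate contingent, as any global exploited-species set does --
  ## the tropics vs extra-tropics contrast needs production in both
  lat_center <- if (cfg$warm_affiliated) {
    n_trop <- round_half_up(0.7 * n_species)
    centers <- c(stats::runif(n_trop, -20, 20),
                 sample(c(-1, 1), n_species - n_trop, TRUE) *
                   stats::runif(n_species - n_trop, 25, 45))
    sample(centers)
  } else {
    stats::runif(n_species, -60, 60)
  }
  lat_half <- stats::runif(n_species, 10, 30)
  lat_min <- pmax(lat_center - lat_half, -90)
  lat_max <- pmin(lat_center + lat_half, 90)

  ## thermal envelope anchored to climatological temperature at range center
  cfg_f <- forcing_config()
  t_center <- base_sst(lat_center, cfg_f) -
    ifelse(habitat == "demersal", cfg_f$sbt_offset, 0)
  pref_half <- stats::runif(n_species, 1.5, 3)
  pref_min <- t_center - pref_half
  pref_max <- t_center + pref_half
  tol_min <- pref_min - stats::runif(n_species, 1, 3)
  ## warm-edge thermal safety margins are narrow for low-latitude species
  ## and widen toward the poles -- the pattern behind tropical sensitivity
  tol_warm <- stats::runif(n_species, 0.5, 2) +
    2 * clamp((abs(lat_center) - 20) / 40, 0, 1)
  tol_max <- pref_max + tol_warm

  depth_min <- ifelse(habitat == "pelagic", 0, stats::runif(n_species, 20, 100))
  depth_max <- ifelse(habitat == "pelagic",
                      stats::runif(n_species, 200, 600),
                      depth_min + stats::runif(n_species, 150, 600))

  winf <- stats::rlnorm(n_species,
                        meanlog = log(ifelse(grp == "large_pelagic", 2e4, 500)),
                        sdlog = 0.8)
  k_growth <- stats::runif(n_species, 0.2, 0.6)
  m_nat <- stats::runif(n_species, 0.2, 0.5)
  r_intr <- stats::runif(n_species, 0.5, 1.0)
  b0 <- stats::rlnorm(n_species, meanlog = log(5e4), sdlog = 0.6) *
    ifelse(grp == "small_pelagic", 4, 1)   # forage stocks dominate biomass

  farmed <- grp == "bivalve" | stats::runif(n_species) < cfg$farmed_frac
  feed_requiring <- farmed & grp %in% c(finfish_group_names, "crustacean")

  species <- data.frame(
    species_id = sprintf("sp%03d", seq_len(n_species)),
    class = cls, order = taxa$order, family = taxa$family, genus = taxa$genus,
    species = sprintf("%s_sp%03d", tolower(sub("Gen_", "", taxa$genus)),
                      seq_len(n_species)),
    functional_group = grp, habitat = habitat,
    depth_min = depth_min, depth_max = depth_max,
    lat_min = lat_min, lat_max = lat_max,
    tol_min = tol_min, tol_max = tol_max,
    pref_min = pref_min, pref_max = pref_max,
    winf_g = winf, k_growth = k_growth, m_nat = m_nat, r_intr = r_intr,
    b0_t = b0, farmed = farmed, feed_requiring = feed_requiring,
    stringsAsFactors = FALSE
  )

  ## farm-gate price history: AR(1) around a group-level mean price
  price_mean <- ifelse(grp %in% c("crustacean", "large_pelagic"), 6000,
                       ifelse(grp == "bivalve", 1500, 2500))
  yrs <- 1991:2014
  prices <- do.call(rbind, lapply(seq_len(n_species), function(i) {
    p <- numeric(length(yrs)); p[1] <- price_mean[i] * exp(stats::rnorm(1, 0, 0.1))
    for (t in 2:length(yrs)) {
      p[t] <- price_mean[i] + 0.8 * (p[t - 1] - price_mean[i]) +
        stats::rnorm(1, 0, 0.05 * price_mean[i])
    }
    data.frame(species_id = species$species_id[i], year = yrs, price = pmax(p, 1))
  }))

  list(species = species, prices = prices)
}
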