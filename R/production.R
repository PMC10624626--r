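#' Configuration for the synthetic production-history generator
#'
#' @param total_catch_t expected global annual fisheries catch (t live
#'   weight) at the start of the series.
#' @param small_pelagic_share share of total fisheries tonnage from
#'   small pelagics (forage fish); catches are skewed onto this group.
#' @param reduction_frac fraction of small-pelagic catch directed to
#'   reduction (fishmeal/oil). With the default shares,
#'   reduction / total = 0.6 x 0.55 = 33% of fisheries catches, the
#'   long-run share of reduction fisheries in world landings.
#' @param mariculture_start_t expected mariculture output per farmed
#'   species in the first year.
#' @param mariculture_growth annual expansion rate of mariculture.
#' @param noise_sd lognormal sd of species-year tonnage noise.
#' @return named list.
#' @export
production_config <- function(total_catch_t = 1e6, small_pelagic_share = 0.55,
                              reduction_frac = 0.6, mariculture_start_t = 2e3,
                              mariculture_growth = 0.05, noise_sd = 0.1) {
  list(total_catch_t = total_catch_t, small_pelagic_share = small_pelagic_share,
       reduction_frac = reduction_frac, mariculture_start_t = mariculture_start_t,
       mariculture_growth = mariculture_growth, noise_sd = noise_sd)
}

## EEZs whose latitudinal extent overlaps a species' range; nearest
## (by centroid) if none overlap
species_eez_weights <- function(species_row, world) {
  et <- world$eez_table
  half <- world$lat_step  # EEZ blocks span two grid rows
  inside <- which(et$centroid_lat + half >= species_row$lat_min &
                  et$centroid_lat - half <= species_row$lat_max)
  if (!length(inside)) {
    inside <- which.min(pmin(abs(et$centroid_lat - species_row$lat_min),
                             abs(et$centroid_lat - species_row$lat_max)))
  }
  w <- et$area_km2[inside]
  stats::setNames(w / sum(w), et$eez_id[inside])
}

#' Generate synthetic fisheries and mariculture production histories
#'
#' Emulates reconstructed catch and mariculture records: tonnage per
#' (year, species, EEZ, sector, end-use). Fisheries catches follow a
#' right-skewed distribution across species, concentrated on small
#' pelagics; a configured fraction of small-pelagic catch is split into
#' `end_use = "reduction"` records (fishmeal and oil), tuned so that
#' reduction is about one-third of total fisheries tonnage. Mariculture
#' records exist only for farmed species and expand over the series.
#' Species catches are allocated to the EEZs overlapping their
#' latitudinal range, proportionally to EEZ area.
#'
#' @param pool output of [generate_species_pool()].
#' @param world an `fc_world`.
#' @param years contiguous span of >= 20 years.
#' @param seed integer seed.
#' @param config list from [production_config()].
#' @return data.frame (`year`, `species_id`, `eez_id`, `sector`,
#'   `tonnes`, `end_use`) with attribute `yearly_totals` (per-year,
#'   per-sector totals, the generator's own summary).
#' @export
generate_production_history <- function(pool, world, years = 1991:2014,
                                        seed = 1, config = production_config()) {
  if (length(years) < 20) stopf("years span must be >= 20")
  species <- pool$species
  set.seed(child_seed(seed, 41))
  cfg <- config
  n <- nrow(species)

  ## per-species base weights, rescaled so small pelagics hold their share
  w <- stats::rlnorm(n, 0, 1) * species$b0_t
  sp_mask <- species$functional_group == "small_pelagic"
  if (any(sp_mask) && any(!sp_mask)) {
    w[sp_mask] <- w[sp_mask] / sum(w[sp_mask]) * cfg$small_pelagic_share
    w[!sp_mask] <- w[!sp_mask] / sum(w[!sp_mask]) * (1 - cfg$small_pelagic_share)
  } else {
    w <- w / sum(w)
  }

  eez_w <- lapply(seq_len(n), function(i) species_eez_weights(species[i, ], world))

  ## mild hump in total catch (rise to the mid-series, then slight decline)
  ty <- seq_along(years) / length(years)
  total_mult <- 0.85 + 0.4 * sin(pi * pmin(ty * 1.3, 1))

  rec <- vector("list", n * length(years) * 2L)
  k <- 0L
  for (t in seq_along(years)) {
    tonnes_sp <- cfg$total_catch_t * total_mult[t] * w *
      exp(stats::rnorm(n, 0, cfg$noise_sd))
    for (i in seq_len(n)) {
      ew <- eez_w[[i]]
      red <- if (sp_mask[i]) cfg$reduction_frac else 0
      for (j in seq_along(ew)) {
        tt <- tonnes_sp[i] * ew[j]
        k <- k + 1L
        rec[[k]] <- data.frame(year = years[t], species_id = species$species_id[i],
                               eez_id = as.integer(names(ew)[j]),
                               sector = "fisheries",
                               tonnes = tt * (1 - red), end_use = "direct")
        if (red > 0) {
          k <- k + 1L
          rec[[k]] <- data.frame(year = years[t], species_id = species$species_id[i],
                                 eez_id = as.integer(names(ew)[j]),
                                 sector = "fisheries",
                                 tonnes = tt * red, end_use = "reduction")
        }
      }
    }
  }

  ## mariculture: farmed species only, expanding, in their home EEZs
  farmed_idx <- which(species$farmed)
  mc_scale <- stats::rlnorm(length(farmed_idx), 0, 0.5)
  for (t in seq_along(years)) {
    for (fi in seq_along(farmed_idx)) {
      i <- farmed_idx[fi]
      ew <- eez_w[[i]]
      tot <- cfg$mariculture_start_t * mc_scale[fi] *
        (1 + cfg$mariculture_growth)^(t - 1) * exp(stats::rnorm(1, 0, cfg$noise_sd))
      for (j in seq_along(ew)) {
        k <- k + 1L
        rec[[k]] <- data.frame(year = years[t], species_id = species$species_id[i],
                               eez_id = as.integer(names(ew)[j]),
                               sector = "mariculture",
                               tonnes = tot * ew[j], end_use = "direct")
      }
    }
  }

  out <- do.call(rbind, rec[seq_len(k)])
  rownames(out) <- NULL
  yearly <- stats::aggregate(tonnes ~ year + sector, data = out, FUN = sum)
  attr(out, "yearly_totals") <- yearly
  out
}
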