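## Nutrient availability accounting.
##
## Unit conventions: production in tonnes live weight; concentrations
## per edible mass (calcium, iron mg/100 g; omega-3 g/100 g; protein %
## i.e. g/100 g). Availability is reported in tonnes of nutrient:
## tonnes live x edible fraction x concentration x unit factor, with
## unit factor 1e-5 for mg/100 g and 1e-2 for g/100 g.

nutrient_unit_factor <- c(calcium = 1e-5, iron = 1e-5, omega3 = 1e-2,
                          protein = 1e-2)

#' Relative change of a production-potential series vs a reference period
#'
#' `value_year / mean(reference years) - 1`, as a fraction. The default
#' reference period is 1991-2010.
#'
#' @param series data.frame `year`, `value` (or a named numeric vector).
#' @param reference two-element year span `c(first, last)`.
#' @return data.frame `year`, `rel`.
#' @export
relative_change <- function(series, reference = c(1991, 2010)) {
  if (!is.data.frame(series)) {
    series <- data.frame(year = as.integer(names(series)),
                         value = as.numeric(series))
  }
  ref <- series$value[series$year >= reference[1] & series$year <= reference[2]]
  if (!length(ref)) stopf("reference span outside series", class = "fc_span_error")
  m <- mean(ref)
  if (m == 0) {
    stopf("reference-period mean is zero: relative change undefined",
          class = "fc_undefined_change")
  }
  data.frame(year = series$year, rel = series$value / m - 1)
}

#' Nutrient availability from production records
#'
#' Converts production tonnage into tonnes of each nutrient available
#' for direct human consumption:
#' `tonnes x edible fraction (by functional group) x concentration`,
#' unit-converted. Records flagged `end_use = "reduction"` (fishmeal and
#' oil) contribute nothing when `exclude_reduction` is on.
#'
#' @param production data.frame `year`, `species_id`, `eez_id`,
#'   `sector`, `tonnes`, `end_use`.
#' @param profiles nutrient profiles (`species_id`, `nutrient`, `point`,
#'   ... ) from [predict_nutrient_profiles()].
#' @param portions edible-portion table (see
#'   [default_edible_portions()]).
#' @param species_groups data.frame `species_id`, `functional_group`.
#' @param exclude_reduction drop reduction-fishery records (default TRUE).
#' @param conc_col column of `profiles` holding the concentration to use
#'   (default `"point"`; Monte Carlo passes a sampled column).
#' @param portion_col column of `portions` holding the edible fraction
#'   (default `"mean"`).
#' @return data.frame `nutrient`, `region` (EEZ id, character), `year`,
#'   `sector`, `available_t`, of class `fc_availability`.
#' @export
compute_availability <- function(production, profiles, portions, species_groups,
                                 exclude_reduction = TRUE, conc_col = "point",
                                 portion_col = "mean") {
  sp_in <- unique(production$species_id)
  miss_prof <- setdiff(sp_in, unique(profiles$species_id))
  grp <- species_groups$functional_group[match(sp_in, species_groups$species_id)]
  miss_grp <- sp_in[is.na(grp)]
  miss_port <- sp_in[!is.na(grp) & !grp %in% portions$functional_group]
  bad <- unique(c(miss_prof, miss_grp, miss_port))
  if (length(bad)) {
    stopf("species missing nutrient profile or edible portion: %s",
          paste(bad, collapse = ", "), class = "fc_accounting_error")
  }

  pr <- production
  if (exclude_reduction) pr <- pr[pr$end_use != "reduction", , drop = FALSE]
  if (!nrow(pr)) {
    return(structure(data.frame(nutrient = character(), region = character(),
                                year = integer(), sector = character(),
                                available_t = numeric()),
                     class = c("fc_availability", "data.frame")))
  }
  pr$functional_group <- species_groups$functional_group[
    match(pr$species_id, species_groups$species_id)]
  pr$edible <- portions[[portion_col]][
    match(pr$functional_group, portions$functional_group)]

  out <- lapply(unique(profiles$nutrient), function(nut) {
    pf <- profiles[profiles$nutrient == nut, ]
    conc <- pf[[conc_col]][match(pr$species_id, pf$species_id)]
    val <- pr$tonnes * pr$edible * conc * nutrient_unit_factor[[nut]]
    agg <- stats::aggregate(val,
                            by = list(region = as.character(pr$eez_id),
                                      year = pr$year, sector = pr$sector),
                            FUN = sum)
    data.frame(nutrient = nut, region = agg$region, year = agg$year,
               sector = agg$sector, available_t = agg$x)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("fc_availability", "data.frame")
  out
}

#' Project nutrient availability from relative production-potential changes
#'
#' Applies the reference-period reported production times
#' `(1 + relative change)` rule: for each species, sector and EEZ, the
#' baseline is the mean annual reported production over the reference
#' period (reduction records excluded), and the projected production in
#' each year scales that baseline by the species' relative change in
#' catch / mariculture production potential. Availability is then
#' accounted as in [compute_availability()]. Species present in the
#' projections but absent from the baseline are excluded and listed in
#' the diagnostics.
#'
#' @param baseline_production historical production records.
#' @param mcp_relative data.frame `species_id`, `year`, `rel` (optional
#'   `eez_id` for EEZ-specific changes) for the fisheries sector.
#' @param mpp_relative same for mariculture (may be `NULL`).
#' @param profiles,portions,species_groups as in [compute_availability()].
#' @param reference reference span (default 1991-2010).
#' @param conc_col,portion_col forwarded to [compute_availability()].
#' @return `fc_availability` data.frame (all `end_use = "direct"`), with
#'   attribute `diagnostics$excluded_species`.
#' @export
project_availability <- function(baseline_production, mcp_relative,
                                 mpp_relative = NULL, profiles, portions,
                                 species_groups, reference = c(1991, 2010),
                                 conc_col = "point", portion_col = "mean") {
  base <- baseline_production[baseline_production$end_use != "reduction" &
                              baseline_production$year >= reference[1] &
                              baseline_production$year <= reference[2], ]
  nyr <- length(unique(base$year))
  base_mean <- stats::aggregate(tonnes ~ species_id + eez_id + sector,
                                data = base, FUN = function(x) sum(x) / nyr)

  build <- function(relchg, sector) {
    if (is.null(relchg) || !nrow(relchg)) return(NULL)
    bm <- base_mean[base_mean$sector == sector, ]
    if (!"eez_id" %in% names(relchg)) {
      merged <- merge(bm, relchg, by = "species_id")
    } else {
      merged <- merge(bm, relchg, by = c("species_id", "eez_id"))
    }
    if (!nrow(merged)) return(NULL)
    data.frame(year = merged$year, species_id = merged$species_id,
               eez_id = merged$eez_id, sector = sector,
               tonnes = pmax(merged$tonnes * (1 + merged$rel), 0),
               end_use = "direct")
  }
  proj <- rbind(build(mcp_relative, "fisheries"), build(mpp_relative, "mariculture"))
  excluded <- setdiff(unique(c(mcp_relative$species_id, mpp_relative$species_id)),
                      unique(base_mean$species_id))
  if (is.null(proj) || !nrow(proj)) {
    stopf("no projected species overlap the baseline", class = "fc_accounting_error")
  }
  out <- compute_availability(proj, profiles, portions, species_groups,
                              exclude_reduction = TRUE, conc_col = conc_col,
                              portion_col = portion_col)
  attr(out, "diagnostics") <- list(excluded_species = excluded)
  out
}

## one truncated-at-zero normal draw per row: mean = point, sd = width/3.92
sample_truncnorm <- function(n, mean, sd) {
  sd <- pmax(sd, 0)
  lo <- stats::pnorm(0, mean, sd)
  lo[sd == 0] <- 0
  u <- stats::runif(n)
  x <- stats::qnorm(lo + u * (1 - lo), mean, sd)
  x[sd == 0] <- mean[sd == 0]
  pmax(x, 0)
}

#' Monte Carlo uncertainty bands for a nutrient-availability pipeline
#'
#' Each draw samples one concentration per species-nutrient from a
#' truncated-at-zero normal parameterized by the profile's mean and 95%
#' interval (`sd = width / 3.92`), and one edible portion per functional
#' group uniformly on `[min, max]`; the sampled values are held fixed
#' across all years within the draw. The pipeline closure is re-run per
#' draw and the envelope is the pointwise median and 2.5th / 97.5th
#' percentiles over draws. The default draw count is 1,000.
#'
#' @param pipeline function `(profiles_draw, portions_draw) ->
#'   fc_availability`-like data.frame whose last column is the value.
#' @param profiles nutrient profiles with `point`, `lower`, `upper`.
#' @param portions edible-portion table with `mean`, `min`, `max`.
#' @param draws number of Monte Carlo draws (>= 2; default 1000).
#' @param seed integer seed.
#' @return `fc_envelope` data.frame: the pipeline's key columns plus
#'   `median`, `lo95`, `hi95`; attributes `draws`, `seed`.
#' @export
monte_carlo_bands <- function(pipeline, profiles, portions, draws = 1000,
                              seed = 1) {
  if (!is_count(draws) || draws < 2) {
    stopf("draws must be an integer >= 2", class = "fc_config_error")
  }
  set.seed(child_seed(seed, 53))
  sdz <- (profiles$upper - profiles$lower) / 3.92

  results <- vector("list", draws)
  for (d in seq_len(draws)) {
    prof_d <- profiles
    prof_d$point <- sample_truncnorm(nrow(profiles), profiles$point, sdz)
    port_d <- portions
    port_d$mean <- portions$min + stats::runif(nrow(portions)) *
      (portions$max - portions$min)
    results[[d]] <- pipeline(prof_d, port_d)
  }

  val_col <- names(results[[1]])[ncol(results[[1]])]
  key_cols <- setdiff(names(results[[1]]), val_col)
  ## align all draws on the first draw's keys
  key_of <- function(df) do.call(paste, c(df[key_cols], sep = "\r"))
  k0 <- key_of(results[[1]])
  mat <- vapply(results, function(df) {
    df[[val_col]][match(k0, key_of(df))]
  }, numeric(length(k0)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)

  out <- results[[1]][key_cols]
  out$median <- apply(mat, 1, stats::median)
  out$lo95 <- apply(mat, 1, q_lo)
  out$hi95 <- apply(mat, 1, q_hi)
  rownames(out) <- NULL
  structure(out, draws = draws, seed = seed,
            class = c("fc_envelope", "data.frame"))
}

#' Per-capita nutrient availability and the population-race comparison
#'
#' Divides EEZ-level availability by the coastal population trajectory.
#' The comparison table contrasts, per EEZ, the relative change in
#' availability with the relative change in coastal population between
#' two years: EEZs whose availability change falls short of their
#' population change (`comparison < 0`) sit "above the line" — their
#' per-capita supply declines even if total supply grows.
#'
#' @param availability `fc_availability`-like data.frame with EEZ `region`.
#' @param world an `fc_world` (coastal population trajectories).
#' @param compare_years optional `c(start, end)` years for the
#'   comparison table.
#' @return list with `per_capita` (availability rows plus `population`,
#'   `per_capita_t`) and, when `compare_years` is given, `comparison`
#'   (`eez_id`, `nutrient`, `avail_change`, `pop_change`, `comparison`,
#'   `above_line`).
#' @export
per_capita <- function(availability, world, compare_years = NULL) {
  pop <- world$population
  key <- paste(availability$region, availability$year)
  pk <- paste(pop$eez_id, pop$year)
  p <- pop$population[match(key, pk)]
  if (anyNA(p)) {
    stopf("population trajectory does not cover availability years",
          class = "fc_span_error")
  }
  if (any(p <= 0)) stopf("zero population", class = "fc_division_error")
  pc <- availability
  pc$population <- p
  pc$per_capita_t <- pc$available_t / p

  comparison <- NULL
  if (!is.null(compare_years)) {
    y0 <- compare_years[1]; y1 <- compare_years[2]
    agg <- stats::aggregate(available_t ~ nutrient + region + year,
                            data = availability[availability$year %in% c(y0, y1), ],
                            FUN = sum)
    rows <- list()
    for (nut in unique(agg$nutrient)) {
      for (rg in unique(agg$region)) {
        a0 <- agg$available_t[agg$nutrient == nut & agg$region == rg & agg$year == y0]
        a1 <- agg$available_t[agg$nutrient == nut & agg$region == rg & agg$year == y1]
        if (!length(a0) || !length(a1) || a0 == 0) next
        p0 <- pop$population[pop$eez_id == as.integer(rg) & pop$year == y0]
        p1 <- pop$population[pop$eez_id == as.integer(rg) & pop$year == y1]
        ac <- a1 / a0 - 1
        pcg <- p1 / p0 - 1
        rows[[length(rows) + 1]] <- data.frame(
          eez_id = as.integer(rg), nutrient = nut, avail_change = ac,
          pop_change = pcg, comparison = ac - pcg,
          above_line = (ac - pcg) < -1e-12)  # tolerance keeps parity on-line
      }
    }
    comparison <- do.call(rbind, rows)
  }
  list(per_capita = pc, comparison = comparison)
}

#' Aggregate EEZ-level availability to coarser regions
#'
#' @param availability `fc_availability` with EEZ ids in `region`.
#' @param world an `fc_world`.
#' @param grouping `"global"`, `"tropics"` (tropical vs extra-tropical
#'   by the 23.5 degree centroid rule) or `"income"` (GDP per capita at
#'   or below the median of all EEZs vs above).
#' @return data.frame `nutrient`, `region` (group label), `year`,
#'   `sector`, `available_t`.
#' @export
aggregate_availability <- function(availability, world,
                                   grouping = c("global", "tropics", "income")) {
  grouping <- match.arg(grouping)
  et <- world$eez_table
  lab <- switch(grouping,
    global = rep("global", nrow(et)),
    tropics = ifelse(et$tropical, "tropical", "extratropical"),
    income = ifelse(et$gdp_pc <= stats::median(et$gdp_pc),
                    "lower_income", "upper_income"))
  availability$group <- lab[match(as.integer(availability$region), et$eez_id)]
  agg <- stats::aggregate(available_t ~ nutrient + group + year + sector,
                          data = availability, FUN = sum)
  names(agg)[names(agg) == "group"] <- "region"
  agg[order(agg$nutrient, agg$region, agg$year), ]
}
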