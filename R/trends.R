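#' Linear trend of an availability series
#'
#' Ordinary least squares of availability on year, after normalizing
#' the series to its value at the window start (so the slope reads as a
#' fraction of the start-of-window level per year). Supply separate
#' windows to fit pre/post-breakpoint segments (e.g. a 1990 split); the
#' breakpoint itself is user-supplied, not estimated.
#'
#' @param series data.frame `year`, `value`.
#' @param window optional `c(first, last)` years (default: full span).
#' @return `fc_trend_fit`: `slope` (fraction / yr), `intercept`, `se`
#'   (slope standard error), `p`, `window`, `n`.
#' @export
fit_trend <- function(series, window = NULL) {
  if (is.null(window)) window <- range(series$year)
  s <- series[series$year >= window[1] & series$year <= window[2], ]
  if (nrow(s) < 3) stopf("need >= 3 points in window", class = "fc_fit_error")
  y0 <- s$value[which.min(s$year)]
  if (y0 == 0) stopf("window-start value is zero", class = "fc_fit_error")
  s$norm <- s$value / y0
  fit <- stats::lm(norm ~ year, data = s)
  cf <- summary(fit)$coefficients
  structure(list(slope = unname(cf["year", "Estimate"]),
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 se = unname(cf["year", "Std. Error"]),
                 p = unname(cf["year", "Pr(>|t|)"]),
                 window = window, n = nrow(s)),
            class = "fc_trend_fit")
}

#' Warming-level scaling regression
#'
#' OLS of percent availability change on the global surface air
#' temperature anomaly, pooling years, scenarios and model runs
#' (unweighted). Each point is one annual projection expressed relative
#' to a baseline year (2000 by convention).
#'
#' @param points data.frame `delta_t` (degC), `pct_change` (%).
#' @param scope label carried through (e.g. "global", "lower_income").
#' @param nutrient optional nutrient label.
#' @return `fc_scaling_fit`: `slope` (% per degC), `intercept` (%),
#'   `se`, `p`, `n`, `scope`, `nutrient`.
#' @export
fit_warming_scaling <- function(points, scope = "global", nutrient = NA_character_) {
  if (nrow(points) < 3) stopf("need >= 3 points", class = "fc_fit_error")
  if (diff(range(points$delta_t)) <= 0.5) {
    stopf("degenerate warming spread (<= 0.5 degC)", class = "fc_fit_error")
  }
  fit <- stats::lm(pct_change ~ delta_t, data = points)
  cf <- summary(fit)$coefficients
  structure(list(slope = unname(cf["delta_t", "Estimate"]),
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 se = unname(cf["delta_t", "Std. Error"]),
                 p = unname(cf["delta_t", "Pr(>|t|)"]),
                 n = nrow(points), scope = scope, nutrient = nutrient),
            class = "fc_scaling_fit")
}

#' Build warming-scaling points from an availability series
#'
#' Converts a yearly availability series and the matching warming
#' series into (anomaly, % change vs baseline year) pairs.
#'
#' @param avail data.frame `year`, `available_t` (one nutrient/region).
#' @param delta_t named numeric anomaly by year.
#' @param baseline_year year whose availability defines 0% (default 2000).
#' @return data.frame `delta_t`, `pct_change`, `year`.
#' @export
scaling_points <- function(avail, delta_t, baseline_year = 2000) {
  base <- avail$available_t[avail$year == baseline_year]
  if (!length(base) || base[1] == 0) {
    stopf("baseline year %d missing or zero", baseline_year, class = "fc_fit_error")
  }
  dt <- delta_t[as.character(avail$year)]
  data.frame(delta_t = unname(dt),
             pct_change = 100 * (avail$available_t / base[1] - 1),
             year = avail$year)
}

#' Regional disparity summary at projection horizons
#'
#' Percent change (median and 95% band) of nutrient availability at
#' each horizon year relative to a reference year, for tropical vs
#' extra-tropical EEZ groups and for below- vs above-median GDP per
#' capita groups (ties to the lower-income group), per nutrient plus
#' the unweighted mean across the four nutrients ("pooled").
#'
#' @param envelope `fc_envelope` with EEZ ids in `region` (or a plain
#'   availability data.frame with `available_t`, treated as a zero-width
#'   envelope).
#' @param world an `fc_world`.
#' @param horizon_years years to summarize.
#' @param reference_year baseline year (default 2010).
#' @return data.frame `grouping`, `group`, `nutrient`, `horizon`,
#'   `pct_change`, `pct_lo`, `pct_hi`.
#' @export
disparity_summary <- function(envelope, world, horizon_years,
                              reference_year = 2010) {
  env <- as.data.frame(envelope)
  if (!"median" %in% names(env)) {
    env$median <- env$available_t
    env$lo95 <- env$available_t
    env$hi95 <- env$available_t
  }
  ## collapse sectors if present
  agg_cols <- intersect(c("nutrient", "region", "year"), names(env))
  env <- stats::aggregate(env[c("median", "lo95", "hi95")], by = env[agg_cols],
                          FUN = sum)

  et <- world$eez_table
  groups <- list(
    tropics = list(tropical = et$eez_id[et$tropical],
                   extratropical = et$eez_id[!et$tropical]),
    income = list(lower_income = et$eez_id[et$gdp_pc <= stats::median(et$gdp_pc)],
                  upper_income = et$eez_id[et$gdp_pc > stats::median(et$gdp_pc)])
  )
  rows <- list()
  for (gset in names(groups)) {
    for (g in names(groups[[gset]])) {
      ids <- as.character(groups[[gset]][[g]])
      if (!length(ids)) {
        stopf("empty group '%s' (%s split)", g, gset, class = "fc_grouping_error")
      }
      sub <- env[env$region %in% ids, ]
      if (!nrow(sub)) next  # group exists but carries no availability

      for (nut in unique(sub$nutrient)) {
        sn <- sub[sub$nutrient == nut, ]
        ref <- vapply(c("median", "lo95", "hi95"), function(cl) {
          sum(sn[[cl]][sn$year == reference_year])
        }, numeric(1))
        if (ref[["median"]] == 0) next
        for (h in horizon_years) {
          cur <- vapply(c("median", "lo95", "hi95"), function(cl) {
            sum(sn[[cl]][sn$year == h])
          }, numeric(1))
          rows[[length(rows) + 1]] <- data.frame(
            grouping = gset, group = g, nutrient = nut, horizon = h,
            pct_change = 100 * (cur[["median"]] / ref[["median"]] - 1),
            pct_lo = 100 * (cur[["lo95"]] / ref[["median"]] - 1),
            pct_hi = 100 * (cur[["hi95"]] / ref[["median"]] - 1))
        }
      }
    }
  }
  out <- do.call(rbind, rows)

  ## pooled across nutrients: unweighted mean of the per-nutrient % changes
  pooled <- stats::aggregate(out[c("pct_change", "pct_lo", "pct_hi")],
                             by = out[c("grouping", "group", "horizon")],
                             FUN = mean)
  pooled$nutrient <- "pooled"
  out <- rbind(out, pooled[names(out)])
  rownames(out) <- NULL
  out
}
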