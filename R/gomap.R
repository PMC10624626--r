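#' Spatial filters for mariculture suitability
#'
#' @param max_depth maximum bottom depth (m) for farm siting.
#' @param max_ice maximum tolerated sea-ice fraction.
#' @param hsi_cutoff minimum habitat suitability for a cell to count as
#'   suitable farming area.
#' @return named list.
#' @export
farm_filters <- function(max_depth = 200, max_ice = 0.5, hsi_cutoff = 0.5) {
  list(max_depth = max_depth, max_ice = max_ice, hsi_cutoff = hsi_cutoff)
}

#' Mariculture farm suitability and suitable area per EEZ
#'
#' Scores cells with the same envelope machinery as the catch model's
#' habitat suitability index, then applies the physical and
#' socioeconomic siting filters: bottom depth at most `max_depth`, cell
#' inside an EEZ, sea-ice fraction at most `max_ice`. Suitable area per
#' EEZ is the summed area of cells passing the filters with HSI at or
#' above `hsi_cutoff`.
#'
#' @param species one species row; must be flagged `farmed`.
#' @param forcing_slice field list (needs the species' temperature
#'   field; `ice` used when present).
#' @param world an `fc_world`.
#' @param filters list from [farm_filters()].
#' @return list of class `fc_suitability`: `species_id`, `hsi` (matrix),
#'   `pass` (logical matrix), `area_by_eez` (named, km^2),
#'   `mean_hsi_by_eez` (named, mean HSI over each EEZ's suitable cells).
#' @export
farm_suitability <- function(species, forcing_slice, world,
                             filters = farm_filters()) {
  if (!isTRUE(species$farmed)) {
    stopf("species %s is not farmed", species$species_id, class = "fc_usage_error")
  }
  hsi <- compute_hsi(species, forcing_slice, world)
  pass <- world$depth <= filters$max_depth & !is.na(world$eez)
  if (!is.null(forcing_slice$ice)) pass <- pass & forcing_slice$ice <= filters$max_ice
  suitable <- pass & unclass(hsi) >= filters$hsi_cutoff

  ids <- world$eez_table$eez_id
  area_by_eez <- stats::setNames(vapply(ids, function(k) {
    sum(world$area[suitable & !is.na(world$eez) & world$eez == k])
  }, numeric(1)), ids)
  mean_hsi_by_eez <- stats::setNames(vapply(ids, function(k) {
    sel <- suitable & !is.na(world$eez) & world$eez == k
    if (any(sel)) mean(unclass(hsi)[sel]) else 0
  }, numeric(1)), ids)

  structure(list(species_id = species$species_id, hsi = hsi, pass = pass,
                 area_by_eez = area_by_eez, mean_hsi_by_eez = mean_hsi_by_eez),
            class = "fc_suitability")
}

#' Mean-reverting farm-gate price forecast
#'
#' First-order autoregressive surrogate for the price forecaster: fits
#' `x_t - mu = phi (x_(t-1) - mu) + eps` by least squares on the
#' history, then iterates the point forecast forward from the last
#' observed price. Forecasts are clamped at zero; a constant history
#' yields a flat forecast.
#'
#' @param history numeric price series (length >= 3, non-negative).
#' @param horizon number of years to forecast.
#' @return list of class `fc_price_forecast`: `forecast` (numeric,
#'   length `horizon`), `phi`, `mu`.
#' @export
forecast_price <- function(history, horizon) {
  if (length(history) < 3) {
    stopf("price history needs >= 3 points, got %d", length(history),
          class = "fc_data_error")
  }
  mu <- mean(history)
  x <- history - mu
  denom <- sum(x[-length(x)]^2)
  phi <- if (denom > 0) sum(x[-1] * x[-length(x)]) / denom else 0
  phi <- clamp(phi, -0.98, 0.98)
  fc <- numeric(horizon)
  last <- history[length(history)] - mu
  for (h in seq_len(horizon)) {
    last <- phi * last
    fc[h] <- max(mu + last, 0)
  }
  structure(list(forecast = fc, phi = phi, mu = mu), class = "fc_price_forecast")
}

#' Fishmeal demand and crude-protein index for a farmed species
#'
#' Feed-formulation step: fishmeal demand is
#' `production x FCR x inclusion x meal_yield` for feed-requiring
#' species (fed finfish and crustaceans) and zero otherwise (bivalves
#' and other unfed groups). The forage-fish usage fraction applied to
#' projections is the arithmetic mean of the 2010-2014 usage fractions.
#' The crude-protein index is a dimensionless supply-vs-demand summary,
#' `supply_protein / (supply_protein + demand_protein)` in `[0, 1]` — a
#' documented stand-in (the index has no published formula) that is
#' monotone increasing in forage supply for fixed demand and equals 1
#' for unfed species.
#'
#' @param species one species row (`feed_requiring` flag).
#' @param production production to feed (t).
#' @param forage_catch_history data.frame `year`, `tonnes` (forage catch
#'   to reduction), `usage_fraction`; must cover 2010-2014.
#' @param fcr feed conversion ratio (> 0).
#' @param inclusion fishmeal inclusion fraction in the feed, `[0, 1]`.
#' @param meal_yield fishmeal yield conversion (default 1).
#' @param feed_protein protein content of fishmeal (fraction).
#' @return list of class `fc_feed`: `species_id`, `fishmeal_demand_t`,
#'   `crude_protein_index`, `forage_usage_fraction`, `index_is_standin`.
#' @export
feed_requirements <- function(species, production, forage_catch_history,
                              fcr = 1.5, inclusion = 0.3, meal_yield = 1,
                              feed_protein = 0.65) {
  stopifnot(fcr > 0, inclusion >= 0, inclusion <= 1)
  ref_years <- 2010:2014
  if (!all(ref_years %in% forage_catch_history$year)) {
    stopf("forage catch history must cover 2010-2014", class = "fc_span_error")
  }
  recent <- forage_catch_history[forage_catch_history$year %in% ref_years, ]
  usage <- mean(recent$usage_fraction)

  demand <- if (isTRUE(species$feed_requiring)) {
    production * fcr * inclusion * meal_yield
  } else 0
  supply <- mean(recent$tonnes) * usage * meal_yield
  s_prot <- supply * feed_protein
  d_prot <- demand * feed_protein
  cpi <- if (s_prot + d_prot > 0) s_prot / (s_prot + d_prot) else 1

  structure(list(species_id = species$species_id, fishmeal_demand_t = demand,
                 crude_protein_index = cpi, forage_usage_fraction = usage,
                 index_is_standin = TRUE),
            class = "fc_feed")
}

#' Fit the empirical mariculture-production model
#'
#' Penalized spline additive regression (via [mgcv::gam()]) of observed
#' mariculture production on the four suitability-economics predictors:
#' suitable area, farm-gate price, HSI and crude-protein index.
#' Constant predictors are dropped with a warning; predictions are
#' clipped at zero.
#'
#' @param training data.frame with columns `area`, `price`, `hsi`,
#'   `protein_index`, `production` (>= 20 rows).
#' @return `fc_mpp_model`: list with the `gam` fit, `terms_used`,
#'   `dropped`, `sigma2` (residual variance), `edf`, `ranges`
#'   (training hull per predictor).
#' @export
fit_mpp_model <- function(training) {
  need <- c("area", "price", "hsi", "protein_index", "production")
  if (!all(need %in% names(training))) {
    stopf("training table needs columns: %s", paste(need, collapse = ", "),
          class = "fc_fit_error")
  }
  if (nrow(training) < 20) {
    stopf("need >= 20 training rows, got %d", nrow(training),
          class = "fc_fit_error")
  }
  preds <- c("area", "price", "hsi", "protein_index")
  const <- preds[vapply(preds, function(p) {
    s <- stats::sd(training[[p]])
    s == 0 || s < 1e-10 * max(abs(training[[p]]), 1)
  }, logical(1))]
  if (length(const)) {
    warnf("dropping constant predictor(s): %s", paste(const, collapse = ", "))
  }
  used <- setdiff(preds, const)
  if (!length(used)) stopf("all predictors constant", class = "fc_fit_error")

  terms <- vapply(used, function(p) {
    k <- min(10, length(unique(training[[p]])) - 1)
    if (k >= 3) sprintf("s(%s, k = %d)", p, k) else p
  }, character(1))
  form <- stats::as.formula(paste("production ~", paste(terms, collapse = " + ")))
  fit <- if (stats::sd(training$production) == 0) {
    ## degenerate response: smoothing has nothing to do, fall back to
    ## the unpenalized additive fit (an exact constant)
    mgcv::gam(production ~ 1, data = training)
  } else {
    tryCatch(
      mgcv::gam(form, data = training, method = "REML"),
      error = function(e) {
        ## near-singular smooths (clustered designs at small scale):
        ## fall back to the linear additive fit
        lin <- stats::as.formula(paste("production ~",
                                       paste(used, collapse = " + ")))
        mgcv::gam(lin, data = training)
      })
  }

  structure(list(fit = fit, terms_used = used, dropped = const,
                 sigma2 = fit$sig2, edf = sum(fit$edf),
                 ranges = lapply(training[used], range)),
            class = "fc_mpp_model")
}

#' Predict from a fitted mariculture-production model
#'
#' @param object an `fc_mpp_model`.
#' @param newdata data.frame with the predictor columns.
#' @param ... unused.
#' @return numeric predictions, clipped at zero; attribute
#'   `extrapolated` flags rows with any predictor outside the training
#'   hull.
#' @export
predict.fc_mpp_model <- function(object, newdata, ...) {
  p <- as.numeric(mgcv::predict.gam(object$fit, newdata = newdata))
  extrap <- rep(FALSE, nrow(newdata))
  for (v in object$terms_used) {
    rg <- object$ranges[[v]]
    extrap <- extrap | newdata[[v]] < rg[1] | newdata[[v]] > rg[2]
  }
  structure(pmax(p, 0), extrapolated = extrap)
}

#' Serialize a fitted mariculture-production model to JSON
#'
#' Stores coefficients, smoothing parameters and training hull — enough
#' to audit a fit (not to re-predict without refitting).
#'
#' @param model an `fc_mpp_model`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
mpp_model_to_json <- function(model, path) {
  jsonlite::write_json(list(
    terms_used = model$terms_used, dropped = model$dropped,
    coefficients = as.list(stats::coef(model$fit)),
    smoothing = as.list(model$fit$sp), sigma2 = model$sigma2,
    edf = model$edf, ranges = model$ranges
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Project mariculture production potential per EEZ and year
#'
#' Drives the fitted empirical model with year-varying farm suitability
#' (area and HSI recomputed from each year's forcing), the price
#' forecast and the crude-protein index series. Production potential is
#' zero wherever suitable area is zero; rows whose predictors fall
#' outside the training hull are flagged in the diagnostics but still
#' returned.
#'
#' @param model an `fc_mpp_model`.
#' @param species one species row (farmed).
#' @param forcing an `fc_forcing`.
#' @param world an `fc_world`.
#' @param price_forecast numeric vector of prices, one per projection year.
#' @param feed_series numeric crude-protein index, one per year (or one
#'   scalar, recycled).
#' @param years projection years (default: forcing years).
#' @param filters list from [farm_filters()].
#' @param eez_ids EEZs to project (default: all; pass the EEZs with
#'   established production to honour the established-producers rule).
#' @return `fc_mpp`: data.frame `species_id`, `eez_id`, `year`, `mpp_t`
#'   with attribute `diagnostics` (extrapolation flags).
#' @export
project_mpp <- function(model, species, forcing, world, price_forecast,
                        feed_series, years = forcing$years,
                        filters = farm_filters(),
                        eez_ids = world$eez_table$eez_id) {
  ny <- length(years)
  if (length(price_forecast) == 1) price_forecast <- rep(price_forecast, ny)
  if (length(feed_series) == 1) feed_series <- rep(feed_series, ny)
  if (length(price_forecast) < ny || length(feed_series) < ny) {
    stopf("price/feed series shorter than projection years", class = "fc_span_error")
  }
  rows <- vector("list", ny)
  for (t in seq_len(ny)) {
    sl <- forcing_slice(forcing, years[t])
    suit <- farm_suitability(species, sl, world, filters)
    rows[[t]] <- data.frame(
      species_id = species$species_id, eez_id = eez_ids, year = years[t],
      area = unname(suit$area_by_eez[as.character(eez_ids)]),
      hsi = unname(suit$mean_hsi_by_eez[as.character(eez_ids)]),
      price = price_forecast[t], protein_index = feed_series[t])
  }
  df <- do.call(rbind, rows)
  pred <- predict(model, df)
  df$mpp_t <- ifelse(df$area <= 0, 0, as.numeric(pred))
  out <- df[, c("species_id", "eez_id", "year", "mpp_t")]
  attr(out, "diagnostics") <- list(extrapolated = attr(pred, "extrapolated"),
                                   n_extrapolated = sum(attr(pred, "extrapolated")))
  class(out) <- c("fc_mpp", "data.frame")
  out
}
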