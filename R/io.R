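## Forcing serialization.
##
## Gridded forcing is stored as a plain-text bundle: a long-format CSV
## (year, lat, lon, one column per field) plus a JSON sidecar holding
## the scenario label, seed, grid definition, yearly global anomaly and
## generator config. The layout mirrors CF conventions (time/lat/lon
## dimensions, one variable per field) in text form; no binary NetCDF
## library is required at run time.

forcing_required_fields <- c("sst", "sbt", "npp", "sal", "ice", "u", "v")

#' Write / read a climate forcing bundle
#'
#' `write_forcing()` creates `fields.csv` and `meta.json` under `path`;
#' `read_forcing()` restores an `fc_forcing` from them. Round-trips
#' preserve values to storage precision (15 significant digits) and all
#' metadata (scenario, seed, warming series, config).
#'
#' @param forcing an `fc_forcing`.
#' @param path directory for the bundle (created if needed).
#' @return `write_forcing` returns `path` invisibly; `read_forcing`
#'   returns the `fc_forcing`.
#' @export
write_forcing <- function(forcing, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nlat <- dim(forcing$fields$sst)[1]
  nlon <- dim(forcing$fields$sst)[2]
  ny <- length(forcing$years)
  ## expand.grid varies the first factor fastest, matching column-major
  ## array order, so field columns are plain as.vector() dumps
  grid <- expand.grid(ilat = seq_len(nlat), ilon = seq_len(nlon),
                      iyear = seq_len(ny))
  df <- data.frame(year = forcing$years[grid$iyear],
                   lat = grid$ilat, lon = grid$ilon)
  for (nm in forcing_required_fields) {
    df[[nm]] <- as.vector(forcing$fields[[nm]])
  }
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   file.path(path, "fields.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(list(scenario = forcing$scenario, seed = forcing$seed,
                            years = forcing$years, nlat = nlat, nlon = nlon,
                            delta_t = as.list(forcing$delta_t),
                            config = forcing$config),
                       file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_forcing
#' @export
read_forcing <- function(path) {
  fcsv <- file.path(path, "fields.csv")
  fmeta <- file.path(path, "meta.json")
  if (!file.exists(fcsv) || !file.exists(fmeta)) {
    stopf("forcing bundle incomplete at %s", path, class = "fc_format_error")
  }
  df <- utils::read.csv(fcsv)
  for (nm in forcing_required_fields) {
    if (!nm %in% names(df)) {
      stopf("forcing bundle missing variable '%s'", nm, class = "fc_format_error")
    }
  }
  meta <- jsonlite::read_json(fmeta, simplifyVector = TRUE)
  nlat <- meta$nlat; nlon <- meta$nlon
  years <- as.integer(meta$years)
  ny <- length(years)
  if (nrow(df) != nlat * nlon * ny) {
    stopf("forcing bundle dimension mismatch (time axis length %d expected)",
          ny, class = "fc_format_error")
  }
  ord <- order(match(df$year, years), df$lon, df$lat)  # back to array order
  df <- df[ord, ]
  fields <- lapply(forcing_required_fields, function(nm) {
    a <- array(df[[nm]], dim = c(nlat, nlon, ny))
    dimnames(a) <- list(NULL, NULL, years)
    a
  })
  names(fields) <- forcing_required_fields
  delta_t <- unlist(meta$delta_t)
  structure(list(years = years, delta_t = delta_t, fields = fields,
                 scenario = meta$scenario, seed = meta$seed,
                 config = meta$config),
            class = "fc_forcing")
}

## deterministic CSV writer (fixed numeric formatting, no quoting games)
write_table_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (nm in names(df)[num]) {
    df[[nm]] <- format(df[[nm]], digits = 15, trim = TRUE, scientific = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
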