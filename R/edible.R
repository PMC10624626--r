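#' Default edible-portion table by functional group
#'
#' Edible fraction of live weight (mean, min, max), grouped by
#' functional group. Anchors: molluscs excluding cephalopods (bivalves,
#' gastropods) average 28% edible and crustaceans 56%, while finfish
#' span 33-92%; cephalopods are almost fully edible and sit well above
#' the other molluscs. Finfish groups share one row; the mean (60%) is
#' a mid-range fillet-plus yield.
#'
#' @return data.frame: `functional_group`, `mean`, `min`, `max`.
#' @export
default_edible_portions <- function() {
  fin <- c(mean = 0.60, min = 0.33, max = 0.92)
  rows <- list(
    small_pelagic = fin, large_pelagic = fin, demersal = fin, benthopelagic = fin,
    bivalve = c(mean = 0.28, min = 0.15, max = 0.45),
    gastropod = c(mean = 0.28, min = 0.15, max = 0.45),
    cephalopod = c(mean = 0.70, min = 0.50, max = 0.85),
    crustacean = c(mean = 0.56, min = 0.35, max = 0.70)
  )
  out <- data.frame(functional_group = names(rows),
                    mean = vapply(rows, `[[`, numeric(1), "mean"),
                    min = vapply(rows, `[[`, numeric(1), "min"),
                    max = vapply(rows, `[[`, numeric(1), "max"))
  rownames(out) <- NULL
  out
}

#' Look up the edible portion for a functional group
#'
#' Accepts functional group names from the species pool and
#' `finfish`-prefixed aliases (`"finfish"`, `"finfish_demersal"`, ...),
#' which all resolve to the shared finfish row.
#'
#' @param functional_group group name.
#' @param table portion table (default [default_edible_portions()]).
#' @return list with `functional_group`, `mean`, `min`, `max`.
#' @export
lookup_edible_portion <- function(functional_group,
                                  table = default_edible_portions()) {
  key <- functional_group
  if (!key %in% table$functional_group && grepl("^finfish", key)) {
    key <- "demersal"  # any finfish alias -> shared finfish row
  }
  i <- match(key, table$functional_group)
  if (is.na(i)) {
    stopf("unknown functional group '%s'", functional_group,
          class = "fc_lookup_error")
  }
  list(functional_group = functional_group,
       mean = table$mean[i], min = table$min[i], max = table$max[i])
}
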