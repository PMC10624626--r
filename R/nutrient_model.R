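## Hierarchical taxonomic nutrient-content estimation.
##
## Level means are computed on the concentration scale as means-of-means
## going up the taxonomy (a family mean is the unweighted mean of its
## observed genus means, etc.), matching the descending-priority
## taxonomic fallback used for invertebrates. Variance components come
## from a method-of-moments decomposition and drive both the shrinkage
## weight for species with their own data and the widths of prediction
## intervals (symmetric normal, zero-floored with an upward shift so
## interval width is a monotone function of the variance ladder).

taxo_levels <- c("species", "genus", "family", "order", "class")

#' Fit the hierarchical taxonomic nutrient model
#'
#' For each nutrient, computes observation means at every taxonomic
#' level present (species up to class, plus a pooled grand mean) on the
#' concentration scale, and method-of-moments variance components
#' (residual, species-, genus-, family-, order- and class-level).
#' These are the ingredients for shrinkage prediction and taxonomic
#' fallback in [predict_nutrient_content()].
#'
#' @param observations data.frame with `species_id`, `nutrient`,
#'   `concentration` (>= 0).
#' @param taxonomy data.frame with `species_id`, `class`, `order`,
#'   `family`, `genus` covering at least all observed species.
#' @return `fc_nutrient_model`: per nutrient, the level means, per-level
#'   observation counts, variance components (`sigma2_e`, `sigma2_species`,
#'   `sigma2_genus`, `sigma2_family`, `sigma2_order`, `sigma2_class`),
#'   plus the taxonomy and flags. Serializable with
#'   [nutrient_model_to_json()].
#' @export
fit_hierarchical_nutrients <- function(observations, taxonomy) {
  if (is.null(observations) || nrow(observations) == 0) {
    stopf("empty observation table", class = "fc_fit_error")
  }
  taxonomy <- if (!is.data.frame(taxonomy)) taxonomy$species else taxonomy
  missing_tax <- setdiff(unique(observations$species_id), taxonomy$species_id)
  if (length(missing_tax)) {
    stopf("observed species missing from taxonomy: %s",
          paste(missing_tax, collapse = ", "), class = "fc_fit_error")
  }

  fits <- list()
  for (nut in unique(observations$nutrient)) {
    o <- observations[observations$nutrient == nut, , drop = FALSE]
    o$z <- o$concentration
    o <- merge(o, taxonomy[, c("species_id", "class", "order", "family", "genus")],
               by = "species_id")

    ## species-level summaries
    sp_mean <- c(tapply(o$z, o$species_id, mean))
    sp_n <- c(tapply(o$z, o$species_id, length))
    sp_var <- c(tapply(o$z, o$species_id, function(x) {
      if (length(x) >= 2) stats::var(x) else NA_real_
    }))
    tax <- taxonomy[match(names(sp_mean), taxonomy$species_id), ]

    ## means-of-means up the hierarchy
    up_mean <- function(child_means, parent_of_child) {
      c(tapply(child_means, parent_of_child, mean))
    }
    gen_mean <- up_mean(sp_mean, tax$genus)
    gen_parent <- tax$family[match(names(gen_mean), tax$genus)]
    fam_mean <- up_mean(gen_mean, gen_parent)
    fam_parent <- tax$order[match(names(fam_mean), tax$family)]
    ord_mean <- up_mean(fam_mean, fam_parent)
    ord_parent <- tax$class[match(names(ord_mean), tax$order)]
    cls_mean <- up_mean(ord_mean, ord_parent)
    pooled <- mean(cls_mean)

    ## observation counts under each taxon (for sampling variances)
    n_under <- function(group_of_species) {
      c(tapply(sp_n, group_of_species, sum))
    }
    n_gen <- n_under(tax$genus); n_fam <- n_under(tax$family)
    n_ord <- n_under(tax$order); n_cls <- n_under(tax$class)

    ## method-of-moments variance components (clamped at zero)
    sigma2_e <- {
      v <- sp_var[!is.na(sp_var)]
      if (length(v)) mean(v) else 0
    }
    comp_between <- function(child_means, parent_of_child, child_sampling_var) {
      ## average within-parent variance of child means, minus the mean
      ## sampling variance of a child mean
      split_means <- split(unname(child_means), parent_of_child)
      vs <- vapply(split_means, function(x) {
        if (length(x) >= 2) stats::var(x) else NA_real_
      }, numeric(1))
      vs <- vs[!is.na(vs)]
      if (!length(vs)) return(0)
      max(0, mean(vs) - mean(child_sampling_var))
    }
    samp_sp <- sigma2_e / unname(sp_n)
    sigma2_species <- comp_between(sp_mean, tax$genus, samp_sp)
    samp_gen <- sigma2_species + sigma2_e / unname(n_gen)[match(names(gen_mean), names(n_gen))]
    sigma2_genus <- comp_between(gen_mean, gen_parent, samp_gen)
    samp_fam <- sigma2_genus + sigma2_species +
      sigma2_e / unname(n_fam)[match(names(fam_mean), names(n_fam))]
    sigma2_family <- comp_between(fam_mean, fam_parent, samp_fam)
    samp_ord <- sigma2_family + sigma2_genus + sigma2_species +
      sigma2_e / unname(n_ord)[match(names(ord_mean), names(n_ord))]
    sigma2_order <- comp_between(ord_mean, ord_parent, samp_ord)
    sigma2_class <- if (length(cls_mean) >= 2) {
      max(0, stats::var(unname(cls_mean)))
    } else 0

    fits[[nut]] <- list(
      means = list(species = sp_mean, genus = gen_mean, family = fam_mean,
                   order = ord_mean, class = cls_mean, pooled = pooled),
      n_obs = list(species = sp_n, genus = n_gen, family = n_fam,
                   order = n_ord, class = n_cls, pooled = sum(sp_n)),
      varcomp = c(sigma2_e = unname(sigma2_e),
                  sigma2_species = sigma2_species, sigma2_genus = sigma2_genus,
                  sigma2_family = sigma2_family, sigma2_order = sigma2_order,
                  sigma2_class = sigma2_class),
      single_observation = sum(sp_n) == 1
    )
  }

  structure(list(fits = fits, taxonomy = taxonomy,
                 nutrients = names(fits),
                 ## fallback interval sd (z-scale) when all components are zero
                 default_sd = 1.0),
            class = "fc_nutrient_model")
}

## variance floor used inside shrinkage weights only (reported components
## keep their raw, possibly zero, values)
.var_floor <- 1e-8

## cumulative prediction variance at each provenance level, monotone
## non-decreasing from species to pooled
provenance_variances <- function(fit, n_at_level) {
  vc <- fit$varcomp
  below <- c(species = 0,
             genus = vc[["sigma2_species"]],
             family = vc[["sigma2_species"]] + vc[["sigma2_genus"]],
             order = vc[["sigma2_species"]] + vc[["sigma2_genus"]] +
               vc[["sigma2_family"]],
             class = vc[["sigma2_species"]] + vc[["sigma2_genus"]] +
               vc[["sigma2_family"]] + vc[["sigma2_order"]],
             pooled = vc[["sigma2_species"]] + vc[["sigma2_genus"]] +
               vc[["sigma2_family"]] + vc[["sigma2_order"]] + vc[["sigma2_class"]])
  v <- below + vc[["sigma2_e"]] / pmax(n_at_level, 1)
  cummax(v)  # interval never narrows as provenance coarsens
}

#' Predict nutrient content for one species
#'
#' Uses the lowest taxonomic level with data, in descending order of
#' priority (species > genus > family > order > class > pooled). A
#' species with its own observations gets a shrinkage estimate between
#' its observation mean and its parent-level mean (weight
#' `n / (n + sigma2_e / sigma2_species)`); a species without
#' observations gets its nearest observed ancestor's mean exactly. 95%
#' intervals are symmetric normal on the concentration scale, floored
#' at zero with an upward shift that preserves the width; interval
#' width is non-decreasing as the provenance level coarsens. Farmed
#' species inherit wild values unchanged.
#'
#' @param model an `fc_nutrient_model`.
#' @param species one row of a species table (needs `species_id`,
#'   `genus`, `family`, `order`, `class`).
#' @return data.frame, one row per nutrient: `species_id`, `nutrient`,
#'   `point`, `lower`, `upper` (concentration scale), `provenance`.
#' @export
predict_nutrient_content <- function(model, species) {
  stopifnot(inherits(model, "fc_nutrient_model"))
  sp <- as.list(species[1, ])
  lineage <- c(species = sp$species_id, genus = sp$genus, family = sp$family,
               order = sp$order, class = sp$class)

  out <- lapply(model$nutrients, function(nut) {
    fit <- model$fits[[nut]]
    ## provenance: lowest level with data
    prov <- "pooled"
    for (lv in taxo_levels) {
      if (lineage[[lv]] %in% names(fit$means[[lv]])) { prov <- lv; break }
    }
    n_lv <- vapply(taxo_levels, function(lv) {
      nn <- fit$n_obs[[lv]][lineage[[lv]]]
      if (is.na(nn)) 0 else as.numeric(nn)
    }, numeric(1))
    n_lv <- c(n_lv, pooled = as.numeric(fit$n_obs$pooled))
    vars <- provenance_variances(fit, n_lv)

    if (prov == "species") {
      n <- n_lv[["species"]]
      ybar <- unname(fit$means$species[lineage[["species"]]])
      ## nearest observed ancestor mean as the shrinkage target
      parent <- unname(fit$means$pooled)
      for (lv in taxo_levels[-1]) {
        if (lineage[[lv]] %in% names(fit$means[[lv]])) {
          parent <- unname(fit$means[[lv]][lineage[[lv]]]); break
        }
      }
      lambda <- fit$varcomp[["sigma2_e"]] /
        max(fit$varcomp[["sigma2_species"]], .var_floor)
      w <- n / (n + max(lambda, .var_floor))
      z <- w * ybar + (1 - w) * parent
      sd_z <- sqrt(1 / (n / max(fit$varcomp[["sigma2_e"]], .var_floor) +
                        1 / max(fit$varcomp[["sigma2_species"]], .var_floor)))
      sd_z <- min(sd_z, sqrt(vars[["species"]] + .var_floor))
    } else {
      z <- if (prov == "pooled") unname(fit$means$pooled)
           else unname(fit$means[[prov]][lineage[[prov]]])
      sd_z <- sqrt(vars[[prov]])
    }
    if (sd_z == 0 && fit$single_observation) sd_z <- model$default_sd

    ## interval: symmetric normal on the concentration scale; when the
    ## lower bound would fall below zero it is floored at zero and the
    ## interval shifted up, so the width 2 * 1.96 * sd is preserved and
    ## widths stay monotone as provenance coarsens
    point <- max(z, 0)
    half <- 1.96 * sd_z
    lower <- point - half
    upper <- point + half
    if (lower < 0) {
      upper <- upper - lower
      lower <- 0
    }
    data.frame(species_id = sp$species_id, nutrient = nut,
               point = point, lower = lower, upper = upper, provenance = prov)
  })
  do.call(rbind, out)
}

#' Predict nutrient profiles for a whole species table
#'
#' @param model an `fc_nutrient_model`.
#' @param species_table species data.frame (one row per species).
#' @return stacked data.frame of [predict_nutrient_content()] rows.
#' @export
predict_nutrient_profiles <- function(model, species_table) {
  out <- do.call(rbind, lapply(seq_len(nrow(species_table)), function(i) {
    predict_nutrient_content(model, species_table[i, ])
  }))
  rownames(out) <- NULL
  out
}

#' Serialize / restore a fitted nutrient model as JSON
#'
#' @param model an `fc_nutrient_model`.
#' @param path file path.
#' @return `nutrient_model_to_json` invisibly returns `path`;
#'   `nutrient_model_from_json` returns the restored model.
#' @export
nutrient_model_to_json <- function(model, path) {
  ser <- list(nutrients = model$nutrients, default_sd = model$default_sd,
              taxonomy = model$taxonomy[, c("species_id", "class", "order",
                                            "family", "genus")],
              fits = lapply(model$fits, function(f) {
                list(means = lapply(f$means, function(m) as.list(m)),
                     n_obs = lapply(f$n_obs, function(m) as.list(m)),
                     varcomp = as.list(f$varcomp),
                     single_observation = f$single_observation)
              }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname nutrient_model_to_json
#' @export
nutrient_model_from_json <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  fits <- lapply(ser$fits, function(f) {
    list(means = lapply(f$means, function(m) unlist(m)),
         n_obs = lapply(f$n_obs, function(m) unlist(m)),
         varcomp = unlist(f$varcomp),
         single_observation = isTRUE(f$single_observation))
  })
  tax <- do.call(rbind, lapply(ser$taxonomy, function(r) as.data.frame(r)))
  structure(list(fits = fits, taxonomy = tax, nutrients = unlist(ser$nutrients),
                 default_sd = ser$default_sd),
            class = "fc_nutrient_model")
}
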