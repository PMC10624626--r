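Package: fishcast
Title: Climate-Driven Projections of Seafood Nutrient Availability
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale integrated climate-fisheries-mariculture-nutrient
    projection pipeline. Couples a gridded dynamic bioclimate envelope model
    of exploited marine species (habitat suitability, advection-diffusion-
    reaction population dynamics, maximum catch potential under F = M) with a
    mariculture production-potential model (farm suitability, price
    forecasting, feed formulation, empirical production relationship),
    hierarchical taxonomic estimation of seafood nutrient content with
    edible-portion accounting, Monte Carlo uncertainty propagation of
    nutrient availability by region, and warming-level scaling statistics.
    A synthetic-world generator with known ground truth drives every stage,
    so the full pipeline runs offline with recoverable parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
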