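## shared fixtures, all built in code

tiny_world <- function(n_eez = 4, rows = 9, cols = 18, seed = 1) {
  generate_world(n_eez, c(rows, cols), seed = seed)
}

## a single-row species table with overridable traits
test_species <- function(...) {
  sp <- data.frame(
    species_id = "tsp1", class = "Actinopterygii", order = "OrdT",
    family = "FamT", genus = "GenT", species = "gent_tsp1",
    functional_group = "small_pelagic", habitat = "pelagic",
    depth_min = 0, depth_max = 1e4, lat_min = -90, lat_max = 90,
    tol_min = 10, tol_max = 30, pref_min = 15, pref_max = 25,
    winf_g = 1000, k_growth = 0.3, m_nat = 0.2, r_intr = 0.5,
    b0_t = 100, farmed = TRUE, feed_requiring = TRUE,
    stringsAsFactors = FALSE)
  ov <- list(...)
  for (nm in names(ov)) sp[[nm]] <- ov[[nm]]
  sp
}

## a spatially uniform forcing slice on a world's grid
uniform_slice <- function(world, sst = 20, sbt = 16, npp = 1, ice = 0,
                          sal = 34, u = 0, v = 0) {
  m <- function(x) matrix(x, length(world$lat), length(world$lon))
  list(sst = m(sst), sbt = m(sbt), npp = m(npp), ice = m(ice), sal = m(sal),
       u = m(u), v = m(v), year = NA_integer_, delta_t = 0)
}

## a hand-built stationary forcing object (identical fields every year)
const_forcing <- function(world, slice, years, scenario = "climatology",
                          delta_t = rep(0, length(years))) {
  nlat <- length(world$lat); nlon <- length(world$lon); ny <- length(years)
  fields <- lapply(slice[c("sst", "sbt", "npp", "sal", "ice", "u", "v")],
                   function(mm) {
                     a <- array(rep(mm, ny), dim = c(nlat, nlon, ny))
                     dimnames(a) <- list(NULL, NULL, years)
                     a
                   })
  structure(list(years = years, delta_t = stats::setNames(delta_t, years),
                 fields = fields, scenario = scenario, seed = 0,
                 config = forcing_config()),
            class = "fc_forcing")
}

## small observation table + taxonomy for nutrient-model unit tests
toy_taxonomy <- function() {
  data.frame(
    species_id = c("a1", "a2", "b1", "b2", "c1", "inv1"),
    class = c(rep("Actinopterygii", 5), "Bivalvia"),
    order = c(rep("Ord1", 5), "OrdB"),
    family = c(rep("Fam1", 4), "Fam2", "FamB"),
    genus = c("GenA", "GenA", "GenB", "GenB", "GenC", "GenInv"),
    stringsAsFactors = FALSE)
}

toy_observations <- function(values) {
  ## values: named list species_id -> numeric vector of calcium obs
  do.call(rbind, lapply(names(values), function(sp) {
    data.frame(species_id = sp, nutrient = "calcium",
               concentration = values[[sp]],
               study_id = seq_along(values[[sp]]))
  }))
}
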