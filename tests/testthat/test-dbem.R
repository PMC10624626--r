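test_that("HSI follows the trapezoid-geometric-mean rule", {
  w <- tiny_world()
  sp <- test_species()  # tol 10-30, pref 15-25, pelagic

  ## everything hotter than tolerance max -> no habitat anywhere
  hot <- uniform_slice(w, sst = 35)
  expect_true(all(compute_hsi(sp, hot, w) == 0))

  ## preferred mid-range, no ice, full lat/depth range -> HSI 1
  mid <- uniform_slice(w, sst = 20)
  expect_true(all(compute_hsi(sp, mid, w) == 1))

  ## temperature membership 0.5, ice membership 1 -> sqrt(0.5)
  half <- uniform_slice(w, sst = 12.5)
  expect_equal(unique(as.vector(compute_hsi(sp, half, w))), sqrt(0.5),
               tolerance = 1e-12)

  ## latitudinal range filter zeroes outside cells
  banded <- test_species(lat_min = -20, lat_max = 20)
  h <- compute_hsi(banded, mid, w)
  latm <- outer(w$lat, rep(1, length(w$lon)))
  expect_true(all(h[abs(latm) > 20] == 0))

  ## demersal species needs sbt
  dem <- test_species(habitat = "demersal")
  no_sbt <- mid; no_sbt$sbt <- NULL
  err <- tryCatch(compute_hsi(dem, no_sbt, w), error = identity)
  expect_s3_class(err, "fc_forcing_error")
  expect_match(conditionMessage(err), "sbt")
})

test_that("carrying capacity preserves B0 under the share rule", {
  sp <- test_species(b0_t = 100)
  hsi <- structure(matrix(1, 2, 2), class = c("fc_hsi", "matrix", "array"))
  npp <- matrix(1, 2, 2)
  kc <- carrying_capacity(sp, hsi, npp)
  expect_equal(as.vector(kc), rep(25, 4))

  ## zero HSI -> zero capacity in that cell; total still B0
  hsi2 <- structure(matrix(c(0, 1, 0.4, 0.8), 2, 2),
                    class = c("fc_hsi", "matrix", "array"))
  npp2 <- matrix(c(2, 1, 0.5, 3), 2, 2)
  kc2 <- carrying_capacity(sp, hsi2, npp2)
  expect_equal(kc2[1, 1], 0)
  expect_equal(sum(kc2), 100, tolerance = 1e-9)

  ## arbitrary random grids: summation oracle
  set.seed(5)
  for (i in 1:5) {
    h <- structure(matrix(runif(30), 5, 6), class = c("fc_hsi", "matrix", "array"))
    n <- matrix(runif(30, 0, 2), 5, 6)
    expect_equal(sum(carrying_capacity(sp, h, n)), 100, tolerance = 1e-9)
  }

  expect_warning(kc0 <- carrying_capacity(sp, hsi2 * 0, npp2), "no habitat")
  expect_true(all(kc0 == 0))
  expect_true(attr(kc0, "no_habitat"))
})

test_that("single-cell step matches the discrete logistic exactly", {
  sp <- test_species(r_intr = 0.5)
  state <- list(biomass = matrix(50, 1, 1), weight = matrix(500, 1, 1), time = 0)
  kc <- matrix(100, 1, 1)
  sl <- list(sst = matrix(20, 1, 1))
  p <- dbem_params(D = 0, larval_D = 0, dt = 0.25)
  s2 <- step_population(state, sp, sl, p, fishing_mortality = 0, kc = kc)
  expect_equal(s2$biomass[1, 1], 50 + 0.25 * 0.5 * 50 * (1 - 50 / 100),
               tolerance = 1e-14)

  ## at capacity with no transport and no fishing: fixed point
  st_cap <- list(biomass = matrix(100, 1, 1), weight = matrix(500, 1, 1), time = 0)
  s3 <- step_population(st_cap, sp, sl, p, fishing_mortality = 0, kc = kc)
  expect_equal(s3$biomass[1, 1], 100, tolerance = 1e-14)
})

test_that("transport conserves biomass and the stability bound is enforced", {
  set.seed(11)
  sp <- test_species(r_intr = 0)  # reaction off
  n <- 12
  B <- matrix(runif(n * n, 0, 10), n, n)
  kc <- matrix(1, n, n)
  sl <- list(sst = matrix(20, n, n),
             u = matrix(0.4 * sin(seq_len(n)), n, n),
             v = matrix(0.3 * cos(seq_len(n)), n, n, byrow = TRUE))
  p <- dbem_params(D = 1, larval_D = 0, dt = 0.25)
  st <- list(biomass = B, weight = matrix(500, n, n), time = 0)
  for (i in 1:200) st <- step_population(st, sp, sl, p, 0, kc = kc)
  expect_equal(sum(st$biomass), sum(B), tolerance = 1e-10)
  expect_true(all(st$biomass >= 0))

  bad <- dbem_params(D = 2, dt = 0.25)
  err <- tryCatch(step_population(st, sp, sl, bad, 0, kc = kc), error = identity)
  expect_s3_class(err, "fc_step_error")
  expect_match(conditionMessage(err), "dt \\* D")
})

test_that("habitat mask keeps biomass out of lethal cells at equilibrium", {
  w <- tiny_world()
  sp <- test_species(lat_min = -30, lat_max = 30, r_intr = 0.8)
  sl <- uniform_slice(w, sst = 20)
  st <- initialize_distribution(sp, w, sl, dbem_params(spinup_years = 60))
  kc <- attr(st, "diagnostics")$kc
  expect_true(all(st$biomass[kc == 0] < 1e-8))
  expect_lte(sum(st$biomass), sp$b0_t * (1 + 1e-9))
})

test_that("spin-up reaches equilibrium and honours its contracts", {
  w <- tiny_world()
  sp <- test_species(r_intr = 0.6)
  sl <- uniform_slice(w, sst = 20)

  ## start at capacity, no transport: unchanged within 1e-9
  p0 <- dbem_params(D = 0, larval_D = 0, spinup_years = 5, init_frac = 1)
  sl0 <- sl; sl0$u <- NULL; sl0$v <- NULL
  st0 <- initialize_distribution(sp, w, sl0, p0)
  kc0 <- attr(st0, "diagnostics")$kc
  expect_equal(max(abs(st0$biomass - kc0)), 0, tolerance = 1e-9 * max(kc0))

  ## default spin-up length is recorded in the diagnostics
  expect_equal(dbem_params()$spinup_years, 100)
  p1 <- dbem_params(D = 0, larval_D = 0, spinup_years = 100, init_frac = 0.01)
  st1 <- initialize_distribution(sp, w, sl0, p1)
  d <- attr(st1, "diagnostics")
  expect_identical(d$spinup_years, 100)
  expect_true(d$converged)
  expect_lt(d$max_rel_change, 1e-3)
  ## logistic convergence: biomass within 0.5% of capacity cell-wise
  kc1 <- d$kc
  on <- kc1 > 0
  expect_lt(max(abs(st1$biomass[on] - kc1[on]) / kc1[on]), 0.005)
})

test_that("MSY rule and the F = M surplus-production equilibrium hold", {
  expect_identical(msy_top_ten(1:15), 10.5)
  expect_identical(msy_top_ten(c(3, 1)), 2)

  ## single-cell logistic, r = 0.5, KC = 1000, F = M = 0.2:
  ## equilibrium annual catch F*KC*(1 - F/r) = 120 t
  sp <- test_species(r_intr = 0.5, m_nat = 0.2)
  kc <- matrix(1000, 1, 1)
  sl <- list(sst = matrix(20, 1, 1))
  p <- dbem_params(D = 0, larval_D = 0, dt = 0.1)
  st <- list(biomass = matrix(1000, 1, 1), weight = matrix(500, 1, 1), time = 0)
  for (yr in 1:60) {
    for (i in 1:10) st <- step_population(st, sp, sl, p, 0.2, kc = kc)
  }
  annual <- 0
  for (i in 1:10) {
    st <- step_population(st, sp, sl, p, 0.2, kc = kc)
    annual <- annual + sum(attr(st, "catch"))
  }
  expect_equal(annual, 120, tolerance = 0.01 * 120)
})

test_that("projection rejects years outside the forcing span", {
  w <- tiny_world()
  f <- generate_forcing(w, "climatology", 2001:2010, seed = 1)
  sp <- test_species()
  expect_error(project_catch_potential(sp, f, dbem_params(spinup_years = 2), w,
                                       years = 2001:2030),
               class = "fc_span_error")
})

test_that("EEZ aggregates sum member cells and weights stay in (0, Winf]", {
  w <- tiny_world()
  sl <- uniform_slice(w, sst = 20)
  f <- const_forcing(w, sl, 2001:2012)
  sp <- test_species(lat_min = -40, lat_max = 40)
  p <- dbem_params(spinup_years = 10)
  run <- project_catch_potential(sp, f, p, w, burn_in_years = 2)
  ## per-year EEZ totals never exceed the global catch
  agg <- stats::aggregate(tonnes ~ year, data = run$catch_by_eez, FUN = sum)
  expect_true(all(agg$tonnes <= run$annual_catch[as.character(agg$year)] + 1e-9))
  expect_true(all(run$final_state$weight > 0 &
                  run$final_state$weight <= sp$winf_g))
  expect_equal(run$msy, msy_top_ten(run$annual_catch))
})
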