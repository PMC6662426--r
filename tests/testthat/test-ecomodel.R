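test_that("the daily carbon balance closes over random states and weather", {
  set.seed(31)
  params <- ecophys_params()
  site <- test_site()
  for (i in 1:300) {
    st <- random_state()
    met <- random_met()
    out <- step_day(st, met, params, site)
    d_pools <- sum(out$state[c_pools]) - sum(st[c_pools])
    rhs <- out$fluxes[["gpp"]] - out$fluxes[["maint_resp"]] -
      out$fluxes[["growth_resp"]] - out$fluxes[["heterotrophic_resp"]] -
      out$fluxes[["fire_loss"]] - out$fluxes[["harvest"]]
    expect_lt(abs(d_pools - rhs), 1e-9 * max(1, sum(st[c_pools])))
    expect_true(all(out$state[c_pools] >= 0))   # fluxes limited at source
  }
})

test_that("the daily step is pure", {
  set.seed(32)
  st <- random_state(); met <- random_met()
  params <- ecophys_params(); site <- test_site()
  a <- step_day(st, met, params, site)
  b <- step_day(st, met, params, site)
  expect_identical(a, b)
})

test_that("a dark winter day changes pools only via turnover and decay", {
  params <- ecophys_params()
  st <- test_init()
  st["deadstemC"] <- 1
  met <- make_met(tmax = -2, tmin = -10, srad = 0, phase = 0, tsoil = -3)
  out <- step_day(st, met, params, test_site())
  expect_equal(out$fluxes[["gpp"]], 0)
  expect_equal(out$fluxes[["heterotrophic_resp"]], 0)  # frozen soil
  expect_equal(out$fluxes[["growth_resp"]], 0)
})

test_that("live wood turnover matches the daily-compounded decay oracle", {
  params <- ecophys_params(mortality = 0, fire_mortality = 0)
  st <- empty_state_like()
  st["livestemC"] <- 1
  met <- make_met(tmax = -2, tmin = -8, srad = 0, phase = 0, tsoil = -5)
  for (d in 1:365) st <- step_day(st, met, params, test_site())$state
  r <- params$livewood_turnover / 365
  expect_equal(unname(st["livestemC"]), (1 - r)^365, tolerance = 1e-12)
  expect_equal(unname(st["deadstemC"]), 1 - (1 - r)^365, tolerance = 1e-12)
  # close to (but distinct from) the continuous limit
  expect_lt(abs(st[["deadstemC"]] - (1 - exp(-0.7))), 0.001)
})

test_that("labile litter decays by the analytic first-order oracle", {
  params <- ecophys_params(fire_mortality = 0)
  site <- test_site()
  st <- empty_state_like()
  st["litr_lab"] <- 1
  st["litrN"] <- 1 / 45
  st["soil_water"] <- soil_water_capacity(site)   # moisture scalar 1
  met <- make_met(tmax = 25, tmin = 15, prcp_cm = 1, srad = 0, phase = 0,
                  tsoil = 20)                     # temperature scalar 1
  hr <- 0
  for (d in 1:50) {
    out <- step_day(st, met, params, site)
    st <- out$state
  }
  k <- params$k_lab
  expect_equal(unname(st["litr_lab"]), (1 - k)^50, tolerance = 1e-6)
  # half-life of the daily-compounded process
  t_half <- log(0.5) / log(1 - k)
  expect_equal((1 - k)^t_half, 0.5, tolerance = 1e-12)
  # frozen soil halts decomposition entirely
  st2 <- empty_state_like(); st2["litr_lab"] <- 1
  met2 <- make_met(tmax = 0, tmin = -10, srad = 0, phase = 0, tsoil = -1)
  out2 <- step_day(st2, met2, params, site)
  expect_equal(unname(out2$state["litr_lab"]), 1)
})

test_that("decomposition partitions pool loss into respiration and soil", {
  params <- ecophys_params(fire_mortality = 0)
  site <- test_site()
  st <- empty_state_like()
  st["litr_lab"] <- 0.5; st["litr_cel"] <- 0.5; st["litr_lig"] <- 0.5
  st["litrN"] <- 1.5 / 45
  st["soil_water"] <- soil_water_capacity(site)
  met <- make_met(tmax = 25, tmin = 15, prcp_cm = 1, srad = 0, phase = 0,
                  tsoil = 20)
  out <- step_day(st, met, params, site)
  litter_loss <- sum(st[c("litr_lab", "litr_cel", "litr_lig")]) -
    sum(out$state[c("litr_lab", "litr_cel", "litr_lig")])
  gained_soil <- out$state[["soilC"]] - st[["soilC"]] +
    st[["soilC"]] * params$k_soil   # soil's own decay at scalar 1
  expect_equal(litter_loss,
               out$fluxes[["heterotrophic_resp"]] -
                 st[["soilC"]] * params$k_soil + gained_soil,
               tolerance = 1e-12)
})

test_that("senescence empties the canopy and conserves carbon", {
  params <- ecophys_params(mortality = 0, fire_mortality = 0)
  site <- test_site()
  st <- empty_state_like()
  st["leafC"] <- 0.2; st["frootC"] <- 0.15
  leaf0 <- st[["leafC"]] + st[["frootC"]]
  fall <- 0
  n_days <- 10
  for (d in seq_len(n_days)) {
    met <- make_met(tmax = 12, tmin = 4, srad = 0, phase = 3,
                    days_left = n_days - d + 1, tsoil = -1)
    out <- step_day(st, met, params, site)
    fall <- fall + out$fluxes[["litterfall_C"]]
    st <- out$state
  }
  expect_equal(unname(st["leafC"]), 0)
  expect_equal(unname(st["frootC"]), 0)
  expect_equal(fall, leaf0, tolerance = 1e-12)
})

test_that("allocation splits follow the prescribed organ ratios", {
  # transfer of 1 kg C with frc=1, sc=2, crc=0.5, growth resp 0.3:
  # tissue per unit leaf = 1+1+2+1 = 5; leaf gain = 1/(5*1.3)
  params <- ecophys_params(frc_lc = 1, sc_lc = 2, crc_sc = 0.5,
                           mortality = 0, fire_mortality = 0)
  st <- empty_state_like()
  st["transferC"] <- 1
  st["sminN"] <- 1                      # ample N
  met <- make_met(srad = 0, phase = 1, days_left = 1)
  out <- step_day(st, met, params, test_site())
  expect_equal(unname(out$state["leafC"]), 1 / (5 * 1.3), tolerance = 1e-9)
  expect_equal(unname(out$state["frootC"]), 1 / (5 * 1.3), tolerance = 1e-9)
  stem <- out$state[["livestemC"]] + out$state[["deadstemC"]]
  croot <- out$state[["livecrootC"]] + out$state[["deadcrootC"]]
  expect_equal(stem, 2 / (5 * 1.3), tolerance = 1e-9)
  expect_equal(croot / stem, 0.5, tolerance = 1e-9)
  gain <- sum(out$state[c("leafC", "frootC", "livestemC", "deadstemC",
                          "livecrootC", "deadcrootC")])
  expect_equal(gain + out$fluxes[["growth_resp"]], 1, tolerance = 1e-12)
  # measured coarse-root ratio is honoured exactly
  p47 <- ecophys_params(mortality = 0, fire_mortality = 0)
  out47 <- step_day(st, met, p47, test_site())
  stem47 <- out47$state[["livestemC"]] + out47$state[["deadstemC"]]
  croot47 <- out47$state[["livecrootC"]] + out47$state[["deadcrootC"]]
  expect_equal(croot47 / stem47, 0.47, tolerance = 1e-9)
})

test_that("canopy photosynthesis scales linearly with daylength", {
  params <- ecophys_params()
  st <- test_init()
  st["leafC"] <- 0.1
  m1 <- make_met(tmax = 26, tmin = 16, srad = 350, daylength = 20000,
                 vpd = 600, phase = 2)
  m2 <- make_met(tmax = 26, tmin = 16, srad = 350, daylength = 40000,
                 vpd = 600, phase = 2)
  g1 <- step_day(st, m1, params, test_site())$fluxes[["gpp"]]
  g2 <- step_day(st, m2, params, test_site())$fluxes[["gpp"]]
  expect_gt(g1, 0)
  expect_equal(g2 / g1, 2, tolerance = 1e-9)
  # no leaves, no carbon uptake
  st0 <- st; st0["leafC"] <- 0
  expect_equal(step_day(st0, m1, params, test_site())$fluxes[["gpp"]], 0)
})

test_that("water balance obeys its bucket limits", {
  params <- ecophys_params()
  site <- test_site()
  cap <- soil_water_capacity(site)
  st <- test_init()
  st["soil_water"] <- cap
  met <- make_met(prcp_cm = 5, srad = 0, phase = 0)
  out <- step_day(st, met, params, site)
  expect_lte(out$state[["soil_water"]], cap)
  expect_gte(out$fluxes[["drainage"]], 0)
  # no canopy: zero interception
  expect_equal(out$fluxes[["interception"]], 0)
  # repeated dry days: monotone nonincreasing storage
  st["soil_water"] <- cap / 2
  dry <- make_met(prcp_cm = 0, srad = 300, phase = 2)
  w <- numeric(10)
  for (d in 1:10) {
    out <- step_day(st, dry, params, site)
    w[d] <- out$state[["soil_water"]]
    st <- out$state
  }
  expect_true(all(diff(c(cap / 2, w)) <= 0))
})

test_that("run_years reports annual maxima deterministically", {
  params <- ecophys_params()
  f <- test_forcing()
  r1 <- run_years(params, test_site(), f, 5, init = test_init())
  r2 <- run_years(params, test_site(), f, 5, init = test_init())
  expect_identical(r1, r2)
  expect_equal(nrow(r1$series), 5)
  expect_true(all(r1$series$AC >= 0))
  expect_true(all(diff(r1$series$AC) > 0))   # young stand accrues wood
  r0 <- run_years(params, test_site(), f, 0, init = test_init())
  expect_equal(nrow(r0$series), 0)
})

test_that("doubling fire mortality never increases stored plant carbon", {
  f <- test_forcing()
  base <- ecophys_params()
  hot <- ecophys_params(fire_mortality = 2 * base$fire_mortality)
  r1 <- run_years(base, test_site(), f, 10, init = test_init())
  r2 <- run_years(hot, test_site(), f, 10, init = test_init(hot))
  expect_lte(total_plant_c(r2$final_state), total_plant_c(r1$final_state))
})

test_that("grass spin-up reaches a quasi-steady soil pool", {
  sp <- suppressWarnings(spin_up(test_site(), test_forcing(), years = 1200))
  expect_true(sp$converged)
  expect_lt(sp$drift, 0.005)
  expect_gt(sp$soilC, 1)
  # harvest exports accumulate year on year
  expect_gt(sp$state[["cum_harvest"]], 0)
})

test_that("with no production the soil pool decays toward zero", {
  site <- test_site()
  params <- grass_params(fertilization = 0)
  st <- empty_state_like()
  st["soilC"] <- 5; st["soilN"] <- 0.5
  st["soil_water"] <- soil_water_capacity(site)
  met <- make_met(tmax = 25, tmin = 15, prcp_cm = 1, srad = 0, phase = 0,
                  tsoil = 20)
  soil <- numeric(30)
  for (d in 1:30) {
    st <- step_day(st, met, params, site)$state
    soil[d] <- st[["soilC"]]
  }
  expect_true(all(diff(c(5, soil)) < 0))
})
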