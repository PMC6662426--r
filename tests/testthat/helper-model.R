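# shared fixtures, built once per test run and cached
.test_cache <- new.env(parent = emptyenv())

test_site <- function() site_info()

test_forcing <- function(years = 12, seed = 42) {
  key <- sprintf("forcing_%d_%d", years, seed)
  if (is.null(.test_cache[[key]])) {
    w <- generate_weather(weather_gen_config(seed = seed), years)
    .test_cache[[key]] <- prepare_forcing(w, test_site(), ecophys_params())
  }
  .test_cache[[key]]
}

test_soil_init <- function() {
  if (is.null(.test_cache$soil)) {
    sp <- suppressWarnings(spin_up(test_site(), test_forcing(), years = 1200))
    .test_cache$soil <- sp$state
  }
  .test_cache$soil
}

test_init <- function(params = ecophys_params()) {
  initial_state(test_site(), params, soil = test_soil_init())
}

# one met row as a data.frame compatible with step_day()
make_met <- function(tmax = 20, tmin = 10, prcp_cm = 0, vpd = 800,
                     srad = 300, daylength = 43200, co2 = 380,
                     tsoil = NULL, phase = 2, days_left = 0, onset = 0) {
  tavg <- (tmax + tmin) / 2
  data.frame(tmax = tmax, tmin = tmin, tday = tavg + 0.45 * (tmax - tavg),
             tavg = tavg, tsoil = if (is.null(tsoil)) tavg else tsoil,
             prcp_cm = prcp_cm, vpd = vpd, srad = srad,
             daylength = daylength, co2 = co2, phase = phase,
             days_left = days_left, onset = onset)
}

c_pools <- c("leafC", "frootC", "livestemC", "deadstemC", "livecrootC",
             "deadcrootC", "storageC", "transferC", "litr_lab", "litr_cel",
             "litr_lig", "cwdC", "soilC")

empty_state_like <- function() {
  st <- initial_state(test_site(), ecophys_params())
  st[] <- 0
  st
}

total_plant_c <- function(state) {
  sum(state[c("leafC", "frootC", "livestemC", "deadstemC", "livecrootC",
              "deadcrootC", "storageC", "transferC")])
}

random_state <- function() {
  st <- initial_state(test_site(), ecophys_params())
  st["leafC"] <- runif(1, 0, 0.3)
  st["frootC"] <- runif(1, 0, 0.3)
  st["livestemC"] <- runif(1, 0, 0.5)
  st["deadstemC"] <- runif(1, 0, 4)
  st["livecrootC"] <- runif(1, 0, 0.3)
  st["deadcrootC"] <- runif(1, 0, 2)
  st["storageC"] <- runif(1, 0, 1)
  st["transferC"] <- runif(1, 0, 1)
  st["litr_lab"] <- runif(1, 0, 0.5)
  st["litr_cel"] <- runif(1, 0, 0.5)
  st["litr_lig"] <- runif(1, 0, 0.5)
  st["cwdC"] <- runif(1, 0, 2)
  st["soilC"] <- runif(1, 1, 12)
  st["litrN"] <- st["litr_lab"] / 45
  st["cwdN"] <- st["cwdC"] / 442
  st["soilN"] <- st["soilC"] / 10
  st["sminN"] <- runif(1, 0, 0.05)
  st["soil_water"] <- runif(1, 10, soil_water_capacity(test_site()))
  st
}

random_met <- function() {
  tmin <- runif(1, -10, 22)
  tmax <- tmin + runif(1, 0.5, 15)
  make_met(tmax = tmax, tmin = tmin, prcp_cm = ifelse(runif(1) < 0.3,
                                                      runif(1, 0, 3), 0),
           vpd = runif(1, 0, 3500), srad = runif(1, 0, 500),
           daylength = runif(1, 30000, 55000),
           tsoil = runif(1, -5, 28),
           phase = sample(0:3, 1),
           days_left = sample(1:30, 1),
           onset = as.numeric(runif(1) < 0.05))
}

# closed-form OLS via the normal equations, the fitting oracle
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))   # (intercept, slope)
}

# bisection oracle for the coupled supply-demand CO2 solver
bisect_ci <- function(g, ca, vcmax, j, gamma, kc, ko, o2, rd,
                      tol = 1e-10) {
  a_dem <- function(ci) farquhar_a(vcmax, j, ci, gamma, kc, ko, o2, rd)[["A"]]
  h <- function(ci) g * (ca - ci) - a_dem(ci)
  lo <- 1e-9; hi <- 2 * ca
  if (h(lo) < 0 || h(hi) > 0) return(NA_real_)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (h(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}
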