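#' Configuration for the stochastic daily weather generator
#'
#' Defaults emulate the site climatology of a semi-arid Loess Plateau
#' station: annual mean temperature 13.7 degrees C with a 14-degree
#' seasonal amplitude, and 686 mm annual precipitation delivered by a
#' two-state Markov occurrence process with gamma-distributed wet-day
#' amounts.
#'
#' @param annual_mean_T annual mean air temperature, degrees C.
#' @param seasonal_amplitude half-range of the sinusoidal seasonal cycle,
#'   degrees C.
#' @param daily_T_sd standard deviation of day-to-day temperature noise.
#' @param diurnal_range_mean mean diurnal range (Tmax - Tmin), degrees C.
#' @param annual_precip target mean annual precipitation, mm.
#' @param wet_day_prob unconditional probability that a day following a
#'   dry day is wet.
#' @param wet_after_wet_prob probability a day following a wet day is wet.
#' @param precip_gamma_shape shape of the gamma wet-day amount law.
#' @param wet_day_range_factor compression of the diurnal temperature
#'   range on wet (cloudy) days; 0.7 reproduces the humid-summer VPD
#'   climatology of monsoon-influenced stations.
#' @param seed integer seed; identical configurations generate identical
#'   records.
#' @return An object of class `weather_gen_config`.
#' @export
weather_gen_config <- function(annual_mean_T = 13.7, seasonal_amplitude = 14,
                               daily_T_sd = 3, diurnal_range_mean = 10,
                               annual_precip = 686, wet_day_prob = 0.22,
                               wet_after_wet_prob = 0.45,
                               precip_gamma_shape = 0.75,
                               wet_day_range_factor = 0.7, seed = 1L) {
  stopifnot(wet_day_prob >= 0, wet_day_prob <= 1,
            wet_after_wet_prob >= 0, wet_after_wet_prob <= 1,
            seasonal_amplitude >= 0, daily_T_sd >= 0,
            diurnal_range_mean >= 0, annual_precip >= 0,
            precip_gamma_shape > 0,
            wet_day_range_factor > 0, wet_day_range_factor <= 1)
  structure(list(annual_mean_T = annual_mean_T,
                 seasonal_amplitude = seasonal_amplitude,
                 daily_T_sd = daily_T_sd,
                 diurnal_range_mean = diurnal_range_mean,
                 annual_precip = annual_precip,
                 wet_day_prob = wet_day_prob,
                 wet_after_wet_prob = wet_after_wet_prob,
                 precip_gamma_shape = precip_gamma_shape,
                 wet_day_range_factor = wet_day_range_factor,
                 seed = as.integer(seed)),
            class = "weather_gen_config")
}

#' Generate a seeded synthetic daily weather record
#'
#' Daily mean temperature is a sinusoidal annual cycle (minimum in
#' mid-January) plus Gaussian noise; Tmax/Tmin are placed symmetrically
#' around it with a slightly variable diurnal range. Precipitation
#' occurrence follows a two-state Markov chain and wet-day amounts a gamma
#' law whose scale is set so the expected annual total matches
#' `annual_precip`, with a seasonal concentration in summer. Years have
#' 365 days.
#'
#' @param cfg a [weather_gen_config()].
#' @param years number of years (>= 1).
#' @return data.frame with `year`, `doy`, `tmax`, `tmin`, `prcp_cm`.
#' @export
generate_weather <- function(cfg, years) {
  stopifnot(inherits(cfg, "weather_gen_config"))
  if (years < 1) stop("years must be >= 1")
  n <- years * 365
  doy <- rep(1:365, years)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  tmean <- cfg$annual_mean_T -
    cfg$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365) +
    stats::rnorm(n, 0, cfg$daily_T_sd)
  dr <- pmax(1, cfg$diurnal_range_mean *
               (1 + stats::rnorm(n, 0, ifelse(cfg$daily_T_sd > 0, 0.15, 0))))

  # stationary wet-day frequency of the two-state chain
  p01 <- cfg$wet_day_prob; p11 <- cfg$wet_after_wet_prob
  pi_wet <- if (p01 + (1 - p11) > 0) p01 / (p01 + 1 - p11) else 0
  wet <- logical(n)
  u <- stats::runif(n)
  prev <- FALSE
  for (i in seq_len(n)) {
    p <- if (prev) p11 else p01
    wet[i] <- u[i] < p
    prev <- wet[i]
  }
  # cloud cover on wet days compresses the diurnal range
  dr[wet] <- dr[wet] * cfg$wet_day_range_factor
  tmax <- tmean + dr / 2
  tmin <- tmean - dr / 2
  # summer-weighted amounts: seasonal factor integrates to 1 over the year
  sf <- 1 + 0.8 * sin(2 * pi * (doy - 105) / 365)
  amount <- numeric(n)
  if (pi_wet > 0 && cfg$annual_precip > 0) {
    mean_amt_mm <- cfg$annual_precip / (365 * pi_wet)
    amount[wet] <- stats::rgamma(sum(wet), shape = cfg$precip_gamma_shape,
                                 scale = mean_amt_mm * sf[wet] /
                                   cfg$precip_gamma_shape)
  }
  data.frame(year = rep(seq_len(years), each = 365), doy = doy,
             tmax = tmax, tmin = tmin, prcp_cm = amount / 10)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Configuration for the synthetic biometric survey generator
#'
#' Emulates the design of the field campaign this workflow supports:
#' a handful of harvested model trees whose per-organ dry weights obey
#' known linear allometries in D^2 H (woody parts) and D^2 (leaves) with
#' multiplicative lognormal noise, plus fixed-area inventory quadrats and
#' monotone tree-ring diameter series.
#'
#' @param n_harvest_trees number of harvested model trees.
#' @param n_quadrats number of inventory quadrats.
#' @param trees_per_quadrat trees per quadrat.
#' @param quadrat_area quadrat area, m2.
#' @param true_allometry list with components `above`, `below` (slope and
#'   intercept on D^2 H, kg) and `leaf` (slope and intercept on D^2).
#' @param D_mean,D_sd diameter distribution at the survey age, m.
#' @param H_mean mean tree height at the survey age, m.
#' @param ages number of stand ages covered by the ring series.
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal organ-weight noise.
#' @param seed integer seed.
#' @return An object of class `survey_gen_config`.
#' @export
survey_gen_config <- function(n_harvest_trees = 7, n_quadrats = 4,
                              trees_per_quadrat = 16, quadrat_area = 150,
                              true_allometry = list(
                                above = c(slope = 373.5, intercept = 3.2),
                                below = c(slope = 162.6, intercept = 1.2),
                                leaf = c(slope = 392.3, intercept = 0.0)),
                              D_mean = 0.105, D_sd = 0.02, H_mean = 7.8,
                              ages = 11, noise_cv = 0.1, seed = 1L) {
  stopifnot(n_harvest_trees >= 1, n_quadrats >= 1, trees_per_quadrat >= 1,
            quadrat_area > 0, noise_cv >= 0, ages >= 1)
  need <- c("above", "below", "leaf")
  if (!all(need %in% names(true_allometry)))
    stop("true_allometry must supply 'above', 'below' and 'leaf'")
  structure(list(n_harvest_trees = n_harvest_trees, n_quadrats = n_quadrats,
                 trees_per_quadrat = trees_per_quadrat,
                 quadrat_area = quadrat_area, true_allometry = true_allometry,
                 D_mean = D_mean, D_sd = D_sd, H_mean = H_mean, ages = ages,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "survey_gen_config")
}

# logistic diameter growth scaled to end exactly at final D
ring_curve <- function(D_final, ages, k = 0.45, mid = 0.45) {
  a <- seq_len(ages)
  g <- 1 / (1 + exp(-k * (a - mid * ages)))
  g0 <- 1 / (1 + exp(k * mid * ages))
  d <- (g - g0) / (g[ages] - g0) * D_final
  pmax(0, d)
}

#' Generate a seeded synthetic biometric survey
#'
#' Returns harvest-tree records (organ dry weights = allometric
#' prediction times lognormal noise with the configured CV), quadrat
#' inventories, strictly nondecreasing tree-ring diameter series ending at
#' each harvest tree's final D, and a height-by-age table.
#'
#' @param cfg a [survey_gen_config()].
#' @return list with data.frames `harvest`, `quadrats`, `rings`,
#'   `height_by_age`.
#' @export
generate_survey <- function(cfg) {
  stopifnot(inherits(cfg, "survey_gen_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  lnoise <- function(n) {
    if (cfg$noise_cv == 0) return(rep(1, n))
    sdl <- sqrt(log(1 + cfg$noise_cv^2))
    stats::rlnorm(n, -sdl^2 / 2, sdl)
  }
  nh <- cfg$n_harvest_trees
  D <- pmax(0.02, stats::rnorm(nh, cfg$D_mean, cfg$D_sd))
  H <- pmax(1, cfg$H_mean * (D / cfg$D_mean)^0.5 *
              (1 + stats::rnorm(nh, 0, 0.03)))
  al <- cfg$true_allometry
  pred <- function(cf, x) unname(cf["slope"]) * x + unname(cf["intercept"])
  harvest <- data.frame(
    tree_id = sprintf("T%02d", seq_len(nh)), D = D, H = H,
    wt_above = pred(al$above, D^2 * H) * lnoise(nh),
    wt_below = pred(al$below, D^2 * H) * lnoise(nh),
    wt_leaf = pred(al$leaf, D^2) * lnoise(nh),
    leaf_excluded = FALSE)

  nq <- cfg$n_quadrats * cfg$trees_per_quadrat
  Dq <- pmax(0.02, stats::rnorm(nq, cfg$D_mean, cfg$D_sd))
  Hq <- pmax(1, cfg$H_mean * (Dq / cfg$D_mean)^0.5 *
               (1 + stats::rnorm(nq, 0, 0.03)))
  quadrats <- data.frame(
    quadrat_id = rep(sprintf("Q%d", seq_len(cfg$n_quadrats)),
                     each = cfg$trees_per_quadrat),
    area = cfg$quadrat_area,
    tree_id = sprintf("QT%03d", seq_len(nq)), D = Dq, H = Hq)

  rings <- do.call(rbind, lapply(seq_len(nh), function(i) {
    data.frame(tree_id = harvest$tree_id[i], age = seq_len(cfg$ages),
               ring_D = ring_curve(D[i], cfg$ages))
  }))
  hba <- data.frame(age = seq_len(cfg$ages),
                    H = ring_curve(cfg$H_mean, cfg$ages, k = 0.4, mid = 0.4))
  list(harvest = harvest, quadrats = quadrats, rings = rings,
       height_by_age = hba)
}

#' Generate model-derived carbon-density observations
#'
#' Runs the process model with known ("true") ecophysiological parameters
#' and returns the annual AC/BC/LC series, optionally perturbed by
#' multiplicative lognormal noise — the ground truth for
#' parameter-recovery experiments.
#'
#' @param params true [ecophys_params()].
#' @param site a [site_info()].
#' @param forcing a `daily_climate` from [prepare_forcing()].
#' @param years number of stand ages to simulate.
#' @param obs_noise_cv observation noise CV (0 for exact model output).
#' @param seed integer seed for the noise.
#' @param init optional initial model state (defaults to
#'   [initial_state()]).
#' @return A `carbon_density_series` data.frame.
#' @export
generate_observations <- function(params, site, forcing, years,
                                  obs_noise_cv = 0, seed = 1L, init = NULL) {
  sim <- run_years(params, site, forcing, years, init = init)
  obs <- sim$series
  if (obs_noise_cv > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
    sdl <- sqrt(log(1 + obs_noise_cv^2))
    for (col in c("AC", "BC", "LC"))
      obs[[col]] <- obs[[col]] * stats::rlnorm(years, -sdl^2 / 2, sdl)
  }
  obs
}
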