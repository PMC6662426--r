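#' Ecophysiological parameter set for the stand model
#'
#' Builds the full ecophysiological parameter vector used by the daily
#' process model. Defaults are the standard deciduous-broadleaf-forest
#' (DBF) set of the Biome-BGC lineage together with the site-measured
#' values for this monitoring workflow: coarse-root allocation
#' (`crc_sc = 0.47`, the measured BC:AC ratio) and leaf C:N
#' (`cn_leaf = 26`).
#'
#' The tunable parameters that matter most for calibration are the
#' allocation ratios `frc_lc` (new fine root C : new leaf C) and `sc_lc`
#' (new stem C : new leaf C), the specific leaf area `sla` (m2 of
#' projected leaf area per kg leaf C) and the maximum stomatal conductance
#' `gsmax` (m/s).
#'
#' @param ... named overrides of any default, e.g. `sla = 15`.
#' @return An object of class `ecophys_params` (a named list).
#' @examples
#' p <- ecophys_params(sla = 15, gsmax = 0.003)
#' p$sla
#' @export
ecophys_params <- function(...) {
  p <- list(
    # allocation
    frc_lc = 1.0,              # new fine root C : new leaf C
    sc_lc = 2.2,               # new stem C : new leaf C
    crc_sc = 0.47,             # new coarse root C : new stem C (measured)
    live_wood_frac = 0.1,      # new live wood C : new total wood C
    current_growth_prop = 0.5, # displayed this season vs stored
    # canopy
    sla = 30,                  # m2 / kg-C, projected, sunlit
    sla_shade_ratio = 2.0,
    flnr = 0.08,               # fraction of leaf N in Rubisco
    k_ext = 0.7,               # canopy light extinction coefficient
    lai_allsided_ratio = 2.0,
    # conductances (m/s, projected area basis)
    gsmax = 0.005,
    g_cuticular = 0.00001,
    g_boundary = 0.01,
    # stomatal stress ramps
    lwp_start = -0.6,          # MPa, start of conductance reduction
    lwp_final = -2.3,          # MPa, complete reduction
    vpd_start = 930,           # Pa
    vpd_final = 4100,          # Pa
    # stoichiometry (kg-C / kg-N)
    cn_leaf = 26,
    cn_litter = 49,
    cn_froot = 42,
    cn_livewood = 50,
    cn_deadwood = 442,
    # turnover and disturbance (1/year)
    leaf_froot_turnover = 1.0,
    livewood_turnover = 0.7,
    mortality = 0.005,
    fire_mortality = 0.0025,
    # phenology fractions of the growing season
    transfer_frac = 0.2,
    litterfall_frac = 0.2,
    # litter composition
    litter_labile = 0.39, litter_cellulose = 0.44, litter_lignin = 0.17,
    froot_labile = 0.30, froot_cellulose = 0.45, froot_lignin = 0.25,
    deadwood_cellulose = 0.76, deadwood_lignin = 0.24,
    canopy_intercept = 0.041,  # 1/LAI/day
    # physiological constants (documented simplifications)
    growth_resp_frac = 0.3,    # growth respiration per unit new tissue C
    act25 = 60000,             # Rubisco activity at 25 C, umol/kg-Rub/s
    q10_act = 2.4,
    rd_frac = 0.015,           # day respiration as fraction of Vcmax
    jmax_ratio = 2.1,          # Jmax = 2.1 Vcmax
    alpha_j = 0.3,             # initial slope of the J light response
    par_frac = 0.45,           # PAR fraction of shortwave
    ppfd_per_j = 4.6,          # umol photons per J of PAR
    ppfd_half = 75,            # half-saturation PPFD of the light multiplier
    tmin_lo = -8, tmin_hi = 0, # freezing-night conductance ramp, deg C
    mr_per_n = 0.218,          # kg C / kg N / day at 20 C
    q10_mr = 2.0,
    q10_hr = 2.0,
    # decomposition base rates (1/day at 20 C, wet soil)
    k_lab = 0.08, k_cel = 0.014, k_lig = 0.0014, k_cwd = 0.0015,
    k_soil = 0.00025,
    rf_lab = 0.39, rf_cel = 0.55, rf_lig = 0.29,  # respired fractions
    cn_soil = 10,
    soil_evap_max = 0.4,       # kg H2O / m2 / day, bare wet soil
    sminn_loss_rate = 0.002,   # 1/day bulk leaching/denitrification
    # plant form / management
    woody = TRUE,
    harvest_frac = 0,          # fraction of leaf fall removed (grass)
    fertilization = 0          # kg-N/m2/y added to mineral N
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_ecophys(p)
  structure(p, class = "ecophys_params")
}

validate_ecophys <- function(p) {
  num <- p[!names(p) %in% "woody"]
  if (any(!vapply(num, is.numeric, logical(1))))
    stop("all ecophysiological parameters except 'woody' must be numeric")
  nonneg <- setdiff(names(num), c("lwp_start", "lwp_final", "tmin_lo",
                                  "tmin_hi"))
  if (any(unlist(num[nonneg]) < 0))
    stop("ecophysiological parameters must be nonnegative")
  if (p$vpd_final <= p$vpd_start)
    stop("vpd_final must exceed vpd_start")
  if (p$lwp_final >= p$lwp_start)
    stop("lwp_final must be below lwp_start")
  for (set in list(c("litter_labile", "litter_cellulose", "litter_lignin"),
                   c("froot_labile", "froot_cellulose", "froot_lignin"),
                   c("deadwood_cellulose", "deadwood_lignin"))) {
    if (abs(sum(unlist(p[set])) - 1) > 1e-9)
      stop("litter composition fractions must sum to 1: ",
           paste(set, collapse = ", "))
  }
  invisible(p)
}

#' @export
print.ecophys_params <- function(x, ...) {
  cat("<ecophys_params>", if (isTRUE(x$woody)) "woody" else "non-woody", "\n")
  key <- c("frc_lc", "sc_lc", "crc_sc", "sla", "gsmax", "vpd_start",
           "vpd_final", "cn_leaf")
  for (k in key) cat(sprintf("  %-10s %g\n", k, x[[k]]))
  cat("  (", length(x), "parameters; see ?ecophys_params )\n")
  invisible(x)
}

#' Annual C4 grass parameter variant used for soil spin-up
#'
#' A managed annual grass (cropland stand-in) with no woody pools, annual
#' harvest of half of the aboveground biomass and fertilizer N supply,
#' used to bring soil carbon and nitrogen to quasi-steady state before
#' planting.
#'
#' @param fertilization nitrogen supply by fertilization, kg-N/m2/y.
#' @param harvest_frac fraction of aboveground (leaf) biomass removed at
#'   the end of each growing season.
#' @param ... further overrides passed to [ecophys_params()].
#' @return An `ecophys_params` object.
#' @export
grass_params <- function(fertilization = 0.03, harvest_frac = 0.5, ...) {
  ecophys_params(
    woody = FALSE, sc_lc = 0, crc_sc = 0, live_wood_frac = 0,
    livewood_turnover = 0, mortality = 0.0, fire_mortality = 0.0,
    sla = 45, cn_leaf = 25, cn_litter = 45, gsmax = 0.006,
    current_growth_prop = 0.5,
    harvest_frac = harvest_frac, fertilization = fertilization, ...)
}

#' Site description for the simulation
#'
#' Site constants: terrain, soil texture (which sets the water-holding
#' capacity and the soil-water retention curve), nitrogen inputs, the
#' first-year planting size, and the atmospheric CO2 record by calendar
#' year. Defaults describe a Loess Plateau plantation site at 1,000 m,
#' 34.27 deg N on silty soil (5% sand, 68% silt, 27% clay) with
#' atmospheric N deposition of 0.002 kg-N/m2/y.
#'
#' @param elevation m above sea level.
#' @param latitude degrees north.
#' @param albedo shortwave albedo (fraction).
#' @param soil_depth effective rooting depth, m.
#' @param first_year_max_leafC,first_year_max_stemC seedling pools, kg-C/m2.
#' @param n_deposition,n_fixation nitrogen inputs, kg-N/m2/y.
#' @param sand,silt,clay soil texture percentages (must sum to 100).
#' @param co2_by_year named numeric vector of annual mean CO2 (ppm) keyed
#'   by calendar year; defaults to the bundled 1981-2010 global means.
#' @return An object of class `site_info`.
#' @export
site_info <- function(elevation = 1000, latitude = 34.27, albedo = 0.2,
                      soil_depth = 1.0,
                      first_year_max_leafC = 0.001,
                      first_year_max_stemC = 0.002,
                      n_deposition = 0.002, n_fixation = 0.0004,
                      sand = 5, silt = 68, clay = 27,
                      co2_by_year = co2_annual_1981_2010()) {
  if (abs(sand + silt + clay - 100) > 1e-6)
    stop("sand + silt + clay must equal 100")
  structure(list(
    elevation = elevation, latitude = latitude, albedo = albedo,
    soil_depth = soil_depth,
    first_year_max_leafC = first_year_max_leafC,
    first_year_max_stemC = first_year_max_stemC,
    n_deposition = n_deposition, n_fixation = n_fixation,
    sand = sand, silt = silt, clay = clay,
    co2_by_year = co2_by_year), class = "site_info")
}

#' @export
print.site_info <- function(x, ...) {
  cat(sprintf("<site_info> %g m a.s.l., %g degN, texture %g/%g/%g (sand/silt/clay)\n",
              x$elevation, x$latitude, x$sand, x$silt, x$clay))
  invisible(x)
}

#' Bundled global annual mean atmospheric CO2, 1981-2010
#'
#' Annual global mean CO2 mole fractions (ppm) for 1981-2010, used as the
#' default forcing CO2 record. Values are the NOAA marine-surface global
#' means rounded to 0.1 ppm.
#'
#' @return Named numeric vector (names are calendar years).
#' @export
co2_annual_1981_2010 <- function() {
  c(`1981` = 340.1, `1982` = 341.4, `1983` = 343.0, `1984` = 344.6,
    `1985` = 346.0, `1986` = 347.4, `1987` = 349.2, `1988` = 351.6,
    `1989` = 353.1, `1990` = 354.4, `1991` = 355.6, `1992` = 356.4,
    `1993` = 357.1, `1994` = 358.8, `1995` = 360.8, `1996` = 362.6,
    `1997` = 363.7, `1998` = 366.7, `1999` = 368.4, `2000` = 369.5,
    `2001` = 371.1, `2002` = 373.2, `2003` = 375.8, `2004` = 377.5,
    `2005` = 379.8, `2006` = 381.9, `2007` = 383.8, `2008` = 385.6,
    `2009` = 387.4, `2010` = 389.9)
}

# site list with only scalar fields, for the C++ engine
site_for_engine <- function(site) {
  site[c("elevation", "latitude", "albedo", "soil_depth",
         "first_year_max_leafC", "first_year_max_stemC",
         "n_deposition", "n_fixation", "sand", "silt", "clay")]
}

#' Soil water holding capacity of a site
#'
#' Bucket capacity implied by the site's texture and effective depth
#' (saturated volumetric water content from the sand fraction).
#'
#' @param site a [site_info()] object.
#' @return capacity in kg H2O / m2.
#' @export
soil_water_capacity <- function(site) {
  vwc_sat <- 0.489 - 0.00126 * site$sand
  site$soil_depth * vwc_sat * 1000
}
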