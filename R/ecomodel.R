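#' Farquhar assimilation rates at a known intercellular CO2
#'
#' `Ac = Vcmax (Ci - Gamma*) / (Ci + Kc (1 + O2/Ko)) - Rd` (carboxylation
#' limited), `Aj = J (Ci - Gamma*) / (4.5 Ci + 10.5 Gamma*) - Rd`
#' (RuBP-regeneration limited), and `A = min(Ac, Aj)`.
#'
#' @param vcmax maximum carboxylation rate, umol CO2 m-2 s-1.
#' @param j actual electron transport rate, umol m-2 s-1.
#' @param ci intercellular CO2 partial pressure, Pa.
#' @param gamma_star CO2 compensation point without photorespiration, Pa.
#' @param kc,ko Michaelis constants for CO2 and O2, Pa.
#' @param o2 O2 partial pressure, Pa.
#' @param rd day respiration, umol m-2 s-1.
#' @return named vector `A`, `Ac`, `Aj` (umol CO2 m-2 s-1; may be
#'   negative).
#' @export
farquhar_a <- function(vcmax, j, ci, gamma_star, kc, ko, o2, rd) {
  .farquhar_cpp(vcmax, j, ci, gamma_star, kc, ko, o2, rd)
}

#' Maximum carboxylation rate from leaf nitrogen
#'
#' `Vcmax = lnc * flnr * fnr * act` with `fnr = 7.16` kg Rubisco per kg of
#' Rubisco nitrogen.
#'
#' @param lnc leaf N per unit projected sunlit leaf area, kg-N/m2.
#' @param flnr fraction of leaf N in Rubisco.
#' @param act Rubisco activity, umol CO2 kg-Rubisco-1 s-1.
#' @return Vcmax, umol CO2 m-2 s-1.
#' @export
vcmax_from_leafn <- function(lnc, flnr, act) {
  stopifnot(lnc >= 0, flnr >= 0, act >= 0)
  lnc * flnr * 7.16 * act
}

#' Stomatal conductance under environmental stress
#'
#' Scales the maximum stomatal conductance by multipliers in [0, 1] for
#' light (hyperbolic in PPFD), soil water potential (linear ramp between
#' `lwp_start` and `lwp_final`), freezing night temperature (ramp between
#' -8 and 0 degrees C) and vapour pressure deficit (1 below `vpd_start`,
#' 0 above `vpd_final`, linear between).
#'
#' @param gsmax maximum stomatal conductance, m/s.
#' @param ppfd photosynthetic photon flux density, umol m-2 s-1.
#' @param soil_psi soil water potential, MPa.
#' @param tmin daily minimum temperature, degrees C.
#' @param vpd vapour pressure deficit, Pa.
#' @param params an [ecophys_params()] (ramp endpoints).
#' @return list with `g` (m/s) and the four multipliers.
#' @export
stomatal_g <- function(gsmax, ppfd, soil_psi, tmin, vpd,
                       params = ecophys_params()) {
  stopifnot(gsmax > 0)
  m <- .stomatal_mult_cpp(ppfd, soil_psi, tmin, vpd, params$ppfd_half,
                          params$lwp_start, params$lwp_final,
                          params$tmin_lo, params$tmin_hi,
                          params$vpd_start, params$vpd_final)
  list(g = gsmax * prod(m), multipliers = m)
}

#' Solve the coupled supply-demand system for Ci and A
#'
#' Substitutes the supply equation `A = g (Ca - Ci)` into each Farquhar
#' limitation, solves the resulting quadratic for the admissible root, and
#' returns the branch with the smaller assimilation (`A = min` of the two
#' branch solutions).
#'
#' @param g leaf-scale CO2 conductance, umol m-2 s-1 Pa-1.
#' @param ca atmospheric CO2 partial pressure, Pa.
#' @inheritParams farquhar_a
#' @return named vector `ci` (Pa) and `A` (umol m-2 s-1).
#' @export
solve_ci <- function(g, ca, vcmax, j, gamma_star, kc, ko, o2, rd) {
  if (g < 0) stop("g must be nonnegative")
  if (ca <= gamma_star) stop("ca must exceed gamma_star")
  .solve_ci_cpp(g, ca, vcmax, j, gamma_star, kc, ko, o2, rd)
}

#' Initial model state at planting
#'
#' Seedling pools sized from the site's first-year maxima: the transfer
#' pool holds enough carbon to express the first-year leaf (plus the
#' paired fine root and its growth respiration) during the first transfer
#' phase; stems start at the first-year stem carbon. Soil pools come from
#' a spin-up state when given.
#'
#' @param site a [site_info()].
#' @param params an [ecophys_params()].
#' @param soil optional named vector (a `final_state` from [spin_up()])
#'   whose litter/soil/N/water pools seed the run.
#' @return named numeric state vector.
#' @export
initial_state <- function(site, params = ecophys_params(), soil = NULL) {
  st <- empty_state()
  denom <- if (isTRUE(params$woody)) {
    1 + params$frc_lc + params$sc_lc * (1 + params$crc_sc)
  } else 1 + params$frc_lc
  st["transferC"] <- site$first_year_max_leafC * denom *
    (1 + params$growth_resp_frac)
  st["livestemC"] <- params$live_wood_frac * site$first_year_max_stemC
  st["deadstemC"] <- (1 - params$live_wood_frac) * site$first_year_max_stemC
  cap <- soil_water_capacity(site)
  st["soil_water"] <- 0.7 * cap
  st["soilC"] <- 4; st["soilN"] <- 0.4; st["sminN"] <- 0.05
  if (!is.null(soil)) {
    pools <- c("litr_lab", "litr_cel", "litr_lig", "cwdC", "soilC",
               "litrN", "cwdN", "soilN", "sminN", "soil_water")
    st[pools] <- soil[pools]
  }
  st
}

empty_state <- function() {
  nm <- c("leafC", "frootC", "livestemC", "deadstemC", "livecrootC",
          "deadcrootC", "storageC", "transferC", "litr_lab", "litr_cel",
          "litr_lig", "cwdC", "soilC", "litrN", "cwdN", "soilN", "sminN",
          "soil_water", "cum_fire", "cum_harvest")
  stats::setNames(numeric(length(nm)), nm)
}

# one met row (named numeric) in engine order from a daily_climate row
met_row <- function(climate_row) {
  as.numeric(climate_row[c("tmax", "tmin", "tday", "tavg", "tsoil",
                           "prcp_cm", "vpd", "srad", "daylength", "co2",
                           "phase", "days_left", "onset")])
}

#' Advance the model by one day
#'
#' Composes canopy photosynthesis, maintenance respiration, allocation,
#' phenology transfer/litterfall, turnover/mortality/fire, the
#' decomposition cascade and the bucket water balance. The step is pure:
#' identical state and forcing give identical output, and the carbon
#' balance closes exactly (change in total pool carbon equals
#' `gpp - maint_resp - growth_resp - heterotrophic_resp - fire - harvest`).
#'
#' @param state named state vector (see [initial_state()]).
#' @param climate_day one row of a `daily_climate` data.frame.
#' @param params an [ecophys_params()].
#' @param site a [site_info()].
#' @return list with the new `state` and the named `fluxes` vector.
#' @export
step_day <- function(state, climate_day, params, site) {
  .bgc_step_cpp(as.numeric(state), met_row(climate_day), unclass(params),
                site_for_engine(site))
}

#' Run the stand model over whole years
#'
#' Runs the daily model over `years` 365-day years (recycling the forcing
#' cyclically if it is shorter) and reports the annual-maximum aboveground
#' woody (AC = live + dead stem), belowground (BC = coarse roots + fine
#' roots) and leaf (LC) carbon densities per stand age, along with soil
#' and litter pools and annual fluxes.
#'
#' @param params an [ecophys_params()].
#' @param site a [site_info()].
#' @param forcing a `daily_climate` data.frame from [prepare_forcing()].
#' @param years number of years to simulate.
#' @param init optional initial state; defaults to [initial_state()].
#' @return list with `series` (a `carbon_density_series`), `annual`
#'   (full annual summary data.frame) and `final_state`.
#' @export
run_years <- function(params, site, forcing, years, init = NULL) {
  stopifnot(inherits(params, "ecophys_params"))
  if (years == 0) {
    return(list(series = carbon_density_series(integer(0), numeric(0),
                                               numeric(0), numeric(0)),
                annual = data.frame(), final_state = init))
  }
  if (is.null(init)) init <- initial_state(site, params)
  out <- .bgc_run_cpp(forcing_matrix(forcing), unclass(params),
                      site_for_engine(site), as.numeric(init), years)
  ann <- as.data.frame(out$annual)
  series <- carbon_density_series(ann$year, ann$AC, ann$BC, ann$LC)
  list(series = series, annual = ann, final_state = out$final_state)
}

#' Spin up soil carbon and nitrogen under managed annual grass
#'
#' Runs the model with an annual-grass parameter set (no woody pools,
#' yearly removal of part of the aboveground biomass, fertilizer N) for
#' up to `years` years and reports the quasi-steady soil state.
#' Convergence requires the mean annual change of soil carbon over the
#' final 100 years to be below `tol` of its mean.
#'
#' @param site a [site_info()].
#' @param forcing a `daily_climate` (recycled cyclically).
#' @param grass a grass [ecophys_params()]; defaults to [grass_params()]
#'   with 0.03 kg-N/m2/y fertilization and 50% harvest.
#' @param years spin-up length in years.
#' @param tol relative drift tolerance over the final 100 years.
#' @return list with `state` (final state vector), `soilC`, `converged`,
#'   `drift` (relative drift) and the annual `soilC` trajectory.
#' @export
spin_up <- function(site, forcing, grass = grass_params(), years = 6000,
                    tol = 0.005) {
  st <- empty_state()
  st["transferC"] <- 0.02
  st["soil_water"] <- 0.7 * soil_water_capacity(site)
  st["sminN"] <- 0.05
  out <- .bgc_run_cpp(forcing_matrix(forcing), unclass(grass),
                      site_for_engine(site), as.numeric(st), years)
  ann <- as.data.frame(out$annual)
  soil <- ann$soilC
  nlast <- min(100, years - 1)
  drift <- if (nlast >= 2) {
    tail_soil <- soil[(years - nlast):years]
    abs(mean(diff(tail_soil))) / max(mean(tail_soil), 1e-12)
  } else Inf
  converged <- is.finite(drift) && drift < tol
  if (!converged)
    warning(sprintf("spin-up not converged after %d years (drift %.3g)",
                    years, drift))
  list(state = out$final_state, soilC = soil[years], converged = converged,
       drift = drift, soilC_annual = soil)
}
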