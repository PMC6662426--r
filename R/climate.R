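#' Saturation vapour pressure of water (Tetens)
#'
#' Tetens-type formula over liquid water,
#' `es(T) = 610.78 * exp(17.269 T / (T + 237.3))` Pa. At 0 degrees C this
#' gives 610.78 Pa, within 2% of the commonly quoted 611 Pa anchor.
#'
#' @param temp_c air temperature, degrees C.
#' @return saturation vapour pressure, Pa.
#' @export
saturation_vp <- function(temp_c) {
  610.78 * exp(17.269 * temp_c / (temp_c + 237.3))
}

#' Daylength from standard solar geometry
#'
#' @param latitude_deg latitude in degrees north.
#' @param doy day of year, 1-365.
#' @return daylength in seconds.
#' @export
daylength_s <- function(latitude_deg, doy) {
  lat <- latitude_deg * pi / 180
  decl <- -23.45 * pi / 180 * cos(2 * pi * (doy + 10) / 365)
  x <- -tan(lat) * tan(decl)
  x <- pmin(1, pmax(-1, x))
  86400 * acos(x) / pi
}

# daylight-average top-of-atmosphere shortwave flux, W/m2
toa_daylight_avg <- function(latitude_deg, doy) {
  lat <- latitude_deg * pi / 180
  decl <- -23.45 * pi / 180 * cos(2 * pi * (doy + 10) / 365)
  x <- pmin(1, pmax(-1, -tan(lat) * tan(decl)))
  h0 <- acos(x)                       # half-day angle, radians
  coszbar <- ifelse(h0 > 0,
                    sin(lat) * sin(decl) + cos(lat) * cos(decl) * sin(h0) / h0,
                    0)
  1360 * pmax(0, coszbar)
}

#' Estimate daytime temperature, VPD, shortwave radiation and daylength
#'
#' A deliberately small estimator in the spirit of mountain-microclimate
#' simulators: daytime temperature is `Tavg + 0.45 (Tmax - Tavg)`;
#' dewpoint is taken as Tmin so `VPD = es(Tday) - es(Tmin)` (floored at
#' zero); daylength comes from solar geometry; and daylight-average
#' shortwave is top-of-atmosphere radiation times a transmittance that
#' grows with the diurnal temperature range (`0.16 sqrt(Tmax - Tmin)`,
#' capped at 0.75) and is reduced by 25% on wet days. It is not a full
#' MTCLIM implementation (no snow correction, horizon shading or
#' slope/aspect radiation).
#'
#' @param tmax,tmin daily maximum/minimum air temperature, degrees C.
#' @param precip_cm daily precipitation, cm (wet-day flag for SRAD).
#' @param latitude_deg site latitude, degrees north.
#' @param elevation_m site elevation, m (kept for interface compatibility;
#'   the transmittance model does not use it).
#' @param doy day of year (1-365), recycled against `tmax`.
#' @param tday_coef weighting of Tmax in the daytime temperature.
#' @return A data.frame with columns `tday`, `tavg`, `vpd`, `srad`,
#'   `daylength`.
#' @export
estimate_vpd_srad <- function(tmax, tmin, precip_cm, latitude_deg,
                              elevation_m = 0, doy, tday_coef = 0.45) {
  if (any(tmax < tmin)) stop("tmax must be >= tmin for every day")
  tavg <- (tmax + tmin) / 2
  tday <- tavg + tday_coef * (tmax - tavg)
  vpd <- pmax(0, saturation_vp(tday) - saturation_vp(tmin))
  dl <- daylength_s(latitude_deg, doy)
  trans <- pmin(0.75, 0.16 * sqrt(pmax(0, tmax - tmin)))
  trans <- trans * ifelse(precip_cm > 0, 0.75, 1)
  srad <- toa_daylight_avg(latitude_deg, doy) * trans
  data.frame(tday = tday, tavg = tavg, vpd = vpd, srad = srad,
             daylength = dl)
}

#' Read a GSOD-like daily weather CSV
#'
#' Expects columns `date`, `tmax`, `tmin`, `prcp`. Units convert to
#' degrees C and cm on request; Feb 29 records are dropped so every year
#' has 365 days; missing values (NA) are filled by linear interpolation
#' across gaps of at most `max_gap` days, longer gaps are an error naming
#' the dates.
#'
#' @param path CSV file path.
#' @param temp_unit `"C"` or `"F"`.
#' @param prcp_unit `"cm"`, `"mm"` or `"in"`.
#' @param max_gap longest gap (days) filled by interpolation.
#' @return data.frame with `date`, `tmax`, `tmin`, `prcp_cm` and one row
#'   per non-leap calendar day.
#' @export
read_gsod_csv <- function(path, temp_unit = c("C", "F"),
                          prcp_unit = c("cm", "mm", "in"), max_gap = 3) {
  temp_unit <- match.arg(temp_unit)
  prcp_unit <- match.arg(prcp_unit)
  if (!file.exists(path)) stop("weather file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmax", "tmin", "prcp")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("weather file lacks column(s): ",
                         paste(miss, collapse = ", "))
  d$date <- as.Date(d$date)
  d <- d[order(d$date), ]
  d <- d[!(format(d$date, "%m-%d") == "02-29"), ]
  if (temp_unit == "F") {
    d$tmax <- (d$tmax - 32) * 5 / 9
    d$tmin <- (d$tmin - 32) * 5 / 9
  }
  d$prcp_cm <- switch(prcp_unit, cm = d$prcp, mm = d$prcp / 10,
                      "in" = d$prcp * 2.54)
  for (col in c("tmax", "tmin", "prcp_cm")) {
    v <- d[[col]]
    if (anyNA(v)) {
      r <- rle(is.na(v))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      long <- which(r$values & r$lengths > max_gap)
      if (length(long)) {
        i <- long[1]
        stop(sprintf("gap of %d days in '%s' (%s to %s) exceeds %d-day limit",
                     r$lengths[i], col, d$date[starts[i]], d$date[ends[i]],
                     max_gap))
      }
      d[[col]] <- stats::approx(seq_along(v)[!is.na(v)], v[!is.na(v)],
                                xout = seq_along(v), rule = 2)$y
    }
  }
  d$prcp_cm <- pmax(0, d$prcp_cm)
  bad <- d$tmax < d$tmin
  if (any(bad)) {   # occasional station glitches: swap
    tmp <- d$tmax[bad]; d$tmax[bad] <- d$tmin[bad]; d$tmin[bad] <- tmp
  }
  d[c("date", "tmax", "tmin", "prcp_cm")]
}

#' Build the model's daily forcing from raw weather
#'
#' Derives daytime temperature, VPD, SRAD and daylength from raw
#' Tmax/Tmin/precipitation via [estimate_vpd_srad()], attaches the annual
#' CO2 record, a 21-day running-mean soil temperature proxy, and a
#' temperature-threshold phenology: the growing season opens when the
#' trailing 10-day mean of Tavg first exceeds `t_thresh` (after day 32)
#' and closes when it first drops below `t_thresh` after midsummer. The
#' first `transfer_frac` of the season is the storage-transfer phase and
#' the final `litterfall_frac` the senescence phase.
#'
#' @param weather data.frame with `tmax`, `tmin`, `prcp_cm` (and
#'   optionally `date`), one row per day, whole 365-day years.
#' @param site a [site_info()] object.
#' @param params an [ecophys_params()] object (phenology fractions).
#' @param t_thresh growing-season temperature threshold, degrees C.
#' @param years_co2 calendar years to map onto the CO2 record; defaults to
#'   the names of `site$co2_by_year` recycled over the record.
#' @return A `daily_climate` data.frame with one row per day.
#' @export
prepare_forcing <- function(weather, site, params = ecophys_params(),
                            t_thresh = 5, years_co2 = NULL) {
  n <- nrow(weather)
  if (n %% 365 != 0) stop("weather must cover whole 365-day years")
  ny <- n / 365
  doy <- rep(1:365, ny)
  est <- estimate_vpd_srad(weather$tmax, weather$tmin, weather$prcp_cm,
                           site$latitude, site$elevation, doy)
  co2v <- site$co2_by_year
  if (is.null(years_co2)) {
    co2 <- rep(unname(co2v)[((seq_len(ny) - 1) %% length(co2v)) + 1],
               each = 365)
  } else {
    if (length(years_co2) != ny) stop("years_co2 must have one entry per year")
    idx <- match(as.character(years_co2), names(co2v))
    if (anyNA(idx)) stop("co2_by_year lacks year(s): ",
                         paste(years_co2[is.na(idx)], collapse = ", "))
    co2 <- rep(unname(co2v)[idx], each = 365)
  }
  # soil temperature proxy: trailing 21-day mean of Tavg, with circular
  # initialisation (the record is used cyclically, so the first days of
  # the record continue from its end)
  tavg <- est$tavg
  tsoil <- stats::filter(c(utils::tail(tavg, 20), tavg), rep(1 / 21, 21),
                         sides = 1)
  tsoil <- as.numeric(tsoil)[-(1:20)]

  ph <- phenology_flags(tavg, ny, params$transfer_frac,
                        params$litterfall_frac, t_thresh)
  out <- data.frame(
    year = rep(seq_len(ny), each = 365), doy = doy,
    tmax = weather$tmax, tmin = weather$tmin, tday = est$tday,
    tavg = tavg, tsoil = tsoil, prcp_cm = weather$prcp_cm,
    vpd = est$vpd, srad = est$srad, daylength = est$daylength,
    co2 = co2, phase = ph$phase, days_left = ph$days_left,
    onset = ph$onset)
  class(out) <- c("daily_climate", "data.frame")
  out
}

# phenophase codes per day: 0 dormant, 1 transfer, 2 growth, 3 senescence
phenology_flags <- function(tavg, ny, transfer_frac, litterfall_frac,
                            t_thresh) {
  phase <- integer(length(tavg))
  days_left <- numeric(length(tavg))
  onset_flag <- numeric(length(tavg))
  run10 <- as.numeric(stats::filter(c(utils::tail(tavg, 9), tavg),
                                    rep(0.1, 10), sides = 1))[-(1:9)]
  for (y in seq_len(ny)) {
    i0 <- (y - 1) * 365
    r <- run10[i0 + (1:365)]
    on <- which(r[32:200] > t_thresh)
    on <- if (length(on)) 31 + on[1] else 120
    off <- which(r[201:365] < t_thresh)
    off <- if (length(off)) 200 + off[1] else 330
    if (off <= on + 20) { on <- 120; off <- 300 }
    L <- off - on + 1
    n_tr <- max(1, round(transfer_frac * L))
    n_sn <- max(1, round(litterfall_frac * L))
    ph <- integer(365)
    dl <- numeric(365)
    ph[on:(on + n_tr - 1)] <- 1
    dl[on:(on + n_tr - 1)] <- n_tr:1
    sn0 <- off - n_sn + 1
    ph[(on + n_tr):(sn0 - 1)] <- 2
    ph[sn0:off] <- 3
    dl[sn0:off] <- n_sn:1
    phase[i0 + (1:365)] <- ph
    days_left[i0 + (1:365)] <- dl
    onset_flag[i0 + on] <- 1
  }
  list(phase = phase, days_left = days_left, onset = onset_flag)
}

#' Rotate a whole-year climate record cyclically
#'
#' Output year `j` is input year `(start_year_index + j) mod N`; used to
#' build the start-year ensemble for projections. Only the weather is
#' rotated: a `co2` column, being a calendar forcing tied to the project
#' year rather than part of the climate anomaly, keeps its original
#' order.
#'
#' @param climate a `daily_climate` data.frame (or any data.frame with
#'   whole 365-day years).
#' @param start_year_index 0-based index of the input year that becomes
#'   the first output year.
#' @return data.frame of the same shape.
#' @export
cyclic_forcing <- function(climate, start_year_index) {
  n <- nrow(climate)
  if (n %% 365 != 0) stop("climate must cover whole 365-day years")
  ny <- n / 365
  if (start_year_index < 0 || start_year_index >= ny)
    stop("start_year_index must be in [0, ", ny - 1, "]")
  ord <- ((start_year_index + seq_len(ny) - 1) %% ny)
  rows <- unlist(lapply(ord, function(y) y * 365 + 1:365))
  out <- climate[rows, , drop = FALSE]
  rownames(out) <- NULL
  if ("year" %in% names(out)) out$year <- rep(seq_len(ny), each = 365)
  if ("co2" %in% names(out)) out$co2 <- climate$co2
  out
}

# engine forcing matrix from a daily_climate data.frame
forcing_matrix <- function(climate) {
  need <- c("tmax", "tmin", "tday", "tavg", "tsoil", "prcp_cm", "vpd",
            "srad", "daylength", "co2", "phase", "days_left", "onset")
  miss <- setdiff(need, names(climate))
  if (length(miss)) stop("forcing lacks column(s): ",
                         paste(miss, collapse = ", "))
  as.matrix(climate[need])
}
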