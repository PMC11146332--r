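# FAO-56 Penman-Monteith daily engine (Allen et al. 1998 conventions).
# All radiation terms in MJ m-2 d-1, pressures in kPa, temperatures in deg C.

GSC <- 0.0820          # solar constant, MJ m-2 min-1
STEFAN_BOLTZMANN <- 4.903e-9  # MJ K-4 m-2 d-1
ALBEDO <- 0.23         # reference grass surface

#' Saturation vapour pressure
#'
#' `e0(T) = 0.6108 * exp(17.27 T / (T + 237.3))`, strictly increasing in T.
#'
#' @param temp_c Air temperature, deg C (vectorised).
#' @return Saturation vapour pressure, kPa.
#' @export
saturation_vapour_pressure <- function(temp_c) {
  stopifnot(all(temp_c > -60 & temp_c < 70))
  0.6108 * exp(17.27 * temp_c / (temp_c + 237.3))
}

#' Slope of the saturation vapour-pressure curve
#' @param temp_c Daily mean air temperature, deg C.
#' @return Delta, kPa per deg C.
#' @export
svp_slope <- function(temp_c) {
  4098 * saturation_vapour_pressure(temp_c) / (temp_c + 237.3)^2
}

#' Psychrometric constant from elevation
#'
#' Atmospheric pressure `P = 101.3 ((293 - 0.0065 z) / 293)^5.26` kPa, then
#' `gamma = 0.000665 P`. Decreasing in elevation.
#'
#' @param elevation Metres above sea level (>= -430).
#' @return gamma, kPa per deg C.
#' @export
psychrometric_constant <- function(elevation) {
  stopifnot(all(elevation >= -430))
  pressure <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
  0.000665 * pressure
}

#' Saturation and actual vapour pressure from temperature extremes and mean RH
#'
#' `es` is the mean of the saturation pressures at the daily extremes;
#' `ea = rh_mean/100 * es`, so `ea <= es` always.
#'
#' @param tmin,tmax Daily temperature extremes, deg C (`tmin <= tmax`).
#' @param rh_mean Daily mean relative humidity, percent in [0, 100].
#' @return List with numeric elements `es` and `ea` (kPa).
#' @export
vapour_pressure_terms <- function(tmin, tmax, rh_mean) {
  stopifnot(all(tmin <= tmax), all(rh_mean >= 0 & rh_mean <= 100))
  es <- (saturation_vapour_pressure(tmax) + saturation_vapour_pressure(tmin)) / 2
  list(es = es, ea = rh_mean / 100 * es)
}

#' Extraterrestrial radiation
#'
#' Daily top-of-atmosphere radiation from the inverse relative earth-sun
#' distance, solar declination and sunset hour angle.
#'
#' @param doy Day of year, 1..366 (vectorised).
#' @param latitude Decimal degrees, positive north.
#' @return Ra, MJ m-2 d-1.
#' @export
extraterrestrial_radiation <- function(doy, latitude) {
  stopifnot(all(doy >= 1 & doy <= 366))
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  decl <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  # clamp for polar day/night where -tan(phi)tan(decl) leaves [-1, 1]
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(decl))))
  24 * 60 / pi * GSC * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
}

#' Clear-sky solar radiation ceiling
#'
#' `Rso = (0.75 + 2e-5 z) Ra`; the maximum radiation reaching the surface
#' under cloudless sky.
#'
#' @inheritParams extraterrestrial_radiation
#' @param elevation Metres above sea level.
#' @return Rso, MJ m-2 d-1.
#' @export
clear_sky_radiation <- function(doy, latitude, elevation) {
  (0.75 + 2e-5 * elevation) * extraterrestrial_radiation(doy, latitude)
}

#' Daily net radiation budget
#'
#' Net shortwave `Rns = (1 - 0.23) sr`; net longwave `Rnl` by the
#' Stefan-Boltzmann form with humidity correction `0.34 - 0.14 sqrt(ea)` and
#' cloudiness factor `1.35 (sr/Rso) - 0.35`, the ratio clamped to
#' [0.05, 1] to avoid degenerate overcast/clear blowup; `Rn = Rns - Rnl`.
#' `sr` exceeding `Rso` by more than `sr_tol` triggers a warning (the ratio
#' is clamped regardless).
#'
#' @param sr Measured solar radiation, MJ m-2 d-1.
#' @param doy Day of year.
#' @param latitude Decimal degrees, positive north.
#' @param elevation Metres above sea level.
#' @param tmin,tmax Daily temperature extremes, deg C.
#' @param ea Actual vapour pressure, kPa.
#' @param sr_tol Tolerance (MJ m-2 d-1) before an `sr > Rso` warning; default 0.1.
#' @return List with elements `Ra_extra`, `Rso`, `Rns`, `Rnl`, `Rn`
#'   (vectorised over the inputs).
#' @export
radiation_budget <- function(sr, doy, latitude, elevation, tmin, tmax, ea,
                             sr_tol = 0.1) {
  stopifnot(all(sr >= 0))
  ra <- extraterrestrial_radiation(doy, latitude)
  rso <- (0.75 + 2e-5 * elevation) * ra
  if (any(sr > rso + sr_tol)) {
    warning(sprintf("%d record(s) with sr above the clear-sky ceiling Rso",
                    sum(sr > rso + sr_tol)), call. = FALSE)
  }
  rns <- (1 - ALBEDO) * sr
  ratio <- pmin(1, pmax(0.05, sr / rso))
  rnl <- STEFAN_BOLTZMANN * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(ea)) * (1.35 * ratio - 0.35)
  list(Ra_extra = ra, Rso = rso, Rns = rns, Rnl = rnl, Rn = rns - rnl)
}

#' Daily FAO-56 Penman-Monteith reference evapotranspiration
#'
#' The combination equation for a well-watered reference grass surface:
#' \deqn{ET_0 = \frac{0.408\,\Delta\,(R_n - G) +
#'   \gamma \frac{900}{T+273} u_2 (e_s - e_a)}
#'   {\Delta + \gamma (1 + 0.34\,u_2)}}
#' with daily soil heat flux `G = 0`, `T` the mean of the daily extremes,
#' `ea` from mean relative humidity, and `Rn` from [radiation_budget()].
#' Wind speed is taken as measured at 2 m; no height conversion is applied.
#' Negative values (possible on strongly negative net-radiation days) are
#' reported as computed unless `floor_negative = TRUE`.
#'
#' @param series A [weather_series()] carrying all five variables.
#' @param site A [site_meta()]; defaults to the series' own site.
#' @param floor_negative If `TRUE`, negative ET0 is floored at 0.
#' @return Numeric vector of ET0 in mm per day, one value per record.
#' @examples
#' s <- generate_synthetic_weather(10, site_meta("demo", 26.4, 80), seed = 1)
#' reference_et0(s)
#' @export
reference_et0 <- function(series, site = attr(series, "site"),
                          floor_negative = FALSE) {
  stopifnot(inherits(series, "weather_series"), inherits(site, "site_meta"))
  missing_vars <- setdiff(WEATHER_VARS, names(series))
  if (length(missing_vars)) {
    stop("reference ET0 needs all five variables; missing: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  doy <- as.integer(format(series$date, "%j"))
  et0_penman_monteith(series$tmin, series$tmax, series$rh, series$ws,
                      series$sr, doy, site$latitude, site$elevation,
                      floor_negative = floor_negative)
}

#' Penman-Monteith ET0 on raw vectors
#'
#' Low-level vectorised form of [reference_et0()] for callers that do not
#' hold a `weather_series`.
#'
#' @param tmin,tmax Temperature extremes, deg C.
#' @param rh Mean relative humidity, percent.
#' @param ws Wind speed at 2 m, m/s.
#' @param sr Solar radiation, MJ m-2 d-1.
#' @param doy Day of year.
#' @param latitude,elevation Site coordinates.
#' @param floor_negative If `TRUE`, floor negative ET0 at 0.
#' @return ET0, mm per day.
#' @export
et0_penman_monteith <- function(tmin, tmax, rh, ws, sr, doy, latitude,
                                elevation, floor_negative = FALSE) {
  tmean <- (tmin + tmax) / 2
  delta <- svp_slope(tmean)
  gamma <- psychrometric_constant(elevation)
  vp <- vapour_pressure_terms(tmin, tmax, rh)
  rad <- radiation_budget(sr, doy, latitude, elevation, tmin, tmax, vp$ea)
  g <- 0  # daily soil heat flux
  et0 <- (0.408 * delta * (rad$Rn - g) +
            gamma * 900 / (tmean + 273) * ws * (vp$es - vp$ea)) /
    (delta + gamma * (1 + 0.34 * ws))
  if (floor_negative) et0 <- pmax(0, et0)
  et0
}
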