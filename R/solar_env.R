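#' Solar declination
#'
#' Harmonic (FAO-56) solar declination,
#' `0.409 sin(2 pi doy / 365 - 1.39)`: accurate to ~0.3 degrees and exactly
#' antisymmetric half a year apart, which keeps daylength hemispherically
#' symmetric.
#'
#' @param doy day of year (1-366).
#' @return Declination (radians).
#' @export
solar_declination <- function(doy) {
  0.409 * sin(2 * pi * doy / 365 - 1.39)
}

#' Daylength from latitude and day of year
#'
#' Sunrise-to-sunset duration from the sunset hour angle
#' `ws = acos(-tan(lat) tan(decl))`, clipped to 0 (polar night) or 86400 s
#' (polar day) where the sun never rises or sets.
#'
#' @param lat latitude (degrees, -90..90), vector allowed.
#' @param doy day of year (1-366), vector allowed.
#' @return Daylength (s).
#' @export
#' @examples
#' daylength(45, 172) / 3600 # hours near the June solstice
daylength <- function(lat, doy) {
  if (any(abs(lat) > 90)) stop("latitude must be within [-90, 90]")
  decl <- solar_declination(doy)
  x <- -tan(lat * pi / 180) * tan(decl)
  ws <- acos(pmin(pmax(x, -1), 1))
  86400 * ws / pi
}

# Sunset hour angle (radians), clipped for polar cases
sunset_hour_angle <- function(lat, doy) {
  x <- -tan(lat * pi / 180) * tan(solar_declination(doy))
  acos(pmin(pmax(x, -1), 1))
}

#' Daily top-of-atmosphere shortwave radiation
#'
#' Extraterrestrial radiation on a horizontal surface integrated over the
#' day (FAO-56 formulation), used as the denominator of the clearness index.
#'
#' @inheritParams daylength
#' @return Radiation (MJ m-2 day-1).
#' @export
toa_radiation <- function(lat, doy) {
  phi <- lat * pi / 180
  decl <- solar_declination(doy)
  ws <- sunset_hour_angle(lat, doy)
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
}

#' Cosine of the solar zenith angle
#'
#' @inheritParams daylength
#' @param hour local solar time (h, 0-24; 12 is solar noon).
#' @return cos(zenith), negative when the sun is below the horizon.
#' @export
cos_zenith <- function(lat, doy, hour) {
  phi <- lat * pi / 180
  decl <- solar_declination(doy)
  h <- pi * (hour - 12) / 12
  sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(h)
}

#' Representative daytime solar zenith angle
#'
#' Radiation-weighted (cosine-weighted) daytime mean of the solar zenith:
#' `cos(theta_rep) = integral(cos^2 theta) / integral(cos theta)` over the
#' daylight period, evaluated analytically from the hour-angle integrals.
#' This is the single zenith used for the daily sunlit/shaded partition.
#'
#' @inheritParams daylength
#' @return Representative zenith angle (degrees); `NA` during polar night.
#' @export
representative_zenith <- function(lat, doy) {
  phi <- lat * pi / 180
  decl <- solar_declination(doy)
  ws <- sunset_hour_angle(lat, doy)
  a <- sin(phi) * sin(decl)
  b <- cos(phi) * cos(decl)
  i1 <- a * ws + b * sin(ws)                               # int cos(theta) dh
  i2 <- a^2 * ws + 2 * a * b * sin(ws) + b^2 * (ws / 2 + sin(2 * ws) / 4)
  ct <- ifelse(ws > 0 & i1 > 0, i2 / i1, NA_real_)
  acos(pmin(pmax(ct, 0), 1)) * 180 / pi
}

#' Mean air temperature over the daylight period
#'
#' The photosynthesis-period temperature Tp: the daytime mean of a
#' sinusoidal diurnal temperature reconstruction with the minimum at sunrise
#' and the maximum `peak_lag_h` hours after mid-day,
#' `T(t) = tmin + (tmax - tmin) sin(pi (t - trise) / (D + 2 p))`
#' (Parton-Logan form), averaged analytically over `t` in `[trise, trise+D]`:
#' `Tp = tmin + (tmax - tmin) (D + 2p) / (pi D) (1 - cos(pi D / (D + 2p)))`.
#' With `method = "mean"` the arithmetic mean `(tmax + tmin)/2` is used
#' instead. The result always lies within `[tmin, tmax]`.
#'
#' @param tmax,tmin daily extreme air temperatures (degC), `tmax >= tmin`.
#' @param daylength daylight duration (s).
#' @param method `"sine"` (default) or `"mean"`.
#' @param peak_lag_h hours between mid-daylight and the temperature maximum.
#' @return Tp (degC).
#' @export
daytime_temperature <- function(tmax, tmin, daylength, method = c("sine", "mean"),
                                peak_lag_h = 1.8) {
  method <- match.arg(method)
  if (any(tmax < tmin)) stop("tmax must be >= tmin")
  if (method == "mean") return((tmax + tmin) / 2)
  d_h <- daylength / 3600
  per <- d_h + 2 * peak_lag_h
  frac <- ifelse(d_h > 0, (per / (pi * d_h)) * (1 - cos(pi * d_h / per)), 0.5)
  tmin + (tmax - tmin) * frac
}

# Diurnal temperature at hour-since-sunrise t_h (daytime branch of the
# sinusoid used by daytime_temperature); used by the synthetic generator.
diurnal_temperature <- function(tmax, tmin, t_h, daylength_h, peak_lag_h = 1.8) {
  per <- daylength_h + 2 * peak_lag_h
  tmin + (tmax - tmin) * sin(pi * t_h / per)
}

#' Saturation vapour pressure (Tetens, over water)
#'
#' @param t air temperature (degC).
#' @return Saturation vapour pressure (Pa).
#' @export
esat <- function(t) 610.78 * exp(17.27 * t / (t + 237.3))

#' Vapour pressure deficit from temperature and relative humidity
#'
#' @param t air temperature (degC).
#' @param rh relative humidity (%, 0-100).
#' @return VPD (Pa).
#' @export
vpd_from <- function(t, rh) {
  if (any(rh < 0 | rh > 100)) stop("rh must be within [0, 100] %")
  esat(t) * (1 - rh / 100)
}

#' VPD downregulation scalar
#'
#' Piecewise-linear humidity stress scalar: 1 below `vpd_min`, 0 above
#' `vpd_max`, and `(vpd_max - vpd) / (vpd_max - vpd_min)` in between. The
#' default breakpoints (650 and 4500 Pa) are the calibrated values shared by
#' all four vegetation types.
#'
#' @param vpd vapour pressure deficit (Pa), vector allowed.
#' @param vpd_max,vpd_min ramp breakpoints (Pa), `vpd_max > vpd_min > 0`.
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' f_vpd(c(500, 2575, 5000))
f_vpd <- function(vpd, vpd_max = 4500, vpd_min = 650) {
  if (!(vpd_max > vpd_min && vpd_min > 0)) {
    stop("need vpd_max > vpd_min > 0")
  }
  pmin(pmax((vpd_max - vpd) / (vpd_max - vpd_min), 0), 1)
}

#' Daily diffuse fraction of incident radiation
#'
#' Diffuse skylight fraction from the daily clearness index
#' `R = rg_daily / toa_radiation(lat, doy)`, using the quartic
#' clearness-index polynomial of the sunlit/shaded canopy literature
#' (configurable via `config$radiation$diffuse_poly`, lowest order first),
#' clipped to `config$radiation$diffuse_clip` (default \[0.13, 1\]; zero
#' radiation is fully diffuse).
#'
#' @inheritParams daylength
#' @param rg_daily daily global shortwave radiation (MJ m-2 day-1).
#' @param config configuration list, see [tlrhm_config()].
#' @return Diffuse fraction in `[0, 1]`.
#' @export
diffuse_fraction <- function(rg_daily, lat, doy, config = tlrhm_config()) {
  if (any(rg_daily < 0)) stop("rg_daily must be >= 0")
  n <- max(length(rg_daily), length(lat), length(doy))
  rg_daily <- rep_len(rg_daily, n)
  ra <- rep_len(toa_radiation(lat, doy), n)
  clearness <- numeric(n)
  clearness[ra > 0] <- pmin(rg_daily[ra > 0] / ra[ra > 0], 1)
  co <- config$radiation$diffuse_poly
  df <- drop(outer(clearness, seq_along(co) - 1, `^`) %*% co)
  clip <- config$radiation$diffuse_clip
  df <- pmin(pmax(df, clip[1]), clip[2])
  # no beam at all: fully diffuse, overriding the regression's intercept
  df[rg_daily == 0] <- 1
  df
}
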