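#' Configuration of the synthetic site-year generator
#'
#' Defines the study conditions a synthetic flux site emulates: a mid-latitude
#' seasonal climate, daily stochastic cloudiness, a growing-season LAI
#' phenology, and a prescribed "true" Vcmax,25 for parameter-recovery
#' experiments. All randomness is governed by `seed`.
#'
#' @param lat site latitude (degrees).
#' @param vegetation_type `"ENF"`, `"DBF"`, `"GRA"` or `"EBF"`.
#' @param true_vcmax25 Vcmax,25 (umol m-2 s-1) used by the half-hourly truth
#'   oracle.
#' @param lai_max peak leaf area index (m2 m-2).
#' @param lai_min leaf area index outside the growing season.
#' @param t_mean_annual annual mean air temperature (degC).
#' @param t_seasonal_amp seasonal half-amplitude of the daily mean (degC).
#' @param t_peak_doy day of year of the warmest daily mean.
#' @param diurnal_range tmax - tmin (degC); 0 gives constant-temperature
#'   days.
#' @param t_noise_sd day-to-day temperature noise s.d. (degC).
#' @param rh_base,rh_noise_sd mean relative humidity (%) and its daily noise.
#' @param cloudiness `"stochastic"` (daily clearness index drawn from a
#'   scaled Beta(3, 1.5) on `kt_range`) or `"clear"` (constant
#'   `max(kt_range)`).
#' @param kt_range clearness-index bounds for the stochastic draw.
#' @param diurnal_shape `"sine"` or `"sinesine"` half-hourly radiation
#'   profile.
#' @param year calendar year of the generated dates.
#' @param seed integer seed; the same configuration and seed give
#'   bit-identical output.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(lat = 45, vegetation_type = "DBF",
                         true_vcmax25 = 60, lai_max = 5, lai_min = 0.3,
                         t_mean_annual = 9, t_seasonal_amp = 12,
                         t_peak_doy = 200, diurnal_range = 8,
                         t_noise_sd = 1.5, rh_base = 75, rh_noise_sd = 6,
                         cloudiness = c("stochastic", "clear"),
                         kt_range = c(0.2, 0.72),
                         diurnal_shape = c("sine", "sinesine"),
                         year = 2005, seed = 1) {
  cloudiness <- match.arg(cloudiness)
  diurnal_shape <- match.arg(diurnal_shape)
  stopifnot(abs(lat) <= 66, true_vcmax25 > 0, lai_max > 0,
            lai_min >= 0, lai_min <= lai_max, diurnal_range >= 0,
            kt_range[1] > 0, kt_range[2] <= 1, kt_range[1] <= kt_range[2])
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

# growing-season double-logistic, normalised to [0, 1]
lai_phenology <- function(doy) {
  f <- 1 / (1 + exp(-0.08 * (doy - 125))) - 1 / (1 + exp(-0.08 * (doy - 280)))
  f / max(f)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic site-year
#'
#' Builds one year of half-hourly meteorology (PPFD following the configured
#' diurnal profile scaled by a daily stochastic clearness factor; air
#' temperature from a seasonal trend plus a sunrise-to-afternoon diurnal
#' sinusoid consistent with the day's extremes; constant-within-day relative
#' humidity) and aggregates it with [aggregate_halfhourly()] into the daily
#' driver table, so the daily drivers are exactly the aggregate of the
#' half-hourly record. Deterministic given `cfg$seed`.
#'
#' @param cfg [synth_config()] object.
#' @return List with `site` (a [site_year()]) and `halfhourly` (data.frame
#'   `date, hour, ppfd, t_air, rh`).
#' @export
generate_site_year <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    doy <- 1:365
    dates <- as.Date(paste0(cfg$year, "-01-01")) + doy - 1
    dl_h <- daylength(cfg$lat, doy) / 3600
    trise <- 12 - dl_h / 2

    t_day_mean <- cfg$t_mean_annual +
      cfg$t_seasonal_amp * cos(2 * pi * (doy - cfg$t_peak_doy) / 365) +
      stats::rnorm(365, 0, cfg$t_noise_sd)
    tmin <- t_day_mean - cfg$diurnal_range / 2
    tmax <- t_day_mean + cfg$diurnal_range / 2

    kt <- if (cfg$cloudiness == "clear") {
      rep(max(cfg$kt_range), 365)
    } else {
      cfg$kt_range[1] + diff(cfg$kt_range) * stats::rbeta(365, 3, 1.5)
    }
    rg <- kt * toa_radiation(cfg$lat, doy)
    rcfg <- tlrhm_config()$radiation
    par_umol <- rg * rcfg$par_fraction * rcfg$umol_per_j * 1e6 # umol m-2 d-1
    rh_day <- pmin(pmax(cfg$rh_base + stats::rnorm(365, 0, cfg$rh_noise_sd),
                        20), 100)
    lai_day <- cfg$lai_min + (cfg$lai_max - cfg$lai_min) * lai_phenology(doy)

    hours <- seq(0.25, 23.75, by = 0.5)
    grid <- expand.grid(hour = hours, i = doy)
    t_h <- grid$hour - trise[grid$i]                 # hours since sunrise
    inday <- t_h > 0 & t_h < dl_h[grid$i]
    shape <- ifelse(inday, sin(pi * t_h / dl_h[grid$i]), 0)
    if (cfg$diurnal_shape == "sinesine") shape <- shape^2
    noon_coef <- if (cfg$diurnal_shape == "sine") pi / 2 else 2
    ppfd <- noon_coef * par_umol[grid$i] / (dl_h[grid$i] * 3600) * shape

    t_air <- ifelse(inday,
                    diurnal_temperature(tmax[grid$i], tmin[grid$i], t_h,
                                        dl_h[grid$i]),
                    tmin[grid$i])
    hh <- data.frame(date = dates[grid$i], hour = grid$hour,
                     ppfd = ppfd, t_air = t_air, rh = rh_day[grid$i])

    daily <- aggregate_halfhourly(
      hh, lai = data.frame(date = dates, lai = lai_day))
    sy <- site_year(
      sprintf("SYN-%s-%03d", cfg$vegetation_type, cfg$seed),
      cfg$lat, cfg$vegetation_type, daily,
      lai_max = cfg$lai_max, vcmax25 = cfg$true_vcmax25)
    list(site = sy, halfhourly = hh)
  })
}

#' Half-hourly enzyme-kinetic truth GPP
#'
#' The process-model reference the daily closed forms are validated against:
#' the instantaneous EK leaf model is evaluated every half hour for the
#' sunlit and shaded leaf classes at the configured "true" Vcmax,25 and
#' summed to daily totals. With `partition = "daily"` (default) the
#' sunlit/shaded partition is done once per day at the representative zenith
#' with the daily diffuse fraction, and each class's daily absorbed PAR is
#' distributed over the half hours in proportion to the incident PPFD -- so
#' the comparison with the daily model isolates the hyperbola-compression
#' error. With `partition = "instantaneous"` the partition is recomputed at
#' every half hour from the instantaneous solar zenith. The same VPD
#' downregulation scalar as the daily model is applied (so the truth series
#' reflects the humidity stress the daily model includes); disable with
#' `apply_vpd = FALSE`.
#'
#' @param sy [site_year()] from [generate_site_year()].
#' @param hh matching half-hourly table.
#' @param params [leaf_ek_params()]; defaults to the surface-generation
#'   template at the site's `vcmax25`.
#' @param partition `"daily"` or `"instantaneous"`.
#' @param apply_vpd apply the daily `f(VPD)` scalar.
#' @param config configuration list.
#' @return data.frame `date, gpp_truth` (g C m-2 day-1).
#' @export
truth_gpp_halfhourly <- function(sy, hh, params = NULL,
                                 partition = c("daily", "instantaneous"),
                                 apply_vpd = TRUE, config = tlrhm_config()) {
  partition <- match.arg(partition)
  stopifnot(inherits(sy, "site_year"))
  if (is.null(params)) {
    if (is.null(sy$vcmax25)) stop("params not given and site has no vcmax25")
    params <- leaf_ek_params(vcmax25 = sy$vcmax25)
  }
  d <- sy$days
  step_s <- 1800
  dl <- daylength(sy$lat, d$doy)
  tp <- daytime_temperature(d$tmax_c, d$tmin_c, dl,
                            method = config$temperature$tp_method,
                            peak_lag_h = config$temperature$peak_lag_h)
  df <- diffuse_fraction(d$rg_mj_m2, sy$lat, d$doy, config)
  th <- representative_zenith(sy$lat, d$doy)
  par_daily <- d$rg_mj_m2 * config$radiation$par_fraction *
    config$radiation$umol_per_j                      # mol m-2 d-1

  hh_date <- as.Date(hh$date)
  gpp <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    rows <- which(hh_date == d$date[i])
    if (!length(rows) || d$lai[i] <= 0 || is.na(th[i])) next
    pp <- hh$ppfd[rows]; ta <- pmin(pmax(hh$t_air[rows], 0), 50)
    if (all(pp <= 0)) next
    if (partition == "daily") {
      lp <- partition_lai(d$lai[i], sy$omega, th[i])
      ap <- partition_apar(par_daily[i], df[i], d$lai[i], sy$omega, th[i],
                           config)
      tot <- sum(pp) * step_s                        # umol m-2 d-1 incident
      flux_sun <- ap$apar_sunlit * 1e6 * pp / tot    # umol m-2 s-1 per leaf
      flux_sh <- ap$apar_shaded * 1e6 * pp / tot
      lai_sun <- rep(lp$lai_sunlit, length(rows))
      lai_sh <- rep(lp$lai_shaded, length(rows))
    } else {
      ct <- cos_zenith(sy$lat, d$doy[i], hh$hour[rows])
      theta <- acos(pmin(pmax(ct, 0), 1)) * 180 / pi
      theta <- pmin(theta, 89.9)
      lp <- partition_lai(rep(d$lai[i], length(rows)), sy$omega, theta)
      ap <- partition_apar(pp, df[i], d$lai[i], sy$omega, theta, config)
      flux_sun <- ap$apar_sunlit; flux_sh <- ap$apar_shaded
      lai_sun <- lp$lai_sunlit; lai_sh <- lp$lai_shaded
    }
    a_sun <- gross_assimilation(params, pmax(flux_sun, 0), ta)
    a_sh <- gross_assimilation(params, pmax(flux_sh, 0), ta)
    gpp[i] <- sum((a_sun * lai_sun + a_sh * lai_sh) * step_s) * GC_PER_UMOL
  }
  if (apply_vpd) {
    vpd <- if (!is.null(d$vpd_pa)) d$vpd_pa else vpd_from(tp, d$rh_pct)
    gpp <- gpp * f_vpd(vpd, config$vpd$vpd_max, config$vpd$vpd_min)
  }
  data.frame(date = d$date, gpp_truth = gpp)
}
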