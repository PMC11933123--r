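#' Sunlit / shaded leaf area partition
#'
#' Chen-type two-leaf separation of the canopy leaf area index:
#' `lai_sunlit = 2 cos(theta) (1 - exp(-0.5 omega lai / cos(theta)))`,
#' `lai_shaded = lai - lai_sunlit`, where `omega` is the clumping index and
#' `theta` the representative daytime solar zenith angle.
#'
#' @param lai total leaf area index (m2 m-2), >= 0.
#' @param omega clumping index, (0, 1].
#' @param theta_rep representative solar zenith (degrees, 0 <= theta < 90).
#' @return List with `lai_sunlit` and `lai_shaded` (each >= 0; their sum is
#'   exactly `lai`).
#' @export
#' @examples
#' partition_lai(lai = 4, omega = 0.8, theta_rep = 30)
partition_lai <- function(lai, omega, theta_rep) {
  if (any(lai < 0)) stop("lai must be >= 0")
  if (any(omega <= 0 | omega > 1)) stop("omega must be in (0, 1]")
  if (any(theta_rep < 0 | theta_rep >= 90)) {
    stop("theta_rep must be in [0, 90) degrees")
  }
  ct <- cos(theta_rep * pi / 180)
  lai_sunlit <- 2 * ct * (1 - exp(-0.5 * omega * lai / ct))
  lai_sunlit <- pmin(lai_sunlit, lai)
  list(lai_sunlit = lai_sunlit, lai_shaded = lai - lai_sunlit)
}

#' Absorbed PAR of sunlit and shaded leaves
#'
#' Splits the daily incident PAR into per-leaf-area absorbed PAR of the two
#' leaf classes following the standard sunlit/shaded radiation scheme.
#' Shaded leaves receive the diffuse irradiance attenuated through the
#' canopy plus a multiple-scattering term,
#' `par_shaded = (I_dif - I_dif,under) / lai + C`, with
#' `I_dif,under = I_dif exp(-0.5 omega lai / cos(57.3 deg))` (representative
#' zenith of the diffuse sky) and
#' `C = 0.07 omega I_dir (1.1 - 0.1 lai) exp(-cos(theta))` (switchable via
#' `config$two_leaf$scattering`). Sunlit leaves receive the same plus the
#' direct beam on the mean leaf-sun geometry,
#' `par_sunlit = I_dir cos(beta) / cos(theta) + par_shaded` with
#' `cos(beta) = 0.5` (spherical leaf-angle distribution). Both are scaled by
#' the leaf absorptance.
#'
#' @param par_daily daily incident PAR on the canopy (mol photons m-2
#'   ground day-1).
#' @param diffuse_frac diffuse fraction of `par_daily`, in `[0, 1]`.
#' @param lai total leaf area index (m2 m-2).
#' @param omega clumping index (0, 1].
#' @param theta_rep representative solar zenith (degrees).
#' @param config configuration list ([tlrhm_config()]); uses
#'   `radiation$absorptance`, `two_leaf$cos_beta`, `two_leaf$scattering`.
#' @return List with `apar_sunlit` and `apar_shaded`, daily absorbed PAR per
#'   unit leaf area of each class (mol photons m-2 leaf day-1).
#' @export
partition_apar <- function(par_daily, diffuse_frac, lai, omega, theta_rep,
                           config = tlrhm_config()) {
  if (any(par_daily < 0)) stop("par_daily must be >= 0")
  if (any(diffuse_frac < 0 | diffuse_frac > 1)) {
    stop("diffuse_frac must be in [0, 1]")
  }
  n <- max(length(par_daily), length(diffuse_frac), length(lai),
           length(omega), length(theta_rep))
  par_daily <- rep_len(par_daily, n); diffuse_frac <- rep_len(diffuse_frac, n)
  lai <- rep_len(lai, n); omega <- rep_len(omega, n)
  theta_rep <- rep_len(theta_rep, n)

  ct <- cos(theta_rep * pi / 180)
  i_dif <- diffuse_frac * par_daily
  i_dir <- (1 - diffuse_frac) * par_daily
  # diffuse transmitted below the canopy, representative sky zenith 57.3 deg
  i_dif_under <- i_dif * exp(-0.5 * omega * lai / cos(57.3 * pi / 180))
  scat <- if (isTRUE(config$two_leaf$scattering)) {
    0.07 * omega * i_dir * (1.1 - 0.1 * lai) * exp(-ct)
  } else 0
  par_shaded <- ifelse(lai > 0, (i_dif - i_dif_under) / lai, 0) + scat
  par_shaded <- pmax(par_shaded, 0)
  par_sunlit <- ifelse(ct > 0, i_dir * config$two_leaf$cos_beta / ct, 0) +
    par_shaded
  ab <- config$radiation$absorptance
  list(apar_sunlit = ab * par_sunlit, apar_shaded = ab * par_shaded)
}

#' Daily canopy GPP for one day of drivers
#'
#' The full per-day chain of the two-leaf daily model: look up the
#' rectangular-hyperbola parameters `(alpha, Pm)` at the daytime temperature
#' `Tp` and the prescribed `Vcmax,25`; partition leaf area and absorbed PAR
#' into sunlit and shaded classes; evaluate the closed-form daily leaf GPP
#' ([gpp_daily_sine()] or [gpp_daily_sinesine()]) once per class with that
#' class's per-leaf-area APAR; sum
#' `gpp_canopy = gpp_sunlit lai_sunlit + gpp_shaded lai_shaded`; and
#' downregulate by the VPD scalar, `gpp_actual = gpp_canopy f(VPD)`.
#'
#' @param drivers a one-row data.frame (or list) with fields `doy`, `lat`,
#'   `rg` (MJ m-2 day-1) or `par` (mol m-2 day-1), `tmax`, `tmin` (degC),
#'   `rh` (%) or `vpd` (Pa), `lai`; optionally `omega`.
#' @param surface [build_surface()] result.
#' @param vcmax25 vegetation-type Vcmax,25 (umol m-2 s-1).
#' @param form `"sine"` or `"sinesine"` diurnal radiation assumption.
#' @param omega clumping index used if `drivers$omega` is absent.
#' @param config configuration list ([tlrhm_config()]); supplies the VPD
#'   ramp, PAR conversion and partition constants.
#' @return List of class `canopy_gpp` with `gpp_sunlit`, `gpp_shaded`
#'   (g C m-2 leaf day-1), `gpp_canopy`, `gpp_actual` (g C m-2 ground
#'   day-1), `f_vpd`, `lai_sunlit`, `lai_shaded`, `tp`, `daylength`, `form`.
#' @export
canopy_gpp_daily <- function(drivers, surface, vcmax25,
                             form = c("sine", "sinesine"),
                             omega = 0.8, config = tlrhm_config()) {
  form <- match.arg(form)
  need <- c("doy", "lat", "tmax", "tmin", "lai")
  missing_f <- setdiff(need, names(drivers))
  has_rad <- any(c("rg", "par") %in% names(drivers))
  has_hum <- any(c("rh", "vpd") %in% names(drivers))
  if (length(missing_f) || !has_rad || !has_hum) {
    stop("missing driver field(s): ",
         paste(c(missing_f, if (!has_rad) "rg|par", if (!has_hum) "rh|vpd"),
               collapse = ", "))
  }
  dl <- daylength(drivers$lat, drivers$doy)
  tp <- daytime_temperature(drivers$tmax, drivers$tmin, dl,
                            method = config$temperature$tp_method,
                            peak_lag_h = config$temperature$peak_lag_h)
  if (!is.null(drivers$par)) {
    par_daily <- drivers$par
    rg <- par_daily / (config$radiation$par_fraction *
                         config$radiation$umol_per_j)
  } else {
    rg <- drivers$rg
    par_daily <- rg * config$radiation$par_fraction *
      config$radiation$umol_per_j
  }
  om <- if (!is.null(drivers$omega)) drivers$omega else omega
  df <- diffuse_fraction(rg, drivers$lat, drivers$doy, config)
  th <- representative_zenith(drivers$lat, drivers$doy)
  vpd <- if (!is.null(drivers$vpd)) drivers$vpd else vpd_from(tp, drivers$rh)
  fv <- f_vpd(vpd, config$vpd$vpd_max, config$vpd$vpd_min)

  n <- max(length(dl), length(drivers$lai))
  gpp_sun <- gpp_sh <- numeric(n)
  lp <- list(lai_sunlit = numeric(n), lai_shaded = numeric(n))
  day <- dl > 0 & !is.na(th)
  if (any(day)) {
    lp_d <- partition_lai(rep_len(drivers$lai, n)[day], om,
                          rep_len(th, n)[day])
    ap <- partition_apar(rep_len(par_daily, n)[day],
                         rep_len(df, n)[day],
                         rep_len(drivers$lai, n)[day], om,
                         rep_len(th, n)[day], config)
    pars <- surface_lookup(surface, rep_len(tp, n)[day], vcmax25,
                           clamp = TRUE)
    gfun <- if (form == "sine") gpp_daily_sine else gpp_daily_sinesine
    gpp_sun[day] <- umol_to_gc(
      gfun(pars$alpha, pars$pm, ap$apar_sunlit, rep_len(dl, n)[day]))
    gpp_sh[day] <- umol_to_gc(
      gfun(pars$alpha, pars$pm, ap$apar_shaded, rep_len(dl, n)[day]))
    lp$lai_sunlit[day] <- lp_d$lai_sunlit
    lp$lai_shaded[day] <- lp_d$lai_shaded
  }
  gpp_canopy <- gpp_sun * lp$lai_sunlit + gpp_sh * lp$lai_shaded
  out <- list(gpp_sunlit = gpp_sun, gpp_shaded = gpp_sh,
              gpp_canopy = gpp_canopy, gpp_actual = gpp_canopy * fv,
              f_vpd = fv, lai_sunlit = lp$lai_sunlit,
              lai_shaded = lp$lai_shaded, tp = tp, daylength = dl,
              form = form)
  class(out) <- "canopy_gpp"
  out
}

#' @export
print.canopy_gpp <- function(x, ...) {
  cat(sprintf("Two-leaf daily GPP (%s form), %d day(s)\n",
              x$form, length(x$gpp_canopy)))
  cat(sprintf("  canopy %.3f  actual %.3f g C m-2 day-1 (means)\n",
              mean(x$gpp_canopy), mean(x$gpp_actual)))
  invisible(x)
}

#' Simulate a site-year with the two-leaf daily model
#'
#' Runs [canopy_gpp_daily()] over every day of a [site_year()] object for
#' one or both diurnal-radiation forms.
#'
#' @param sy [site_year()] object.
#' @param surface [build_surface()] result.
#' @param vcmax25 Vcmax,25 (umol m-2 s-1); defaults to the site metadata
#'   value if present.
#' @param form `"sine"`, `"sinesine"`, or `"both"`.
#' @param config configuration list.
#' @return data.frame with one row per day: `date`, `gpp_sine`,
#'   `gpp_sinesine`, `gpp_actual_sine`, `gpp_actual_sinesine` (whichever
#'   forms were requested), `f_vpd`, `lai_sunlit`, `lai_shaded`, `tp`,
#'   `daylength`.
#' @export
simulate_site_year <- function(sy, surface, vcmax25 = sy$vcmax25,
                               form = c("both", "sine", "sinesine"),
                               config = tlrhm_config()) {
  form <- match.arg(form)
  stopifnot(inherits(sy, "site_year"))
  if (is.null(vcmax25)) stop("vcmax25 not given and absent from site metadata")
  d <- sy$days
  drv <- list(doy = d$doy, lat = sy$lat, tmax = d$tmax_c, tmin = d$tmin_c,
              lai = d$lai, rg = d$rg_mj_m2, omega = sy$omega)
  if (!is.null(d$vpd_pa)) drv$vpd <- d$vpd_pa else drv$rh <- d$rh_pct
  forms <- if (form == "both") c("sine", "sinesine") else form
  out <- data.frame(date = d$date)
  for (f in forms) {
    res <- canopy_gpp_daily(drv, surface, vcmax25, f, config = config)
    out[[paste0("gpp_", f)]] <- res$gpp_canopy
    out[[paste0("gpp_actual_", f)]] <- res$gpp_actual
  }
  out$f_vpd <- res$f_vpd
  out$lai_sunlit <- res$lai_sunlit
  out$lai_shaded <- res$lai_shaded
  out$tp <- res$tp
  out$daylength <- res$daylength
  out
}
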