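#' Construct a site-year
#'
#' Bundles one year (or any contiguous span) of daily drivers with the site
#' metadata the model needs. `days` must have one row per calendar day with
#' no gaps or duplicates.
#'
#' @param site_id character site identifier.
#' @param lat latitude (degrees).
#' @param vegetation_type one of `"ENF"`, `"DBF"`, `"GRA"`, `"EBF"`.
#' @param days data.frame with columns `date` (Date or ISO-8601 character),
#'   `rg_mj_m2` (or `par_mol_m2`), `tmax_c`, `tmin_c`, `rh_pct` (or
#'   `vpd_pa`), `lai`, and optionally `gpp_obs_gc_m2`. Extra columns are
#'   preserved.
#' @param omega clumping index; defaults to the vegetation-type value.
#' @param lai_max measured maximum LAI (optional metadata).
#' @param vcmax25 site Vcmax,25 (optional metadata).
#' @return Object of class `site_year`.
#' @export
site_year <- function(site_id, lat, vegetation_type, days,
                      omega = default_omega(vegetation_type),
                      lai_max = NULL, vcmax25 = NULL) {
  if (!vegetation_type %in% c("ENF", "DBF", "GRA", "EBF")) {
    stop("unknown vegetation type: ", vegetation_type,
         " (expected ENF, DBF, GRA or EBF)")
  }
  if (abs(lat) > 90) stop("latitude must be within [-90, 90]")
  days <- validate_daily_drivers(days)
  obj <- list(site_id = site_id, lat = lat,
              vegetation_type = vegetation_type, omega = omega,
              lai_max = lai_max, vcmax25 = vcmax25, days = days)
  class(obj) <- "site_year"
  obj
}

validate_daily_drivers <- function(days) {
  stopifnot(is.data.frame(days))
  if (!"date" %in% names(days)) stop("daily drivers need a 'date' column")
  dates <- as.Date(days$date)
  if (anyNA(dates)) {
    stop("unparseable date(s) at line ", which(is.na(dates))[1])
  }
  if (anyDuplicated(dates)) {
    stop("duplicate date(s): ", dates[duplicated(dates)][1])
  }
  if (nrow(days) > 1 && !all(diff(dates) == 1)) {
    stop("days must cover a contiguous date range (gap after ",
         dates[which(diff(dates) != 1)[1]], ")")
  }
  rad <- intersect(c("rg_mj_m2", "par_mol_m2"), names(days))
  hum <- intersect(c("rh_pct", "vpd_pa"), names(days))
  need <- c("tmax_c", "tmin_c", "lai")
  miss <- setdiff(need, names(days))
  if (length(miss) || !length(rad) || !length(hum)) {
    stop("missing required driver column(s): ",
         paste(c(miss, if (!length(rad)) "rg_mj_m2|par_mol_m2",
                 if (!length(hum)) "rh_pct|vpd_pa"), collapse = ", "))
  }
  for (col in c(need, rad, hum)) {
    if (anyNA(days[[col]])) {
      stop("missing value in required column '", col, "' at line ",
           which(is.na(days[[col]]))[1])
    }
    days[[col]] <- as.double(days[[col]]) # integer-valued columns read back
  }
  if (!is.null(days$gpp_obs_gc_m2)) {
    days$gpp_obs_gc_m2 <- as.double(days$gpp_obs_gc_m2)
  }
  if (any(days$tmax_c < days$tmin_c)) {
    stop("tmax_c < tmin_c at line ", which(days$tmax_c < days$tmin_c)[1])
  }
  days$date <- dates
  days$doy <- as.integer(strftime(dates, "%j"))
  days
}

#' @export
print.site_year <- function(x, ...) {
  cat(sprintf("Site-year %s (%s, lat %.3f, omega %.2f): %d days, %s..%s\n",
              x$site_id, x$vegetation_type, x$lat, x$omega, nrow(x$days),
              min(x$days$date), max(x$days$date)))
  if (!is.null(x$days$gpp_obs_gc_m2)) cat("  with measured GPP\n")
  invisible(x)
}

#' Read a site-year from a daily driver CSV and a metadata JSON
#'
#' The CSV must carry the documented header (`date, rg_mj_m2` (or
#' `par_mol_m2`), `tmax_c, tmin_c, rh_pct` (or `vpd_pa`), `lai`, optional
#' `gpp_obs_gc_m2`); unknown extra columns are preserved. The JSON supplies
#' `site_id`, `lat`, `vegetation_type`, and optionally `omega`, `lai_max`,
#' `vcmax25`. Rows with missing required fields, duplicate or gapped dates,
#' or an unknown vegetation type raise descriptive errors.
#'
#' @param csv_path path to the daily driver CSV.
#' @param meta_path path to the site metadata JSON.
#' @return Object of class `site_year`.
#' @export
read_site_year <- function(csv_path, meta_path) {
  stopifnot(file.exists(csv_path), file.exists(meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("site_id", "lat", "vegetation_type")) {
    if (is.null(meta[[f]])) stop("site metadata missing field '", f, "'")
  }
  days <- utils::read.csv(csv_path, check.names = FALSE)
  site_year(meta$site_id, meta$lat, meta$vegetation_type, days,
            omega = if (!is.null(meta$omega)) meta$omega
                    else default_omega(meta$vegetation_type),
            lai_max = meta$lai_max, vcmax25 = meta$vcmax25)
}

#' Write a site-year to a daily driver CSV and metadata JSON
#'
#' Numeric fields are written at full double precision so that
#' [read_site_year()] reproduces them bit-exactly.
#'
#' @param sy [site_year()] object.
#' @param csv_path,meta_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_site_year <- function(sy, csv_path, meta_path) {
  stopifnot(inherits(sy, "site_year"))
  d <- sy$days
  d$doy <- NULL
  for (col in names(d)) {
    if (is.double(d[[col]])) d[[col]] <- format(d[[col]], digits = 17)
  }
  utils::write.csv(d, csv_path, row.names = FALSE, quote = FALSE)
  meta <- list(site_id = sy$site_id, lat = sy$lat,
               vegetation_type = sy$vegetation_type, omega = sy$omega)
  if (!is.null(sy$lai_max)) meta$lai_max <- sy$lai_max
  if (!is.null(sy$vcmax25)) meta$vcmax25 <- sy$vcmax25
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, meta_path))
}

#' Aggregate half-hourly meteorology to daily drivers
#'
#' Sums half-hourly PPFD to the daily shortwave total (time-step-weighted
#' sum, converted from umol m-2 s-1 through the PAR energy and PAR/global
#' fractions), takes the temperature extrema and the mean relative humidity.
#'
#' @param hh data.frame with columns `date`, `ppfd` (umol m-2 s-1), `t_air`
#'   (degC), `rh` (%); one row per half hour.
#' @param lai optional data.frame `date, lai` merged onto the result.
#' @param step_s record duration (s), default 1800.
#' @param config configuration list (PAR conversion constants).
#' @return Daily driver data.frame (`date, rg_mj_m2, tmax_c, tmin_c,
#'   rh_pct`, and `lai` if given).
#' @export
aggregate_halfhourly <- function(hh, lai = NULL, step_s = 1800,
                                 config = tlrhm_config()) {
  stopifnot(all(c("date", "ppfd", "t_air", "rh") %in% names(hh)))
  if (any(hh$ppfd < 0)) stop("ppfd must be >= 0")
  date <- as.Date(hh$date)
  # umol m-2 s-1 -> J m-2 per step of PAR -> global shortwave MJ m-2 day-1
  j_par <- hh$ppfd / config$radiation$umol_per_j * step_s
  rg <- tapply(j_par, date, sum) / config$radiation$par_fraction * 1e-6
  out <- data.frame(
    date = as.Date(names(rg)),
    rg_mj_m2 = as.numeric(rg),
    tmax_c = as.numeric(tapply(hh$t_air, date, max)),
    tmin_c = as.numeric(tapply(hh$t_air, date, min)),
    rh_pct = as.numeric(tapply(hh$rh, date, mean))
  )
  if (!is.null(lai)) out <- merge(out, lai, by = "date", sort = TRUE)
  out[order(out$date), , drop = FALSE]
}

#' Rescale a coarse LAI time series to a measured maximum
#'
#' Multiplies the series by `lai_max_measured / max(series)` so its maximum
#' equals the measured maximum LAI; the seasonal shape (and the day of
#' maximum) is preserved.
#'
#' @param series non-negative LAI values with `max(series) > 0`.
#' @param lai_max_measured measured maximum LAI (> 0).
#' @return Rescaled series.
#' @export
#' @examples
#' rescale_lai(c(1, 2, 4), 6)
rescale_lai <- function(series, lai_max_measured) {
  if (any(series < 0)) stop("LAI series must be non-negative")
  if (!(lai_max_measured > 0)) stop("lai_max_measured must be > 0")
  mx <- max(series)
  if (mx == 0) stop("degenerate LAI series: all values are zero")
  series * (lai_max_measured / mx)
}
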