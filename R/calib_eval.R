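#' Agreement metrics between modelled and measured daily GPP
#'
#' R2 (squared Pearson correlation by default, or the coefficient of
#' determination `1 - SSres/SStot` with `r2_type = "cod"`), root-mean-square
#' error, mean bias (modelled minus measured) and the number of paired days.
#' Pairs with a missing value on either side are dropped and counted.
#'
#' @param modeled,measured equal-length numeric series, paired by day.
#' @param r2_type `"pearson"` (default) or `"cod"`.
#' @return List of class `gpp_metrics`: `r2`, `rmse`, `bias`, `n`,
#'   `n_dropped`.
#' @export
#' @examples
#' gpp_metrics(c(1, 3), c(2, 5))$rmse # sqrt(5/2)
gpp_metrics <- function(modeled, measured, r2_type = c("pearson", "cod")) {
  r2_type <- match.arg(r2_type)
  if (length(modeled) != length(measured)) {
    stop("modeled and measured must have equal length")
  }
  ok <- stats::complete.cases(modeled, measured)
  n_dropped <- sum(!ok)
  m <- modeled[ok]; o <- measured[ok]
  if (length(m) < 2) stop("need at least 2 paired days")
  if (stats::var(o) == 0) {
    stop("measured series has zero variance; R2 is undefined")
  }
  r2 <- if (r2_type == "pearson") {
    stats::cor(m, o)^2
  } else {
    1 - sum((o - m)^2) / sum((o - mean(o))^2)
  }
  out <- list(r2 = r2, rmse = sqrt(mean((m - o)^2)), bias = mean(m - o),
              n = length(m), n_dropped = n_dropped)
  class(out) <- "gpp_metrics"
  out
}

#' @export
print.gpp_metrics <- function(x, ...) {
  cat(sprintf("R2 = %.3f, RMSE = %.3f g C m-2 day-1, bias = %+.3f, n = %d\n",
              x$r2, x$rmse, x$bias, x$n))
  invisible(x)
}

#' Ensemble-run calibration of Vcmax,25
#'
#' Runs the full two-leaf daily model over every candidate Vcmax,25, pools
#' all days across the supplied site-years, and selects the candidate with
#' the smallest RMSE against measured GPP (`gpp_obs_gc_m2`); ties break
#' toward the smaller Vcmax,25. Deterministic given the data and grid.
#'
#' @param site_years list of [site_year()] objects, each carrying a
#'   `gpp_obs_gc_m2` column.
#' @param surface [build_surface()] result; `grid` must lie within its
#'   Vcmax range.
#' @param grid candidate Vcmax,25 values (umol m-2 s-1).
#' @param form `"sine"` or `"sinesine"`.
#' @param config configuration list.
#' @return List of class `vcmax_calibration`: `vcmax25_opt`, `grid`,
#'   `rmse_profile`, `r2_profile`, `r2_at_opt`, `n_days`, `form`.
#' @export
calibrate_vcmax <- function(site_years, surface, grid = seq(20, 180, by = 1),
                            form = c("sine", "sinesine"),
                            config = tlrhm_config()) {
  form <- match.arg(form)
  if (inherits(site_years, "site_year")) site_years <- list(site_years)
  if (!length(grid)) stop("empty candidate grid")
  if (min(grid) < min(surface$vcmax_grid) ||
      max(grid) > max(surface$vcmax_grid)) {
    stop("candidate grid extends beyond the parameter surface's Vcmax range")
  }
  for (sy in site_years) {
    if (is.null(sy$days$gpp_obs_gc_m2)) {
      stop("site-year ", sy$site_id, " has no measured GPP (gpp_obs_gc_m2)")
    }
  }
  measured <- unlist(lapply(site_years, function(sy) sy$days$gpp_obs_gc_m2))
  rmse <- r2 <- numeric(length(grid))
  for (k in seq_along(grid)) {
    modeled <- unlist(lapply(site_years, function(sy) {
      simulate_site_year(sy, surface, vcmax25 = grid[k], form = form,
                         config = config)[[paste0("gpp_actual_", form)]]
    }))
    met <- gpp_metrics(modeled, measured)
    rmse[k] <- met$rmse
    r2[k] <- met$r2
  }
  best <- which(rmse == min(rmse))[1] # ties toward the smaller candidate
  out <- list(vcmax25_opt = grid[best], grid = grid, rmse_profile = rmse,
              r2_profile = r2, r2_at_opt = r2[best],
              n_days = length(measured), form = form)
  class(out) <- "vcmax_calibration"
  out
}

#' @export
print.vcmax_calibration <- function(x, ...) {
  cat(sprintf(
    "Vcmax,25 calibration (%s form, %d candidates, %d pooled days)\n",
    x$form, length(x$grid), x$n_days))
  cat(sprintf("  optimum %.4g umol m-2 s-1 (RMSE %.3f, R2 %.3f)\n",
              x$vcmax25_opt, min(x$rmse_profile), x$r2_at_opt))
  invisible(x)
}

#' Write a calibration report
#'
#' Writes the per-candidate profile as CSV (`vcmax25, rmse, r2`) and a JSON
#' summary (`vcmax25_opt`, `rmse_at_opt`, `r2_at_opt`, `n_days`, `form`).
#'
#' @param cal [calibrate_vcmax()] result.
#' @param csv_path,json_path output paths.
#' @return Invisibly, the paths.
#' @export
write_calibration <- function(cal, csv_path, json_path) {
  stopifnot(inherits(cal, "vcmax_calibration"))
  utils::write.csv(
    data.frame(vcmax25 = cal$grid, rmse = cal$rmse_profile,
               r2 = cal$r2_profile),
    csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(vcmax25_opt = cal$vcmax25_opt, rmse_at_opt = min(cal$rmse_profile),
         r2_at_opt = cal$r2_at_opt, n_days = cal$n_days, form = cal$form),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
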