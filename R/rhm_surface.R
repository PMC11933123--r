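#' Fit a rectangular hyperbola to a light-response curve
#'
#' Least-squares fit of the rectangular hyperbolic model (RHM)
#' `GPP = alpha * Pm * I / (Pm + alpha * I)` to (PPFD, gross assimilation)
#' pairs, by Levenberg-Marquardt nonlinear least squares. `alpha` is the
#' quantum yield (initial slope, umol CO2 per umol photons) and `Pm` the
#' light-saturated maximum photosynthetic rate (umol m-2 s-1). Initial
#' guesses: `alpha0` = slope over the first two points, `Pm0` = maximum
#' response; on failure one restart from `(0.04, 1.2 * max response)`.
#'
#' @param points `data.frame` with columns `ppfd` (strictly increasing,
#'   >= 5 rows) and `a_gross` (all >= 0, at least one > 0).
#' @return Object of class `rhm_fit`: list with `alpha`, `pm`, `r2`
#'   (1 - SSres/SStot over the fitted points).
#' @export
#' @examples
#' I <- seq(50, 2000, 50)
#' pts <- data.frame(ppfd = I, a_gross = 0.05 * 20 * I / (20 + 0.05 * I))
#' fit_hyperbola(pts)
fit_hyperbola <- function(points) {
  stopifnot(is.data.frame(points), all(c("ppfd", "a_gross") %in% names(points)))
  if (nrow(points) < 5) stop("need at least 5 light-response points")
  if (is.unsorted(points$ppfd, strictly = TRUE)) {
    stop("ppfd must be strictly increasing")
  }
  if (any(points$a_gross < 0)) stop("a_gross must be >= 0")
  if (all(points$a_gross == 0)) {
    stop("degenerate light response: all responses are zero")
  }

  alpha0 <- diff(points$a_gross[1:2]) / diff(points$ppfd[1:2])
  if (!is.finite(alpha0) || alpha0 <= 0) alpha0 <- points$a_gross[1] / points$ppfd[1]
  if (!is.finite(alpha0) || alpha0 <= 0) alpha0 <- 0.04
  pm0 <- max(points$a_gross)

  do_fit <- function(a0, p0) {
    tryCatch(
      minpack.lm::nlsLM(
        a_gross ~ alpha * pm * ppfd / (pm + alpha * ppfd),
        data = points,
        start = list(alpha = a0, pm = p0),
        lower = c(1e-8, 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  fit <- do_fit(alpha0, pm0)
  if (is.null(fit)) fit <- do_fit(0.04, 1.2 * pm0)
  if (is.null(fit)) {
    stop("rectangular-hyperbola fit failed to converge (initial guesses ",
         "alpha0 = ", signif(alpha0, 3), ", Pm0 = ", signif(pm0, 3), ")")
  }
  cf <- stats::coef(fit)
  pred <- stats::predict(fit)
  ss_res <- sum((points$a_gross - pred)^2)
  ss_tot <- sum((points$a_gross - mean(points$a_gross))^2)
  out <- list(alpha = unname(cf[["alpha"]]), pm = unname(cf[["pm"]]),
              r2 = 1 - ss_res / ss_tot)
  class(out) <- "rhm_fit"
  out
}

#' @export
print.rhm_fit <- function(x, ...) {
  cat(sprintf("RHM fit: alpha = %.5g umol/umol, Pm = %.5g umol m-2 s-1, R2 = %.6f\n",
              x$alpha, x$pm, x$r2))
  invisible(x)
}

#' Build the alpha / Pm parameter surfaces
#'
#' For every combination of air temperature and `Vcmax,25`, generates an
#' enzyme-kinetic light-response curve over `ppfd_grid` and fits the
#' rectangular hyperbola, producing gridded maps of the quantum yield
#' `alpha(Vcmax,25, T)` and maximum photosynthetic rate `Pm(Vcmax,25, T)`.
#' Every cell must reach a fit R2 of at least `r2_gate` (default 0.99, the
#' fidelity the compression is required to achieve); any cell below the gate
#' aborts the build naming the offending `(T, Vcmax)` combination.
#'
#' @param params [leaf_ek_params()] template; its `vcmax25` is replaced by
#'   each grid value in turn.
#' @param t_grid ascending air temperatures (degC), default 1-40 step 1.
#' @param vcmax_grid ascending Vcmax,25 values (umol m-2 s-1), default
#'   20-180 step 10.
#' @param ppfd_grid PPFD sampling of each light-response curve
#'   (umol m-2 s-1), default 50-2000 step 50.
#' @param r2_gate minimum acceptable fit R2 per cell.
#' @return Object of class `rhm_surface`: grids plus `alpha`, `pm`, `r2`
#'   matrices (rows = temperatures, columns = Vcmax values) and the EK
#'   parameter template used.
#' @export
build_surface <- function(params = leaf_ek_params(),
                          t_grid = 1:40,
                          vcmax_grid = seq(20, 180, by = 10),
                          ppfd_grid = seq(50, 2000, by = 50),
                          r2_gate = 0.99) {
  stopifnot(length(t_grid) >= 1, length(vcmax_grid) >= 1,
            !is.unsorted(t_grid, strictly = TRUE),
            !is.unsorted(vcmax_grid, strictly = TRUE))
  if (min(ppfd_grid) > 50 || max(ppfd_grid) < 2000) {
    stop("ppfd_grid must span the 50-2000 umol m-2 s-1 sampling range")
  }

  nt <- length(t_grid); nv <- length(vcmax_grid)
  alpha <- pm <- r2 <- matrix(NA_real_, nt, nv,
                              dimnames = list(t_grid, vcmax_grid))
  for (jv in seq_len(nv)) {
    p <- params
    p$vcmax25 <- vcmax_grid[jv]
    for (it in seq_len(nt)) {
      fit <- fit_hyperbola(light_response(p, ppfd_grid, t_grid[it]))
      if (fit$r2 < r2_gate) {
        stop(sprintf(
          "surface fidelity violated: R2 = %.5f < %.3f at T = %g degC, Vcmax,25 = %g",
          fit$r2, r2_gate, t_grid[it], vcmax_grid[jv]))
      }
      alpha[it, jv] <- fit$alpha
      pm[it, jv] <- fit$pm
      r2[it, jv] <- fit$r2
    }
  }
  out <- list(t_grid = as.numeric(t_grid), vcmax_grid = as.numeric(vcmax_grid),
              alpha = alpha, pm = pm, r2 = r2,
              ppfd_grid = as.numeric(ppfd_grid), ek_params = params)
  class(out) <- "rhm_surface"
  out
}

#' @export
print.rhm_surface <- function(x, ...) {
  cat("Rectangular-hyperbola parameter surface\n")
  cat(sprintf("  T: %g..%g degC (%d) x Vcmax,25: %g..%g umol m-2 s-1 (%d)\n",
              min(x$t_grid), max(x$t_grid), length(x$t_grid),
              min(x$vcmax_grid), max(x$vcmax_grid), length(x$vcmax_grid)))
  cat(sprintf("  alpha: %.4g..%.4g  Pm: %.4g..%.4g  min R2: %.6f\n",
              min(x$alpha), max(x$alpha), min(x$pm), max(x$pm), min(x$r2)))
  invisible(x)
}

#' Interpolate alpha and Pm at an off-grid condition
#'
#' Bilinear interpolation of the parameter surfaces at `(t, vcmax25)`;
#' exact at grid nodes. Queries outside the grid raise an error unless
#' `clamp = TRUE`, in which case they are evaluated at the nearest edge
#' (useful when winter temperatures fall below the 1 degC grid floor).
#'
#' @param surface [build_surface()] result.
#' @param t air temperature (degC), vector allowed.
#' @param vcmax25 Vcmax,25 (umol m-2 s-1), vector allowed.
#' @param clamp clamp out-of-range queries to the grid edge instead of
#'   erroring.
#' @return List with vectors `alpha` and `pm`.
#' @export
surface_lookup <- function(surface, t, vcmax25, clamp = FALSE) {
  stopifnot(inherits(surface, "rhm_surface"))
  n <- max(length(t), length(vcmax25))
  t <- rep_len(t, n); vcmax25 <- rep_len(vcmax25, n)
  tg <- surface$t_grid; vg <- surface$vcmax_grid
  if (clamp) {
    t <- pmin(pmax(t, tg[1]), tg[length(tg)])
    vcmax25 <- pmin(pmax(vcmax25, vg[1]), vg[length(vg)])
  } else if (any(t < tg[1] | t > tg[length(tg)] |
                 vcmax25 < vg[1] | vcmax25 > vg[length(vg)])) {
    bad <- which(t < tg[1] | t > tg[length(tg)] |
                   vcmax25 < vg[1] | vcmax25 > vg[length(vg)])[1]
    stop("query outside the parameter surface (T = ", t[bad], ", Vcmax,25 = ",
         vcmax25[bad], "); use clamp = TRUE to evaluate at the grid edge")
  }
  bilinear <- function(m) {
    it <- pmin(pmax(findInterval(t, tg), 1L), length(tg) - 1L)
    iv <- pmin(pmax(findInterval(vcmax25, vg), 1L), length(vg) - 1L)
    if (length(tg) == 1L) it <- it * 0L + 1L
    if (length(vg) == 1L) iv <- iv * 0L + 1L
    it2 <- pmin(it + 1L, length(tg)); iv2 <- pmin(iv + 1L, length(vg))
    wt <- ifelse(it2 == it, 0, (t - tg[it]) / (tg[it2] - tg[it]))
    wv <- ifelse(iv2 == iv, 0, (vcmax25 - vg[iv]) / (vg[iv2] - vg[iv]))
    wt[!is.finite(wt)] <- 0; wv[!is.finite(wv)] <- 0
    (1 - wt) * (1 - wv) * m[cbind(it, iv)] +
      wt * (1 - wv) * m[cbind(it2, iv)] +
      (1 - wt) * wv * m[cbind(it, iv2)] +
      wt * wv * m[cbind(it2, iv2)]
  }
  list(alpha = bilinear(surface$alpha), pm = bilinear(surface$pm))
}

#' Persist a parameter surface as CSV maps plus a JSON sidecar
#'
#' Writes `<stem>_alpha.csv`, `<stem>_pm.csv` and `<stem>_r2.csv` (rows =
#' temperature grid, columns = Vcmax,25 grid, full double precision) and
#' `<stem>_meta.json` holding the grids, the PPFD sampling and the EK
#' configuration used to build the surface. The round trip through
#' [read_surface()] is bit-exact.
#'
#' @param surface [build_surface()] result.
#' @param stem path stem for the four files.
#' @return Invisibly, the paths written.
#' @export
write_surface <- function(surface, stem) {
  stopifnot(inherits(surface, "rhm_surface"))
  paths <- paste0(stem, c("_alpha.csv", "_pm.csv", "_r2.csv", "_meta.json"))
  write_map <- function(m, path) {
    df <- data.frame(t_c = format(surface$t_grid, digits = 17),
                     format(m, digits = 17), check.names = FALSE)
    names(df) <- c("t_c", format(surface$vcmax_grid, digits = 17))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  write_map(surface$alpha, paths[1])
  write_map(surface$pm, paths[2])
  write_map(surface$r2, paths[3])
  ek <- surface$ek_params
  class(ek) <- NULL
  jsonlite::write_json(
    list(t_grid = surface$t_grid, vcmax_grid = surface$vcmax_grid,
         ppfd_grid = surface$ppfd_grid, ek_params = ek),
    paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a persisted parameter surface
#'
#' @param stem path stem used in [write_surface()].
#' @return Object of class `rhm_surface`.
#' @export
read_surface <- function(stem) {
  paths <- paste0(stem, c("_alpha.csv", "_pm.csv", "_r2.csv", "_meta.json"))
  if (!all(file.exists(paths))) {
    stop("missing surface file(s): ",
         paste(paths[!file.exists(paths)], collapse = ", "))
  }
  meta <- jsonlite::read_json(paths[4], simplifyVector = TRUE)
  read_map <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    dimnames(m) <- list(meta$t_grid, meta$vcmax_grid)
    m
  }
  ek <- meta$ek_params
  kin <- ek$kinetics
  ek$kinetics <- NULL
  p <- do.call(leaf_ek_params, c(ek, list(kinetics = kin)))
  out <- list(t_grid = meta$t_grid, vcmax_grid = meta$vcmax_grid,
              alpha = read_map(paths[1]), pm = read_map(paths[2]),
              r2 = read_map(paths[3]), ppfd_grid = meta$ppfd_grid,
              ek_params = p)
  class(out) <- "rhm_surface"
  out
}
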