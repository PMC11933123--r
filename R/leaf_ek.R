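#' Parameters of the coupled enzyme-kinetic leaf photosynthesis model
#'
#' Builds the parameter set for the instantaneous leaf model: a Farquhar-type
#' enzyme-kinetic (EK) biochemistry coupled to the Ball-Woodrow-Berry (BWB)
#' stomatal conductance model `gs = m * An * rh / Cs + b`. The
#' Rubisco-limited rate is `Wc = Vcmax (Ci - G*) / (Ci + Kc (1 + O/Ko))` and
#' the RuBP-regeneration limited rate `Wj = J (Ci - G*) / (4 Ci + 8 G*)`,
#' with electron transport following a rectangular-hyperbolic light
#' dependence `J = aq I Jmax / (aq I + 2.1 Jmax)`. The two limits are
#' combined by the usual quadratic co-limitation (hyperbolic minimum): gross
#' assimilation is the smaller root of
#' `theta_cl W^2 - (Wc + Wj) W + Wc Wj = 0`, and `A_n = W - Rd`.
#' `theta_cl = 1` recovers the sharp `min(Wc, Wj)`; the default 0.85 gives
#' the gradual co-limitation transition observed in gas-exchange data, under
#' which every light-response curve in the working temperature x Vcmax,25
#' range is rectangular-hyperbola-like (fit R2 > 0.99), the regime in which
#' the surface compression of [build_surface()] is valid.
#'
#' Kinetic constants (25 degC values and activation energies for Kc, Ko, the
#' CO2 compensation point G*, Vcmax, Jmax and Rd) default to the Bernacchi
#' in-vivo set; Vcmax and Jmax use peaked Arrhenius responses so capacity
#' declines above the thermal optimum. `Jmax,25 = 1.3 Vcmax,25` (a
#' warm-acclimated capacity ratio) and `Rd,25 = 0.01 Vcmax,25` by default.
#' The leaf-surface CO2 is approximated by the ambient mole fraction
#' (boundary-layer conductance non-limiting) and leaf temperature equals air
#' temperature.
#'
#' @param vcmax25 maximum carboxylation rate at 25 degC (umol m-2 s-1).
#' @param jmax25_ratio Jmax,25 / Vcmax,25 (dimensionless).
#' @param rd25_ratio Rd,25 / Vcmax,25 (dimensionless).
#' @param theta_cl curvature of the Wc/Wj co-limitation quadratic, (0, 1];
#'   1 is the sharp minimum.
#' @param alpha_q quantum yield of electron transport (mol e- per mol photons).
#' @param bwb_slope,bwb_intercept BWB slope m (dimensionless) and intercept b
#'   (mol m-2 s-1, water-vapour basis; CO2 conductance is gs/1.6).
#' @param ca ambient CO2 mole fraction (umol mol-1).
#' @param oa ambient O2 mole fraction (mmol mol-1).
#' @param rh leaf-surface relative humidity (fraction, 0-1).
#' @param kinetics named list overriding any of the kinetic constants
#'   `kc25, ea_kc, ko25, ea_ko, gstar25, ea_gstar, ha_vcmax, hd_vcmax,
#'   s_vcmax, ha_jmax, hd_jmax, s_jmax, ea_rd` (energies J mol-1, entropies
#'   J mol-1 K-1).
#' @return Object of class `leaf_ek_params`.
#' @export
#' @examples
#' p <- leaf_ek_params(vcmax25 = 52)
#' gross_assimilation(p, ppfd = 1500, t_leaf = 25)
leaf_ek_params <- function(vcmax25 = 60,
                           jmax25_ratio = 1.3,
                           rd25_ratio = 0.01,
                           theta_cl = 0.85,
                           alpha_q = 0.385,
                           bwb_slope = 10,
                           bwb_intercept = 0.01,
                           ca = 380,
                           oa = 210,
                           rh = 0.7,
                           kinetics = list()) {
  kin <- list(
    kc25 = 404.9,  ea_kc = 79430,      # umol mol-1
    ko25 = 278.4,  ea_ko = 36380,      # mmol mol-1
    gstar25 = 42.75, ea_gstar = 37830, # umol mol-1
    ha_vcmax = 65330, hd_vcmax = 2e5, s_vcmax = 640,
    ha_jmax  = 43540, hd_jmax  = 2e5, s_jmax  = 640,
    ea_rd = 46390
  )
  bad <- setdiff(names(kinetics), names(kin))
  if (length(bad)) stop("unknown kinetic constant(s): ", paste(bad, collapse = ", "))
  kin[names(kinetics)] <- kinetics

  p <- list(vcmax25 = vcmax25, jmax25_ratio = jmax25_ratio,
            rd25_ratio = rd25_ratio, theta_cl = theta_cl, alpha_q = alpha_q,
            bwb_slope = bwb_slope, bwb_intercept = bwb_intercept,
            ca = ca, oa = oa, rh = rh, kinetics = kin)
  class(p) <- "leaf_ek_params"
  validate_leaf_ek_params(p)
  p
}

validate_leaf_ek_params <- function(p) {
  stopifnot(inherits(p, "leaf_ek_params"))
  if (!(p$vcmax25 > 0)) stop("vcmax25 must be > 0")
  if (!(p$rh > 0 && p$rh <= 1)) stop("rh must be in (0, 1]")
  if (!(p$jmax25_ratio > 0)) stop("jmax25_ratio must be > 0")
  if (!(p$ca > p$kinetics$gstar25)) {
    stop("ambient CO2 (ca = ", p$ca, ") must exceed the 25 degC CO2 ",
         "compensation point (", p$kinetics$gstar25, ")")
  }
  if (!(p$bwb_intercept > 0)) stop("bwb_intercept must be > 0")
  if (!(p$theta_cl > 0 && p$theta_cl <= 1)) stop("theta_cl must be in (0, 1]")
  invisible(p)
}

#' @export
print.leaf_ek_params <- function(x, ...) {
  cat("Coupled enzyme-kinetic / Ball-Berry leaf model parameters\n")
  cat(sprintf("  Vcmax,25 %.1f  Jmax,25 %.1f  Rd,25 %.3f (umol m-2 s-1)\n",
              x$vcmax25, x$vcmax25 * x$jmax25_ratio, x$vcmax25 * x$rd25_ratio))
  cat(sprintf("  BWB m %.1f  b %.3f mol m-2 s-1  Ca %.0f umol mol-1  rh %.2f\n",
              x$bwb_slope, x$bwb_intercept, x$ca, x$rh))
  invisible(x)
}

# Arrhenius response normalised to 25 degC
arrhenius <- function(ea, t_c) {
  tk <- t_c + 273.15
  exp(ea * (tk - 298.15) / (298.15 * 8.314 * tk))
}

# Peaked (deactivating) Arrhenius response normalised to 25 degC
peaked_arrhenius <- function(ha, hd, s, t_c) {
  tk <- t_c + 273.15
  arrhenius(ha, t_c) *
    (1 + exp((298.15 * s - hd) / (298.15 * 8.314))) /
    (1 + exp((s * tk - hd) / (8.314 * tk)))
}

# Temperature-adjusted kinetic quantities at leaf temperature t_c.
ek_rates <- function(p, t_c) {
  k <- p$kinetics
  list(
    vcmax = p$vcmax25 * peaked_arrhenius(k$ha_vcmax, k$hd_vcmax, k$s_vcmax, t_c),
    jmax  = p$vcmax25 * p$jmax25_ratio *
      peaked_arrhenius(k$ha_jmax, k$hd_jmax, k$s_jmax, t_c),
    rd    = p$vcmax25 * p$rd25_ratio * arrhenius(k$ea_rd, t_c),
    kc    = k$kc25 * arrhenius(k$ea_kc, t_c),
    ko    = k$ko25 * arrhenius(k$ea_ko, t_c),
    gstar = k$gstar25 * arrhenius(k$ea_gstar, t_c)
  )
}

# Solve the supply-demand balance for Ci by vectorised bisection.
# Returns list(ci, gross, an). The residual
#   f(Ci) = (gs_w(An)/1.6) (Ca - Ci) - An(Ci)
# is strictly decreasing in Ci (demand increases, supply decreases), so the
# root is unique; the bracket [G*, Ca + 1.6 Rd / b + 10] always contains it
# (at Ci = G* demand is -Rd < supply; at the upper end supply < -Rd <= demand).
ek_solve <- function(p, ppfd, t_leaf, tol = 1e-4) {
  n <- max(length(ppfd), length(t_leaf))
  ppfd <- rep_len(ppfd, n)
  t_leaf <- rep_len(t_leaf, n)
  r <- ek_rates(p, t_leaf)
  j <- p$alpha_q * ppfd * r$jmax / (p$alpha_q * ppfd + 2.1 * r$jmax)
  km <- r$kc * (1 + p$oa / r$ko)

  # smaller root of theta W^2 - (wc + wj) W + wc wj = 0; theta = 1 is min()
  colimit <- function(wc, wj) {
    th <- p$theta_cl
    if (th == 1) return(pmin(wc, wj))
    s <- wc + wj
    (s - sqrt(pmax(s^2 - 4 * th * wc * wj, 0))) / (2 * th)
  }
  an_at <- function(ci) {
    wc <- r$vcmax * (ci - r$gstar) / (ci + km)
    wj <- j * (ci - r$gstar) / (4 * ci + 8 * r$gstar)
    w <- colimit(wc, wj)
    list(an = w - r$rd, gross = w)
  }
  resid_at <- function(ci) {
    an <- an_at(ci)$an
    gs_c <- (p$bwb_slope * pmax(an, 0) * p$rh / p$ca + p$bwb_intercept) / 1.6
    gs_c * (p$ca - ci) - an
  }

  lo <- rep_len(r$gstar + 1e-9, n)
  hi <- rep_len(p$ca + 1.6 * max(r$rd) / p$bwb_intercept + 10, n)
  if (any(resid_at(lo) < 0) || any(resid_at(hi) > 0)) {
    bad <- which(resid_at(lo) < 0 | resid_at(hi) > 0)[1]
    stop("no root of the stomatal supply / biochemical demand balance in (",
         "G*, bracket] for ppfd = ", ppfd[bad], ", t_leaf = ", t_leaf[bad])
  }
  n_iter <- ceiling(log2((hi[1] - lo[1]) / tol)) + 2L
  for (i in seq_len(n_iter)) {
    mid <- 0.5 * (lo + hi)
    pos <- resid_at(mid) > 0
    lo <- ifelse(pos, mid, lo)
    hi <- ifelse(pos, hi, mid)
  }
  ci <- 0.5 * (lo + hi)
  out <- an_at(ci)
  list(ci = ci, gross = pmax(out$gross, 0), an = out$an)
}

#' Instantaneous leaf gross assimilation
#'
#' Gross CO2 assimilation (net assimilation plus dark respiration, i.e.
#' `min(Wc, Wj)`) at the intercellular CO2 that simultaneously satisfies the
#' biochemical demand curve and the Ball-Woodrow-Berry stomatal supply curve.
#' The balance is solved by bisection on the supply-demand residual
#' (absolute Ci tolerance 1e-4 umol mol-1); vectorised over `ppfd` and
#' `t_leaf`.
#'
#' @param params [leaf_ek_params()] object.
#' @param ppfd incident photosynthetic photon flux density (umol m-2 s-1),
#'   vector allowed.
#' @param t_leaf leaf (= air) temperature (degC, 0-50), vector allowed.
#' @return Gross assimilation (umol CO2 m-2 s-1), non-negative, same length
#'   as the longer of `ppfd` / `t_leaf`.
#' @export
#' @examples
#' p <- leaf_ek_params(vcmax25 = 52)
#' gross_assimilation(p, ppfd = c(0, 500, 1000, 2000), t_leaf = 25)
gross_assimilation <- function(params, ppfd, t_leaf) {
  validate_leaf_ek_params(params)
  if (any(ppfd < 0)) stop("ppfd must be >= 0")
  if (any(t_leaf < 0 | t_leaf > 50)) stop("t_leaf must be within [0, 50] degC")
  ek_solve(params, ppfd, t_leaf)$gross
}

#' Enzyme-kinetic light-response curve
#'
#' Evaluates the leaf model over a PPFD sweep at fixed temperature, the raw
#' material for rectangular-hyperbola fitting.
#'
#' @inheritParams gross_assimilation
#' @param ppfd_grid ascending PPFD values (umol m-2 s-1).
#' @return `data.frame(ppfd, a_gross)`.
#' @export
light_response <- function(params, ppfd_grid = seq(50, 2000, by = 50),
                           t_leaf = 25) {
  stopifnot(length(t_leaf) == 1, !is.unsorted(ppfd_grid, strictly = TRUE))
  data.frame(ppfd = ppfd_grid,
             a_gross = gross_assimilation(params, ppfd_grid, t_leaf))
}
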