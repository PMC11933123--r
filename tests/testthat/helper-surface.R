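# Shared fixtures built once per test run.

# Coarse but full-range parameter surface; cheap (~0.4 s) and sufficient for
# canopy-level tests. Cells are exact fits, interpolation is coarser than the
# default surface.
test_surface <- local({
  surf <- NULL
  function() {
    if (is.null(surf)) {
      surf <<- build_surface(t_grid = seq(1, 40, by = 3),
                             vcmax_grid = seq(20, 180, by = 20))
    }
    surf
  }
})

# Exact rectangular hyperbola sample
exact_hyperbola <- function(alpha = 0.05, pm = 20,
                            ppfd = seq(50, 2000, by = 50)) {
  data.frame(ppfd = ppfd, a_gross = alpha * pm * ppfd / (pm + alpha * ppfd))
}

# Brute-force Ci-scan oracle for the coupled leaf model: scans Ci on a fine
# grid for the supply-demand sign change, independently of the bisection
# solver.
ek_ci_scan <- function(p, ppfd, t_leaf, ci_step = 0.01) {
  r <- tlrhm:::ek_rates(p, t_leaf)
  j <- p$alpha_q * ppfd * r$jmax / (p$alpha_q * ppfd + 2.1 * r$jmax)
  km <- r$kc * (1 + p$oa / r$ko)
  ci <- seq(r$gstar + ci_step, p$ca + 1.6 * r$rd / p$bwb_intercept + 10,
            by = ci_step)
  wc <- r$vcmax * (ci - r$gstar) / (ci + km)
  wj <- j * (ci - r$gstar) / (4 * ci + 8 * r$gstar)
  w <- if (p$theta_cl == 1) pmin(wc, wj) else
    ((wc + wj) - sqrt(pmax((wc + wj)^2 - 4 * p$theta_cl * wc * wj, 0))) /
      (2 * p$theta_cl)
  an <- w - r$rd
  res <- ((p$bwb_slope * pmax(an, 0) * p$rh / p$ca + p$bwb_intercept) / 1.6) *
    (p$ca - ci) - an
  i <- which(res <= 0)[1]
  list(ci = ci[i], gross = max(w[i], 0))
}
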