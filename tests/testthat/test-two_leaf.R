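test_that("leaf-area partition matches its gap-probability formula", {
  p0 <- partition_lai(0, 0.8, 30)
  expect_equal(p0$lai_sunlit, 0); expect_equal(p0$lai_shaded, 0)
  # direct evaluation of 2 cos(t) (1 - exp(-0.5 omega lai / cos(t)))
  p <- partition_lai(4, 0.8, 30)
  ct <- cos(30 * pi / 180)
  expect_equal(p$lai_sunlit, 2 * ct * (1 - exp(-0.5 * 0.8 * 4 / ct)))
  expect_equal(p$lai_shaded, 4 - p$lai_sunlit)
  # dense-canopy asymptote at zenith 0, omega 1: 2 cos(theta) = 2
  expect_equal(partition_lai(60, 1, 0)$lai_sunlit, 2, tolerance = 1e-6)
  expect_error(partition_lai(4, 0.8, 90), "theta")
  expect_error(partition_lai(4, 1.5, 30), "omega")
})

test_that("leaf area is conserved for arbitrary inputs", {
  set.seed(11)
  lai <- runif(200, 0, 10); om <- runif(200, 0.3, 1)
  th <- runif(200, 0, 89.9)
  p <- partition_lai(lai, om, th)
  expect_equal(p$lai_sunlit + p$lai_shaded, lai)
  expect_true(all(p$lai_sunlit >= 0) && all(p$lai_shaded >= 0))
})

test_that("APAR partition obeys its limiting cases", {
  z <- partition_apar(0, 0.3, 4, 0.8, 30)
  expect_equal(z$apar_sunlit, 0); expect_equal(z$apar_shaded, 0)
  # fully diffuse sky: no direct beam, classes see the same flux
  d <- partition_apar(40, 1, 4, 0.8, 30)
  expect_equal(d$apar_sunlit, d$apar_shaded)
  set.seed(21)
  for (i in 1:50) {
    ap <- partition_apar(runif(1, 1, 60), runif(1), runif(1, 0.1, 8),
                         runif(1, 0.4, 1), runif(1, 5, 80))
    expect_gte(ap$apar_sunlit, ap$apar_shaded)
    expect_gte(ap$apar_shaded, 0)
  }
})

test_that("APAR partition matches a step-by-step evaluation", {
  cfg <- tlrhm_config()
  par <- 40; df <- 0.3; lai <- 4; om <- 0.8; th <- 30
  i_dif <- df * par; i_dir <- (1 - df) * par
  under <- i_dif * exp(-0.5 * om * lai / cos(57.3 * pi / 180))
  scat <- 0.07 * om * i_dir * (1.1 - 0.1 * lai) * exp(-cos(th * pi / 180))
  sh <- (i_dif - under) / lai + scat
  su <- i_dir * 0.5 / cos(th * pi / 180) + sh
  got <- partition_apar(par, df, lai, om, th, cfg)
  expect_equal(got$apar_shaded, 0.9 * sh)
  expect_equal(got$apar_sunlit, 0.9 * su)
  # scattering term switchable
  cfg2 <- tlrhm_config(two_leaf = list(scattering = FALSE))
  got2 <- partition_apar(par, df, lai, om, th, cfg2)
  expect_equal(got2$apar_shaded, 0.9 * (i_dif - under) / lai)
})

make_day <- function(doy = 180, lat = 45, rg = 25, tmax = 24, tmin = 14,
                     rh = 70, lai = 4) {
  list(doy = doy, lat = lat, rg = rg, tmax = tmax, tmin = tmin, rh = rh,
       lai = lai)
}

test_that("canopy GPP chains lookup, daily form, two-leaf sum and f(VPD)", {
  surf <- test_surface()
  drv <- make_day()
  res <- canopy_gpp_daily(drv, surf, vcmax25 = 60, form = "sine")
  # hand-chained oracle outside the operation
  cfg <- tlrhm_config()
  dl <- daylength(drv$lat, drv$doy)
  tp <- daytime_temperature(drv$tmax, drv$tmin, dl)
  par <- drv$rg * 0.47 * 4.55
  df <- diffuse_fraction(drv$rg, drv$lat, drv$doy)
  th <- representative_zenith(drv$lat, drv$doy)
  lp <- partition_lai(drv$lai, 0.8, th)
  ap <- partition_apar(par, df, drv$lai, 0.8, th)
  pars <- surface_lookup(surf, tp, 60)
  g_sun <- umol_to_gc(gpp_daily_sine(pars$alpha, pars$pm, ap$apar_sunlit, dl))
  g_sh <- umol_to_gc(gpp_daily_sine(pars$alpha, pars$pm, ap$apar_shaded, dl))
  canopy <- g_sun * lp$lai_sunlit + g_sh * lp$lai_shaded
  fv <- f_vpd(vpd_from(tp, drv$rh))
  expect_equal(res$gpp_sunlit, g_sun)
  expect_equal(res$gpp_shaded, g_sh)
  expect_equal(res$gpp_canopy, canopy)
  expect_equal(res$gpp_actual, canopy * fv)
  expect_equal(res$f_vpd, fv)
})

test_that("canopy edge cases: bare ground, saturating VPD, missing fields", {
  surf <- test_surface()
  bare <- canopy_gpp_daily(make_day(lai = 0), surf, 60)
  expect_equal(bare$gpp_canopy, 0)
  expect_equal(bare$gpp_actual, 0)
  dry <- make_day(); dry$vpd <- 5000; dry$rh <- NULL
  res <- canopy_gpp_daily(dry, surf, 60)
  expect_equal(res$gpp_actual, 0)
  expect_gt(res$gpp_canopy, 0)
  drv <- make_day(); drv$tmax <- NULL; drv$rh <- NULL
  expect_error(canopy_gpp_daily(drv, surf, 60), "tmax.*rh")
})

test_that("sine form dominates sinesine form across random synthetic days", {
  surf <- test_surface()
  set.seed(31)
  for (i in 1:60) {
    drv <- make_day(doy = sample(365, 1), lat = runif(1, 0, 60),
                    rg = runif(1, 1, 30), tmin = runif(1, 0, 20),
                    rh = runif(1, 30, 100), lai = runif(1, 0.1, 8))
    drv$tmax <- drv$tmin + runif(1, 0, 15)
    if (daylength(drv$lat, drv$doy) == 0) next
    s <- canopy_gpp_daily(drv, surf, 60, form = "sine")
    ss <- canopy_gpp_daily(drv, surf, 60, form = "sinesine")
    expect_gte(s$gpp_canopy, ss$gpp_canopy)
    expect_gte(s$gpp_actual, ss$gpp_actual)
  }
})

test_that("canopy GPP does not decrease with LAI on a clear day", {
  surf <- test_surface()
  g <- vapply(seq(0, 8, by = 0.5), function(l) {
    canopy_gpp_daily(make_day(lai = l, rg = 28), surf, 60)$gpp_canopy
  }, 0)
  expect_true(all(diff(g) >= -1e-9))
})

test_that("VPD boundaries switch downregulation on and off", {
  surf <- test_surface()
  wet <- make_day(); wet$vpd <- 650; wet$rh <- NULL
  res <- canopy_gpp_daily(wet, surf, 60)
  expect_equal(res$gpp_actual, res$gpp_canopy)
  moist <- make_day(); moist$vpd <- 2575; moist$rh <- NULL
  res2 <- canopy_gpp_daily(moist, surf, 60)
  expect_equal(res2$gpp_actual, res2$gpp_canopy * 0.5)
})
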