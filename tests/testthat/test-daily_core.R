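test_that("no absorbed light gives zero daily GPP", {
  expect_equal(gpp_daily_sine(0.05, 20, 0, 12 * 3600), 0)
  expect_equal(gpp_daily_sinesine(0.05, 20, 0, 12 * 3600), 0)
  expect_equal(gpp_daily_numeric(0.05, 20, 0, 12 * 3600, "sine"), 0)
})

# apar_daily (mol m-2 d-1) that yields a given shape parameter a
apar_for_a <- function(a, alpha, pm, daylength, noon_coef) {
  pm / (alpha * a) * daylength / noon_coef / 1e6
}

test_that("strong light saturation approaches Pm * Daylength", {
  al <- 0.05; pm <- 20; D <- 12 * 3600
  g <- gpp_daily_sine(al, pm, apar_for_a(1e-4, al, pm, D, pi / 2), D)
  expect_equal(g / (pm * D), 1, tolerance = 1e-3)
  # the squared-sine form converges as sqrt(a): 1% at a = 1e-4, 0.1% at 1e-6
  g4 <- gpp_daily_sinesine(al, pm, apar_for_a(1e-4, al, pm, D, 2), D)
  expect_equal(g4 / (pm * D), 1 - sqrt(1e-4 / (1 + 1e-4)), tolerance = 1e-6)
  g6 <- gpp_daily_sinesine(al, pm, apar_for_a(1e-6, al, pm, D, 2), D)
  expect_equal(g6 / (pm * D), 1, tolerance = 1.1e-3)
})

test_that("closed forms agree with adaptive quadrature over a random sweep", {
  set.seed(101)
  for (i in 1:400) {
    al <- runif(1, 0.01, 0.1); pm <- runif(1, 2, 50)
    D <- runif(1, 4, 20) * 3600; ap <- runif(1, 0.5, 70)
    cs <- gpp_daily_sine(al, pm, ap, D)
    ns <- gpp_daily_numeric(al, pm, ap, D, "sine")
    expect_equal(cs, ns, tolerance = 1e-6)
    css <- gpp_daily_sinesine(al, pm, ap, D)
    nss <- gpp_daily_numeric(al, pm, ap, D, "sinesine")
    expect_equal(css, nss, tolerance = 1e-6)
  }
})

test_that("the three sine branches join continuously at a = 1", {
  al <- 0.05; pm <- 20; D <- 12 * 3600
  at_one <- gpp_daily_sine(al, pm, apar_for_a(1, al, pm, D, pi / 2), D)
  expect_equal(at_one / (pm * D), 1 - 2 / pi, tolerance = 1e-12)
  for (da in c(1e-5, 1e-7)) {
    above <- gpp_daily_sine(al, pm, apar_for_a(1 + da, al, pm, D, pi / 2), D)
    below <- gpp_daily_sine(al, pm, apar_for_a(1 - da, al, pm, D, pi / 2), D)
    expect_equal(above, at_one, tolerance = 1e-4)
    expect_equal(below, at_one, tolerance = 1e-4)
    expect_equal(above,
                 gpp_daily_numeric(al, pm, apar_for_a(1 + da, al, pm, D,
                                                      pi / 2), D, "sine"),
                 tolerance = 1e-6)
  }
})

test_that("daily GPP is monotone in alpha, Pm and APAR and bounded", {
  set.seed(7)
  for (fun in list(gpp_daily_sine, gpp_daily_sinesine)) {
    for (i in 1:50) {
      al <- runif(1, 0.01, 0.1); pm <- runif(1, 2, 50)
      D <- runif(1, 4, 20) * 3600; ap <- runif(1, 0.5, 70)
      g <- fun(al, pm, ap, D)
      expect_gte(g, 0); expect_lte(g, pm * D)
      expect_gte(fun(al * 1.1, pm, ap, D), g)
      expect_gte(fun(al, pm * 1.1, ap, D), g)
      expect_gte(fun(al, pm, ap * 1.1, D), g)
    }
  }
})

test_that("sine-profile GPP dominates squared-sine GPP for identical inputs", {
  set.seed(13)
  for (i in 1:300) {
    al <- runif(1, 0.01, 0.1); pm <- runif(1, 2, 50)
    D <- runif(1, 4, 20) * 3600; ap <- runif(1, 0.1, 70)
    expect_gte(gpp_daily_sine(al, pm, ap, D),
               gpp_daily_sinesine(al, pm, ap, D))
  }
})

test_that("noon factors integrate each profile back to the daily total", {
  D <- 13.5 * 3600; ap <- 40 # mol m-2 d-1
  sine_noon <- (pi / 2) * ap / D
  back <- stats::integrate(function(t) sine_noon * sin(pi * t / D), 0, D,
                           rel.tol = 1e-12)$value
  expect_equal(back, ap, tolerance = 1e-10)
  ss_noon <- 2 * ap / D
  back2 <- stats::integrate(function(t) ss_noon * sin(pi * t / D)^2, 0, D,
                            rel.tol = 1e-12)$value
  expect_equal(back2, ap, tolerance = 1e-10)
})

test_that("quadrature oracle is converged in its step limit", {
  g1 <- gpp_daily_numeric(0.05, 20, 30, 12 * 3600, "sine", n_steps = 1e4)
  g2 <- gpp_daily_numeric(0.05, 20, 30, 12 * 3600, "sine", n_steps = 2e4)
  expect_equal(g1, g2, tolerance = 1e-8)
})

test_that("degenerate daylength and negative inputs are rejected", {
  expect_error(gpp_daily_sine(0.05, 20, 30, 0), "daylength")
  expect_error(gpp_daily_sine(0.05, 20, -1, 3600), "apar")
  expect_error(gpp_daily_sinesine(-0.05, 20, 30, 3600), "alpha")
})
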