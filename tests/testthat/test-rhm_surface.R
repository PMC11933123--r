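test_that("an exact hyperbola is recovered to machine precision", {
  fit <- fit_hyperbola(exact_hyperbola(alpha = 0.05, pm = 20))
  expect_equal(fit$alpha, 0.05, tolerance = 1e-6)
  expect_equal(fit$pm, 20, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("fitting is scale-consistent in the response", {
  pts <- exact_hyperbola(alpha = 0.04, pm = 12)
  f1 <- fit_hyperbola(pts)
  pts$a_gross <- pts$a_gross * 3.7
  f2 <- fit_hyperbola(pts)
  expect_equal(f2$alpha / f1$alpha, 3.7, tolerance = 1e-6)
  expect_equal(f2$pm / f1$pm, 3.7, tolerance = 1e-6)
})

test_that("enzyme-kinetic curves fit with the claimed fidelity", {
  f <- fit_hyperbola(light_response(leaf_ek_params(vcmax25 = 52), t_leaf = 25))
  expect_gte(f$r2, 0.99)
})

test_that("nonlinear fit matches a two-stage grid-search oracle", {
  pts <- light_response(leaf_ek_params(vcmax25 = 100), t_leaf = 10)
  sse <- function(a, pm) {
    sum((pts$a_gross - a * pm * pts$ppfd / (pm + a * pts$ppfd))^2)
  }
  # coarse scan over alpha in (0, 0.12], Pm in (0, 60], then local refine
  best <- c(a = NA, pm = NA); best_sse <- Inf
  for (a in seq(0.002, 0.12, by = 0.002)) {
    for (pm in seq(0.5, 60, by = 0.5)) {
      s <- sse(a, pm)
      if (s < best_sse) { best_sse <- s; best <- c(a = a, pm = pm) }
    }
  }
  for (a in seq(best["a"] * 0.9, best["a"] * 1.1, length.out = 81)) {
    for (pm in seq(best["pm"] * 0.95, best["pm"] * 1.05, length.out = 81)) {
      s <- sse(a, pm)
      if (s < best_sse) { best_sse <- s; best <- c(a = a, pm = pm) }
    }
  }
  fit <- fit_hyperbola(pts)
  expect_equal(fit$alpha, unname(best["a"]), tolerance = 0.01)
  expect_equal(fit$pm, unname(best["pm"]), tolerance = 0.01)
})

test_that("degenerate or malformed light responses are rejected", {
  expect_error(fit_hyperbola(data.frame(ppfd = 1:10, a_gross = 0)),
               "degenerate")
  expect_error(fit_hyperbola(exact_hyperbola(ppfd = seq(50, 200, 50))),
               "at least 5")
  pts <- exact_hyperbola()
  pts$ppfd[2] <- pts$ppfd[3]
  expect_error(fit_hyperbola(pts), "strictly increasing")
  pts <- exact_hyperbola(); pts$a_gross[1] <- -1
  expect_error(fit_hyperbola(pts), ">= 0")
})

test_that("surface maps are positive, smooth and physically ordered", {
  surf <- test_surface()
  expect_true(all(is.finite(surf$alpha)), info = "alpha finite")
  expect_true(all(surf$alpha > 0) && all(surf$pm > 0))
  expect_gte(min(surf$r2), 0.99)
  # Pm strictly increasing in Vcmax,25 near 25 degC, as direct EK
  # evaluations at saturating light confirm
  row25 <- which.min(abs(surf$t_grid - 25))
  expect_true(all(diff(surf$pm[row25, ]) > 0))
  sat <- vapply(surf$vcmax_grid, function(vc) {
    gross_assimilation(leaf_ek_params(vcmax25 = vc), 2000,
                       surf$t_grid[row25])
  }, 0)
  expect_true(all(diff(sat) > 0))
  # continuity smoke check on this deliberately coarse grid; the 25 %
  # adjacent-cell bound is asserted on the default-resolution surface in
  # the end-to-end suite
  rel_jump <- function(m) {
    max(abs(diff(m)) / m[-1, ], abs(t(diff(t(m)))) / m[, -1])
  }
  expect_lt(rel_jump(surf$alpha), 0.5)
  expect_lt(rel_jump(surf$pm), 0.5)
})

test_that("a single-cell surface equals a direct fit", {
  surf1 <- build_surface(t_grid = 25, vcmax_grid = 52)
  fit <- fit_hyperbola(light_response(leaf_ek_params(vcmax25 = 52),
                                      t_leaf = 25))
  expect_equal(as.numeric(surf1$alpha), fit$alpha)
  expect_equal(as.numeric(surf1$pm), fit$pm)
})

test_that("the fidelity gate names the offending cell", {
  expect_error(build_surface(t_grid = c(25, 30), vcmax_grid = c(52, 60),
                             r2_gate = 0.9999999),
               "T = 25.*Vcmax,25 = 52")
})

test_that("bilinear lookup is exact at nodes and averages at midpoints", {
  surf <- test_surface()
  it <- 3; iv <- 4
  node <- surface_lookup(surf, surf$t_grid[it], surf$vcmax_grid[iv])
  expect_identical(node$alpha, surf$alpha[it, iv])
  expect_identical(node$pm, surf$pm[it, iv])
  tm <- mean(surf$t_grid[it:(it + 1)])
  vm <- mean(surf$vcmax_grid[iv:(iv + 1)])
  mid <- surface_lookup(surf, tm, vm)
  expect_equal(mid$alpha, mean(surf$alpha[it:(it + 1), iv:(iv + 1)]))
  expect_equal(mid$pm, mean(surf$pm[it:(it + 1), iv:(iv + 1)]))
})

test_that("interpolated parameters match a fresh off-grid fit within 2%", {
  surf <- test_surface()
  q <- surface_lookup(surf, 22.3, 63)
  fresh <- fit_hyperbola(light_response(leaf_ek_params(vcmax25 = 63),
                                        t_leaf = 22.3))
  expect_equal(q$alpha, fresh$alpha, tolerance = 0.02)
  expect_equal(q$pm, fresh$pm, tolerance = 0.02)
})

test_that("out-of-range queries error unless clamping is requested", {
  surf <- test_surface()
  expect_error(surface_lookup(surf, 45, 60), "outside")
  expect_error(surface_lookup(surf, 25, 300), "outside")
  cl <- surface_lookup(surf, 45, 60, clamp = TRUE)
  edge <- surface_lookup(surf, max(surf$t_grid), 60)
  expect_equal(cl$pm, edge$pm)
})

test_that("surface persistence round-trips bit-exactly", {
  surf <- test_surface()
  stem <- file.path(tempdir(), "surf_rt")
  write_surface(surf, stem)
  back <- read_surface(stem)
  expect_identical(back$alpha, surf$alpha)
  expect_identical(back$pm, surf$pm)
  expect_identical(back$r2, surf$r2)
  expect_equal(back$t_grid, surf$t_grid)
  expect_equal(back$vcmax_grid, surf$vcmax_grid)
  expect_equal(back$ek_params$vcmax25, surf$ek_params$vcmax25)
  expect_equal(back$ek_params$kinetics, surf$ek_params$kinetics)
})
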