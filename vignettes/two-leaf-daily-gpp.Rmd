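---
title: "Methods: a two-leaf daily GPP model from a temperature-adapted rectangular hyperbola"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-leaf daily GPP model from a temperature-adapted rectangular hyperbola}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlrhm)
```

## The modelling problem

Daily gross primary productivity (GPP) of a vegetated site is usually
estimated either with light-use-efficiency models (simple, daily, but with
little physiological mechanism) or with process models built on the
enzyme-kinetic (EK, Farquhar-type) leaf photosynthesis model coupled to a
stomatal conductance model, run at half-hourly steps (mechanistic, but
demanding sub-daily forcing). This package implements a middle road: the EK
leaf model is *compressed* into the two parameters of a rectangular
hyperbola whose values depend on air temperature and on the vegetation-type
carboxylation capacity, the hyperbola is *integrated analytically* over an
assumed diurnal radiation course, and the result is upscaled to the canopy
with a sunlit/shaded two-leaf scheme and downregulated by a vapour pressure
deficit (VPD) scalar. The model then needs only daily drivers — radiation,
temperature extremes, humidity, leaf area index (LAI) — while retaining an
enzyme-kinetic backbone.

## The leaf model and its compression

The instantaneous leaf model (`leaf_ek_params()`, `gross_assimilation()`)
is the canonical coupled system:

* Rubisco-limited rate $W_c = V_{cmax}\,(C_i-\Gamma^*)/(C_i + K_c(1+O/K_o))$,
* RuBP-regeneration rate $W_j = J\,(C_i-\Gamma^*)/(4C_i + 8\Gamma^*)$ with a
  rectangular-hyperbolic light dependence
  $J = \alpha_q I J_{max}/(\alpha_q I + 2.1 J_{max})$,
* Ball–Woodrow–Berry conductance $g_s = m A_n\,rh/C_s + b$, with the
  leaf-surface CO$_2$ approximated by the ambient mole fraction and leaf
  temperature equal to air temperature,
* Bernacchi-type Arrhenius kinetics, with peaked (deactivating) responses
  for $V_{cmax}$ and $J_{max}$.

$C_i$ is solved by bisection on the supply–demand residual (absolute
tolerance $10^{-4}\,\mu$mol mol$^{-1}$, vectorised); a brute-force
$C_i$-scan oracle in the test suite confirms the root to better than
0.1 $\mu$mol mol$^{-1}$.

The two limiting rates are combined with the standard quadratic
co-limitation (hyperbolic minimum) with curvature $\theta_{cl}$; gross
assimilation is the smaller root of
$\theta_{cl} W^2 - (W_c + W_j)W + W_c W_j = 0$. This choice matters more
here than in ordinary leaf simulation, because the whole construction rests
on every light-response curve in the working range being
rectangular-hyperbola-like. With a sharp minimum ($\theta_{cl}=1$) the
curves develop Blackman-type kinks wherever the Rubisco ceiling cuts the
rising RuBP-limited branch, and hyperbola fits at cold or hot, low-capacity
corners of the grid degrade to $R^2 \approx 0.89$–0.96. We therefore adopt
the gradual co-limitation observed in gas-exchange data,
$\theta_{cl} = 0.85$, together with a warm-acclimated capacity ratio
$J_{max,25} = 1.3\,V_{cmax,25}$ and $R_{d,25} = 0.01\,V_{cmax,25}$; under
these defaults every cell of the default surface fits with $R^2 > 0.996$.
All of these constants are arguments of `leaf_ek_params()`, and
$\theta_{cl}=1$ restores the sharp minimum for users who want it.

Compression (`build_surface()`): for every combination of air temperature
$T$ (1–40 °C, step 1) and $V_{cmax,25}$ (20–180 $\mu$mol m$^{-2}$ s$^{-1}$,
step 10), a light-response curve is generated at PPFD 50–2000 (step 50)
$\mu$mol m$^{-2}$ s$^{-1}$ and fitted with

$$\mathrm{GPP}(I) = \frac{\alpha P_m I}{P_m + \alpha I},$$

by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`; initial slope
and maximum response as starting values, one restart on failure). The fits
define the maps $\alpha(V_{cmax,25},T)$ and $P_m(V_{cmax,25},T)$, queried
by bilinear interpolation (`surface_lookup()`; exact at nodes, error — or
optional clamping — outside the grid). A fidelity gate aborts the build if
any cell fits with $R^2$ below 0.99, so a surface object can only exist in
the regime where the compression is valid. During surface generation the
ambient CO$_2$ is fixed at 380 $\mu$mol mol$^{-1}$ and the leaf-surface
relative humidity at 0.70; humidity variation enters the daily model
through the VPD scalar instead, and CO$_2$ effects are outside the model's
scope.

The PPFD step of 50 (40 points per curve) balances fit stability against
cost; the fit is to *gross* assimilation (net plus day respiration), since
the quantity being modelled is GPP. $R^2$ is computed unweighted against
the fitted points.

## Analytical daily integration

Writing the absorbed PAR course as $\mathrm{APAR}(t) =
\mathrm{APAR}_{noon}\sin(\pi t/D)$ or $\mathrm{APAR}_{noon}\sin^2(\pi t/D)$
over the daylight period $D$, the noon values that integrate back to the
daily total $\mathrm{APAR}_{daily}$ are $\frac{\pi}{2}\,
\mathrm{APAR}_{daily}/D$ (sine) and $2\,\mathrm{APAR}_{daily}/D$
(squared sine) — verified in the tests by quadrature to $10^{-10}$
relative. With the saturation parameter
$a = P_m/(\alpha\,\mathrm{APAR}_{noon})$ the daily integral of the
hyperbola has closed forms (`gpp_daily_sine()`, `gpp_daily_sinesine()`):

* sine, $a^2>1$: $P_m D\left[1-\frac{2a}{\pi\sqrt{a^2-1}}
  \left(\frac{\pi}{2}-\arctan\frac{1}{\sqrt{a^2-1}}\right)\right]$
* sine, $a=1$: $P_m D\,(1-2/\pi)$
* sine, $a^2<1$: $P_m D\left[1-\frac{a}{\pi\sqrt{1-a^2}}
  \ln\frac{1+\sqrt{1-a^2}}{1-\sqrt{1-a^2}}\right]$
* squared sine (all $a$): $P_m D\left(1-\sqrt{a/(a+1)}\right)$

All branches were re-derived symbolically from the integral and accepted
only once they matched an adaptive-quadrature oracle
(`gpp_daily_numeric()`) to $10^{-6}$ relative over $10^4$ random parameter
draws, including a dense sweep across $a=1$. Numerical care: queries with
$|a-1|<10^{-9}$ are routed to the $a=1$ branch to avoid catastrophic
cancellation; the squared-sine form is evaluated as
$P_m D/\big((a{+}1)(1+\sqrt{a/(a+1)})\big)$, which is stable for large $a$;
$\mathrm{APAR}_{daily}=0$ returns exactly zero. Small $a$ means light
saturation (GPP $\to P_m D$, at $\sqrt a$ rate for the squared-sine form),
large $a$ light limitation (GPP $\to \alpha\,\mathrm{APAR}_{daily}$).

For identical $(\alpha, P_m, \mathrm{APAR}_{daily}, D)$ the sine form is
never smaller than the squared-sine form: the squared-sine profile
concentrates more radiation into the already-saturated noon hours. The
test suite asserts this ordering on $10^3$ random days and at canopy level.

## Environment derivations

* **Daylength and solar geometry** (`daylength()`, `toa_radiation()`): the
  harmonic FAO-56 declination $0.409\sin(2\pi\,\mathrm{doy}/365 - 1.39)$,
  sunset hour angle, and the FAO-56 extraterrestrial daily radiation. The
  harmonic declination is exactly antisymmetric half a year apart, which
  keeps daylength hemispherically symmetric; it agrees with an independent
  reference computation to within minutes.
* **Daytime temperature $T_p$** (`daytime_temperature()`): the daily model
  needs the mean temperature of the photosynthetically active (daylight)
  period. We reconstruct a diurnal sinusoid with its minimum at sunrise and
  its maximum 1.8 h after mid-day (Parton–Logan form) and average it
  analytically over the daylight window; `method = "mean"` falls back to
  $(t_{max}+t_{min})/2$. Whether flux processing derives $T_p$ from
  daytime half-hourly means or from the extremes is site-specific; the
  choice is exposed in the configuration.
* **VPD** (`vpd_from()`, `f_vpd()`): Tetens saturation over water;
  downregulation is 1 below 650 Pa, 0 above 4500 Pa, linear between —
  the calibrated breakpoints shared by all four vegetation types. A
  provided `vpd_pa` column takes precedence over computation from
  $(T_p, rh)$.
* **Diffuse fraction** (`diffuse_fraction()`): quartic polynomial in the
  daily clearness index (the form used throughout the sunlit/shaded GPP
  literature), coefficients recorded in `tlrhm_config()` so they are
  auditable, clipped to $[0.13, 1]$, with zero radiation treated as fully
  diffuse.
* **PAR conversion**: PAR = 0.47 × global shortwave; 4.55 $\mu$mol
  photons J$^{-1}$. Configurable.

## Two-leaf upscaling

With $\Omega$ the clumping index (defaults per vegetation type: ENF 0.6,
DBF 0.8, GRA 0.9, EBF 0.8) and $\theta$ the representative zenith:

$$\mathrm{LAI}_{sun} = 2\cos\theta\,(1 - e^{-0.5\,\Omega\,
\mathrm{LAI}/\cos\theta}), \qquad \mathrm{LAI}_{sh} = \mathrm{LAI} -
\mathrm{LAI}_{sun}.$$

Shaded leaves receive the canopy-attenuated diffuse flux plus a
multiple-scattering term $0.07\,\Omega I_{dir}(1.1-0.1\,\mathrm{LAI})
e^{-\cos\theta}$ (switchable); sunlit leaves add the direct beam on the
mean leaf–sun geometry ($\cos\beta = 0.5$, spherical leaf angles). Leaf
absorptance is 0.9. Because a daily model has no within-day zenith, the
partition uses a single representative $\theta$: the radiation-weighted
daytime mean, $\cos\theta_{rep} = \int\cos^2\theta\,dt / \int\cos\theta\,
dt$, evaluated analytically (`representative_zenith()`). Both leaf classes
share the same $(\alpha, P_m)$ — only their absorbed PAR differs — and each
class's daily APAR is assumed to follow the same diurnal shape as the
canopy total, so the closed forms apply per class:

$$\mathrm{GPP}_{canopy} = \mathrm{GCA}_{sun}\,\mathrm{LAI}_{sun} +
\mathrm{GCA}_{sh}\,\mathrm{LAI}_{sh}, \qquad \mathrm{GPP}_{actual} =
\mathrm{GPP}_{canopy}\, f(\mathrm{VPD}).$$

Outputs are converted to g C m$^{-2}$ day$^{-1}$ (12.011 × 10$^{-6}$ g per
$\mu$mol CO$_2$) only at the reporting boundary. Winter temperatures below
the 1 °C surface floor are clamped to the grid edge in the simulation path
(LAI is near its floor then, so the effect on annual totals is negligible).

## Calibration

`calibrate_vcmax()` performs ensemble runs over a candidate grid of
$V_{cmax,25}$, pools all days across the supplied site-years, and selects
the candidate minimising RMSE against measured GPP (ties toward the smaller
candidate; $R^2$ — squared Pearson correlation by default, coefficient of
determination by flag — reported alongside). RMSE is the objective because
it is scale-aware; pooling across sites is the default, per-site weighting
being a trivial variation the user can apply by calibrating sites
separately. The function's default grid is 20–180 step 1; the package's
parameter-recovery experiments use step 5 (the resolution at which
vegetation-type capacities are ecologically distinct) over the full range,
which keeps a ten-seed ensemble under a minute. Recovery of a known
generating $V_{cmax,25} = 60$ succeeds to within one grid step in the test
suite across ten seeds.

## The synthetic generator and its truth oracle

`generate_site_year()` emulates one year at a mid-latitude flux site:
seasonal sinusoidal temperature (annual mean 9 °C, half-amplitude 12 °C,
warmest around day 200, diurnal range 8 °C, day-to-day noise 1.5 °C),
radiation as top-of-atmosphere flux times a daily stochastic clearness
index (scaled Beta(3, 1.5) on [0.2, 0.72]; "clear" mode fixes it at 0.72),
a double-logistic LAI phenology between 0.3 and 5 m$^2$ m$^{-2}$, and
constant-within-day relative humidity around 75%. Half-hourly PPFD follows
the configured sine or squared-sine profile; half-hourly temperature
follows the same Parton–Logan sinusoid the daily model assumes. The daily
driver table is produced by aggregating the half-hourly record with
`aggregate_halfhourly()`, so daily and half-hourly data are exactly
consistent by construction. A single seed determines everything.

`truth_gpp_halfhourly()` is the process-model reference: the EK leaf model
evaluated every half hour for both leaf classes at the true $V_{cmax,25}$
and summed to daily totals. Its default `partition = "daily"` performs the
sunlit/shaded split once per day at the representative zenith and
distributes each class's daily absorbed PAR over the half hours in
proportion to incident PPFD; the comparison against the daily closed form
then isolates exactly the hyperbola-compression error, which is the claim
under test (asserted to be within 5% on clear constant-temperature days).
`partition = "instantaneous"` recomputes the split from the
instantaneous zenith each half hour for users who want the fuller process
chain; the two agree to within ~15% and the choice is asserted in the
tests. The truth series applies the same $f(\mathrm{VPD})$ scalar as the
daily model so that calibration targets are not biased by construction.

What the generator does *not* emulate: measurement noise and gap structure
of real eddy-covariance data, within-day weather instability (the
stochastic clearness scales a smooth diurnal shape; the profile-mismatch
switch exists precisely to demonstrate the resulting overestimation
qualitatively), soil-water stress, and CO$_2$ trends. Passing the
synthetic end-to-end checks therefore demonstrates internal consistency of
the compression + integration + upscaling chain, not field accuracy —
field accuracy requires site data supplied through `read_site_year()` and
the `evaluate` command.

## Problem sizes and budgets

The default surface is 40 × 17 cells × 40-point curves (≈ 27k leaf-model
solves + 680 fits, ~20 s). The quadrature validation uses $10^4$ random
draws; ordering checks $10^3$ days; calibration recovery ten seeded
site-years with 33-candidate ensembles. These sizes are the package's
standing test conditions and complete in a few minutes on one core.

## Known limitations

* The $(\alpha, P_m)$ surfaces inherit every assumption of the leaf
  parameterization; absolute values shift with the chosen kinetic
  constants, and a site's calibrated $V_{cmax,25}$ absorbs such scale
  factors. Comparisons of calibrated capacities across different
  parameterizations are therefore not meaningful.
* The diurnal-shape assumption fails on convectively unstable days; the
  daily forms then tend to overestimate.
* No soil-water limitation, no CO$_2$ response, no seasonal $V_{cmax,25}$
  phenology, no energy balance (leaf = air temperature), single-layer
  canopy with a single daily representative zenith.
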