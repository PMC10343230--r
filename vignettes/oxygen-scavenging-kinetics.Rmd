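---
title: "Kinetic modelling of enzymatic oxygen scavenging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of enzymatic oxygen scavenging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxyscav)
```

## The system

Oxidases such as glucose oxidase (Glucox) and laccase are used as oxygen
scavengers in sealed packages: supplied with an excess co-substrate
(glucose, or a phenolic such as ABTS), they consume dissolved O₂ until it
is either exhausted or balanced by resupply from a gas headspace. Because
every other reactant is in large excess, the elaborate multi-step redox
cycle of each enzyme collapses to pseudo-first-order kinetics in the one
rate-limiting species, dissolved oxygen. `oxyscav` implements the forward
models for this regime, the estimators that recover the rate constants
from measured traces, and a synthetic-trace generator for validating the
whole chain.

Three observation schemes are covered:

1. **No headspace, direct probe.** A completely filled vial; a
   luminescence-lifetime probe reports oxygen. The model is plain
   exponential depletion,
   $$[\mathrm{O_2}](t) = [\mathrm{O_2}]_i\, e^{-k_1 t},$$
   with complete exhaustion at long times. `decay_no_headspace()` /
   `fit_first_order_decay()`.

2. **Chromogenic stopped-flow.** Oxygen consumption is read indirectly at
   436 nm. For laccase the oxidized chromophore is stable and absorbance
   grows as $A(t) = A_\infty (1 - e^{-k_{1L} t})$ (`abts_growth()` /
   `fit_growth()`). For Glucox the H₂O₂ by-product drives a peroxidase
   (HRP) oxidation of guaiacol to a coloured quinone that itself decays,
   giving two consecutive first-order steps,
   $$\mathrm{O_2} \xrightarrow{k_2} \mathrm{quinone} \xrightarrow{k_3} \textstyle\sum P_i,
   \qquad
   Q(t) = \frac{s\,k_2\,[\mathrm{O_2}]_i}{k_3 - k_2}
          \left(e^{-k_2 t} - e^{-k_3 t}\right),$$
   a dome-shaped curve (`quinone_consecutive()` / `fit_consecutive()`).
   The stoichiometric factor $s$ defaults to 4 (one O₂ yields four quinone
   equivalents through the four-electron peroxidase couple), which couples
   the scheme to the oxygen constant as $k_{1G} = s\,k_2$, i.e.
   $k_2 = 0.25\,k_{1G}$.

3. **Headspace competition.** With gas above the liquid, transfer feeds
   oxygen back as scavenging removes it:
   $$\frac{d[\mathrm{O_2}]}{dt} = k_{tr}\,p(\mathrm{O_2}) - k_1 [\mathrm{O_2}],$$
   reaching a quasi-steady residual $[\mathrm{O_2}]_e = k_{tr}\,p_i/k_1$
   instead of exhaustion (`headspace_trace()` / `fit_headspace()`). The
   initial condition is the Henry equilibrium
   $[\mathrm{O_2}]_i = K_H\,p_i$.

### The steady-state line and the transfer ratio

Writing the dimensionless transfer-to-scavenging ratio
$r = k_{tr}/(K_H k_1)$, the depletion extent is linear through the origin
in the initial content:
$$\Delta[\mathrm{O_2}] = [\mathrm{O_2}]_i - [\mathrm{O_2}]_e
  = (1 - r)\,[\mathrm{O_2}]_i .$$
`estimate_transfer_ratio()` fits this line through the origin across a
series of initial pressures and reports $r$; a value near 1 means transfer
nearly balances scavenging and only a few percent of the dissolved oxygen
is removed at steady state, while the residual itself shrinks in
proportion to added enzyme ($k_1$ is proportional to enzyme activity).
Note the convention: the package reports the *dimensionless* $r$, because
it is exactly the steady-state fraction $[\mathrm{O_2}]_e/[\mathrm{O_2}]_i$
and is what the through-origin slope $1-r$ determines. The raw quotient
$k_{tr}/k_1$ (units µM/hPa) carries the Henry constant and is available
from any headspace fit as `k_tr / k1`; keeping both on the surface avoids
the ambiguity that arises when a ratio of unlike-dimensioned constants is
quoted as a bare number.

## Units and solubility

Canonical internal units are minutes, hPa, µM, mL, and kelvin. All
conversions live in the solubility module:

* `saturation_ppm(T)` interpolates the instrument-supplied solubility
  table (0–40 °C, 5 °C grid) piecewise-linearly. The grid is coarse and
  the curve gently convex; a spline would add wiggle without information.
* The Henry constant is *derived*, not fitted:
  $K_H(T) = \mathrm{sat}(T)/p_\mathrm{ref}$ with
  $p_\mathrm{ref} = 210$ hPa, the oxygen partial pressure of air at
  atmospheric pressure. ppm means mg O₂ per litre; molar mass 32.0 g/mol.
* `headspace_micromoles()` applies the ideal gas law. For the default
  geometry (22 mL vial, 4 mL liquid, 18 mL headspace) at 50 hPa and 293 K
  the headspace holds ≈ 37 µmol of O₂, versus ≈ 0.27 µmol dissolved in
  the liquid (the Henry-consistent figure) — two orders of magnitude.
  This mole budget is what licenses the quasi-static treatment of the
  headspace pressure.

## The probe model

Lifetime probes obey the Stern–Volmer law
$\tau_0/\tau = 1 + K_{SV}\,p(\mathrm{O_2})$, handled in the linear form
$1/\tau = A\,p + B$. Calibration (`fit_probe_calibration()`) regresses
$1/\tau$ on $p$ — the decay *rate* is what photon-counting estimates
deliver with approximately Gaussian error, so the rate domain is where an
unweighted least-squares noise contract is defensible. The film response
depends on temperature with no agreed functional form, so calibrations
are stored per temperature and selected by nearest neighbour
(`probe_calibration_set()`). No published lot constants exist; the
package default (`default_probe_calibration()`) is **synthetic**, built
from the typical lifetime span of ruthenium-complex films: τ₀ = 5 µs
unquenched and 1 µs at air saturation.

## Estimation choices

All fitters use bounded Levenberg–Marquardt nonlinear least squares
(`minpack.lm`), rates bounded below at zero, with tight convergence
tolerances so that noise-free round trips recover generating values to
better than 1 part in 10⁵. Initial guesses are deterministic, documented
heuristics — log-linear regression on the positive tail for decay-type
rates, the observed maximum for amplitudes — so a fit is a pure function
of its trace.

The biexponential is symmetric under exchanging its two rates (with a
sign flip of the prefactor), so `fit_consecutive()` reports the labelled
ordering $k_2 < k_3$ — formation slower than colour loss, the shape that
produces a slow dome — and records the swapped labelling in its
diagnostics. Two practical subtleties:

* **Windows ending before the peak.** With the default constants the
  quinone maximum falls near 13 min, outside a 10-min stopped-flow
  window, so observed traces can be monotone. Rather than moment-matching
  a peak that is not in the data, starting values come from a coarse
  deterministic grid over rate pairs (28 log-spaced rates, amplitude
  solved linearly for each pair); both rates remain identifiable from the
  curvature alone. A monotone window raises a warning; the quinone-decay
  step is pinned near zero (growth-limit fit) only if the full fit fails
  or collapses onto the bound.
* **The $k_3 \to 0$ limit.** When one fitted rate is indistinguishable
  from zero over the window ($k_{\min} T < 10^{-4}$) the model *is* the
  growth curve; the surviving rate then takes the formation label
  regardless of the $k_2 < k_3$ convention, keeping the nested-model
  identity `fit_consecutive` ≡ `fit_growth` exact.

`fit_headspace()` refits with the residual clipped at zero (plain decay)
if the unconstrained steady state comes out materially negative; a
residual within numerical tolerance of zero is clamped silently. The
through-origin regression in `estimate_transfer_ratio()` is the primary
analysis because the steady-state algebra forces a zero intercept; an
intercept-allowed variant is available behind `intercept = TRUE` for
diagnostics only.

No hypothesis-testing or multiple-comparison machinery is included:
the scientific claims here are point estimates with standard errors.

## Numerical choices

* Closed forms are cross-checked in the test suite against an independent
  `deSolve` integration (rtol 10⁻⁸) to ≤ 10⁻⁶ relative, and mass
  conservation of the consecutive scheme
  ($s([\mathrm{O_2}]_i - [\mathrm{O_2}]) = Q + \int k_3 Q\,dt$) to ≤ 10⁻⁴.
* Near-degenerate rates: for $|k_3 - k_2| < 10^{-6}\max(k_2,k_3)$ the
  confluent limit $s k_2 [\mathrm{O_2}]_i\, t\, e^{-k_2 t}$ replaces the
  two-exponential difference to avoid catastrophic cancellation.
* `headspace_trace(mode = "two_compartment")` additionally drains the
  headspace by the transferred moles
  ($dp/dt = -k_{tr} p\, V_{liq} R T / V_{head}$ in consistent units,
  integrated with `lsoda`). For the default geometry the drift is real
  but slow: the quasi-static closed form agrees to better than 1 % over
  the first 40 min and to a few percent (≈ 3 %) by 120 min, consistent
  with the steady-state consumption rate draining ≈ 1.2 of the ≈ 37 µmol
  headspace reservoir over two hours. The quasi-static mode is therefore
  the default for fitting; the two-compartment mode quantifies the
  approximation error and handles small-headspace designs.
* Assumptions of the two-compartment mode: instantaneous liquid mixing
  (glass-bead agitation) and a single lumped transfer coefficient — no
  film or boundary-layer resistance model.

## The synthetic-data generator

`make_oxysense_no_headspace()`, `make_stoppedflow_glucox()`,
`make_stoppedflow_laccase()` and `make_headspace_series()` emulate the
two instruments' designs: probe traces on a 1-min cadence over 0–120 min
at initial pressures 50/100/150/210 hPa (the 210 hPa ceiling is air
saturation; exceeding it requires the `chilled` flag, since only cooled
water holds more), stopped-flow absorbance on a 1-s cadence over
0–10 min (ε = 29 300 M⁻¹cm⁻¹, 2 mm path), and headspace series at
50/100/150/200 hPa — 5–20 % O₂ mixtures at 0.1 MPa — over the 18 mL/4 mL
vial geometry.

Noise is additive Gaussian in the observation domain (pressure for probe
traces, absorbance for stopped-flow) with standard deviation
$\max(\sigma_{abs}, \sigma_{rel}\,|signal|)$; defaults are
$\sigma_{rel} = 2\%$ with floors of 0.5 hPa / 0.002 AU. These defaults
are **synthetic**: neither instrument's true noise is published, so they
are chosen at the scale a practitioner would consider clean data, and
they are configurable. Negative noisy observations are retained by
default so fitters face realistic baselines. A fixed seed makes all
generator output byte-identical.

What the generator does **not** emulate — and therefore what passing
round-trip tests do and do not show: no enzyme inactivation or substrate
depletion over time, no H₂O₂ inhibition of Glucox, no pH drift from
gluconic acid, no probe photobleaching or temperature drift, no
heteroscedastic instrument artefacts beyond the relative-noise term.
Recovery of generating parameters from this generator validates the
estimation machinery, not the adequacy of pseudo-first-order kinetics for
any particular real sample.

## Problem sizes

Defaults used throughout the package's tests and reproduction script:
121-point probe traces (0–120 min), 601-point stopped-flow traces
(0–10 min at 1 s), four-pressure series, 200-replicate Monte-Carlo checks
of estimator bias at 2 % relative noise, and ODE cross-checks on grids of
a few hundred to a few thousand points — sizes at which every analysis
here runs in seconds.

## Worked example

```{r example}
# simulate a headspace series at two enzyme doses, fit, recover the ratio
traces <- make_headspace_series(k1_levels = c(0.02, 0.039), r = 0.97,
                                noise = no_noise())
fits <- lapply(traces, fit_headspace)
pairs <- data.frame(
  O2_i = sapply(fits, function(f) f$params[["O2_init"]]),
  O2_e = sapply(fits, function(f) f$params[["O2_e"]]))
estimate_transfer_ratio(pairs)$params
```

## Known limitations

* Pseudo-first-order validity requires excess co-substrate throughout;
  the package neither checks nor models substrate depletion.
* Solubility covers pure water, 0–40 °C; no salinity or ionic-strength
  corrections, ideal-gas headspace only.
* The enzyme-activity map $k_1 = s_{enz}\cdot(\mathrm{U/mL})$ is a bare
  proportionality; the coefficient must be fitted or supplied.
* Intensity-based (non-lifetime) quenching, multi-site quenching and
  film photophysics are out of scope.
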