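# oxyscav

Kinetic modelling of enzymatic oxygen scavenging in hypoxic systems.

Oxidases — glucose oxidase (Glucox) and laccase — remove dissolved oxygen
from aqueous samples when supplied with an excess co-substrate, which makes
them practical oxygen scavengers for food and pharmaceutical packaging.
With everything but oxygen in excess, the enzymes' multi-step redox cycles
reduce to pseudo-first-order kinetics in dissolved O₂. `oxyscav` is for
anyone who measures such systems — with a luminescence-lifetime oxygen
probe or by chromogenic stopped-flow spectrophotometry — and wants to turn
traces into rate constants.

## Models

* **No headspace (sealed, filled vial):** exponential depletion to zero,
  `[O₂](t) = [O₂]ᵢ e^(−k₁t)`.
* **Chromogenic detection at 436 nm:** for laccase/ABTS a stable
  chromophore, `Abs(t) = Abs∞ (1 − e^(−k₁Lt))`; for Glucox/HRP/guaiacol a
  coloured quinone that itself decays — two consecutive first-order steps
  `O₂ →(k₂) quinone →(k₃) products` with the dome-shaped closed form
  `Q(t) = s·k₂[O₂]ᵢ/(k₃−k₂)·(e^(−k₂t) − e^(−k₃t))`, stoichiometry
  `s = 4` quinone per O₂, so `k₁G = 4k₂`.
* **Headspace competition:** `d[O₂]/dt = kₜᵣ·p(O₂) − k₁[O₂]`, relaxing to
  a steady residual `[O₂]ₑ = kₜᵣ·pᵢ/k₁` instead of exhaustion. Across a
  series of initial pressures the depletion extent is a line through the
  origin, `Δ[O₂] = (1 − r)[O₂]ᵢ` with `r = kₜᵣ/(K_H·k₁)` the dimensionless
  transfer-to-scavenging ratio.
* **Support:** Stern–Volmer lifetime-probe calibration
  (`1/τ = A·p + B`), Henry's-law solubility utilities with the instrument
  solubility table, ideal-gas headspace mole budgets, a synthetic-trace
  generator, and a batch fit pipeline over trace CSVs.

Every scheme has a forward simulator and a bounded Levenberg–Marquardt
least-squares fitter with deterministic initial-guess heuristics;
noise-free round trips recover generating constants to better than 1e−5
relative.

## Worked example

Simulate a noisy probe trace of Glucox scavenging (2 % noise, 0.5 hPa
floor) and fit the decay model:

```r
library(oxyscav)
traces <- make_oxysense_no_headspace(k1 = 0.039,
                                     noise = noise_spec(sigma_rel = 0.02,
                                                        sigma_abs = 0.5,
                                                        seed = 42))
fit_first_order_decay(traces[[1]])
#> <fit_result> model = decay, n = 121, rss = 36.61, converged = TRUE
#>   O2_init    50.4921 (se 0.212)
#>   k1         0.039395 (se 0.000239)
```

The trace was generated at 50 hPa initial p(O₂) with k₁ = 0.039 min⁻¹; the
fit recovers both within one standard error. The indirect stopped-flow
route gives the same constant through the quinone dome:

```r
tr <- make_stoppedflow_glucox(k1G = 0.043, k3 = 0.25, O2_init = 61.1,
                              noise = no_noise(1/60))
fit_consecutive(tr)
#> <fit_result> model = consecutive, n = 601, rss = 1.702e-32, converged = TRUE
#>   k2         0.01075
#>   k3         0.25
#>   C          0.064351
#>   O2_init    61.1
#>   k1G        0.043
```

(`k1G = 4·k2` by the 4:1 quinone:O₂ stoichiometry; `O2_init` is recovered
in µM from the absorbance amplitude via ε = 29 300 M⁻¹cm⁻¹ and the 2 mm
path.) A headspace series at four initial pressures, fitted and passed to
the steady-state line analysis, returns the transfer ratio:

```r
hs <- make_headspace_series(k1_levels = 0.039, r = 0.97, noise = no_noise())
fits <- lapply(hs, fit_headspace)
pairs <- data.frame(O2_i = sapply(fits, function(f) f$params[["O2_init"]]),
                    O2_e = sapply(fits, function(f) f$params[["O2_e"]]))
estimate_transfer_ratio(pairs)$params
#>     r slope
#>  0.97  0.03
```

`r = 0.97` means headspace transfer nearly balances scavenging: the liquid
retains 97 % of its initial dissolved oxygen at steady state, and the
residual halves when the enzyme dose doubles.

See the vignette (`vignettes/oxygen-scavenging-kinetics.Rmd`) for the
model assumptions, estimation and numerical choices, and what the
synthetic generator does and does not emulate. A thin command-line
wrapper over the generator and batch fitter is installed at
`inst/cli/oxyscav.R`.

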