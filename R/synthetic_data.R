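#' Noise specification for synthetic traces
#'
#' Additive Gaussian noise in the observation domain with per-point standard
#' deviation `max(sigma_abs, sigma_rel * |signal|)` — a relative component
#' with an absolute floor. Defaults (2% relative, instrument-scale absolute
#' floors set per generator) are synthetic: the instruments' true noise is
#' not published.
#'
#' @param sigma_rel relative noise level (fraction of the signal), >= 0.
#' @param sigma_abs absolute noise floor in the units of the observed
#'   quantity, >= 0.
#' @param seed integer random seed; a fixed seed makes generator output
#'   byte-identical across runs.
#' @param sampling_interval_min sampling cadence, minutes.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_rel = 0.02, sigma_abs = 0, seed = NULL,
                       sampling_interval_min = 1) {
  if (sigma_rel < 0 || sigma_abs < 0) stop("noise sigmas must be >= 0")
  if (sampling_interval_min <= 0) stop("sampling interval must be positive")
  structure(list(sigma_rel = sigma_rel, sigma_abs = sigma_abs, seed = seed,
                 sampling_interval_min = sampling_interval_min),
            class = "noise_spec")
}

#' Noiseless specification
#' @param sampling_interval_min sampling cadence, minutes.
#' @return a [noise_spec()] with both sigmas zero.
#' @export
no_noise <- function(sampling_interval_min = 1) {
  noise_spec(sigma_rel = 0, sigma_abs = 0,
             sampling_interval_min = sampling_interval_min)
}

# Apply observation noise to a clean signal. Negative observations are
# retained by default so fitters face realistic baselines.
.add_noise <- function(signal, noise, clip = FALSE) {
  if (noise$sigma_rel == 0 && noise$sigma_abs == 0) return(signal)
  sd_i <- pmax(noise$sigma_abs, noise$sigma_rel * abs(signal))
  out <- signal + rnorm(length(signal), mean = 0, sd = sd_i)
  if (clip) out <- pmax(out, 0)
  out
}

.maybe_seed <- function(noise) {
  if (!is.null(noise$seed)) set.seed(as.integer(noise$seed))
}

#' Synthetic no-headspace probe traces
#'
#' Emulates luminescence-probe measurements of dissolved-oxygen decay in
#' completely filled vials: each trace starts at the Henry equilibrium for
#' its preparation atmosphere and decays exponentially with rate `k1`,
#' observed in the pressure domain (the probe reports p(O2)) with additive
#' noise. Initial pressures above the 210 hPa air-saturation ceiling
#' require `chilled = TRUE` (cooling lets water hold slightly more oxygen).
#'
#' @param k1 scavenging rate constant, 1/min.
#' @param p_i_list initial p(O2) values, hPa (default the multi-pressure
#'   design 50/100/150/210).
#' @param T_celsius temperature, degC (default 20).
#' @param noise a [noise_spec()]; default 2% relative with a 0.5 hPa floor.
#' @param duration_min trace length, minutes (default 120).
#' @param chilled allow p_i above 210 hPa.
#' @param clip clip negative noisy observations at zero (default FALSE).
#' @param solubility a [solubility_model()].
#' @return list of [o2_trace()] of kind `pO2_hPa`; each `meta` records the
#'   generating truth (`k1`, `p_i_hPa`, `O2_init_uM`, `T_C`).
#' @export
#' @examples
#' traces <- make_oxysense_no_headspace(0.039, noise = no_noise())
make_oxysense_no_headspace <- function(k1,
                                       p_i_list = c(50, 100, 150, 210),
                                       T_celsius = 20,
                                       noise = noise_spec(sigma_abs = 0.5),
                                       duration_min = 120,
                                       chilled = FALSE,
                                       clip = FALSE,
                                       solubility = solubility_model()) {
  if (any(p_i_list < 0)) stop("p_i must be non-negative")
  if (any(p_i_list > 210) && !chilled)
    stop("p_i above the 210 hPa air-saturation ceiling requires chilled = TRUE")
  .maybe_seed(noise)
  t_grid <- seq(0, duration_min, by = noise$sampling_interval_min)
  lapply(p_i_list, function(p_i) {
    clean <- p_i * exp(-k1 * t_grid)
    o2_trace(t_grid, .add_noise(clean, noise, clip), kind = "pO2_hPa",
             meta = list(scheme = "decay", k1 = k1, p_i_hPa = p_i,
                         T_C = T_celsius,
                         O2_init_uM = dissolved_o2_uM(p_i, T_celsius,
                                                      solubility)))
  })
}

#' Synthetic stopped-flow trace for the glucose-oxidase coupled assay
#'
#' Dome-shaped absorbance of the quinone chromophore from the consecutive
#' scheme: formation at `k2 = k1G / s`, decay at `k3`, observed through the
#' extinction coefficient and optical path with additive absorbance noise.
#'
#' @param k1G glucose-oxidase scavenging constant, 1/min.
#' @param k3 quinone decay constant, 1/min.
#' @param O2_init initial dissolved oxygen, uM.
#' @param spectro a [spectro_config()].
#' @param noise a [noise_spec()]; stopped-flow cadence defaults to 1 s.
#'   Default noise 2% relative with a 0.002 AU floor.
#' @param duration_min observation window, minutes (default 10).
#' @param s stoichiometric factor quinone:O2 (default 4).
#' @param clip clip negative noisy observations at zero.
#' @return an [o2_trace()] of kind `absorbance` with generating truth in
#'   `meta`.
#' @export
make_stoppedflow_glucox <- function(k1G, k3, O2_init,
                                    spectro = spectro_config(),
                                    noise = noise_spec(sigma_abs = 0.002,
                                                       sampling_interval_min = 1 / 60),
                                    duration_min = 10, s = 4,
                                    clip = FALSE) {
  .maybe_seed(noise)
  t_grid <- seq(0, duration_min, by = noise$sampling_interval_min)
  k2 <- k1G / s
  clean <- quinone_consecutive(t_grid, O2_init, k2, k3, s = s,
                               spectro = spectro)
  o2_trace(t_grid, .add_noise(clean$value, noise, clip),
           kind = "absorbance",
           meta = list(scheme = "consecutive", k1G = k1G, k2 = k2, k3 = k3,
                       s = s, O2_init_uM = O2_init,
                       wavelength_nm = spectro$wavelength_nm))
}

#' Synthetic stopped-flow trace for the laccase/ABTS assay
#'
#' Exponential absorbance growth of the stable oxidized chromophore:
#' amplitude `epsilon * l * s_L * [O2]_i`, rate `k1L`, plus noise.
#'
#' @param k1L laccase scavenging constant, 1/min.
#' @param O2_init initial dissolved oxygen, uM.
#' @param spectro a [spectro_config()].
#' @param noise a [noise_spec()] (stopped-flow cadence defaults to 1 s).
#' @param duration_min observation window, minutes (default 10).
#' @param s_L chromophore equivalents per O2 (default 4, the four-electron
#'   reduction of O2 to water).
#' @param clip clip negative noisy observations at zero.
#' @return an [o2_trace()] of kind `absorbance`.
#' @export
make_stoppedflow_laccase <- function(k1L, O2_init,
                                     spectro = spectro_config(),
                                     noise = noise_spec(sigma_abs = 0.002,
                                                        sampling_interval_min = 1 / 60),
                                     duration_min = 10, s_L = 4,
                                     clip = FALSE) {
  .maybe_seed(noise)
  t_grid <- seq(0, duration_min, by = noise$sampling_interval_min)
  amplitude <- absorbance_per_uM(spectro) * s_L * O2_init
  clean <- amplitude * (1 - exp(-k1L * t_grid))
  o2_trace(t_grid, .add_noise(clean, noise, clip), kind = "absorbance",
           meta = list(scheme = "growth", k1L = k1L, amplitude = amplitude,
                       s_L = s_L, O2_init_uM = O2_init,
                       wavelength_nm = spectro$wavelength_nm))
}

#' Synthetic headspace depletion series
#'
#' One trace per (enzyme level, initial pressure) pair from the quasi-static
#' headspace balance, emulating the enzyme-dose and pressure-series designs:
#' `k1` scales with enzyme load while the dimensionless transfer ratio `r`
#' fixes `k_tr = r * K_H * k1`, so every level shares the same steady-state
#' fraction but approaches it at its own rate.
#'
#' @param k1_levels vector of scavenging constants, 1/min (one per enzyme
#'   dose).
#' @param r dimensionless transfer-to-scavenging ratio (default 0.97).
#' @param p_i_list initial p(O2) values, hPa; default 50/100/150/200,
#'   approximating 5-20% O2 mixtures at 0.1 MPa.
#' @param geometry an [experiment_geometry()] (default: 22 mL vial, 4 mL
#'   liquid).
#' @param noise a [noise_spec()]; dissolved-concentration domain, default
#'   2% relative with a 0.5 uM floor.
#' @param duration_min trace length, minutes (default 120).
#' @param clip clip negative noisy observations at zero.
#' @param solubility a [solubility_model()].
#' @return list of [o2_trace()] of kind `dissolved_uM`, generating truth in
#'   each `meta` (`k1`, `k_tr`, `r`, `p_i_hPa`).
#' @export
make_headspace_series <- function(k1_levels, r = 0.97,
                                  p_i_list = c(50, 100, 150, 200),
                                  geometry = experiment_geometry(),
                                  noise = noise_spec(sigma_abs = 0.5),
                                  duration_min = 120,
                                  clip = FALSE,
                                  solubility = solubility_model()) {
  stopifnot(length(k1_levels) >= 1L, all(k1_levels > 0), r >= 0)
  .maybe_seed(noise)
  T_C <- geometry$T_K - 273.15
  K_H <- henry_constant_uM(T_C, solubility)
  t_grid <- seq(0, duration_min, by = noise$sampling_interval_min)
  out <- list()
  for (k1 in k1_levels) {
    k_tr <- r * K_H * k1
    for (p_i in p_i_list) {
      geo <- geometry
      geo$p_O2_init_hPa <- p_i
      clean <- headspace_trace(t_grid, geo,
                               kinetic_params(k1 = k1, k_tr = k_tr),
                               solubility = solubility,
                               mode = "quasi_static")
      tr <- o2_trace(t_grid, .add_noise(clean$value, noise, clip),
                     kind = "dissolved_uM",
                     meta = list(scheme = "headspace", k1 = k1, k_tr = k_tr,
                                 r = r, p_i_hPa = p_i, T_C = T_C,
                                 K_H_uM_per_hPa = K_H,
                                 O2_init_uM = K_H * p_i))
      out[[length(out) + 1L]] <- tr
    }
  }
  out
}
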