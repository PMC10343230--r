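#' Kinetic rate-constant container
#'
#' Rate constants of the scavenging schemes. `k1` is the pseudo-first-order
#' oxygen scavenging constant (1/min); in the consecutive chromogenic scheme
#' `k2` is quinone formation and `k3` quinone decay (1/min), coupled to the
#' oxygen constant by the stoichiometry `k1G = s * k2` (default s = 4:
#' one O2 yields four quinone equivalents via the peroxidase/guaiacol
#' couple). `k_tr` is the headspace-to-liquid transfer coefficient in
#' uM/(min hPa) so that `k_tr * p` is a concentration rate. `s_enz`
#' optionally maps enzyme activity (U/mL) linearly onto `k1`.
#'
#' @param k1,k2,k3 rate constants, 1/min (non-negative or NA).
#' @param k_tr transfer coefficient, uM/(min hPa).
#' @param s stoichiometric factor quinone:O2, positive; default 4.
#' @param s_enz optional k1 per unit enzyme activity, 1/min per U/mL.
#' @return object of class `kinetic_params`.
#' @export
kinetic_params <- function(k1 = NA_real_, k2 = NA_real_, k3 = NA_real_,
                           k_tr = NA_real_, s = 4, s_enz = NA_real_) {
  for (nm in c("k1", "k2", "k3", "k_tr")) {
    v <- get(nm)
    if (!is.na(v) && v < 0) stop(nm, " must be non-negative")
  }
  if (!is.finite(s) || s <= 0) stop("s must be positive")
  structure(list(k1 = k1, k2 = k2, k3 = k3, k_tr = k_tr, s = s,
                 s_enz = s_enz),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  v <- unlist(x[c("k1", "k2", "k3", "k_tr", "s")])
  v <- v[!is.na(v)]
  cat("Kinetic parameters:",
      paste(names(v), signif(v, 4), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Spectrophotometric configuration
#'
#' Links chromophore concentration to absorbance: `Abs = epsilon * l * c`.
#' Defaults are the oxidized-chromophore band at 436 nm
#' (epsilon = 29300 1/(M cm)) in a 2 mm stopped-flow cuvette.
#'
#' @param epsilon_M_cm molar extinction coefficient, 1/(M cm); positive.
#' @param path_cm optical path, cm; positive.
#' @param wavelength_nm detection wavelength, nm.
#' @return object of class `spectro_config`.
#' @export
spectro_config <- function(epsilon_M_cm = 29300, path_cm = 0.2,
                           wavelength_nm = 436) {
  if (!is.finite(epsilon_M_cm) || epsilon_M_cm <= 0)
    stop("epsilon must be positive")
  if (!is.finite(path_cm) || path_cm <= 0) stop("path must be positive")
  structure(list(epsilon_M_cm = epsilon_M_cm, path_cm = path_cm,
                 wavelength_nm = wavelength_nm),
            class = "spectro_config")
}

#' Absorbance per uM of chromophore
#' @param spectro a [spectro_config()].
#' @return AU per uM.
#' @export
absorbance_per_uM <- function(spectro) {
  stopifnot(inherits(spectro, "spectro_config"))
  spectro$epsilon_M_cm * spectro$path_cm * 1e-6
}

#' Exponential oxygen decay without headspace
#'
#' In a completely filled vial the enzymatic scavenging of dissolved oxygen
#' follows pseudo-first-order kinetics, `[O2](t) = [O2]_i exp(-k1 t)`:
#' complete depletion, no residual.
#'
#' @param t_grid times, minutes.
#' @param O2_init initial dissolved oxygen (units of `kind`); non-negative.
#' @param k1 scavenging rate constant, 1/min; non-negative.
#' @param kind trace kind of the values (default `dissolved_uM`).
#' @return an [o2_trace()].
#' @export
#' @examples
#' tr <- decay_no_headspace(0:120, O2_init = 61.1, k1 = 0.039)
decay_no_headspace <- function(t_grid, O2_init, k1, kind = "dissolved_uM") {
  if (!is.finite(O2_init) || O2_init < 0) stop("O2_init must be non-negative")
  if (!is.finite(k1) || k1 < 0) stop("rate constant must be non-negative")
  o2_trace(t_grid, O2_init * exp(-k1 * t_grid), kind = kind,
           meta = list(model = "decay", k1 = k1, O2_init = O2_init))
}

#' Exponential absorbance growth (one-step chromogenic scheme)
#'
#' When the chromophore is stable (laccase/ABTS), its absorbance mirrors the
#' consumed oxygen: `Abs(t) = amplitude * (1 - exp(-k1L t))`, rising from 0
#' to the asymptotic amplitude.
#'
#' @param t_grid times, minutes.
#' @param amplitude asymptotic absorbance, AU; non-negative.
#' @param k1L rate constant, 1/min; non-negative.
#' @return an [o2_trace()] of kind `absorbance`.
#' @export
abts_growth <- function(t_grid, amplitude, k1L) {
  if (!is.finite(amplitude) || amplitude < 0)
    stop("amplitude must be non-negative")
  if (!is.finite(k1L) || k1L < 0) stop("rate constant must be non-negative")
  o2_trace(t_grid, amplitude * (1 - exp(-k1L * t_grid)), kind = "absorbance",
           meta = list(model = "growth", k1L = k1L, amplitude = amplitude))
}

# Closed-form quinone concentration of the consecutive scheme, with the
# confluent limit guarded against catastrophic cancellation when k2 ~ k3.
quinone_closed_form <- function(t, O2_init, k2, k3, s) {
  if (abs(k3 - k2) < 1e-6 * max(k2, k3, .Machine$double.eps)) {
    s * k2 * O2_init * t * exp(-k2 * t)
  } else {
    s * k2 * O2_init / (k3 - k2) * (exp(-k2 * t) - exp(-k3 * t))
  }
}

#' Consecutive-reaction quinone kinetics
#'
#' The glucose-oxidase chromogenic assay proceeds through two consecutive
#' first-order steps, O2 -> quinone (colour) -> products, with `s` quinone
#' equivalents formed per O2 consumed. The quinone concentration is
#' `Q(t) = s k2 [O2]_i / (k3 - k2) * (exp(-k2 t) - exp(-k3 t))` (confluent
#' limit `s k2 [O2]_i t exp(-k2 t)` when k2 = k3): zero at t = 0, a single
#' interior maximum at `t_max = ln(k3/k2)/(k3 - k2)` when both rates are
#' positive, and a slow tail governed by the smaller rate.
#'
#' @param t_grid times, minutes.
#' @param O2_init initial dissolved oxygen, uM; non-negative.
#' @param k2 quinone formation rate, 1/min; non-negative.
#' @param k3 quinone decay rate, 1/min; non-negative.
#' @param s stoichiometric factor quinone:O2, default 4.
#' @param spectro optional [spectro_config()]; if supplied the returned
#'   trace is absorbance (`epsilon * l * Q`), otherwise quinone
#'   concentration in uM.
#' @return an [o2_trace()].
#' @export
#' @examples
#' tr <- quinone_consecutive(seq(0, 10, 1/60), O2_init = 61.1,
#'                           k2 = 0.01075, k3 = 0.25)
quinone_consecutive <- function(t_grid, O2_init, k2, k3, s = 4,
                                spectro = NULL) {
  if (!is.finite(O2_init) || O2_init < 0) stop("O2_init must be non-negative")
  if (!is.finite(k2) || k2 < 0 || !is.finite(k3) || k3 < 0)
    stop("rate constants must be non-negative")
  if (!is.finite(s) || s <= 0) stop("s must be positive")
  q <- quinone_closed_form(t_grid, O2_init, k2, k3, s)
  meta <- list(model = "consecutive", k2 = k2, k3 = k3, s = s,
               O2_init = O2_init)
  if (is.null(spectro)) {
    o2_trace(t_grid, q, kind = "dissolved_uM", meta = meta)
  } else {
    meta$wavelength_nm <- spectro$wavelength_nm
    o2_trace(t_grid, q * absorbance_per_uM(spectro), kind = "absorbance",
             meta = meta)
  }
}

#' Time of the quinone maximum
#' @param k2,k3 positive formation/decay rates, 1/min.
#' @return `ln(k3/k2)/(k3 - k2)` minutes (`1/k2` in the k2 = k3 limit).
#' @export
quinone_peak_time <- function(k2, k3) {
  stopifnot(k2 > 0, k3 > 0)
  if (abs(k3 - k2) < 1e-9 * max(k2, k3)) 1 / k2 else log(k3 / k2) / (k3 - k2)
}

#' Oxygen kinetics in the presence of a headspace
#'
#' With a gas headspace over the liquid, oxygen transfer from the gas phase
#' competes with enzymatic scavenging:
#' `d[O2]/dt = k_tr p(O2) - k1 [O2]`.
#' In `quasi_static` mode the headspace pressure is held at its initial
#' value (justified because the headspace holds two orders of magnitude more
#' oxygen than the liquid), giving the closed form
#' `[O2](t) = [O2]_e + ([O2]_i - [O2]_e) exp(-k1 t)` with the steady-state
#' residual `[O2]_e = k_tr p_i / k1`. In `two_compartment` mode the
#' headspace is additionally depleted by the transferred moles
#' (`dp/dt = -k_tr p V_liq R T / V_head` in consistent units) and the pair
#' is integrated numerically.
#'
#' @param t_grid times, minutes.
#' @param geometry an [experiment_geometry()].
#' @param params a [kinetic_params()] with `k1` and `k_tr` set.
#' @param solubility a [solubility_model()] fixing the Henry constant (the
#'   initial condition is the Henry equilibrium `[O2]_i = K_H p_i`).
#' @param mode `"quasi_static"` (closed form) or `"two_compartment"`
#'   (numerical, headspace mole balance).
#' @return an [o2_trace()] of kind `dissolved_uM`; for `two_compartment`
#'   the headspace pressure history is stored in `meta$p_hPa`.
#' @export
headspace_trace <- function(t_grid, geometry = experiment_geometry(),
                            params, solubility = solubility_model(),
                            mode = c("quasi_static", "two_compartment")) {
  mode <- match.arg(mode)
  stopifnot(inherits(geometry, "experiment_geometry"),
            inherits(params, "kinetic_params"))
  k1 <- params$k1
  k_tr <- params$k_tr
  if (is.na(k1) || is.na(k_tr)) stop("params must set k1 and k_tr")
  T_C <- geometry$T_K - 273.15
  K_H <- henry_constant_uM(T_C, solubility)
  p_i <- geometry$p_O2_init_hPa
  O2_i <- K_H * p_i

  if (mode == "quasi_static") {
    if (k1 == 0 && k_tr > 0)
      stop("no steady state: k1 = 0 with positive transfer gives unbounded accumulation")
    if (k1 == 0) {
      v <- rep(O2_i, length(t_grid))
    } else {
      O2_e <- k_tr * p_i / k1
      v <- O2_e + (O2_i - O2_e) * exp(-k1 * t_grid)
    }
    return(o2_trace(t_grid, v, kind = "dissolved_uM",
                    meta = list(model = "headspace", mode = mode,
                                k1 = k1, k_tr = k_tr, p_i_hPa = p_i,
                                K_H_uM_per_hPa = K_H, O2_init = O2_i)))
  }

  # two-compartment: state (dissolved uM, headspace p in hPa)
  # umol/min leaving the gas phase = k_tr * p * V_liq[L]; converted back to
  # hPa/min through the ideal gas law for the headspace volume.
  p_per_umol <- .R_GAS * geometry$T_K /
    (geometry$V_head_mL * 1e-6) * 1e-6 / 100  # hPa per umol
  V_liq_L <- geometry$V_liq_mL / 1000
  rhs <- function(t, y, parms) {
    transfer <- k_tr * y[2]                 # uM/min into the liquid
    dO2 <- transfer - k1 * y[1]
    dp <- -transfer * V_liq_L * p_per_umol  # hPa/min
    list(c(dO2, dp))
  }
  out <- deSolve::ode(y = c(O2 = O2_i, p = p_i), times = t_grid, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  o2_trace(t_grid, out[, "O2"], kind = "dissolved_uM",
           meta = list(model = "headspace", mode = mode, k1 = k1,
                       k_tr = k_tr, p_i_hPa = p_i, K_H_uM_per_hPa = K_H,
                       O2_init = O2_i, p_hPa = unname(out[, "p"])))
}

#' Steady-state residual oxygen concentration
#'
#' Setting `d[O2]/dt = 0` in the transfer/scavenging balance gives the
#' residual `[O2]_e = k_tr p / k1`: doubling the enzyme load (k1) halves
#' the residual.
#'
#' @param p_O2 headspace oxygen partial pressure, hPa.
#' @param k1 scavenging rate, 1/min; must be positive.
#' @param k_tr transfer coefficient, uM/(min hPa).
#' @return steady-state concentration, uM.
#' @export
steady_state_concentration <- function(p_O2, k1, k_tr) {
  if (!is.finite(k1) || k1 <= 0)
    stop("no steady state exists for k1 <= 0")
  k_tr * p_O2 / k1
}

#' Dimensionless transfer-to-scavenging ratio
#'
#' `r = k_tr / (K_H k1)`, the steady-state fraction `[O2]_e / [O2]_i`.
#' `r = 1` means transfer exactly balances scavenging (no depletion);
#' small `r` means near-complete depletion.
#'
#' @param k1 scavenging rate, 1/min (positive).
#' @param k_tr transfer coefficient, uM/(min hPa).
#' @param K_H Henry constant, uM/hPa.
#' @return dimensionless ratio.
#' @export
transfer_ratio <- function(k1, k_tr, K_H) {
  if (!is.finite(k1) || k1 <= 0) stop("k1 must be positive")
  k_tr / (K_H * k1)
}

#' Steady-state oxygen depletion extent
#'
#' The drop from the initial Henry equilibrium to the steady state,
#' `delta = [O2]_i - [O2]_e = K_H p_i (1 - r)` with `r = k_tr/(K_H k1)`:
#' linear through the origin in the initial partial pressure.
#'
#' @param p_i initial oxygen partial pressure, hPa (vectorized).
#' @param k1 scavenging rate, 1/min (positive).
#' @param k_tr transfer coefficient, uM/(min hPa).
#' @param K_H Henry constant, uM/hPa.
#' @return depletion in uM.
#' @export
delta_O2 <- function(p_i, k1, k_tr, K_H) {
  r <- transfer_ratio(k1, k_tr, K_H)
  if (r > 1)
    warning("transfer outruns scavenging (r > 1): no net depletion")
  K_H * p_i * (1 - r)
}
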