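#' Oxygen solubility model
#'
#' Couples the tabulated temperature dependence of oxygen saturation in water
#' (air-equilibrated, instrument-supplied table) with the reference oxygen
#' partial pressure of air-saturated water, defining a temperature-dependent
#' Henry constant `K_H(T) = sat(T) / p_ref` in ppm/hPa.
#'
#' @param table data frame with columns `temp_C` (strictly increasing) and
#'   `o2_ppm` (strictly decreasing saturation concentration, ppm = mg/L).
#'   Defaults to the packaged table covering 0-40 degC on a 5 degC grid.
#' @param p_ref_hPa reference oxygen partial pressure of air-saturated water,
#'   hPa. Default 210.
#' @param molar_mass_o2 molar mass of O2 in g/mol, default 32.0.
#'
#' @return An object of class `solubility_model`.
#' @export
#' @examples
#' sol <- solubility_model()
#' saturation_ppm(25, sol) # 8.21
solubility_model <- function(table = o2_solubility_table(),
                             p_ref_hPa = 210,
                             molar_mass_o2 = 32.0) {
  stopifnot(is.data.frame(table), all(c("temp_C", "o2_ppm") %in% names(table)))
  if (nrow(table) < 2L)
    stop("solubility table needs at least two rows")
  if (any(diff(table$temp_C) <= 0))
    stop("solubility table temperatures must be strictly increasing")
  if (any(diff(table$o2_ppm) >= 0))
    stop("solubility table concentrations must be strictly decreasing")
  if (!is.numeric(p_ref_hPa) || p_ref_hPa <= 0)
    stop("p_ref_hPa must be a positive number")
  structure(
    list(table = table[, c("temp_C", "o2_ppm")],
         p_ref_hPa = p_ref_hPa,
         molar_mass_o2 = molar_mass_o2),
    class = "solubility_model"
  )
}

#' @export
print.solubility_model <- function(x, ...) {
  cat("Oxygen solubility model:", nrow(x$table), "grid points,",
      sprintf("%g-%g degC; p_ref = %g hPa\n",
              min(x$table$temp_C), max(x$table$temp_C), x$p_ref_hPa))
  invisible(x)
}

#' Packaged oxygen solubility table
#'
#' Saturation concentration of oxygen in air-equilibrated water, 0-40 degC in
#' 5 degC steps (ppm = mg/L), as distributed with luminescence oxygen-probe
#' instruments.
#'
#' @return data frame with columns `temp_C`, `o2_ppm`.
#' @export
o2_solubility_table <- function() {
  path <- system.file("extdata", "o2_solubility.csv", package = "oxyscav",
                      mustWork = TRUE)
  read.csv(path)
}

#' Oxygen saturation concentration at a given temperature
#'
#' Piecewise-linear interpolation of the solubility table. The grid is coarse
#' (5 degC) and the curve gently convex; smoother interpolation schemes are
#' not warranted by the data.
#'
#' @param T_celsius temperature in degrees Celsius, within the table range.
#' @param model a [solubility_model()].
#' @return saturation concentration in ppm (mg/L).
#' @export
saturation_ppm <- function(T_celsius, model = solubility_model()) {
  tab <- model$table
  rng <- range(tab$temp_C)
  if (any(!is.finite(T_celsius)) ||
      any(T_celsius < rng[1]) || any(T_celsius > rng[2]))
    stop(sprintf("temperature out of range: valid range is %g to %g degC",
                 rng[1], rng[2]))
  approx(tab$temp_C, tab$o2_ppm, xout = T_celsius, method = "linear")$y
}

#' Convert dissolved oxygen from ppm to micromolar
#'
#' ppm means mg O2 per litre of water, so uM = 1000 * ppm / molar mass.
#'
#' @param c_ppm concentration in ppm (mg/L), non-negative.
#' @param molar_mass molar mass in g/mol, default 32.0 for O2.
#' @return concentration in uM.
#' @export
ppm_to_micromolar <- function(c_ppm, molar_mass = 32.0) {
  if (any(c_ppm < 0, na.rm = TRUE))
    stop("concentration must be non-negative")
  1000 * c_ppm / molar_mass
}

#' Convert dissolved oxygen from micromolar to ppm
#' @param c_uM concentration in uM, non-negative.
#' @param molar_mass molar mass in g/mol, default 32.0 for O2.
#' @return concentration in ppm (mg/L).
#' @export
micromolar_to_ppm <- function(c_uM, molar_mass = 32.0) {
  if (any(c_uM < 0, na.rm = TRUE))
    stop("concentration must be non-negative")
  c_uM * molar_mass / 1000
}

#' Henry's-law dissolved oxygen concentration
#'
#' Equilibrium dissolved concentration at partial pressure `p_O2`:
#' `K_H(T) * p_O2` with `K_H(T) = saturation_ppm(T) / p_ref`, linear in
#' `p_O2`.
#'
#' @param p_O2 oxygen partial pressure, hPa (non-negative; vectorized).
#' @param T_celsius temperature in degrees Celsius.
#' @param model a [solubility_model()].
#' @return dissolved concentration in ppm.
#' @seealso [dissolved_o2_uM()], [henry_constant_uM()]
#' @export
#' @examples
#' dissolved_o2(210, 25) # 8.21 ppm, air-saturated at 25 degC
#' dissolved_o2(50, 25)  # ~1.955 ppm under a hypoxic atmosphere
dissolved_o2 <- function(p_O2, T_celsius, model = solubility_model()) {
  if (any(p_O2 < 0, na.rm = TRUE))
    stop("partial pressure must be non-negative")
  saturation_ppm(T_celsius, model) * p_O2 / model$p_ref_hPa
}

#' Henry's-law dissolved oxygen concentration in micromolar
#' @inheritParams dissolved_o2
#' @return dissolved concentration in uM.
#' @export
dissolved_o2_uM <- function(p_O2, T_celsius, model = solubility_model()) {
  ppm_to_micromolar(dissolved_o2(p_O2, T_celsius, model),
                    molar_mass = model$molar_mass_o2)
}

#' Henry constant in uM/hPa
#'
#' @inheritParams saturation_ppm
#' @return `K_H` such that `[O2]_uM = K_H * p_O2_hPa` at equilibrium.
#' @export
henry_constant_uM <- function(T_celsius, model = solubility_model()) {
  ppm_to_micromolar(saturation_ppm(T_celsius, model),
                    molar_mass = model$molar_mass_o2) / model$p_ref_hPa
}

#' Moles of oxygen in a vial headspace
#'
#' Ideal-gas mole count `n = p V / (R T)` for the oxygen partial pressure in
#' the gas phase, expressed in micromoles.
#'
#' @param p_O2 oxygen partial pressure, hPa (non-negative).
#' @param V_head_mL headspace volume, mL (non-negative).
#' @param T_K temperature, kelvin (positive).
#' @return amount of oxygen in umol.
#' @export
#' @examples
#' headspace_micromoles(50, 18, 293) # ~36.9 umol, "about 40" in a 22 mL vial
headspace_micromoles <- function(p_O2, V_head_mL, T_K) {
  if (any(p_O2 < 0, na.rm = TRUE)) stop("partial pressure must be non-negative")
  if (any(V_head_mL < 0, na.rm = TRUE)) stop("volume must be non-negative")
  if (any(T_K <= 0, na.rm = TRUE)) stop("temperature must be positive kelvin")
  # p [hPa -> Pa: x100] * V [mL -> m3: x1e-6] / (R T) [mol] -> umol: x1e6
  p_O2 * 100 * V_head_mL / (.R_GAS * T_K)
}

#' Moles of dissolved oxygen in the liquid phase
#'
#' Henry-consistent liquid-phase mole count for a volume equilibrated at
#' `p_O2`: `[O2]_uM * V_liq` in umol.
#'
#' @inheritParams dissolved_o2
#' @param V_liq_mL liquid volume, mL.
#' @return amount of dissolved oxygen in umol.
#' @export
liquid_micromoles <- function(p_O2, V_liq_mL, T_celsius,
                              model = solubility_model()) {
  if (any(V_liq_mL < 0, na.rm = TRUE)) stop("volume must be non-negative")
  dissolved_o2_uM(p_O2, T_celsius, model) * V_liq_mL / 1000
}

#' Experiment geometry
#'
#' Vial geometry and gas-phase conditions for headspace experiments. Defaults
#' describe the standard 22 mL vial with 4 mL of liquid under 18 mL of an
#' Ar/O2 mixture at 0.1 MPa total pressure.
#'
#' @param V_head_mL headspace volume, mL.
#' @param V_liq_mL liquid volume, mL.
#' @param T_K temperature, kelvin.
#' @param p_total_hPa total pressure, hPa.
#' @param p_O2_init_hPa initial oxygen partial pressure, hPa.
#' @return object of class `experiment_geometry`.
#' @export
experiment_geometry <- function(V_head_mL = 18, V_liq_mL = 4,
                                T_K = 293.15, p_total_hPa = 1000,
                                p_O2_init_hPa = 50) {
  if (V_head_mL < 0 || V_liq_mL < 0) stop("volumes must be non-negative")
  if (T_K <= 0) stop("temperature must be positive kelvin")
  if (p_O2_init_hPa < 0 || p_O2_init_hPa > p_total_hPa)
    stop("p_O2_init_hPa must lie in [0, p_total_hPa]")
  structure(
    list(V_head_mL = V_head_mL, V_liq_mL = V_liq_mL, T_K = T_K,
         p_total_hPa = p_total_hPa, p_O2_init_hPa = p_O2_init_hPa),
    class = "experiment_geometry"
  )
}

#' @export
print.experiment_geometry <- function(x, ...) {
  cat(sprintf(
    "Vial geometry: %g mL headspace / %g mL liquid, %g K, p_total %g hPa, initial p(O2) %g hPa\n",
    x$V_head_mL, x$V_liq_mL, x$T_K, x$p_total_hPa, x$p_O2_init_hPa))
  invisible(x)
}
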