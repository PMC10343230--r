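#' Stern-Volmer probe calibration
#'
#' Luminescence-lifetime oxygen probes obey the Stern-Volmer law
#' `tau0/tau = 1 + K_SV * p(O2)`, usually handled in the linear form
#' `1/tau = A * p(O2) + B`. The two parameterizations are equivalent with
#' `tau0 = 1/B` (unquenched lifetime, us) and `K_SV = A/B` (1/hPa).
#'
#' @param A slope of `1/tau` versus `p(O2)`, 1/(us hPa); positive.
#' @param B intercept of `1/tau`, 1/us; positive.
#' @param temp_C optional temperature tag (the film response is
#'   temperature-dependent, so calibrations are held per temperature).
#' @return object of class `probe_calibration` with derived `tau0_us`,
#'   `K_SV_per_hPa`.
#' @export
#' @examples
#' cal <- probe_calibration(A = 0.8 / 210, B = 0.2)
#' pO2_to_tau(210, cal)  # 1 us, the fully air-quenched lifetime
probe_calibration <- function(A, B, temp_C = NA_real_) {
  if (!is.finite(A) || A <= 0) stop("A must be a positive number")
  if (!is.finite(B) || B <= 0)
    stop("calibration invalid: intercept B must be positive")
  structure(
    list(A = A, B = B, tau0_us = 1 / B, K_SV_per_hPa = A / B,
         temp_C = temp_C),
    class = "probe_calibration"
  )
}

#' @export
print.probe_calibration <- function(x, ...) {
  cat(sprintf(
    "Stern-Volmer calibration: A = %.4g 1/(us hPa), B = %.4g 1/us (tau0 = %.3g us, K_SV = %.4g 1/hPa)\n",
    x$A, x$B, x$tau0_us, x$K_SV_per_hPa))
  if (is.finite(x$temp_C)) cat(sprintf("  temperature: %g degC\n", x$temp_C))
  invisible(x)
}

#' Default synthetic probe calibration
#'
#' A stand-in for an instrument film lot (no lot constants are published):
#' unquenched lifetime 5 us and a 1 us lifetime at air saturation (210 hPa),
#' the span typical of ruthenium-complex films.
#'
#' @param temp_C optional temperature tag.
#' @return a [probe_calibration()].
#' @export
default_probe_calibration <- function(temp_C = NA_real_) {
  tau0 <- 5    # us, no oxygen
  tau_air <- 1 # us at 210 hPa
  B <- 1 / tau0
  A <- (1 / tau_air - B) / 210
  probe_calibration(A = A, B = B, temp_C = temp_C)
}

#' Fit a Stern-Volmer calibration from lifetime measurements
#'
#' Ordinary least squares of `1/tau` against `p(O2)` — the rate-domain
#' regression, where photon-counting lifetime estimates have approximately
#' Gaussian noise.
#'
#' @param points data frame with columns `p_o2_hpa` and `tau_us` (and
#'   optionally `temp_C`, recorded on the result); at least two distinct
#'   pressures, all lifetimes positive.
#' @return a [probe_calibration()] with attribute `"fit"` holding the `lm`
#'   object (standard errors, residuals).
#' @export
fit_probe_calibration <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("p_o2_hpa", "tau_us") %in% names(points)))
  p <- points$p_o2_hpa
  tau <- points$tau_us
  if (any(!is.finite(p)) || any(!is.finite(tau)) || any(tau <= 0))
    stop("all lifetimes must be finite and positive")
  if (length(unique(p)) < 2L)
    stop("degenerate design: need at least 2 distinct p(O2) values")
  fit <- lm(I(1 / tau) ~ p)
  B <- unname(coef(fit)[1])
  A <- unname(coef(fit)[2])
  if (B <= 0)
    stop("calibration invalid: fitted intercept B <= 0 (implies infinite or negative unquenched lifetime)")
  if (A <= 0)
    stop("calibration invalid: fitted slope A <= 0 (lifetime must shorten with oxygen)")
  temp <- if ("temp_C" %in% names(points)) points$temp_C[1] else NA_real_
  cal <- probe_calibration(A = A, B = B, temp_C = temp)
  attr(cal, "fit") <- fit
  cal
}

#' Lifetime predicted at a given oxygen partial pressure
#'
#' `tau = 1 / (A p + B)`; strictly decreasing in `p`.
#'
#' @param p_O2 oxygen partial pressure, hPa (non-negative; vectorized).
#' @param calib a [probe_calibration()].
#' @return lifetime in us.
#' @export
pO2_to_tau <- function(p_O2, calib) {
  stopifnot(inherits(calib, "probe_calibration"))
  if (any(p_O2 < 0, na.rm = TRUE))
    stop("partial pressure must be non-negative")
  1 / (calib$A * p_O2 + calib$B)
}

#' Oxygen partial pressure from a measured lifetime
#'
#' Inverts the Stern-Volmer relation: `p = (1/tau - B) / A`. A lifetime
#' above the unquenched `tau0` has no physical pressure; beyond `tol`
#' (relative) it signals a probe fault, within `tol` it is clipped to zero
#' when `clip = TRUE`.
#'
#' @param tau measured lifetime, us (positive; vectorized).
#' @param calib a [probe_calibration()].
#' @param tol relative tolerance on `tau > tau0` before erroring.
#' @param clip clip small super-unquenched excursions (and any negative
#'   result within tolerance) to 0 hPa.
#' @return oxygen partial pressure, hPa.
#' @export
tau_to_pO2 <- function(tau, calib, tol = 1e-6, clip = TRUE) {
  stopifnot(inherits(calib, "probe_calibration"))
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("lifetime must be finite and positive")
  if (any(tau > calib$tau0_us * (1 + tol)))
    stop(sprintf(
      "lifetime exceeds unquenched tau0 = %.4g us beyond tolerance: probe fault",
      calib$tau0_us))
  p <- (1 / tau - calib$B) / calib$A
  if (clip) p <- pmax(p, 0)
  p
}

#' Per-temperature calibration lookup
#'
#' Holds calibrations measured at several temperatures and selects by
#' nearest neighbour; no functional form for the temperature dependence of
#' (A, B) is assumed.
#'
#' @param calibrations list of [probe_calibration()] objects, each with a
#'   finite `temp_C`.
#' @return object of class `probe_calibration_set`.
#' @export
probe_calibration_set <- function(calibrations) {
  stopifnot(length(calibrations) >= 1L,
            all(vapply(calibrations, inherits, logical(1), "probe_calibration")))
  temps <- vapply(calibrations, function(x) x$temp_C, numeric(1))
  if (any(!is.finite(temps)))
    stop("every calibration in a set needs a finite temp_C")
  structure(list(calibrations = calibrations, temps = temps),
            class = "probe_calibration_set")
}

#' Select the calibration nearest a working temperature
#' @param set a [probe_calibration_set()].
#' @param temp_C working temperature, degC.
#' @return the nearest-temperature [probe_calibration()].
#' @export
select_calibration <- function(set, temp_C) {
  stopifnot(inherits(set, "probe_calibration_set"), is.finite(temp_C))
  set$calibrations[[which.min(abs(set$temps - temp_C))]]
}

#' Read / write probe calibration points as CSV
#'
#' Columns `p_o2_hpa`, `tau_us`, optional `temp_C`.
#'
#' @param path CSV file path.
#' @return `read_calibration_csv`: data frame of calibration points.
#' @export
read_calibration_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("p_o2_hpa", "tau_us") %in% names(df)))
    stop("calibration CSV needs columns p_o2_hpa, tau_us")
  df
}

#' @rdname read_calibration_csv
#' @param points data frame of calibration points.
#' @export
write_calibration_csv <- function(points, path) {
  write.csv(points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
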