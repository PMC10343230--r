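#' Fit result container
#'
#' Point estimates, standard errors and diagnostics from a nonlinear
#' least-squares fit of one of the kinetic schemes.
#'
#' @param params named numeric vector of point estimates.
#' @param stderr named numeric vector of standard errors (NA where not
#'   available).
#' @param rss residual sum of squares.
#' @param n_obs number of observations.
#' @param converged logical convergence flag; results with
#'   `converged = FALSE` must not be used downstream.
#' @param model model label (`"decay"`, `"growth"`, `"consecutive"`,
#'   `"headspace"`, `"transfer_ratio"`).
#' @param diagnostics list: iteration count, initial guesses, warnings,
#'   alternative labellings.
#' @return object of class `fit_result`.
#' @export
fit_result <- function(params, stderr, rss, n_obs, converged, model,
                       diagnostics = list()) {
  stopifnot(is.numeric(params), !is.null(names(params)))
  if (any(stderr < 0, na.rm = TRUE)) stop("standard errors must be >= 0")
  if (is.finite(rss) && rss < -1e-12) stop("rss must be >= 0")
  structure(list(params = params, stderr = stderr,
                 rss = max(rss, 0), n_obs = n_obs,
                 converged = isTRUE(converged), model = model,
                 diagnostics = diagnostics),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model = %s, n = %d, rss = %.4g, converged = %s\n",
              x$model, x$n_obs, x$rss, x$converged))
  for (nm in names(x$params)) {
    se <- x$stderr[nm]
    cat(sprintf("  %-10s %.6g%s\n", nm, x$params[[nm]],
                if (is.finite(se)) sprintf(" (se %.3g)", se) else ""))
  }
  invisible(x)
}

#' Flatten a fit result to a one-row data frame
#' @param x a [fit_result()].
#' @param ... unused.
#' @return one-row data frame (model, n_obs, rss, converged, one column per
#'   parameter and per standard error).
#' @export
as.data.frame.fit_result <- function(x, ...) {
  row <- data.frame(model = x$model, n_obs = x$n_obs, rss = x$rss,
                    converged = x$converged)
  for (nm in names(x$params)) row[[nm]] <- x$params[[nm]]
  for (nm in names(x$stderr)) row[[paste0("se_", nm)]] <- x$stderr[[nm]]
  row
}

# Shared nlsLM driver: returns params/stderr/rss/converged from a formula
# fit on data.frame(t, y), with tight tolerances so that noise-free round
# trips recover generating values to near machine precision.
.nls_fit <- function(formula, data, start, lower, model_label,
                     diagnostics = list()) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                     ptol = 1e-15)
  fit <- try(minpack.lm::nlsLM(formula, data = data, start = start,
                               lower = lower, control = ctrl),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    # nlsLM occasionally fails to build its nls object at boundary or
    # zero-residual solutions; retry with the bare Levenberg-Marquardt
    # driver on residuals derived from the same formula.
    rhs <- formula[[3]]
    fn <- function(par) {
      data$y - eval(rhs, c(as.list(par), as.list(data)))
    }
    out <- try(minpack.lm::nls.lm(par = unlist(start), fn = fn,
                                  lower = lower, control = ctrl),
               silent = TRUE)
    if (inherits(out, "try-error") || !(out$info %in% 1:4)) {
      return(fit_result(params = setNames(rep(NA_real_, length(start)),
                                          names(start)),
                        stderr = setNames(rep(NA_real_, length(start)),
                                          names(start)),
                        rss = NA_real_, n_obs = nrow(data),
                        converged = FALSE, model = model_label,
                        diagnostics = c(diagnostics,
                                        list(error = "optimization failed"))))
    }
    se <- setNames(rep(NA_real_, length(out$par)), names(out$par))
    sm <- try(suppressWarnings(summary(out)), silent = TRUE)
    if (!inherits(sm, "try-error"))
      se[rownames(sm$coefficients)] <- sm$coefficients[, "Std. Error"]
    return(fit_result(params = out$par, stderr = se,
                      rss = sum(out$fvec^2), n_obs = nrow(data),
                      converged = TRUE, model = model_label,
                      diagnostics = c(diagnostics,
                                      list(iterations = out$niter,
                                           start = unlist(start),
                                           driver = "nls.lm"))))
  }
  est <- coef(fit)
  se <- rep(NA_real_, length(est))
  names(se) <- names(est)
  sm <- try(summary(fit), silent = TRUE)
  if (!inherits(sm, "try-error"))
    se[rownames(sm$coefficients)] <- sm$coefficients[, "Std. Error"]
  conv <- fit$convInfo$isConv %||% TRUE
  fit_result(params = est, stderr = se,
             rss = sum(residuals(fit)^2), n_obs = nrow(data),
             converged = isTRUE(conv), model = model_label,
             diagnostics = c(diagnostics,
                             list(iterations = fit$convInfo$finIter,
                                  start = unlist(start))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the pseudo-first-order decay model
#'
#' Least-squares fit of `value(t) = O2_init * exp(-k1 t)` to a no-headspace
#' depletion trace. Initial guesses come from a log-linear regression on the
#' strictly positive values, so fits are deterministic and reproducible.
#'
#' @param trace an [o2_trace()] (any concentration- or pressure-kind trace)
#'   with at least 4 non-negative observations.
#' @return a [fit_result()] with parameters `O2_init`, `k1`.
#' @export
#' @examples
#' tr <- decay_no_headspace(0:120, 61.1, 0.039)
#' fit_first_order_decay(tr)$params
fit_first_order_decay <- function(trace) {
  stopifnot(inherits(trace, "o2_trace"))
  t <- trace$time_min; y <- trace$value
  if (length(y) < 4L) stop("need at least 4 observations")
  if (all(y == 0)) stop("degenerate trace: all values are zero")
  pos <- y > max(y) * 1e-9
  if (sum(pos) < 2L) stop("degenerate trace: too few positive values")
  ll <- lm(log(y[pos]) ~ t[pos])
  k1_0 <- max(-unname(coef(ll)[2]), 1e-8)
  O2_0 <- exp(unname(coef(ll)[1]))
  .nls_fit(y ~ O2_init * exp(-k1 * t),
           data = data.frame(t = t, y = y),
           start = list(O2_init = O2_0, k1 = k1_0),
           lower = c(0, 0), model_label = "decay")
}

#' Fit the exponential absorbance-growth model
#'
#' Least-squares fit of `Abs(t) = amplitude * (1 - exp(-k1L t))`. The
#' initial amplitude guess is the maximum observed value; the rate guess is
#' a log-linear regression on the deficit from that amplitude.
#'
#' @param trace an [o2_trace()] with at least 4 observations.
#' @return a [fit_result()] with parameters `amplitude`, `k1L`.
#' @export
fit_growth <- function(trace) {
  stopifnot(inherits(trace, "o2_trace"))
  t <- trace$time_min; y <- trace$value
  if (length(y) < 4L) stop("need at least 4 observations")
  if (all(y == 0)) stop("degenerate trace: all values are zero")
  A0 <- max(y)
  deficit <- A0 - y
  pos <- deficit > A0 * 1e-9 & t > 0
  k_0 <- if (sum(pos) >= 2L) {
    max(-unname(coef(lm(log(deficit[pos]) ~ t[pos]))[2]), 1e-8)
  } else {
    1 / max(t[t > 0])
  }
  .nls_fit(y ~ amplitude * (1 - exp(-k1L * t)),
           data = data.frame(t = t, y = y),
           start = list(amplitude = A0, k1L = k_0),
           lower = c(0, 0), model_label = "growth")
}

# Deterministic coarse grid search for the biexponential
# C * (exp(-ka t) - exp(-kb t)), ka < kb: for each rate pair the amplitude
# is solved linearly, the best-rss pair seeds the nonlinear fit. This keeps
# the fit identifiable even when the observation window ends before the
# peak (a monotone dome segment).
.consecutive_grid_start <- function(t, y) {
  T_end <- max(t)
  rates <- 10^seq(log10(0.005 / T_end), log10(200 / T_end), length.out = 28)
  best <- NULL
  for (i in seq_along(rates)) {
    for (j in seq_along(rates)) {
      if (j <= i) next
      f <- exp(-rates[i] * t) - exp(-rates[j] * t)
      denom <- sum(f * f)
      if (denom <= 0) next
      C <- sum(f * y) / denom
      rss <- sum((y - C * f)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(ka = rates[i], kb = rates[j], C = C, rss = rss)
    }
  }
  best
}

#' Fit the consecutive-reaction (dome-shaped) chromogenic model
#'
#' Least-squares fit of the two-step closed form
#' `value(t) = C (exp(-k2 t) - exp(-k3 t))` with `C = s k2 [O2]_i/(k3-k2)`
#' (times `epsilon l` for absorbance traces). The biexponential is invariant
#' under swapping the two rates, so estimates are reported with the
#' labelling convention `k2 < k3` (slow formation, faster loss of colour);
#' the swapped labelling is recorded in `diagnostics$alternative`. The
#' glucose-oxidase scavenging constant is reported as `k1G = s * k2`.
#'
#' Initial guesses come from a deterministic coarse grid search over rate
#' pairs with a linear amplitude solve. If the trace is monotone within the
#' observation window a warning is raised (the dome peak may lie beyond the
#' window); should the full fit fail or collapse, the quinone-decay step is
#' pinned near zero and a growth-limit fit is returned.
#'
#' @param trace an [o2_trace()] (absorbance or concentration kind) with at
#'   least 6 observations.
#' @param s stoichiometric factor quinone:O2 (default 4).
#' @param spectro a [spectro_config()] used to convert the fitted amplitude
#'   back to `O2_init` when the trace is absorbance; defaults to the
#'   436 nm / 2 mm configuration.
#' @return a [fit_result()] with parameters `k2`, `k3`, `C`, `O2_init`,
#'   `k1G`.
#' @export
fit_consecutive <- function(trace, s = 4, spectro = spectro_config()) {
  stopifnot(inherits(trace, "o2_trace"))
  t <- trace$time_min; y <- trace$value
  if (length(y) < 6L) stop("need at least 6 observations")
  if (all(y == 0)) stop("degenerate trace: all values are zero")
  monotone <- which.max(y) %in% c(1L, length(y))
  if (monotone)
    warning("no interior maximum in the observation window; the dome peak may lie beyond it")

  g <- .consecutive_grid_start(t, y)
  res <- .nls_fit(y ~ C * (exp(-k2 * t) - exp(-k3 * t)),
                  data = data.frame(t = t, y = y),
                  start = list(k2 = g$ka, k3 = g$kb, C = g$C),
                  lower = c(1e-12, 1e-12, -Inf),
                  model_label = "consecutive")

  collapsed <- !res$converged || anyNA(res$params) ||
    res$params[["k3"]] <= 2e-12 || res$params[["k2"]] <= 2e-12
  if (collapsed) {
    # growth limit: k3 ~ 0 gives s k2 O2_i (1 - exp(-k2 t))
    gr <- fit_growth(trace)
    amp <- gr$params[["amplitude"]]; k2 <- gr$params[["k1L"]]
    res <- fit_result(
      params = c(k2 = k2, k3 = 0, C = amp),
      stderr = c(k2 = gr$stderr[["k1L"]], k3 = NA_real_,
                 C = gr$stderr[["amplitude"]]),
      rss = gr$rss, n_obs = gr$n_obs, converged = gr$converged,
      model = "consecutive",
      diagnostics = list(fallback = "k3 pinned near 0 (growth limit)"))
  }

  p <- res$params
  # when one rate is indistinguishable from zero over the window the model
  # is the growth limit: the surviving rate is formation (k2), decay k3 = 0
  kmin <- min(p[["k2"]], p[["k3"]])
  kmax <- max(p[["k2"]], p[["k3"]])
  if (!anyNA(p) && kmin * max(t) < 1e-4 && kmax > 0) {
    A <- if (p[["k2"]] <= p[["k3"]]) p[["C"]] else -p[["C"]]
    se_kmax <- if (p[["k2"]] >= p[["k3"]]) res$stderr[["k2"]] else
      res$stderr[["k3"]]
    res$diagnostics$limit <- "decay step ~ 0 over the window (growth limit)"
    res$params <- c(k2 = kmax, k3 = 0, C = unname(A))
    res$stderr <- c(k2 = unname(se_kmax), k3 = NA_real_,
                    C = unname(res$stderr[["C"]]))
    p <- res$params
  }
  # enforce the k2 < k3 labelling; swapping the rates flips the sign of C
  if (!is.na(p[["k2"]]) && !is.na(p[["k3"]]) && p[["k3"]] > 0 &&
      p[["k2"]] > p[["k3"]]) {
    res$diagnostics$alternative <- p
    p <- c(k2 = unname(p[["k3"]]), k3 = unname(p[["k2"]]),
           C = -unname(p[["C"]]))
    se <- res$stderr
    res$stderr <- c(k2 = unname(se[["k3"]]), k3 = unname(se[["k2"]]),
                    C = unname(se[["C"]]))
    res$params <- p
  }

  scale <- if (trace$kind == "absorbance") absorbance_per_uM(spectro) else 1
  O2_init <- if (p[["k3"]] > 0 && p[["k2"]] > 0) {
    p[["C"]] * (p[["k3"]] - p[["k2"]]) / (s * p[["k2"]] * scale)
  } else if (p[["k2"]] > 0) {
    p[["C"]] / (s * scale)   # growth limit: amplitude = s O2_i (x scale)
  } else NA_real_
  res$params <- c(res$params, O2_init = unname(O2_init),
                  k1G = unname(s * p[["k2"]]))
  res$stderr <- c(res$stderr, O2_init = NA_real_,
                  k1G = unname(s * res$stderr[["k2"]]))
  res$diagnostics$s <- s
  res$diagnostics$monotone_window <- monotone
  res
}

#' Fit the headspace transfer/scavenging model
#'
#' Least-squares fit of the quasi-static closed form
#' `[O2](t) = O2_e + (O2_init - O2_e) exp(-k1 t)` to a headspace depletion
#' trace. The transfer coefficient follows from the steady-state balance:
#' `k_tr = k1 O2_e / p_i`. A fitted residual below zero triggers a refit
#' with `O2_e` clipped at zero (plain decay) and a warning.
#'
#' @param trace an [o2_trace()] of a dissolved-oxygen kind with at least 5
#'   observations.
#' @param p_i initial headspace oxygen partial pressure, hPa (positive);
#'   taken from `trace$meta$p_i_hPa` when missing.
#' @return a [fit_result()] with parameters `O2_init`, `O2_e`, `k1`,
#'   `k_tr`, `residual_fraction` (= O2_e/O2_init).
#' @export
fit_headspace <- function(trace, p_i = NULL) {
  stopifnot(inherits(trace, "o2_trace"))
  p_i <- p_i %||% trace$meta$p_i_hPa
  if (is.null(p_i) || !is.finite(p_i) || p_i <= 0)
    stop("p_i (initial headspace p(O2), hPa) must be supplied or present in trace meta")
  t <- trace$time_min; y <- trace$value
  if (length(y) < 5L) stop("need at least 5 observations")
  if (all(y == 0)) stop("degenerate trace: all values are zero")

  n_tail <- max(3L, ceiling(length(y) / 5))
  O2e_0 <- max(mean(tail(y, n_tail)), 0)
  O2i_0 <- y[1]
  amp <- y - O2e_0
  pos <- amp > max(abs(amp)) * 1e-9
  k1_0 <- if (sum(pos) >= 2L) {
    max(-unname(coef(lm(log(amp[pos]) ~ t[pos]))[2]), 1e-8)
  } else 1 / max(t[t > 0])

  res <- .nls_fit(y ~ O2_e + (O2_init - O2_e) * exp(-k1 * t),
                  data = data.frame(t = t, y = y),
                  start = list(O2_init = O2i_0, O2_e = O2e_0, k1 = k1_0),
                  lower = c(0, -Inf, 0), model_label = "headspace")
  tiny <- 1e-8 * max(abs(y))
  if (res$converged && !is.na(res$params[["O2_e"]]) &&
      res$params[["O2_e"]] < 0 && res$params[["O2_e"]] >= -tiny) {
    res$params[["O2_e"]] <- 0  # numerically zero residual
  }
  if (res$converged && !is.na(res$params[["O2_e"]]) &&
      res$params[["O2_e"]] < 0) {
    warning("fitted steady-state residual < 0; refitting with O2_e clipped at zero")
    dec <- fit_first_order_decay(trace)
    res <- fit_result(
      params = c(O2_init = unname(dec$params[["O2_init"]]), O2_e = 0,
                 k1 = unname(dec$params[["k1"]])),
      stderr = c(O2_init = unname(dec$stderr[["O2_init"]]), O2_e = NA_real_,
                 k1 = unname(dec$stderr[["k1"]])),
      rss = dec$rss, n_obs = dec$n_obs, converged = dec$converged,
      model = "headspace",
      diagnostics = list(fallback = "O2_e clipped at zero"))
  }
  p <- res$params
  k_tr <- p[["k1"]] * p[["O2_e"]] / p_i
  res$params <- c(res$params, k_tr = unname(k_tr),
                  residual_fraction = unname(p[["O2_e"]] / p[["O2_init"]]))
  res$stderr <- c(res$stderr, k_tr = NA_real_, residual_fraction = NA_real_)
  res$diagnostics$p_i_hPa <- p_i
  res
}

#' Transfer-to-scavenging ratio from steady-state depletion extents
#'
#' The depletion extent is linear through the origin in the initial
#' content: `delta[O2] = (1 - r) [O2]_i` with `r = k_tr/(K_H k1)`. A
#' through-origin least-squares line of `delta[O2]` against `[O2]_i`
#' estimates the slope `1 - r`, hence `r`.
#'
#' @param pairs data frame with either columns `O2_i` and `O2_e`
#'   (initial / steady-state dissolved oxygen, uM) or columns `p_i` and
#'   `delta_O2` (initial partial pressure, hPa, and depletion, uM; requires
#'   `K_H`).
#' @param K_H Henry constant in uM/hPa, needed only for the
#'   `(p_i, delta_O2)` form to place the abscissa on the concentration
#'   scale.
#' @param intercept also fit an intercept-allowed line for diagnostics
#'   (the through-origin slope is always what is reported).
#' @return a [fit_result()] with parameters `r` and `slope` (= 1 - r) and
#'   the slope standard error.
#' @export
#' @examples
#' KH <- henry_constant_uM(20)
#' O2i <- KH * c(50, 100, 150, 200)
#' estimate_transfer_ratio(data.frame(O2_i = O2i, O2_e = 0.97 * O2i))$params
estimate_transfer_ratio <- function(pairs, K_H = NULL, intercept = FALSE) {
  stopifnot(is.data.frame(pairs))
  if (all(c("O2_i", "O2_e") %in% names(pairs))) {
    x <- pairs$O2_i
    y <- pairs$O2_i - pairs$O2_e
  } else if (all(c("p_i", "delta_O2") %in% names(pairs))) {
    if (is.null(K_H))
      stop("K_H (uM/hPa) is required for (p_i, delta_O2) pairs")
    x <- K_H * pairs$p_i
    y <- pairs$delta_O2
  } else {
    stop("pairs must have columns (O2_i, O2_e) or (p_i, delta_O2)")
  }
  if (length(unique(x)) < 2L)
    stop("degenerate design: need at least 2 distinct initial contents")
  fit0 <- lm(y ~ 0 + x)
  slope <- unname(coef(fit0)[1])
  rss0 <- sum(residuals(fit0)^2)
  dof <- length(x) - 1L
  se <- if (dof > 0) sqrt(rss0 / dof / sum(x^2)) else NA_real_
  diag <- list(n_pairs = length(x))
  if (intercept) {
    fit1 <- lm(y ~ x)
    diag$with_intercept <- coef(fit1)
  }
  fit_result(params = c(r = 1 - slope, slope = slope),
             stderr = c(r = se, slope = se),
             rss = sum(residuals(fit0)^2), n_obs = length(x),
             converged = TRUE, model = "transfer_ratio",
             diagnostics = diag)
}

#' Serialize a fit result to JSON
#' @param x a [fit_result()].
#' @param path optional file path; when NULL the JSON string is returned.
#' @return JSON string (invisibly the path when written to file).
#' @export
fit_result_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "fit_result"))
  obj <- list(model = x$model, params = as.list(x$params),
              stderr = as.list(x$stderr), rss = x$rss, n_obs = x$n_obs,
              converged = x$converged)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
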