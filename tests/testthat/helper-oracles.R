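# Independent numerical oracles used to cross-check the closed forms.
# These integrate the defining ODEs with deSolve at tight tolerances and
# never call the package's closed-form implementations.

ode_decay_oracle <- function(t_grid, O2_init, k1, rtol = 1e-8) {
  out <- deSolve::ode(y = c(O2 = O2_init), times = t_grid,
                      func = function(t, y, p) list(-k1 * y[1]),
                      parms = NULL, rtol = rtol, atol = rtol * 1e-4)
  unname(out[, "O2"])
}

# Consecutive scheme O2 -> (s x) Q -> P; returns O2, Q and terminal products P
ode_consecutive_oracle <- function(t_grid, O2_init, k2, k3, s = 4,
                                   rtol = 1e-8) {
  rhs <- function(t, y, p) {
    list(c(-k2 * y[1],
           s * k2 * y[1] - k3 * y[2],
           k3 * y[2]))
  }
  out <- deSolve::ode(y = c(O2 = O2_init, Q = 0, P = 0), times = t_grid,
                      func = rhs, parms = NULL, rtol = rtol,
                      atol = rtol * 1e-4)
  list(O2 = unname(out[, "O2"]), Q = unname(out[, "Q"]),
       P = unname(out[, "P"]))
}

# Headspace balance with the gas phase held constant (quasi-static premise)
ode_headspace_oracle <- function(t_grid, O2_init, p_i, k1, k_tr,
                                 rtol = 1e-8) {
  out <- deSolve::ode(y = c(O2 = O2_init), times = t_grid,
                      func = function(t, y, p) list(k_tr * p_i - k1 * y[1]),
                      parms = NULL, rtol = rtol, atol = rtol * 1e-4)
  unname(out[, "O2"])
}

rel_err <- function(x, ref, floor = NULL) {
  if (is.null(floor)) floor <- 1e-9 * max(abs(ref))
  abs(x - ref) / pmax(abs(ref), floor)
}

# Published rate constants used as generating truth across the suite
K1G_OXYSENSE <- 0.039
K1L_OXYSENSE <- 0.046
K1G_STOPFLOW <- 0.043
K1L_STOPFLOW <- 0.042
R_TRANSFER <- 0.97
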