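#' Hodgkin-Huxley gating variable with shiftable voltage dependence
#'
#' A gating variable `u` relaxes toward its voltage-dependent steady state
#' `u_inf(V)` with time constant `tau_u(V)` (ms).  The steady state is a
#' Boltzmann sigmoid and the time constant a bell-shaped curve with a single
#' interior maximum:
#' \deqn{u_\infty(V) = 1/(1 + e^{-(V - V_{1/2})/k}),}
#' \deqn{\tau_u(V) = \tau_0 + a / (e^{(V - V_p)/w_1} + e^{-(V - V_p)/w_2}).}
#' A negative slope factor `k` yields a decreasing (availability-type) steady
#' state.  Both curves can be translated along the voltage axis: `base_shift`
#' is the subtype's nominal right-shift (13 mV for NaV1.2, 0 otherwise) and
#' `delta_inf` / `delta_tau` are the shift-clamp increments applied to the
#' steady state and time constant independently, so the effective curves are
#' `u_inf(V - base_shift - delta_inf)` and `tau_u(V - base_shift - delta_tau)`.
#'
#' @param name Identifier, e.g. `"m"`, `"h"`, `"n"`.
#' @param exponent Positive integer exponent in the conductance product.
#' @param inf_params Named list or vector with `vhalf` (mV) and `k` (mV,
#'   nonzero; negative for availability variables).
#' @param tau_params Named list or vector with `base` (ms, > 0), `amp` (ms,
#'   >= 0), `vmax` (mV), `w1`, `w2` (mV, > 0).
#' @param base_shift Nominal right-shift V_RS in mV.
#' @param delta_inf,delta_tau Additional shift-clamp displacements in mV.
#'
#' @return An object of class `gating_variable`.
#' @export
gating_variable <- function(name, exponent, inf_params, tau_params,
                            base_shift = 0, delta_inf = 0, delta_tau = 0) {
  inf_params <- as.list(inf_params)
  tau_params <- as.list(tau_params)
  stopifnot(exponent >= 1, exponent == round(exponent),
            inf_params$k != 0,
            tau_params$base > 0, tau_params$amp >= 0,
            tau_params$w1 > 0, tau_params$w2 > 0)
  structure(
    list(name = name, exponent = as.integer(exponent),
         inf_params = inf_params[c("vhalf", "k")],
         tau_params = tau_params[c("base", "amp", "vmax", "w1", "w2")],
         base_shift = base_shift, delta_inf = delta_inf,
         delta_tau = delta_tau),
    class = "gating_variable")
}

#' Steady-state value of a gating variable
#'
#' Evaluates `u_inf(V - base_shift - delta_inf)`.
#'
#' @param gv A [gating_variable()].
#' @param V Membrane potential(s) in mV.
#' @return Open probability in `[0, 1]`, vectorized over `V`.
#' @export
steady_state <- function(gv, V) {
  veff <- V - gv$base_shift - gv$delta_inf
  1 / (1 + exp(-(veff - gv$inf_params$vhalf) / gv$inf_params$k))
}

#' Voltage-dependent time constant of a gating variable
#'
#' Evaluates `tau_u(V - base_shift - delta_tau)` in ms; strictly positive for
#' all voltages.
#'
#' @inheritParams steady_state
#' @return Time constant(s) in ms.
#' @export
time_constant <- function(gv, V) {
  veff <- V - gv$base_shift - gv$delta_tau
  tp <- gv$tau_params
  tp$base + tp$amp / (exp((veff - tp$vmax) / tp$w1) +
                      exp(-(veff - tp$vmax) / tp$w2))
}

#' Forward and backward rates from steady state and time constant
#'
#' Inverts the usual relations `u_inf = alpha/(alpha+beta)`,
#' `tau = 1/(alpha+beta)`: `alpha = u_inf/tau`, `beta = (1 - u_inf)/tau`.
#' When `delta_inf == delta_tau` this is identical to translating the rate
#' functions themselves; unequal shifts give the shift-clamped kinetics.
#'
#' @inheritParams steady_state
#' @return A list with numeric components `alpha` and `beta` (1/ms).
#' @export
rates_from_inf_tau <- function(gv, V) {
  uinf <- steady_state(gv, V)
  tau <- time_constant(gv, V)
  list(alpha = uinf / tau, beta = (1 - uinf) / tau)
}

#' Advance a gating variable by one time step
#'
#' Exponential-Euler update, exact for voltage held fixed over the step:
#' `u' = u_inf + (u - u_inf) * exp(-dt/tau)`.  The result always stays in
#' `[0, 1]` for `u` in `[0, 1]`.
#'
#' @param u Current value in `[0, 1]`.
#' @param V Membrane potential in mV (held over the step).
#' @param dt Step in ms.
#' @param gv A [gating_variable()].
#' @return Updated gating value.
#' @export
step_gating <- function(u, V, dt, gv) {
  stopifnot(all(u >= 0 & u <= 1), dt > 0)
  uinf <- steady_state(gv, V)
  uinf + (u - uinf) * exp(-dt / time_constant(gv, V))
}

#' Voltage-gated channel specification
#'
#' Bundles the gating variables of one channel population.  NaV subtypes have
#' activation `m` (exponent 3) and availability `h` (exponent 1), with
#' conductance `gbar * m^3 * h`; the delayed-rectifier KV uses a single
#' activation gate.
#'
#' @param subtype One of `"NaV1.2"`, `"NaV1.6"`, `"KV"`.
#' @param ion Permeant ion, `"Na"`, `"K"` or `"Cl"`.
#' @param gating Named list of [gating_variable()] objects.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(subtype, ion, gating) {
  stopifnot(subtype %in% c("NaV1.2", "NaV1.6", "KV"),
            ion %in% c("Na", "K", "Cl"))
  if (subtype %in% c("NaV1.2", "NaV1.6")) {
    stopifnot(setequal(names(gating), c("m", "h")),
              gating$m$exponent == 3L, gating$h$exponent == 1L)
  }
  structure(list(subtype = subtype, ion = ion, gating = gating),
            class = "channel_spec")
}

#' Shift-clamp conditions
#'
#' The seven combinations of NaV1.2 gating properties whose right-shift can be
#' displaced by `dVrs` while the others are clamped at the nominal shift.
#' @export
shift_conditions <- function() {
  c("all", "tau_h", "h_inf", "h_inf_tau_h", "tau_m", "m_inf", "m_inf_tau_m")
}

#' Apply a shift-clamp transformation to a NaV1.2 channel spec
#'
#' Returns a copy of `spec` in which only the gating properties named by
#' `condition` have their voltage dependence displaced by `dVrs` (mV), on top
#' of the nominal 13 mV right-shift.  `"all"` displaces all four properties
#' (so `dVrs = -13` makes NaV1.2 kinetics coincide with NaV1.6);
#' `"tau_h"` displaces only the availability time constant, etc.
#'
#' @param spec A NaV1.2 [channel_spec()].
#' @param condition One of [shift_conditions()].
#' @param dVrs Shift increment in mV.
#' @return A modified `channel_spec`.
#' @export
shift_clamp <- function(spec, condition, dVrs) {
  stopifnot(inherits(spec, "channel_spec"))
  if (spec$subtype != "NaV1.2")
    stop("shift_clamp() applies to NaV1.2 specs only")
  condition <- match.arg(condition, shift_conditions())
  touch <- switch(condition,
    all         = list(m = c("inf", "tau"), h = c("inf", "tau")),
    tau_h       = list(h = "tau"),
    h_inf       = list(h = "inf"),
    h_inf_tau_h = list(h = c("inf", "tau")),
    tau_m       = list(m = "tau"),
    m_inf       = list(m = "inf"),
    m_inf_tau_m = list(m = c("inf", "tau")))
  for (g in names(spec$gating)) {
    spec$gating[[g]]$delta_inf <- 0
    spec$gating[[g]]$delta_tau <- 0
  }
  for (g in names(touch)) {
    if ("inf" %in% touch[[g]]) spec$gating[[g]]$delta_inf <- dVrs
    if ("tau" %in% touch[[g]]) spec$gating[[g]]$delta_tau <- dVrs
  }
  spec
}

# Default kinetic parameter tables (recipe-level data, not hard-wired into the
# solver).  NaV1.6 is the base subtype; NaV1.2 is the identical functional
# form right-shifted by `nav12_right_shift` (13 mV).  The KV activation
# exponent and time constants are standard cortical-pyramidal choices; the
# functional forms and all numbers live in the recipe and can be overridden.
default_kinetics <- function(nav12_right_shift = 13) {
  nav_m <- list(inf = list(vhalf = -38, k = 6),
                tau = list(base = 0.04, amp = 0.3, vmax = -38, w1 = 15, w2 = 15))
  nav_h <- list(inf = list(vhalf = -66, k = -6),
                tau = list(base = 0.3, amp = 5, vmax = -60, w1 = 12, w2 = 12))
  kv_n <- list(inf = list(vhalf = -25, k = 9),
               tau = list(base = 0.6, amp = 3, vmax = -30, w1 = 20, w2 = 20))
  list(nav_m = nav_m, nav_h = nav_h, kv_n = kv_n,
       nav12_right_shift = nav12_right_shift)
}

# Build channel_spec objects from a kinetics table.
make_channel_specs <- function(kin = default_kinetics()) {
  gv <- function(name, exponent, p, shift)
    gating_variable(name, exponent, p$inf, p$tau, base_shift = shift)
  list(
    nav16 = channel_spec("NaV1.6", "Na",
      list(m = gv("m", 3, kin$nav_m, 0), h = gv("h", 1, kin$nav_h, 0))),
    nav12 = channel_spec("NaV1.2", "Na",
      list(m = gv("m", 3, kin$nav_m, kin$nav12_right_shift),
           h = gv("h", 1, kin$nav_h, kin$nav12_right_shift))),
    kv = channel_spec("KV", "K",
      list(n = gv("n", 1, kin$kv_n, 0))))
}
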