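#' Global simulation parameters
#'
#' Physical constants, temperature, the integration time step and the spatial
#' discretization rule shared by every simulation.
#'
#' @param temperature Absolute temperature in kelvin. Enters only through the
#'   Nernst relation; gating kinetics carry no Q10 scaling.
#' @param dt Integration time step in ms.
#' @param max_seg_len Maximum compartment length in micrometres for sections
#'   that do not specify an explicit segment count. The AIS is discretized
#'   more finely (see [default_recipe()]).
#' @param theta Implicitness of the voltage update: 0.5 gives Crank-Nicolson
#'   (default), 1 gives backward Euler.
#'
#' @return An object of class `ais_globals`.
#' @export
global_params <- function(temperature = 310, dt = 0.025, max_seg_len = 25,
                          theta = 0.5) {
  stopifnot(temperature > 0, dt > 0, max_seg_len > 0,
            theta >= 0.5, theta <= 1)
  structure(
    list(temperature = temperature,
         faraday = .FARADAY,
         gas_constant = .GAS_CONSTANT,
         dt = dt,
         max_seg_len = max_seg_len,
         theta = theta),
    class = "ais_globals")
}

#' @export
print.ais_globals <- function(x, ...) {
  cat("Global parameters: T =", x$temperature, "K, dt =", x$dt,
      "ms, max segment length =", x$max_seg_len,
      "um, theta =", x$theta, "\n")
  invisible(x)
}
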