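#' Propagation criterion
#'
#' Detector settings for backpropagation (BAP) and forward propagation (FP).
#' Backpropagation requires *every* apical tip to exceed `bap_voltage`
#' (default -63 mV, i.e. a 7 mV depolarization above the -70 mV rest) within
#' the evaluation window after stimulus onset; forward propagation requires
#' the distal axon node to cross `fp_voltage` (default 0 mV).
#'
#' @param bap_voltage BAP voltage criterion in mV.
#' @param fp_voltage FP voltage criterion in mV.
#' @param window Evaluation window in ms after stimulus onset.
#' @return An object of class `prop_criterion`.
#' @export
propagation_criterion <- function(bap_voltage = -63, fp_voltage = 0,
                                  window = 25) {
  stopifnot(window > 0)
  structure(list(bap_voltage = bap_voltage, fp_voltage = fp_voltage,
                 window = window), class = "prop_criterion")
}

trace_window_max <- function(traces, cols) {
  onset <- if (is.null(traces$protocol)) 0 else traces$protocol$onset
  win <- traces$time >= onset
  apply(traces$V[win, cols, drop = FALSE], 2, max)
}

#' Detect backpropagation in a trace set
#'
#' TRUE iff every apical tip's maximum voltage within the evaluation window
#' exceeds the BAP criterion (all-tips rule).
#'
#' @param traces A `trace_set` including every apical tip.
#' @param crit A [propagation_criterion()].
#' @return Logical scalar.
#' @export
detect_backpropagation <- function(traces, crit = propagation_criterion()) {
  tips <- grep("^apical_tip", colnames(traces$V), value = TRUE)
  if (length(tips) == 0L) stop("traces do not include any apical tip")
  all(trace_window_max(traces, tips) > crit$bap_voltage)
}

#' Detect forward propagation in a trace set
#'
#' TRUE iff the distal axon node crosses the FP voltage within the window.
#'
#' @inheritParams detect_backpropagation
#' @return Logical scalar.
#' @export
detect_forward_propagation <- function(traces,
                                       crit = propagation_criterion()) {
  if (!"axon_distal" %in% colnames(traces$V))
    stop("traces do not include the distal axon node")
  trace_window_max(traces, "axon_distal") > crit$fp_voltage
}

#' Find a propagation threshold current by bisection
#'
#' Searches for the minimum 1 ms pulse amplitude whose response satisfies the
#' detector, by geometric bracket expansion from `seed` followed by
#' bisection to a relative tolerance.  Axonal stimulation is capped (default
#' 10 nA) to avoid unphysiological local depolarization; a search whose
#' detector is still FALSE at the cap returns `capped = TRUE` and
#' `converged = FALSE`.
#'
#' @param cell A `cell_model` (with profile applied).
#' @param state Equilibrated state from [run_to_steady_state()].
#' @param site `"somatic"` or `"axonal"` (or any section name).
#' @param detector `"bap"` or `"fp"`, or a function
#'   `function(traces, crit) -> logical`.
#' @param crit A [propagation_criterion()].
#' @param seed Initial trial amplitude in nA.
#' @param cap Maximum amplitude in nA (default 10 for axonal sites, 20
#'   otherwise).
#' @param rel_tol Relative bisection tolerance (bracket width / midpoint).
#' @param duration,onset Pulse shape (ms).
#' @param tstop Simulated time; defaults to `onset + window + 2` ms.
#' @return An object of class `threshold_result` with `amplitude` (nA,
#'   bracket midpoint; NA if capped), `bracket`, `converged`, `capped`,
#'   `n_sim`, and the protocol metadata.
#' @export
find_threshold <- function(cell, state, site, detector = "bap",
                           crit = propagation_criterion(), seed = 1,
                           cap = NULL, rel_tol = 0.01, duration = 1,
                           onset = 1, tstop = NULL) {
  if (is.null(cap)) cap <- if (identical(site, "axonal")) 10 else 20
  if (is.null(tstop)) tstop <- onset + crit$window + 2
  det_fun <- if (is.function(detector)) detector
             else switch(match.arg(detector, c("bap", "fp")),
                         bap = detect_backpropagation,
                         fp = detect_forward_propagation)
  n_sim <- 0L
  try_amp <- function(amp) {
    n_sim <<- n_sim + 1L
    tr <- simulate_cell(cell, state,
                        stimulus(site, amp, duration, onset), tstop)
    det_fun(tr, crit)
  }
  # bracket: expand geometrically until the detector fires or the cap is hit
  lo <- 0; hi <- min(seed, cap)
  while (!try_amp(hi)) {
    lo <- hi
    if (hi >= cap) {
      return(structure(list(kind = detector, amplitude = NA_real_,
                            bracket = c(lo, cap), tolerance = NA_real_,
                            converged = FALSE, capped = TRUE, n_sim = n_sim,
                            site = site, crit = crit),
                       class = "threshold_result"))
    }
    hi <- min(2 * hi, cap)
  }
  # bisection on the bracketed step
  repeat {
    mid <- (lo + hi) / 2
    if ((hi - lo) <= rel_tol * mid) break
    if (try_amp(mid)) hi <- mid else lo <- mid
  }
  structure(list(kind = detector, amplitude = (lo + hi) / 2,
                 bracket = c(lo, hi), tolerance = rel_tol * (lo + hi) / 2,
                 converged = TRUE, capped = FALSE, n_sim = n_sim,
                 site = site, crit = crit),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$capped)
    cat(sprintf("threshold (%s, %s): not reached below %g nA (capped)\n",
                if (is.character(x$kind)) x$kind else "custom", x$site,
                x$bracket[2]))
  else
    cat(sprintf("threshold (%s, %s): %.4g nA (bracket [%.4g, %.4g])\n",
                if (is.character(x$kind)) x$kind else "custom", x$site,
                x$amplitude, x$bracket[1], x$bracket[2]))
  invisible(x)
}
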