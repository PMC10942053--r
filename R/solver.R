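#' Assemble the axial coupling operator of a discretized cell
#'
#' Returns the symmetric tree-structured axial conductance operator `L`
#' (siemens): `L[j, k] = -g_jk` for coupled compartments and
#' `L[j, j] = sum_k g_jk`, so every row sums to zero (axial terms carry no
#' leak) and the net axial current at every branch point vanishes for any
#' voltage vector (Kirchhoff).  Applied to a constant vector it returns zero.
#'
#' @param cell A `cell_model`.
#' @return A list with `parent` (integer vector), `g_axial` (S, per
#'   compartment to its parent) and `L` (dense n x n matrix, S).
#' @export
assemble_operator <- function(cell) {
  comp <- cell$comp
  n <- nrow(comp)
  if (n > 1 && any(is.na(comp$parent[-1])))
    stop("disconnected compartment graph")
  L <- matrix(0, n, n)
  for (j in seq_len(n)) {
    p <- comp$parent[j]
    if (is.na(p)) next
    g <- comp$g_axial[j]
    L[j, p] <- L[j, p] - g
    L[p, j] <- L[p, j] - g
    L[j, j] <- L[j, j] + g
    L[p, p] <- L[p, p] + g
  }
  list(parent = comp$parent, g_axial = comp$g_axial, L = L)
}

# Flatten a cell_model into the unit-converted arrays the C++ core consumes.
compile_model <- function(cell, dt = NULL, theta = NULL,
                          ion_dynamics = TRUE, diffusion = TRUE) {
  comp <- cell$comp
  gl <- cell$globals
  if (is.null(dt)) dt <- gl$dt
  if (is.null(theta)) theta <- gl$theta
  sp <- cell$specs
  gcol <- function(gv) {
    c(gv$inf_params$vhalf, gv$inf_params$k,
      gv$tau_params$base, gv$tau_params$amp, gv$tau_params$vmax,
      gv$tau_params$w1, gv$tau_params$w2,
      gv$base_shift + gv$delta_inf, gv$base_shift + gv$delta_tau)
  }
  gate_params <- cbind(
    gcol(sp$nav16$gating$m), gcol(sp$nav16$gating$h),
    gcol(sp$nav12$gating$m), gcol(sp$nav12$gating$h),
    gcol(sp$nav12_ais$gating$m), gcol(sp$nav12_ais$gating$h),
    gcol(sp$kv$gating$n))
  list(
    parent = as.integer(ifelse(is.na(comp$parent), -1L, comp$parent - 1L)),
    area = comp$area, cm = comp$cm,
    g_axial = ifelse(is.na(comp$g_axial), 0, comp$g_axial),
    gbar12 = 1e3 * comp$gbar_nav12, gbar16 = 1e3 * comp$gbar_nav16,
    gbarkv = 1e3 * comp$gbar_kv,
    gleak_na = 1e3 * comp$g_leak_na, gleak_k = 1e3 * comp$g_leak_k,
    gleak_cl = 1e3 * comp$g_leak_cl,
    pump_imax = 1e3 * comp$pump_imax,
    km_k = cell$pump$km_k, km_na = cell$pump$km_na,
    kin12_ais = comp$kind == "ais",
    gate_params = gate_params,
    kv_exp = as.integer(sp$kv$gating$n$exponent),
    vol_in = comp$vol_in, vol_out = comp$vol_out,
    ax_in = ifelse(is.na(comp$ax_in), 0, comp$ax_in),
    ax_out = ifelse(is.na(comp$ax_out), 0, comp$ax_out),
    ds = ifelse(is.na(comp$ds), 1, comp$ds),
    D_na = cell$diffusion[["Na"]], D_k = cell$diffusion[["K"]],
    D_cl = cell$diffusion[["Cl"]],
    nernst_coef = 1e3 * gl$gas_constant * gl$temperature / gl$faraday,
    faraday = gl$faraday,
    dt = dt, theta = theta,
    ion_dynamics = ion_dynamics, diffusion_on = diffusion)
}

#' Initial (pre-equilibration) state of a cell model
#'
#' Uniform voltage at the recipe's resting potential, gating variables at
#' their steady state for that voltage, concentrations from the recipe.
#'
#' @param cell A `cell_model`.
#' @param v Initial voltage (defaults to the recipe `v_rest`).
#' @return A list with `V`, `gates` (n x 5: m12, h12, m16, h16, n) and
#'   `conc` (n x 6: na_in, na_out, k_in, k_out, cl_in, cl_out).
#' @export
init_state <- function(cell, v = NULL) {
  comp <- cell$comp
  if (is.null(v)) v <- cell$recipe$v_rest
  n <- nrow(comp)
  sp <- cell$specs
  is_ais <- comp$kind == "ais"
  m12 <- ifelse(is_ais, steady_state(sp$nav12_ais$gating$m, v),
                steady_state(sp$nav12$gating$m, v))
  h12 <- ifelse(is_ais, steady_state(sp$nav12_ais$gating$h, v),
                steady_state(sp$nav12$gating$h, v))
  gates <- cbind(m12 = m12, h12 = h12,
                 m16 = rep(steady_state(sp$nav16$gating$m, v), n),
                 h16 = rep(steady_state(sp$nav16$gating$h, v), n),
                 n = rep(steady_state(sp$kv$gating$n, v), n))
  conc <- cbind(na_in = comp$na_in, na_out = comp$na_out,
                k_in = comp$k_in, k_out = comp$k_out,
                cl_in = comp$cl_in, cl_out = comp$cl_out)
  list(V = rep(v, n), gates = gates, conc = conc)
}

#' Resolve a recording/stimulation site to a compartment index
#'
#' @param cell A `cell_model`.
#' @param site A section name (compartment nearest `pos`), or one of the
#'   shorthands `"somatic"` (middle of the soma) and `"axonal"` (first
#'   excitable node distal to the AIS, per the recipe).
#' @param pos Normalized position within the section, default 0.5.
#' @return A compartment index (1-based).
#' @export
resolve_site <- function(cell, site, pos = 0.5) {
  st <- cell$recipe$stim_sites
  if (site == "somatic") { site <- st$somatic; pos <- 0.5 }
  else if (site == "axonal") { site <- st$axonal; pos <- 0.5 }
  idx <- which(cell$comp$section == site)
  if (length(idx) == 0L) stop("unknown site: ", site)
  idx[which.min(abs(cell$comp$s_norm[idx] - pos))]
}

#' Current-clamp stimulus protocol
#'
#' @param site Stimulation site (see [resolve_site()]); `"somatic"` (middle
#'   of the soma) or `"axonal"` (the axon just distal to the AIS) select the
#'   standard injection sites.
#' @param amplitude Pulse amplitude in nA.
#' @param duration Pulse duration in ms (default 1).
#' @param onset Pulse onset in ms.
#' @param pos Normalized position within the site section (default 0.5).
#' @return An object of class `stim_protocol`.
#' @export
stimulus <- function(site, amplitude, duration = 1, onset = 1, pos = 0.5) {
  stopifnot(duration > 0, is.finite(amplitude))
  structure(list(site = site, amplitude = amplitude, duration = duration,
                 onset = onset, pos = pos), class = "stim_protocol")
}

default_record_sites <- function(cell) {
  st <- cell$recipe$stim_sites
  sites <- list(soma = c("soma", 0.5),
                ais_prox = c("ais", 0.05), ais_mid = c("ais", 0.5),
                ais_dist = c("ais", 0.95),
                axon_stim = c(st$axonal, 0.5),
                axon_distal = c(st$fp, 0.5))
  tips <- cell$sections$name[cell$sections$kind == "apical_tip"]
  for (tp in tips) sites[[tp]] <- c(tp, 1)
  sites
}

#' Simulate a cell under a current-clamp protocol
#'
#' Advances the coupled voltage/gating/concentration system with the implicit
#' cable integrator and records voltage traces.  Deterministic: identical
#' inputs give bit-identical traces.
#'
#' @param cell A `cell_model`.
#' @param state Initial state, normally the output of
#'   [run_to_steady_state()]; defaults to [init_state()].
#' @param protocol A [stimulus()] protocol, or `NULL` for no stimulus.
#' @param tstop Simulation length in ms.
#' @param record Named list of sites to record, each a `c(section, pos)`
#'   pair; defaults to soma, AIS (proximal/mid/distal), stimulation and
#'   distal axon nodes, and every apical tip terminal.
#' @param dt,theta Overrides for the global integration parameters.
#' @param ion_dynamics,diffusion Logical switches for the concentration
#'   update and longitudinal diffusion (both on by default).
#' @param record_every Store every k-th step (default 1).
#' @return An object of class `trace_set`: `time` (ms), `V` (matrix, one
#'   named column per recorded site), `vmax` (per-site maximum over every
#'   step), `first_cross_time` (per-compartment time of first upward 0 mV
#'   crossing, NA if none), `state` (final full state), and metadata.
#' @export
simulate_cell <- function(cell, state = NULL, protocol = NULL, tstop = 30,
                          record = NULL, dt = NULL, theta = NULL,
                          ion_dynamics = TRUE, diffusion = TRUE,
                          record_every = 1L) {
  stopifnot(inherits(cell, "cell_model"), tstop > 0)
  if (is.null(state)) state <- init_state(cell)
  if (is.null(record)) record <- default_record_sites(cell)
  model <- compile_model(cell, dt = dt, theta = theta,
                         ion_dynamics = ion_dynamics, diffusion = diffusion)
  rec_idx <- vapply(record, function(s)
    resolve_site(cell, s[[1]], as.numeric(s[[2]])), 1L)
  if (is.null(protocol)) {
    stim_comp <- -1L; amp <- 0; dur <- 1; onset <- 0
  } else {
    stopifnot(inherits(protocol, "stim_protocol"))
    stim_comp <- resolve_site(cell, protocol$site,
                              if (is.null(protocol$pos)) 0.5
                              else protocol$pos) - 1L
    amp <- protocol$amplitude; dur <- protocol$duration
    onset <- protocol$onset
  }
  nsteps <- max(1L, as.integer(round(tstop / model$dt)))
  control <- list(nsteps = nsteps, stim_comp = as.integer(stim_comp),
                  stim_amp = amp, stim_onset = onset, stim_dur = dur,
                  record_idx = as.integer(rec_idx - 1L),
                  record_every = as.integer(record_every))
  out <- sim_core(model, state, control)
  V <- out$V
  colnames(V) <- names(record)
  fc <- out$first_cross_step
  structure(list(
    time = out$t, V = V,
    vmax = setNames(out$vmax, names(record)),
    first_cross_time = ifelse(fc < 0, NA_real_, fc * model$dt),
    state = list(V = out$V_final, gates = out$gates_final,
                 conc = out$conc_final),
    max_dvdt = out$max_dvdt,
    protocol = protocol, dt = model$dt,
    record_idx = rec_idx),
    class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("trace_set:", length(x$time), "samples,", ncol(x$V),
      "recorded sites (dt =", x$dt, "ms)\n")
  invisible(x)
}

#' Advance the coupled state by a single time step
#'
#' One implicit voltage solve with staggered gating and concentration
#' updates, without stimulation.  Equivalent to a one-step
#' [simulate_cell()] call; useful for inspecting the integrator.
#'
#' @param cell A `cell_model`.
#' @param state A state list (see [init_state()]).
#' @param dt Step in ms (defaults to the cell's global `dt`).
#' @return The advanced state.
#' @export
step_state <- function(cell, state, dt = NULL) {
  tr <- simulate_cell(cell, state, protocol = NULL,
                      tstop = if (is.null(dt)) cell$globals$dt else dt,
                      record = list(soma = c(cell$comp$section[1], 0.5)),
                      dt = dt)
  tr$state
}

#' Equilibrate a cell model to its resting steady state
#'
#' Integrates the full model with no stimulus in chunks until the voltage is
#' stationary (`max |dV/dt| < tol`) and every ionic concentration drifts by
#' less than `conc_tol` per 100 ms.  The returned state is the initial
#' condition for all experiments.
#'
#' @param cell A `cell_model`.
#' @param tol Voltage stationarity tolerance in mV/ms (default 1e-4).
#' @param conc_tol Concentration drift tolerance in mM per 100 ms.
#' @param max_t Maximum equilibration time in ms.
#' @param chunk Chunk length in ms between convergence checks.
#' @return The equilibrated state (as [init_state()]), with attributes
#'   `v_soma` (somatic resting potential), `t_equil`, `max_dvdt` and
#'   `conc_drift`.
#' @export
run_to_steady_state <- function(cell, tol = 1e-4, conc_tol = 0.01,
                                max_t = 1000, chunk = 100) {
  state <- init_state(cell)
  soma <- resolve_site(cell, "somatic")
  t_run <- 0
  repeat {
    tr <- simulate_cell(cell, state, protocol = NULL, tstop = chunk,
                        record = list(soma = c("soma", 0.5)),
                        record_every = max(1L, as.integer(chunk /
                                                          cell$globals$dt)))
    drift <- max(abs(tr$state$conc - state$conc)) * (100 / chunk)
    state_new <- tr$state
    t_run <- t_run + chunk
    if (tr$max_dvdt < tol && drift < conc_tol) {
      state <- state_new
      break
    }
    state <- state_new
    if (t_run >= max_t)
      stop(sprintf(paste0("no steady state within %g ms: max |dV/dt| = %g ",
                          "mV/ms, concentration drift = %g mM / 100 ms"),
                   max_t, tr$max_dvdt, drift))
  }
  attr(state, "v_soma") <- state$V[soma]
  attr(state, "t_equil") <- t_run
  attr(state, "max_dvdt") <- tr$max_dvdt
  attr(state, "conc_drift") <- drift
  state
}
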