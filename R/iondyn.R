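#' Nernst reversal potential
#'
#' `E_Z = (RT / zF) ln([Z]_out / [Z]_in)` in mV.
#'
#' @param conc_in,conc_out Intra-/extracellular concentrations in mM (> 0).
#' @param z Integer valence (+1 for Na+ and K+, -1 for Cl-).
#' @param temperature Absolute temperature in kelvin.
#' @return Reversal potential(s) in mV.
#' @export
nernst <- function(conc_in, conc_out, z, temperature = 310) {
  if (any(conc_in <= 0) || any(conc_out <= 0))
    stop("concentrations must be positive")
  u <- 1e3 * .GAS_CONSTANT * temperature / (z * .FARADAY) # mV
  u * log(conc_out / conc_in)
}

#' Na+/K+ pump current
#'
#' Michaelis-Menten pump current density
#' `I_pump = I_max (1 + K_MK / [K+]_out)^-2 (1 + K_MNa / [Na+]_in)^-3`
#' (mA/cm^2).  The pump extrudes 3 Na+ and imports 2 K+ per cycle, so the
#' Na+ and K+ components of the membrane current are `+3 I_pump` and
#' `-2 I_pump`, leaving a net outward current `I_pump`.
#'
#' @param k_out Extracellular K+ in mM.
#' @param na_in Intracellular Na+ in mM.
#' @param p List with `imax` (mA/cm^2), `km_k`, `km_na` (mM).
#' @return Pump current density in mA/cm^2.
#' @export
pump_current <- function(k_out, na_in, p) {
  if (any(k_out <= 0) || any(na_in <= 0))
    stop("concentrations must be positive")
  p$imax * (1 + p$km_k / k_out)^-2 * (1 + p$km_na / na_in)^-3
}

#' Per-ion membrane current densities
#'
#' Given the local voltage, gating states, maximal conductances and ionic
#' concentrations, returns the three per-ion current densities (mA/cm^2):
#' \describe{
#'   \item{Cl}{`g_Cl (V - E_Cl)`}
#'   \item{K}{`(gbar_KV n + g_K,leak)(V - E_K) - 2 I_pump`}
#'   \item{Na}{`(gbar_12 m12^3 h12 + gbar_16 m16^3 h16 + g_Na,leak)(V - E_Na)
#'     + 3 I_pump`}
#' }
#' Nernst potentials are computed from the supplied concentrations.
#'
#' @param V Membrane potential in mV.
#' @param gates Named list/vector with `m12`, `h12`, `m16`, `h16`, `n` in
#'   `[0, 1]`.
#' @param gbars Named list/vector with `nav12`, `nav16`, `kv`, `leak_na`,
#'   `leak_k`, `leak_cl` in S/cm^2.
#' @param ions Named list/vector with `na_in`, `na_out`, `k_in`, `k_out`,
#'   `cl_in`, `cl_out` in mM.
#' @param pump List with `imax`, `km_k`, `km_na` (see [pump_current()]).
#' @param temperature Kelvin.
#' @return A list with `I_na`, `I_k`, `I_cl` and `I_total` (mA/cm^2).
#' @export
membrane_currents <- function(V, gates, gbars, ions, pump,
                              temperature = 310) {
  gates <- as.list(gates); gbars <- as.list(gbars); ions <- as.list(ions)
  stopifnot(all(unlist(gates) >= 0), all(unlist(gates) <= 1))
  e_na <- nernst(ions$na_in, ions$na_out, 1, temperature)
  e_k <- nernst(ions$k_in, ions$k_out, 1, temperature)
  e_cl <- nernst(ions$cl_in, ions$cl_out, -1, temperature)
  ip <- pump_current(ions$k_out, ions$na_in, pump)
  g_na <- gbars$nav12 * gates$m12^3 * gates$h12 +
    gbars$nav16 * gates$m16^3 * gates$h16 + gbars$leak_na
  g_k <- gbars$kv * gates$n + gbars$leak_k
  i_na <- g_na * (V - e_na) + 3 * ip
  i_k <- g_k * (V - e_k) - 2 * ip
  i_cl <- gbars$leak_cl * (V - e_cl)
  list(I_na = i_na, I_k = i_k, I_cl = i_cl, I_total = i_na + i_k + i_cl)
}

#' Update ionic concentrations from fluxes and longitudinal diffusion
#'
#' Reference implementation of one concentration step on a compartmentalized
#' tree: the transmembrane flux term moves ions between the intracellular and
#' extracellular pools of each compartment (scaled by the respective
#' volumes), and a discrete Laplacian along the tree applies Fick diffusion
#' within each pool.  Terminal compartments are sealed (zero-flux).  With
#' zero currents and uniform concentrations the state is a fixed point, and
#' pure diffusion conserves total moles per pool to round-off.
#'
#' @param conc_in,conc_out Concentration vectors (mM), one entry per
#'   compartment.
#' @param current Per-compartment transmembrane current density of this ion,
#'   mA/cm^2 (positive outward).
#' @param geom List with per-compartment `area` (cm^2), `vol_in`, `vol_out`
#'   (um^3), `parent` (integer index or NA for the root), `ax_in`, `ax_out`
#'   (um^2 cross-sections toward the parent) and `ds` (um center-to-center
#'   distance).
#' @param D Diffusion coefficient in um^2/ms.
#' @param dt Time step in ms.
#' @return List with updated `conc_in` and `conc_out`.
#' @export
update_concentrations <- function(conc_in, conc_out, current, geom, D, dt) {
  stopifnot(dt > 0)
  # dC_in (mM/ms) = -1e4 * area_um2 * I(mA/cm^2) / (F * vol_um3)
  area_um2 <- geom$area * 1e8
  dcin <- -1e4 * area_um2 * current / (.FARADAY * geom$vol_in)
  dcout <- 1e4 * area_um2 * current / (.FARADAY * geom$vol_out)
  lap <- function(conc, ax, vol) {
    d <- numeric(length(conc))
    for (j in seq_along(conc)) {
      p <- geom$parent[j]
      if (is.na(p)) next
      f <- D * ax[j] / geom$ds[j] * (conc[p] - conc[j]) # mM um^3 / ms
      d[j] <- d[j] + f / vol[j]
      d[p] <- d[p] - f / vol[p]
    }
    d
  }
  new_in <- conc_in + dt * (dcin + lap(conc_in, geom$ax_in, geom$vol_in))
  new_out <- conc_out + dt * (dcout + lap(conc_out, geom$ax_out, geom$vol_out))
  if (any(new_in <= 0) || any(new_out <= 0))
    stop("concentration driven non-positive; reduce dt")
  list(conc_in = new_in, conc_out = new_out)
}
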