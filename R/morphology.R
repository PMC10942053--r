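#' Discretize a section tree into compartments
#'
#' Splits every section into `nseg` cylindrical compartments (taper is
#' linearly interpolated at compartment centers), computes membrane areas,
#' intra-/extracellular volumes, and the axial conductance between adjacent
#' compartment centers from the axial resistivity `ra` and the local
#' diameters.  Sections with `nseg = NA` get `ceiling(length / max_seg_len)`
#' segments, except the AIS which uses the finer `ais_seg_len` rule.
#'
#' @param sections Section table (see [default_recipe()]); parents must be
#'   listed before children.
#' @param globals A [global_params()] object.
#' @param ra Axial resistivity in ohm cm.
#' @param cm Named vector of specific capacitance per section kind with a
#'   `default` entry (uF/cm^2).
#' @param shell_frac Extracellular (periaxonal/annular) shell volume as a
#'   fraction of the intracellular volume.
#' @param ais_seg_len Maximum AIS segment length in um.
#' @return A compartment data frame (one row per compartment).
#' @export
discretize <- function(sections, globals = global_params(), ra = 150,
                       cm = c(default = 1), shell_frac = 0.15,
                       ais_seg_len = 2.5) {
  validate_sections(sections)
  n_sec <- nrow(sections)
  first_idx <- integer(n_sec)   # compartment index of first segment
  names(first_idx) <- sections$name
  rows <- vector("list", n_sec)
  n_comp <- 0L
  for (i in seq_len(n_sec)) {
    s <- sections[i, ]
    nseg <- s$nseg
    if (is.na(nseg)) {
      rule <- if (s$kind == "ais") ais_seg_len else globals$max_seg_len
      nseg <- max(1L, ceiling(s$length / rule))
    }
    nseg <- as.integer(nseg)
    centers <- (seq_len(nseg) - 0.5) / nseg
    diam <- s$diam0 + (s$diam1 - s$diam0) * centers
    len <- s$length / nseg
    cmk <- if (s$kind %in% names(cm)) cm[[s$kind]] else cm[["default"]]
    # parent compartment of the section's first segment
    if (is.na(s$parent)) {
      par_first <- NA_integer_
    } else {
      pi_ <- which(sections$name == s$parent)
      p_nseg <- nrow(rows[[pi_]])
      seg <- min(p_nseg, max(1L, ceiling(s$attach * p_nseg)))
      par_first <- first_idx[[s$parent]] + seg - 1L
    }
    parent <- c(par_first, n_comp + seq_len(nseg - 1L))
    rows[[i]] <- data.frame(
      id = n_comp + seq_len(nseg),
      section = s$name, kind = s$kind,
      s_norm = centers, length = len, diam = diam,
      cm = cmk, parent = parent, stringsAsFactors = FALSE)
    first_idx[i] <- n_comp + 1L
    n_comp <- n_comp + nseg
  }
  comp <- do.call(rbind, rows)
  rownames(comp) <- NULL
  # geometry: membrane area (cm^2), volumes (um^3)
  comp$area <- pi * comp$diam * comp$length * 1e-8
  comp$vol_in <- pi * comp$diam^2 / 4 * comp$length
  comp$vol_out <- shell_frac * comp$vol_in
  # axial conductance (siemens) between each compartment and its parent:
  # series of the two half-compartment resistances
  rhalf <- ra * (comp$length * 1e-4 / 2) / (pi * (comp$diam * 1e-4)^2 / 4)
  g <- rep(NA_real_, n_comp)
  has_par <- !is.na(comp$parent)
  g[has_par] <- 1 / (rhalf[has_par] + rhalf[comp$parent[has_par]])
  comp$g_axial <- g
  # diffusion geometry between compartment centers
  ax_in <- rep(NA_real_, n_comp)
  xs <- pi * comp$diam^2 / 4
  ax_in[has_par] <- (xs[has_par] + xs[comp$parent[has_par]]) / 2
  comp$ax_in <- ax_in
  comp$ax_out <- shell_frac * ax_in
  ds <- rep(NA_real_, n_comp)
  ds[has_par] <- (comp$length[has_par] + comp$length[comp$parent[has_par]]) / 2
  comp$ds <- ds
  comp
}

validate_sections <- function(sections) {
  req <- c("name", "kind", "length", "diam0", "diam1", "parent", "attach")
  if (!all(req %in% names(sections)))
    stop("section table is missing columns: ",
         paste(setdiff(req, names(sections)), collapse = ", "))
  if (anyDuplicated(sections$name))
    stop("duplicate section names")
  if (any(sections$length <= 0) || any(sections$diam0 <= 0) ||
      any(sections$diam1 <= 0))
    stop("section lengths and diameters must be positive")
  roots <- which(is.na(sections$parent))
  if (length(roots) != 1L)
    stop("the section graph must have exactly one root")
  for (i in seq_len(nrow(sections))) {
    p <- sections$parent[i]
    if (is.na(p)) next
    j <- which(sections$name == p)
    if (length(j) == 0L)
      stop("section '", sections$name[i], "' has unknown parent '", p, "'")
    if (j >= i)
      stop("section '", sections$name[i],
           "' must be listed after its parent (tree order)")
    a <- sections$attach[i]
    if (is.na(a) || a < 0 || a > 1)
      stop("attach position of '", sections$name[i], "' must lie in [0, 1]")
  }
  invisible(TRUE)
}

#' Build the reduced pyramidal cell model from a recipe
#'
#' Assembles the full model: discretized morphology, per-compartment channel
#' densities (with the recipe's NaV profile written onto the AIS), ionic
#' concentrations, pump parameters, and leak conductances balanced so that
#' the uniform state `V = v_rest` with stationary concentrations is an exact
#' steady state of the coupled voltage/ion system (see the methods
#' vignette).  Chloride concentrations are chosen so `E_Cl = v_rest`, and the
#' per-compartment Na+ and K+ leaks absorb the resting pump flux.
#'
#' @param recipe An [default_recipe()] object.
#' @param globals A [global_params()] object.
#' @return An object of class `cell_model`.
#' @export
build_reduced_pyramidal <- function(recipe = default_recipe(),
                                    globals = global_params()) {
  stopifnot(inherits(recipe, "ais_recipe"), inherits(globals, "ais_globals"))
  assemble_cell(recipe$sections, recipe, globals)
}

# Shared assembly path: discretize a section table and attach densities,
# concentrations, pump and balanced leaks from the recipe.  Used by both the
# reduced-morphology builder and the SWC reader.
assemble_cell <- function(sections, recipe, globals) {
  comp <- discretize(sections, globals, ra = recipe$ra,
                     cm = recipe$cm, shell_frac = recipe$shell_frac,
                     ais_seg_len = recipe$ais_seg_len)
  # channel densities by section kind
  dmap <- recipe$densities
  unknown <- setdiff(unique(comp$kind), names(dmap))
  if (length(unknown))
    stop("no channel densities for section kind(s): ",
         paste(unknown, collapse = ", "))
  getd <- function(kind, ch) vapply(kind, function(k) dmap[[k]][[ch]], 0)
  comp$gbar_nav12 <- unname(getd(comp$kind, "nav12"))
  comp$gbar_nav16 <- unname(getd(comp$kind, "nav16"))
  comp$gbar_kv <- unname(getd(comp$kind, "kv"))
  g_cl <- recipe$g_leak_cl
  comp$g_leak_cl <- ifelse(comp$kind %in% names(g_cl),
                           unname(g_cl[comp$kind]), g_cl[["default"]])
  # concentrations (uniform; chloride pinned to E_Cl = v_rest)
  cc <- recipe$concentrations
  u <- 1e3 * globals$gas_constant * globals$temperature / globals$faraday # mV
  cl_in <- cc[["cl_out"]] * exp(recipe$v_rest / u)
  comp$na_in <- cc[["na_in"]]; comp$na_out <- cc[["na_out"]]
  comp$k_in <- cc[["k_in"]]; comp$k_out <- cc[["k_out"]]
  comp$cl_in <- cl_in; comp$cl_out <- cc[["cl_out"]]
  # pump density
  comp$pump_imax <- ifelse(comp$kind %in% recipe$pump$kinds_off,
                           0, recipe$pump$imax)
  cell <- structure(
    list(sections = sections, comp = comp,
         specs = make_channel_specs(recipe$kinetics),
         diffusion = recipe$diffusion,
         pump = recipe$pump[c("imax", "km_k", "km_na")],
         globals = globals, recipe = recipe, profile = NULL),
    class = "cell_model")
  cell$specs$nav12_ais <- cell$specs$nav12
  if (any(comp$kind == "ais"))
    cell <- apply_profile(cell, nav_profile(
      gbar_total = recipe$profile$gbar_total, x = recipe$profile$x,
      kappa = recipe$profile$kappa, sigma = recipe$profile$sigma))
  balance_leaks(cell)
}

# Solve the per-compartment Na+/K+ leak conductances and pump density so
# that every per-ion transmembrane flux vanishes at V = v_rest.  The pump's
# 3:2 Na/K stoichiometry is absorbed by the leaks; where the resting
# voltage-gated K+ current exceeds the K+ influx of the recipe's baseline
# pump density (high-KV membrane: AIS, nodes, soma), the local pump density
# is scaled up instead, mirroring the colocalization of Na+/K+-ATPase with
# excitable membrane.  With E_Cl = v_rest this makes the uniform rest state
# an exact fixed point of the coupled voltage/concentration system.
balance_leaks <- function(cell) {
  comp <- cell$comp
  v <- cell$recipe$v_rest
  Tk <- cell$globals$temperature
  e_na <- nernst(comp$na_in, comp$na_out, 1, Tk)
  e_k <- nernst(comp$k_in, comp$k_out, 1, Tk)
  sp <- cell$specs
  rest_g <- function(spec, gbar) {
    g <- gbar
    for (gv in spec$gating) g <- g * steady_state(gv, v)^gv$exponent
    g
  }
  is_ais <- comp$kind == "ais"
  g12 <- ifelse(is_ais, rest_g(sp$nav12_ais, comp$gbar_nav12),
                rest_g(sp$nav12, comp$gbar_nav12))
  g16 <- rest_g(sp$nav16, comp$gbar_nav16)
  gkv <- rest_g(sp$kv, comp$gbar_kv)
  # resting pump occupancy factor (independent of the maximal density)
  occ <- pump_current(comp$k_out, comp$na_in,
                      list(imax = 1, km_k = cell$pump$km_k,
                           km_na = cell$pump$km_na))
  base_on <- comp$pump_imax > 0
  ip_base <- comp$pump_imax * occ
  ip_need <- gkv * (v - e_k) / 2          # K+ balance with zero K+ leak
  ip <- pmax(ip_base, ifelse(base_on, ip_need, 0))
  cell$comp$pump_imax <- ifelse(occ > 0, ip / occ, 0)
  g_na <- 3 * ip / (e_na - v) - (g12 + g16)
  g_k <- 2 * ip / (v - e_k) - gkv
  if (any(g_na < -1e-12))
    warning("resting NaV conductance exceeds the pump-balanced Na+ leak; ",
            "resting potential will deviate from v_rest")
  cell$comp$g_leak_na <- pmax(g_na, 0)
  cell$comp$g_leak_k <- pmax(g_k, 0)
  cell
}

#' @export
print.cell_model <- function(x, ...) {
  cat("cell_model:", nrow(x$sections), "sections,", nrow(x$comp),
      "compartments\n")
  if (!is.null(x$profile))
    cat(sprintf("  AIS profile: x = %g, kappa = %g, sigma = %g, alpha = %g%s\n",
                x$profile$x, x$profile$kappa, x$profile$sigma,
                x$profile$alpha, if (x$profile$flipped) " (flipped)" else ""))
  invisible(x)
}

#' Summary table of a cell model
#'
#' One row per section: kind, length, number of compartments, total membrane
#' area.
#' @param object A `cell_model`.
#' @param ... Unused.
#' @return A data frame.
#' @export
summary.cell_model <- function(object, ...) {
  comp <- object$comp
  agg <- do.call(rbind, lapply(split(comp, comp$section), function(d)
    data.frame(section = d$section[1], kind = d$kind[1],
               length = sum(d$length), n_comp = nrow(d),
               area_cm2 = sum(d$area))))
  agg[match(object$sections$name, agg$section), , drop = FALSE]
}

#' Apply a shift-clamp condition to the AIS NaV1.2 channels of a cell
#'
#' Replaces the kinetics used by NaV1.2 channels in the AIS (only) with the
#' shift-clamped version; NaV1.2 channels elsewhere keep the nominal
#' right-shift.  Leak balancing is rerun because the resting NaV1.2
#' conductance changes (minutely) with the shift.
#'
#' @param cell A `cell_model`.
#' @inheritParams shift_clamp
#' @return The modified cell.
#' @export
apply_shift_clamp <- function(cell, condition, dVrs) {
  stopifnot(inherits(cell, "cell_model"))
  cell$specs$nav12_ais <- shift_clamp(cell$specs$nav12, condition, dVrs)
  balance_leaks(cell)
}
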