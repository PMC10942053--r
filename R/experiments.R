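#' Sweep the backpropagation threshold over the (x, kappa) grid
#'
#' For every combination of separation `x` and crossover `kappa`, writes the
#' density profile onto the AIS and finds the threshold current by bisection.
#' Rows whose threshold exceeds the stimulation cap are recorded with
#' `capped = TRUE`, not dropped.  All rows at `x = 0` agree across `kappa`
#' within the bisection tolerance, since the crossover has no effect on a
#' flat distribution.
#'
#' @param cell A `cell_model`.
#' @param site `"somatic"` or `"axonal"`.
#' @param x_grid,kappa_grid Parameter grids (defaults: x in 0, 0.25, ..., 1;
#'   kappa in 0.1, ..., 0.9).
#' @param flipped Use the longitudinally flipped (backward-AIS) profile.
#' @param detector `"bap"` or `"fp"`.
#' @param state Equilibrated state; computed once from the cell if omitted.
#' @param crit A [propagation_criterion()].
#' @param seed_amp Initial bisection amplitude in nA.
#' @param rel_tol Bisection tolerance.
#' @return A data frame with one row per grid point: `site`, `x`, `kappa`,
#'   `flipped`, `amplitude` (nA, NA if capped), `converged`, `capped`.
#' @export
sweep_xk <- function(cell, site = "somatic",
                     x_grid = c(0, 0.25, 0.5, 0.75, 1),
                     kappa_grid = seq(0.1, 0.9, by = 0.1),
                     flipped = FALSE, detector = "bap", state = NULL,
                     crit = propagation_criterion(), seed_amp = 1,
                     rel_tol = 0.01) {
  stopifnot(length(x_grid) > 0, length(kappa_grid) > 0)
  if (is.null(state)) state <- run_to_steady_state(cell)
  gbar <- cell$recipe$profile$gbar_total
  sigma <- cell$recipe$profile$sigma
  grid <- expand.grid(x = x_grid, kappa = kappa_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- nav_profile(gbar, x = grid$x[i], kappa = grid$kappa[i],
                     sigma = sigma, flipped = flipped)
    th <- find_threshold(apply_profile(cell, p), state, site, detector,
                         crit = crit, seed = seed_amp, rel_tol = rel_tol)
    data.frame(site = site, x = grid$x[i], kappa = grid$kappa[i],
               flipped = flipped, amplitude = th$amplitude,
               converged = th$converged, capped = th$capped)
  })
  do.call(rbind, rows)
}

#' Flipped-AIS (backward) sweep with slope-sign comparison
#'
#' Repeats [sweep_xk()] with the profile mirrored along the AIS and reports,
#' per kappa, the sign of the threshold-versus-x slope for the flipped and
#' unflipped sweeps.  Flipping reverses the somatic slope signs.
#'
#' @inheritParams sweep_xk
#' @return A list with `flipped` and `unflipped` sweep tables and a `slopes`
#'   data frame (`kappa`, `slope_unflipped`, `slope_flipped`).
#' @export
flipped_ais_experiment <- function(cell, site = "somatic",
                                   x_grid = c(0, 0.5, 1),
                                   kappa_grid = c(0.2, 0.7), state = NULL,
                                   ...) {
  if (is.null(state)) state <- run_to_steady_state(cell)
  unf <- sweep_xk(cell, site, x_grid, kappa_grid, flipped = FALSE,
                  state = state, ...)
  flp <- sweep_xk(cell, site, x_grid, kappa_grid, flipped = TRUE,
                  state = state, ...)
  slope_of <- function(tab, k) {
    d <- tab[tab$kappa == k & !tab$capped, ]
    if (nrow(d) < 2) return(NA_real_)
    unname(coef(lm(amplitude ~ x, d))[2])
  }
  slopes <- data.frame(
    kappa = kappa_grid,
    slope_unflipped = vapply(kappa_grid, function(k) slope_of(unf, k), 1),
    slope_flipped = vapply(kappa_grid, function(k) slope_of(flp, k), 1))
  list(unflipped = unf, flipped = flp, slopes = slopes)
}

#' Shift-clamp sensitivity sweep of the backpropagation threshold
#'
#' For each shift-clamp condition, displaces the right-shift of the selected
#' NaV1.2 gating properties in the AIS by each `dvrs` value and recomputes
#' the backpropagation threshold.  All condition curves coincide at
#' `dvrs = 0` (the nominal point) by construction.  The profile is fixed at
#' `x = 1` with a site-specific crossover (0.7 somatic, 0.5 axonal).
#'
#' @param cell A `cell_model`.
#' @param site `"somatic"` or `"axonal"`.
#' @param conditions Character vector of [shift_conditions()].
#' @param dvrs_grid Shift increments in mV.  The default grid is matched to
#'   each mode's sensitivity: +/- 1 mV for axonal stimulation (where
#'   thresholds move by nA per mV and larger shifts hit the 10 nA cap) and
#'   +/- 3 mV for somatic (where threshold changes per mV are tiny).
#' @param kappa Crossover; defaults to 0.7 for somatic, 0.5 for axonal.
#' @param crit,seed_amp,rel_tol Passed to [find_threshold()]; the tight
#'   default tolerance resolves the small somatic slopes.
#' @return A data frame with one row per (condition, dvrs): `amplitude`,
#'   `converged`, `capped`.
#' @export
sweep_shift_clamp <- function(cell, site = "somatic",
                              conditions = shift_conditions(),
                              dvrs_grid = NULL, kappa = NULL,
                              crit = propagation_criterion(), seed_amp = 1,
                              rel_tol = 5e-4) {
  stopifnot(all(conditions %in% shift_conditions()))
  if (is.null(dvrs_grid))
    dvrs_grid <- if (identical(site, "axonal")) c(-1, 0, 1) else c(-3, 0, 3)
  if (is.null(kappa)) kappa <- if (identical(site, "axonal")) 0.5 else 0.7
  gbar <- cell$recipe$profile$gbar_total
  base <- apply_profile(cell, nav_profile(gbar, x = 1, kappa = kappa,
                                          sigma = cell$recipe$profile$sigma))
  rows <- list()
  for (cond in conditions) {
    for (dv in dvrs_grid) {
      cl <- apply_shift_clamp(base, cond, dv)
      st <- run_to_steady_state(cl, max_t = 400)
      th <- find_threshold(cl, st, site, "bap", crit = crit,
                           seed = seed_amp, rel_tol = rel_tol)
      rows[[length(rows) + 1L]] <-
        data.frame(site = site, condition = cond, dvrs = dv,
                   amplitude = th$amplitude, converged = th$converged,
                   capped = th$capped)
    }
  }
  do.call(rbind, rows)
}

#' Slope-sign pattern of a shift-clamp sweep
#'
#' Least-squares slope of threshold versus shift for each condition, using
#' the grid points nearest 0, classified as `"up"`, `"down"`, or `"x"`
#' (negligible) when the relative slope magnitude falls below
#' `negligible_band` (fraction of the nominal threshold per mV).
#'
#' @param sweep Output of [sweep_shift_clamp()].
#' @param negligible_band Relative-slope threshold for "x" (default 1e-4
#'   per mV, i.e. 0.01% of the nominal threshold per mV of shift).
#' @return A data frame: `site`, `condition`, `slope`, `rel_slope`, `sign`.
#' @export
sign_pattern <- function(sweep, negligible_band = 1e-4) {
  out <- lapply(split(sweep, list(sweep$site, sweep$condition), drop = TRUE),
    function(d) {
      d <- d[!d$capped & d$converged, ]
      if (nrow(d) < 2)
        return(data.frame(site = d$site[1], condition = d$condition[1],
                          slope = NA_real_, rel_slope = NA_real_,
                          sign = NA_character_))
      d <- d[order(abs(d$dvrs)), ][seq_len(min(3, nrow(d))), ]
      sl <- unname(coef(lm(amplitude ~ dvrs, d))[2])
      i0 <- d$amplitude[which.min(abs(d$dvrs))]
      rs <- sl / i0
      data.frame(site = d$site[1], condition = d$condition[1], slope = sl,
                 rel_slope = rs,
                 sign = if (abs(rs) < negligible_band) "x"
                        else if (rs > 0) "up" else "down")
    })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Reference slope-sign matrix for the shift-clamp sensitivity analysis
#'
#' The expected sign of the threshold slope for each (site, condition) cell:
#' with axonal stimulation, right-shifting any availability property lowers
#' the threshold and right-shifting activation raises it; with somatic
#' stimulation, activation dominates, availability shifts have a slight
#' lowering effect, and the time-constant-only shifts are negligible.
#'
#' @return A data frame: `site`, `condition`, `expected`.
#' @export
reference_sign_pattern <- function() {
  conds <- shift_conditions()
  rbind(
    data.frame(site = "axonal", condition = conds,
               expected = c("down", "down", "down", "down",
                            "up", "up", "up")),
    data.frame(site = "somatic", condition = conds,
               expected = c("up", "x", "down", "down", "x", "up", "up")))
}

#' Compare an observed sign pattern to the reference matrix
#'
#' @param pattern Output of [sign_pattern()] (one or both sites).
#' @param reference Expected matrix, default [reference_sign_pattern()].
#' @return The pattern joined with `expected` and a logical `match` column;
#'   slight-but-consistent slopes count as matches of their arrow.
#' @export
table1_report <- function(pattern, reference = reference_sign_pattern()) {
  m <- merge(pattern, reference, by = c("site", "condition"), sort = FALSE)
  m$match <- m$sign == m$expected
  m[order(m$site, match(m$condition, shift_conditions())), ]
}

#' Sweep the NaV1.2 scaling factor alpha
#'
#' Rescales the AIS NaV1.2 density profile by each `alpha` (leaving NaV1.6
#' intact, `x = 1`) and recomputes the backpropagation threshold.  With
#' somatic stimulation the threshold stays finite down to `alpha = 0`; with
#' axonal stimulation backpropagation fails below a cutoff alpha (capped
#' rows), and the threshold is nearly flat above it.
#'
#' @inheritParams sweep_shift_clamp
#' @param alpha_grid Scaling factors; include 0 and 1.
#' @return A data frame with one row per alpha, plus (for axonal sweeps) the
#'   attribute `cutoff_alpha`: the largest alpha with no backpropagation
#'   under the cap.
#' @export
sweep_alpha <- function(cell, site = "somatic",
                        alpha_grid = c(0, 0.1, 0.2, 0.3, 0.4, 0.6, 1, 1.5, 2),
                        kappa = 0.5, crit = propagation_criterion(),
                        seed_amp = 1, rel_tol = 0.01) {
  gbar <- cell$recipe$profile$gbar_total
  state <- run_to_steady_state(cell)
  rows <- lapply(alpha_grid, function(a) {
    p <- nav_profile(gbar, x = 1, kappa = kappa,
                     sigma = cell$recipe$profile$sigma, alpha = a)
    th <- find_threshold(apply_profile(cell, p), state, site, "bap",
                         crit = crit, seed = seed_amp, rel_tol = rel_tol)
    data.frame(site = site, alpha = a, amplitude = th$amplitude,
               converged = th$converged, capped = th$capped)
  })
  tab <- do.call(rbind, rows)
  capped <- tab$alpha[tab$capped]
  attr(tab, "cutoff_alpha") <- if (length(capped)) max(capped) else NA_real_
  tab
}

#' Maximum relative threshold change across a sweep
#'
#' `100 * (max - min) / min` over the converged rows of a threshold table —
#' the summary used to quantify how strongly the NaV distribution modulates
#' the backpropagation threshold.
#'
#' @param sweep A threshold table from [sweep_xk()].
#' @return Percentage (scalar).
#' @export
relative_threshold_range <- function(sweep) {
  a <- sweep$amplitude[sweep$converged & !sweep$capped]
  if (length(a) == 0L) return(NA_real_)
  100 * (max(a) - min(a)) / min(a)
}
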