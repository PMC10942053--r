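#' Parameterised NaV1.2 / NaV1.6 density profile along the AIS
#'
#' The two subtypes share a constant total maximal conductance
#' `gbar_total` along the AIS.  With `s` the normalized position (0 proximal,
#' 1 distal), the split is
#' \deqn{\bar g_{1.2}(s) = \alpha \frac{\bar g}{2}\,(1 - x \tanh(\sigma (s - \kappa))),}
#' \deqn{\bar g_{1.6}(s) = \frac{\bar g}{2}\,(1 + x \tanh(\sigma (s - \kappa))).}
#' `x = 0` gives the flat (uniformly mixed) distribution; `x = 1` fully
#' separates the subtypes with NaV1.2 proximal and NaV1.6 distal.  `kappa` is
#' the crossover position where the NaV1.6 density overtakes NaV1.2, `sigma`
#' the reciprocal of the normalized transition width, `alpha` a uniform
#' rescaling of the NaV1.2 profile only, and `flipped = TRUE` mirrors both
#' profiles along the AIS (`s -> 1 - s`), putting the AIS on "backward".
#'
#' @param gbar_total Total NaV maximal conductance in S/cm^2.
#' @param x Separation in `[0, 1]`.
#' @param kappa Crossover position in `[0, 1]`.
#' @param sigma Steepness (> 0), default 10.
#' @param alpha NaV1.2 scaling factor (>= 0), default 1.
#' @param flipped Mirror the profile along the AIS.
#' @return An object of class `nav_profile`.
#' @export
nav_profile <- function(gbar_total, x = 1, kappa = 0.5, sigma = 10,
                        alpha = 1, flipped = FALSE) {
  stopifnot(gbar_total >= 0, x >= 0, x <= 1, kappa >= 0, kappa <= 1,
            sigma > 0, alpha >= 0, is.logical(flipped))
  structure(list(gbar_total = gbar_total, x = x, kappa = kappa,
                 sigma = sigma, alpha = alpha, flipped = flipped),
            class = "nav_profile")
}

#' @export
print.nav_profile <- function(x, ...) {
  cat(sprintf(
    "NaV density profile: gbar = %g S/cm^2, x = %g, kappa = %g, sigma = %g, alpha = %g%s\n",
    x$gbar_total, x$x, x$kappa, x$sigma, x$alpha,
    if (x$flipped) ", flipped" else ""))
  invisible(x)
}

#' Evaluate the NaV subtype densities at normalized AIS positions
#'
#' @param s Normalized position(s) in `[0, 1]`.
#' @param p A [nav_profile()].
#' @return A list with numeric vectors `gbar12` and `gbar16` (S/cm^2).
#' @export
density_at <- function(s, p) {
  stopifnot(inherits(p, "nav_profile"))
  if (any(s < 0 | s > 1)) stop("normalized AIS position s must lie in [0, 1]")
  if (p$flipped) s <- 1 - s
  t <- tanh(p$sigma * (s - p$kappa))
  list(gbar12 = p$alpha * p$gbar_total / 2 * (1 - p$x * t),
       gbar16 = p$gbar_total / 2 * (1 + p$x * t))
}

#' Write a density profile onto the AIS compartments of a cell
#'
#' Sets the NaV1.2 and NaV1.6 maximal conductances of every AIS compartment
#' from [density_at()] evaluated at the compartment's normalized center; all
#' other compartments are untouched.  With `alpha = 1` the per-compartment
#' sum equals `gbar_total` exactly.
#'
#' @param cell A `cell_model` (see [build_reduced_pyramidal()]).
#' @param p A [nav_profile()].
#' @return The modified cell, with the profile stored in `cell$profile`.
#' @export
apply_profile <- function(cell, p) {
  stopifnot(inherits(cell, "cell_model"), inherits(p, "nav_profile"))
  idx <- which(cell$comp$kind == "ais")
  if (length(idx) == 0L) stop("cell has no AIS section")
  g <- density_at(cell$comp$s_norm[idx], p)
  cell$comp$gbar_nav12[idx] <- g$gbar12
  cell$comp$gbar_nav16[idx] <- g$gbar16
  cell$profile <- p
  cell
}

#' Rescale the NaV1.2 density in the AIS by a uniform factor
#'
#' Multiplies every AIS compartment's NaV1.2 maximal conductance by `alpha`,
#' leaving NaV1.6 untouched (no compensation for removed channels).
#'
#' @param cell A `cell_model` with a profile already applied.
#' @param alpha Non-negative scaling factor.
#' @return The modified cell.
#' @export
scale_nav12 <- function(cell, alpha) {
  stopifnot(inherits(cell, "cell_model"))
  if (alpha < 0) stop("alpha must be non-negative")
  idx <- which(cell$comp$kind == "ais")
  if (length(idx) == 0L) stop("cell has no AIS section")
  cell$comp$gbar_nav12[idx] <- alpha * cell$comp$gbar_nav12[idx]
  cell
}
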