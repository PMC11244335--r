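# Unit conventions, centralized:
#   lengths  : micrometres (um)
#   viscosity: millipascal-seconds (mPa.s)
#   volume   : microlitres (uL); 1 uL = 1e9 um^3
#   pressure : pascal (Pa)
#   resistance: Pa.s/uL (12*mu*L / ((1-0.63 a/b) a^3 b) is mPa.s/um^3;
#               multiply by 1e6 to get Pa.s/uL)
.RES_MPAS_UM3_TO_PAS_UL <- 1e6
.UL_PER_UM3 <- 1e-9

#' Rectangular microchannel geometry
#'
#' A channel is described by its cross-sectional width `width` and height
#' `height` and its axial `length`, all in micrometres. The aspect ratio
#' AR = height/width controls how the channel's hydraulic resistance responds
#' to a uniaxial strain applied orthogonally to the channel axis: high-AR
#' (AR > 1) channels become less resistive under tension, low-AR (AR < 1)
#' channels more resistive.
#'
#' @param width Channel width in um (> 0), measured along the strain axis.
#' @param height Channel height in um (> 0).
#' @param length Channel length in um (> 0). Defaults to 1 so that
#'   length-normalized resistances can be formed without a fluid.
#'
#' @return An object of class `samp_channel` with fields `width`, `height`,
#'   `length` (um).
#' @seealso [aspect_ratio()], [deform()], [hydraulic_resistance()]
#' @export
#' @examples
#' ch <- channel(width = 200, height = 600, length = 5000)
#' aspect_ratio(ch)
channel <- function(width, height, length = 1) {
  stopifnot(is.numeric(width), is.numeric(height), is.numeric(length),
            length(width) == 1, length(height) == 1, length(length) == 1)
  if (!is.finite(width) || width <= 0) stop("`width` must be a positive finite number (um)")
  if (!is.finite(height) || height <= 0) stop("`height` must be a positive finite number (um)")
  if (!is.finite(length) || length <= 0) stop("`length` must be a positive finite number (um)")
  structure(list(width = width, height = height, length = length),
            class = "samp_channel")
}

#' @export
print.samp_channel <- function(x, ...) {
  cat(sprintf("<samp_channel> %g x %g um cross-section, L = %g um (AR = %.4g)\n",
              x$width, x$height, x$length, aspect_ratio(x)))
  invisible(x)
}

#' Aspect ratio of a channel
#'
#' @param geometry A [channel()].
#' @return AR = height/width (dimensionless).
#' @export
aspect_ratio <- function(geometry) {
  stopifnot(inherits(geometry, "samp_channel"))
  geometry$height / geometry$width
}

#' Working-fluid properties
#'
#' @param viscosity Dynamic viscosity in mPa.s. Default 28, the viscosity of
#'   the ionic working liquid used in the reference device.
#' @param poisson Poisson's ratio of the elastomer (0 to 0.5). Default 0.5
#'   (incompressible PDMS).
#' @return An object of class `samp_fluid`.
#' @export
fluid <- function(viscosity = 28, poisson = 0.5) {
  stopifnot(is.numeric(viscosity), length(viscosity) == 1,
            is.numeric(poisson), length(poisson) == 1)
  if (!is.finite(viscosity) || viscosity <= 0) stop("`viscosity` must be positive (mPa.s)")
  if (!is.finite(poisson) || poisson < 0 || poisson > 0.5) stop("`poisson` must lie in [0, 0.5]")
  structure(list(viscosity = viscosity, poisson = poisson), class = "samp_fluid")
}

#' @export
print.samp_fluid <- function(x, ...) {
  cat(sprintf("<samp_fluid> viscosity %g mPa.s, Poisson ratio %g\n",
              x$viscosity, x$poisson))
  invisible(x)
}

# Aspect-ratio scale factor gamma = (1 - nu*eps) / (1 + eps), so that the
# deformed aspect ratio is AR' = gamma * AR. Vectorized over eps.
strain_gamma <- function(strain, poisson = 0.5) {
  (1 - poisson * strain) / (1 + strain)
}

#' Deform a channel cross-section under orthogonal uniaxial strain
#'
#' An engineering strain applied orthogonally to the channel axis widens the
#' cross-section along the strain axis and thins it through the elastomer's
#' Poisson contraction: w' = w(1 + eps), h' = h(1 - nu*eps). The channel
#' length is unchanged (the strain axis is orthogonal to the channel
#' elongation). The deformed aspect ratio is AR' = gamma*AR with
#' gamma = (1 - nu*eps)/(1 + eps).
#'
#' @param geometry A [channel()].
#' @param strain Engineering strain (dimensionless, > -1).
#' @param poisson Poisson's ratio, between 0 and 0.5; default 0.5.
#' @return The deformed [channel()].
#' @export
#' @examples
#' deform(channel(200, 600), strain = 0.1)  # -> 220 x 570 um
deform <- function(geometry, strain, poisson = 0.5) {
  stopifnot(inherits(geometry, "samp_channel"),
            is.numeric(strain), length(strain) == 1)
  if (!is.finite(strain) || strain <= -1) stop("`strain` must be finite and > -1")
  if (poisson < 0 || poisson > 0.5) stop("`poisson` must lie in [0, 0.5]")
  h_new <- geometry$height * (1 - poisson * strain)
  if (h_new <= 0) stop("non-physical deformation: deformed height <= 0")
  channel(width = geometry$width * (1 + strain),
          height = h_new,
          length = geometry$length)
}

# Length- and viscosity-normalized resistance of a rectangular duct in the
# single-term lubrication approximation, written with a = min(w, h) and
# b = max(w, h) so the low-AR and high-AR forms are the same expression:
#   R_norm = 1 / ((1 - 0.63 a/b) a^3 b)   [1/um^4]
# Vectorized over w and h.
resistance_norm <- function(w, h) {
  a <- pmin(w, h)
  b <- pmax(w, h)
  1 / ((1 - 0.63 * a / b) * a^3 * b)
}

#' Hydraulic resistance of a rectangular microchannel
#'
#' Single-term lubrication approximation for laminar flow in a rectangular
#' duct, written with a = min(w, h), b = max(w, h) so the same expression
#' covers both aspect-ratio regimes and is exactly symmetric under swapping
#' width and height:
#' \deqn{R = \frac{12 \mu L}{(1 - 0.63\, a/b)\, a^3 b}}
#' Since a/b <= 1 the correction factor is always >= 0.37.
#'
#' @param geometry A [channel()].
#' @param fluid A [fluid()], required unless `normalized = TRUE`.
#' @param normalized If `TRUE`, return the length- and viscosity-normalized
#'   resistance 1/((1 - 0.63 a/b) a^3 b) in 1/um^4; otherwise the full
#'   resistance in Pa.s/uL.
#' @return A positive scalar resistance.
#' @export
#' @examples
#' hydraulic_resistance(channel(100, 100), normalized = TRUE)  # 1/(0.37 * 1e8)
#' hydraulic_resistance(channel(200, 600, length = 5000), fluid())
hydraulic_resistance <- function(geometry, fluid = NULL, normalized = is.null(fluid)) {
  stopifnot(inherits(geometry, "samp_channel"))
  r <- resistance_norm(geometry$width, geometry$height)
  if (normalized) return(r)
  if (is.null(fluid)) stop("a `fluid` is required for a non-normalized resistance")
  stopifnot(inherits(fluid, "samp_fluid"))
  12 * fluid$viscosity * geometry$length * r * .RES_MPAS_UM3_TO_PAS_UL
}

# Small-strain resistance ratio R'(eps)/R(0) for a channel of aspect ratio AR,
# first-order in eps:
#   AR <  1: (1 - 0.63 AR)   / (1 - 0.63 gamma AR)     * 1/(1 - eps/2)
#   AR >  1: (1 - 0.63/AR)   / (1 - 0.63/(gamma AR))   * 1/(1 + 5 eps/2)
# AR == 1 is routed through the low-AR branch by convention (the two branches
# give the same value there at eps = 0 and differ only at O(eps)).
# Vectorized over ar and strain.
approx_resistance_ratio <- function(ar, strain, poisson = 0.5) {
  g <- strain_gamma(strain, poisson)
  low <- ar <= 1
  ratio <- numeric(length(ar))
  ar_l <- ar[low]
  ratio[low] <- (1 - 0.63 * ar_l) / (1 - 0.63 * g * ar_l) / (1 - strain / 2)
  ar_h <- ar[!low]
  ratio[!low] <- (1 - 0.63 / ar_h) / (1 - 0.63 / (g * ar_h)) / (1 + 5 * strain / 2)
  ratio
}

#' Deformed-channel hydraulic resistance
#'
#' Resistance of a channel under orthogonal uniaxial strain, by either route:
#' `"exact"` applies the deformation w' = w(1+eps), h' = h(1-nu*eps) and
#' re-evaluates the rectangular-duct resistance, while `"approximate"` applies
#' the first-order small-strain ratio
#' \deqn{R'_{LAR} \approx R_{LAR}\frac{1-0.63 AR}{1-0.63\gamma AR}\frac{1}{1-\epsilon/2},
#' \quad R'_{HAR} \approx R_{HAR}\frac{1-0.63/AR}{1-0.63/(\gamma AR)}\frac{1}{1+5\epsilon/2}.}
#' The two agree to second order in strain. Under tension (eps > 0) the low-AR
#' resistance rises and the high-AR resistance falls — the deformation
#' asymmetry that makes a pair of such channels rectify an oscillatory flow.
#'
#' @param geometry A [channel()].
#' @param strain Engineering strain, > -1. The approximate form is a
#'   small-strain expansion; a warning is issued for |strain| > 0.15.
#' @param fluid Optional [fluid()]; when supplied its Poisson ratio is used
#'   and the result is in Pa.s/uL, otherwise the normalized resistance is
#'   returned.
#' @param model `"exact"` (default) or `"approximate"`.
#' @param poisson Poisson's ratio used when no `fluid` is given.
#' @return A positive scalar resistance (same units as
#'   [hydraulic_resistance()] with the same `fluid` argument).
#' @export
#' @examples
#' ch <- channel(200, 600)
#' deformed_resistance(ch, 0.1) / hydraulic_resistance(ch)           # < 1 (high AR)
#' deformed_resistance(ch, 0.1, model = "approximate") /
#'   hydraulic_resistance(ch)                                        # 0.83505
deformed_resistance <- function(geometry, strain,
                                fluid = NULL,
                                model = c("exact", "approximate"),
                                poisson = if (is.null(fluid)) 0.5 else fluid$poisson) {
  model <- match.arg(model)
  stopifnot(inherits(geometry, "samp_channel"),
            is.numeric(strain), length(strain) == 1)
  if (model == "approximate") {
    if (abs(strain) > 0.15)
      warning("approximate deformed resistance requested at |strain| > 0.15; ",
              "outside the small-strain validity range", call. = FALSE)
    r0 <- hydraulic_resistance(geometry, fluid = fluid, normalized = is.null(fluid))
    r0 * approx_resistance_ratio(aspect_ratio(geometry), strain, poisson)
  } else {
    hydraulic_resistance(deform(geometry, strain, poisson),
                         fluid = fluid, normalized = is.null(fluid))
  }
}
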