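#' Two-branch pump configuration
#'
#' A valveless strain-actuated pump is a pair of pumping channels with
#' different aspect ratios connected in parallel to a common actuator. In the
#' quasi-static equivalent-circuit picture the actuator is a cyclic flow
#' source and each branch is a resistor; optional observation channels (where
#' the liquid meniscus is read out) add series resistance to their branch.
#'
#' Sides are labelled `left` and `right`; the "HAR side" is whichever branch
#' has the larger aspect ratio. The sign convention throughout is that
#' positive pumping efficiency means net transport from right to left.
#'
#' @param left,right Pumping-channel [channel()] geometries.
#' @param obs_left,obs_right Optional observation-channel [channel()]
#'   geometries, added in series to their branch. They sit outside the
#'   strained footprint, so their resistances are held at rest values.
#' @param stroke_volume Actuator stroke volume V_total in uL displaced per
#'   half-cycle (> 0). Default 1.
#' @param fluid A [fluid()].
#' @return An object of class `samp_pump`.
#' @export
#' @examples
#' pump <- pump_config(left = channel(600, 200, 5000),
#'                     right = channel(200, 600, 5000))
#' pumping_efficiency(pump, strain = 0.1)
pump_config <- function(left, right, obs_left = NULL, obs_right = NULL,
                        stroke_volume = 1, fluid = strainpump::fluid()) {
  stopifnot(inherits(left, "samp_channel"), inherits(right, "samp_channel"),
            inherits(fluid, "samp_fluid"))
  if (!is.null(obs_left)) stopifnot(inherits(obs_left, "samp_channel"))
  if (!is.null(obs_right)) stopifnot(inherits(obs_right, "samp_channel"))
  if (xor(is.null(obs_left), is.null(obs_right)))
    stop("observation channels must be given for both sides or neither")
  if (!is.numeric(stroke_volume) || length(stroke_volume) != 1 ||
      !is.finite(stroke_volume) || stroke_volume <= 0)
    stop("`stroke_volume` must be a positive number (uL)")
  structure(list(left = left, right = right,
                 obs_left = obs_left, obs_right = obs_right,
                 stroke_volume = stroke_volume, fluid = fluid),
            class = "samp_pump")
}

#' @export
print.samp_pump <- function(x, ...) {
  cat(sprintf("<samp_pump> left AR %.3g | right AR %.3g, V_total = %g uL%s\n",
              aspect_ratio(x$left), aspect_ratio(x$right), x$stroke_volume,
              if (is.null(x$obs_left)) " (continuous design)" else " (+ observation channels)"))
  invisible(x)
}

#' Which side is the high-aspect-ratio branch?
#'
#' @param config A [pump_config()].
#' @return `"left"`, `"right"`, or `NA_character_` when the aspect ratios are
#'   equal (no HAR side, no pumping).
#' @export
har_side <- function(config) {
  stopifnot(inherits(config, "samp_pump"))
  arl <- aspect_ratio(config$left); arr <- aspect_ratio(config$right)
  if (arl == arr) return(NA_character_)
  if (arl > arr) "left" else "right"
}

# Total branch resistances (Pa.s/uL) at a given strain: deformed pumping
# channel plus rest-value observation channel in series.
branch_resistances <- function(config, strain, model = "exact") {
  fl <- config$fluid
  r <- vapply(list(config$left, config$right), function(ch) {
    if (strain == 0) hydraulic_resistance(ch, fluid = fl)
    else deformed_resistance(ch, strain, fluid = fl, model = model)
  }, numeric(1))
  if (!is.null(config$obs_left)) {
    r[1] <- r[1] + hydraulic_resistance(config$obs_left, fluid = fl)
    r[2] <- r[2] + hydraulic_resistance(config$obs_right, fluid = fl)
  }
  stats::setNames(r, c("left", "right"))
}

#' Split a flow between two parallel resistive branches
#'
#' The physical current divider: the branch with the lower resistance carries
#' the larger share, Q_a = R_b/(R_a + R_b) * Q_total, and the two flows sum
#' to Q_total exactly.
#'
#' @param R_a,R_b Branch resistances (> 0), any consistent units.
#' @param Q_total Total flow to divide. Vectorized.
#' @return A tibble with columns `Q_a` and `Q_b`.
#' @export
#' @examples
#' flow_split(1, 3, 4)  # Q_a = 3, Q_b = 1
flow_split <- function(R_a, R_b, Q_total) {
  if (any(!is.finite(R_a)) || any(!is.finite(R_b)) || any(R_a <= 0) || any(R_b <= 0))
    stop("branch resistances must be positive and finite")
  tibble::tibble(Q_a = R_b / (R_a + R_b) * Q_total,
                 Q_b = R_a / (R_a + R_b) * Q_total)
}

#' Per-cycle pumping efficiency of a two-branch pump
#'
#' In each strain cycle the actuator draws its stroke volume through the two
#' branches at their strained resistances and returns it at their rest
#' resistances. The flow fraction carried by a branch follows the current
#' divider, so the net volume moved per cycle, normalized by the stroke
#' volume, is the difference of the right branch's divider fractions between
#' the two phases:
#' \deqn{PE = \frac{R'_{left}}{R'_{left}+R'_{right}} - \frac{R_{left}}{R_{left}+R_{right}}}
#' Positive PE is net transport from right to left; for any asymmetric pair
#' the transport direction is from the high-AR branch toward the low-AR
#' branch, and its magnitude equals the HAR branch's strained-minus-relaxed
#' fraction difference. PE is independent of the stroke volume. Observation
#' channels, when present, enter both phases at their rest resistance and
#' only dilute the asymmetry (they reduce |PE|).
#'
#' @param config A [pump_config()].
#' @param strain Applied engineering strain (>= 0) in the strained phase.
#' @param model Resistance model for the strained phase: `"exact"` (default,
#'   deform-then-recompute) or `"approximate"` (first-order small-strain).
#' @return Signed PE (dimensionless, |PE| <= 1).
#' @export
pumping_efficiency <- function(config, strain, model = c("exact", "approximate")) {
  model <- match.arg(model)
  stopifnot(inherits(config, "samp_pump"), is.numeric(strain), length(strain) == 1)
  if (strain < 0) stop("`strain` must be >= 0")
  # equal aspect ratios: both branches' resistances scale by the same factor
  # under strain (the ratio R'(AR)/R(AR) is area-invariant), so the divider
  # fractions are unchanged and the PE is identically zero; without
  # observation channels this holds for any cross-sectional areas
  if (is.null(config$obs_left) &&
      aspect_ratio(config$left) == aspect_ratio(config$right))
    return(0)
  r0 <- branch_resistances(config, 0)
  r1 <- branch_resistances(config, strain, model = model)
  f_right_rest <- r0[["left"]] / (r0[["left"]] + r0[["right"]])
  f_right_strained <- r1[["left"]] / (r1[["left"]] + r1[["right"]])
  unname(f_right_strained - f_right_rest)
}

#' Per-cycle volume budget of a pump
#'
#' Splits the actuator stroke volume through the divider in both half-cycles
#' and reports, per side, the strained-phase volume V+ (drawn from that side),
#' the released-phase volume V- (returned to it), and the net volume gained
#' V_net = V- minus V+. The two nets are equal and opposite: the volume lost
#' by the high-AR side is gained by the low-AR side. Per the usual readout
#' convention the low-AR side's net is positive and the high-AR side's
#' negative.
#'
#' @inheritParams pumping_efficiency
#' @return A tibble of class `samp_cycle` with one row per side (`side`,
#'   `role`, `v_plus`, `v_minus`, `v_net`, all volumes in uL) and attributes
#'   `pe` (signed, right-to-left positive) and `stroke_volume`.
#' @export
net_volume_per_cycle <- function(config, strain, model = c("exact", "approximate")) {
  model <- match.arg(model)
  pe <- pumping_efficiency(config, strain, model = model)
  v <- config$stroke_volume
  r0 <- branch_resistances(config, 0)
  r1 <- branch_resistances(config, strain, model = model)
  split1 <- flow_split(r1[["left"]], r1[["right"]], v)   # strained: drawn from sides
  split0 <- flow_split(r0[["left"]], r0[["right"]], v)   # released: returned to sides
  hs <- har_side(config)
  role <- c(left = "LAR", right = "LAR")
  if (!is.na(hs)) role[hs] <- "HAR" else role[] <- "equal-AR"
  out <- tibble::tibble(
    side = c("left", "right"),
    role = unname(role[c("left", "right")]),
    v_plus = c(split1$Q_a, split1$Q_b),
    v_minus = c(split0$Q_a, split0$Q_b),
    v_net = c(split0$Q_a - split1$Q_a, split0$Q_b - split1$Q_b)
  )
  structure(out, class = c("samp_cycle", class(out)), pe = pe, stroke_volume = v)
}

#' Pumping-efficiency sweep over aspect-ratio pairs
#'
#' Evaluates the signed per-cycle pumping efficiency on a log-spaced grid of
#' (left AR, right AR) pairs, holding cross-sectional areas fixed: either
#' equal on both sides, or with the right side's width and height each scaled
#' by a factor (to study the effect of a resistance imbalance between the two
#' sides). Positive PE means right-to-left transport, so the map is zero on
#' the equal-AR diagonal and antisymmetric under transposition when the areas
#' are equal.
#'
#' @param ar_lo,ar_hi Aspect-ratio range, 0 < ar_lo < ar_hi.
#' @param n_grid Number of grid points per axis (>= 2). Default 101 (odd, so
#'   the diagonal and the corners are sampled exactly).
#' @param strain Applied strain. Default 0.1.
#' @param area_policy `"equal"` or `"right_scaled"`.
#' @param scale Width/height scale factor for the right side under
#'   `"right_scaled"`. Default 1.5.
#' @param model `"exact"` or `"approximate"` strained-resistance model.
#' @param poisson Poisson's ratio. Default 0.5.
#' @return A tibble of class `samp_pe_sweep` with columns `ar_left`,
#'   `ar_right`, `pe`.
#' @export
#' @examples
#' sweep <- pe_sweep(0.1, 10, n_grid = 41, strain = 0.1, model = "approximate")
#' max(abs(sweep$pe))
pe_sweep <- function(ar_lo = 0.1, ar_hi = 10, n_grid = 101, strain = 0.1,
                     area_policy = c("equal", "right_scaled"), scale = 1.5,
                     model = c("exact", "approximate"), poisson = 0.5) {
  area_policy <- match.arg(area_policy)
  model <- match.arg(model)
  if (!(ar_lo > 0 && ar_lo < ar_hi)) stop("need 0 < ar_lo < ar_hi")
  if (!is.numeric(n_grid) || n_grid < 2) stop("`n_grid` must be >= 2")
  ars <- exp(seq(log(ar_lo), log(ar_hi), length.out = n_grid))
  # sample unity exactly: the AR = 1 point is routed through the low-AR
  # branch by convention, and a 1 + eps round-off would flip the branch
  ars[abs(ars - 1) < 1e-9] <- 1
  grid <- tidyr::expand_grid(ar_left = ars, ar_right = ars)
  s <- if (area_policy == "right_scaled") scale else 1
  # unit area on the left; AR = h/w with w = 1/sqrt(AR), h = sqrt(AR)
  wl <- 1 / sqrt(grid$ar_left);  hl <- sqrt(grid$ar_left)
  wr <- s / sqrt(grid$ar_right); hr <- s * sqrt(grid$ar_right)
  if (model == "approximate") {
    r0l <- resistance_norm(wl, hl)
    r0r <- resistance_norm(wr, hr)
    r1l <- r0l * approx_resistance_ratio(grid$ar_left, strain, poisson)
    r1r <- r0r * approx_resistance_ratio(grid$ar_right, strain, poisson)
  } else {
    r0l <- resistance_norm(wl, hl)
    r0r <- resistance_norm(wr, hr)
    r1l <- resistance_norm(wl * (1 + strain), hl * (1 - poisson * strain))
    r1r <- resistance_norm(wr * (1 + strain), hr * (1 - poisson * strain))
  }
  grid$pe <- r1l / (r1l + r1r) - r0l / (r0l + r0r)
  structure(grid, class = c("samp_pe_sweep", class(grid)),
            strain = strain, model = model, area_policy = area_policy,
            scale = s)
}

#' Heat map of a pumping-efficiency sweep
#'
#' @param object A [pe_sweep()] result.
#' @param ... Unused.
#' @return A ggplot heat map of signed PE over log10 aspect ratios, with the
#'   zero-pumping diagonal drawn.
#' @export
autoplot.samp_pe_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = log10(.data$ar_left),
                                       y = log10(.data$ar_right),
                                       fill = .data$pe)) +
    ggplot2::geom_raster() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  name = "PE") +
    ggplot2::labs(x = "log10 AR (left)", y = "log10 AR (right)",
                  title = sprintf("Pumping efficiency, strain = %g (%s model)",
                                  attr(object, "strain"), attr(object, "model"))) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
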