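#' Periodic trapezoidal strain waveform
#'
#' One cycle ramps the strain linearly from 0 to `amplitude` over `ramp`
#' seconds, holds it for `hold` seconds, releases it over `release` seconds
#' and then waits `wait` seconds at zero strain; `cycles` such cycles are
#' concatenated. A zero `ramp` or `release` gives an ideal step (the
#' simulator applies the corresponding pressure jump instantaneously),
#' mirroring the quasi-static model's assumption that the strain is applied
#' in an infinitesimally small time interval. The default 1 s ramps match a
#' benchtop protocol where the device is strained in a second and released in
#' a second.
#'
#' @param amplitude Peak engineering strain (>= 0).
#' @param ramp,hold,release,wait Segment durations in seconds (>= 0).
#' @param cycles Number of cycles (>= 1).
#' @return An object of class `samp_waveform` with a `segments` tibble
#'   (`t0`, `t1`, `eps0`, `eps1`, `cycle`) and a `period`.
#' @export
strain_waveform <- function(amplitude, ramp = 1, hold = 0, release = ramp,
                            wait = 15, cycles = 1) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1, amplitude >= 0,
            ramp >= 0, hold >= 0, release >= 0, wait >= 0, cycles >= 1)
  period <- ramp + hold + release + wait
  if (period <= 0) stop("waveform period must be positive")
  one <- tibble::tibble(
    dt = c(ramp, hold, release, wait),
    eps0 = c(0, amplitude, amplitude, 0),
    eps1 = c(amplitude, amplitude, 0, 0))
  seg <- dplyr::bind_rows(lapply(seq_len(cycles), function(k) {
    s <- one
    s$cycle <- k
    s$t0 <- (k - 1) * period + cumsum(c(0, s$dt[-4]))
    s$t1 <- s$t0 + s$dt
    s
  }))
  # keep zero-duration segments only where the strain actually jumps
  seg <- seg[seg$dt > 0 | seg$eps1 != seg$eps0, c("t0", "t1", "eps0", "eps1", "cycle")]
  structure(list(segments = seg, amplitude = amplitude, period = period,
                 cycles = cycles,
                 durations = c(ramp = ramp, hold = hold,
                               release = release, wait = wait)),
            class = "samp_waveform")
}

#' @export
print.samp_waveform <- function(x, ...) {
  cat(sprintf("<samp_waveform> amplitude %g, period %g s, %d cycle(s)\n",
              x$amplitude, x$period, x$cycles))
  invisible(x)
}

#' Lumped actuator model
#'
#' The actuator is an array of parallel channels that dilate under orthogonal
#' strain. In the lumped transient network it is a compliant chamber: a
#' dilatation source injecting volume V0 * beta * eps(t) in series with a
#' compliance C, so the pressure obeys
#' \deqn{C\,dP/dt = -V_0\beta\,d\epsilon/dt - P\,(1/R_{left} + 1/R_{right}).}
#' The stroke volume per half-cycle is V_total = V0 * beta * eps_max, and the
#' relaxation time constant is tau = C * R_parallel. Defaults give
#' V_total = 1 uL at 5% strain and tau of about two seconds for the default
#' benchtop pump (see [default_pump()]).
#'
#' @param rest_volume Actuator rest volume V0 in uL (> 0). Default 10.
#' @param dilatation Dimensionless dilatation coefficient beta (> 0):
#'   fractional volume gain per unit strain. Default 2.
#' @param compliance Chamber compliance C in uL/Pa (> 0). Default 0.0015.
#' @return An object of class `samp_actuator`.
#' @export
actuator <- function(rest_volume = 10, dilatation = 2, compliance = 0.0015) {
  stopifnot(rest_volume > 0, dilatation > 0, compliance > 0)
  structure(list(rest_volume = rest_volume, dilatation = dilatation,
                 compliance = compliance),
            class = "samp_actuator")
}

#' @export
print.samp_actuator <- function(x, ...) {
  cat(sprintf("<samp_actuator> V0 %g uL, beta %g, C %g uL/Pa\n",
              x$rest_volume, x$dilatation, x$compliance))
  invisible(x)
}

#' Actuator stroke volume at a given strain amplitude
#'
#' @param actuator An [actuator()].
#' @param strain Strain amplitude.
#' @return V_total = V0 * beta * strain, in uL.
#' @export
actuator_stroke <- function(actuator, strain) {
  stopifnot(inherits(actuator, "samp_actuator"))
  actuator$rest_volume * actuator$dilatation * strain
}

#' Benchtop-like default pump configuration
#'
#' An antisymmetric pair (AR 3 and 1/3, equal 200 x 600 um cross-sections,
#' 5 mm long) with, optionally, identical 500 x 200 um x 40 mm observation
#' channels on both sides, filled with the default 28 mPa.s working liquid.
#'
#' @param continuous If `TRUE`, omit the observation channels (the
#'   "continuous" design whose branch resistances do not depend on the
#'   meniscus position).
#' @param stroke_volume Stroke volume in uL; default 1.
#' @return A [pump_config()].
#' @export
default_pump <- function(continuous = FALSE, stroke_volume = 1) {
  obs <- if (continuous) NULL else channel(500, 200, 40000)
  pump_config(left = channel(600, 200, 5000),
              right = channel(200, 600, 5000),
              obs_left = obs, obs_right = obs,
              stroke_volume = stroke_volume)
}

# Per-branch ingredients for the transient network, precomputed once.
# Pumping-channel resistance is an exact function of strain; observation
# channels contribute a per-length resistance times the liquid-filled length
# and a cross-sectional area converting flow to meniscus speed.
.branch_fns <- function(config) {
  fl <- config$fluid
  mk_pump <- function(ch) {
    force(ch)
    function(eps) {
      w <- ch$width * (1 + eps)
      h <- ch$height * (1 - fl$poisson * eps)
      12 * fl$viscosity * ch$length * resistance_norm(w, h) * .RES_MPAS_UM3_TO_PAS_UL
    }
  }
  continuous <- is.null(config$obs_left)
  if (continuous) {
    r_len <- c(0, 0)
    area <- c(config$left$width * config$left$height,
              config$right$width * config$right$height) * .UL_PER_UM3
    l_obs <- c(Inf, Inf)
  } else {
    r_len <- vapply(list(config$obs_left, config$obs_right), function(ch)
      12 * fl$viscosity * resistance_norm(ch$width, ch$height) * .RES_MPAS_UM3_TO_PAS_UL,
      numeric(1))
    area <- c(config$obs_left$width * config$obs_left$height,
              config$obs_right$width * config$obs_right$height) * .UL_PER_UM3
    l_obs <- c(config$obs_left$length, config$obs_right$length)
  }
  list(r_pump = list(left = mk_pump(config$left), right = mk_pump(config$right)),
       r_len = r_len, area = area, l_obs = l_obs, continuous = continuous)
}

#' Relaxation time constant of the lumped network
#'
#' tau = C * R_parallel with the branch resistances evaluated at the given
#' strain and meniscus positions.
#'
#' @param config A [pump_config()].
#' @param actuator An [actuator()].
#' @param strain Strain at which to evaluate the pumping-channel resistances.
#' @param x Meniscus positions (liquid-filled observation-channel lengths,
#'   um), length 2; defaults to half-filled channels.
#' @return tau in seconds.
#' @export
time_constant <- function(config, actuator, strain = 0, x = NULL) {
  b <- .branch_fns(config)
  if (is.null(x)) x <- ifelse(is.finite(b$l_obs), b$l_obs / 2, 0)
  r <- c(b$r_pump$left(strain), b$r_pump$right(strain)) + b$r_len * x
  actuator$compliance / (1 / r[1] + 1 / r[2])
}

#' Simulate repeated strain cycles on the lumped pump network
#'
#' Integrates the single-pressure-state network
#' \deqn{C\,\dot P = -V_0\beta\,\dot\epsilon - P\,(1/R_L + 1/R_R), \qquad
#'       \dot V_i = P / R_i, \qquad \dot x_i = \dot V_i / A_{obs,i},}
#' where each branch resistance is the strained pumping-channel resistance
#' (exact deformation model) plus the observation channel's per-length
#' resistance times its liquid-filled length. Strain discontinuities (ideal
#' steps) are applied as instantaneous pressure jumps -V0*beta*deps/C.
#' Capillary pressure at the menisci and the air column downstream are
#' neglected; outlets are at atmospheric pressure.
#'
#' Integration is fixed-step classical Runge-Kutta (via deSolve), with step
#' size at most tau/100 by default; the linear volume-conservation invariant
#' C P + V0 beta eps + V_L + V_R = const is preserved to round-off.
#'
#' If a meniscus leaves its observation channel the simulation halts at the
#' end of the offending step with a `samp_dynamic_range` warning and the
#' trace is truncated.
#'
#' @param config A [pump_config()].
#' @param actuator An [actuator()].
#' @param waveform A [strain_waveform()].
#' @param dt Fixed integrator step in seconds; default `min(tau/100, ramp/4)`
#'   (the latter so ramps are resolved).
#' @param x_init Initial meniscus positions `c(left, right)` in um; default
#'   half-filled observation channels (0 for the continuous design, where `x`
#'   reports cumulative displacement in the pumping channel instead).
#' @return A tibble of class `samp_trace` with columns `time` (s), `strain`,
#'   `pressure` (Pa), `x_left`, `x_right` (um), `v_left`, `v_right`
#'   (cumulative uL into each branch), and attributes `config`, `actuator`,
#'   `waveform`, `v_total`, `cycle_bounds`, `halted`.
#' @export
simulate_pump <- function(config, actuator, waveform, dt = NULL, x_init = NULL) {
  stopifnot(inherits(config, "samp_pump"), inherits(actuator, "samp_actuator"),
            inherits(waveform, "samp_waveform"))
  b <- .branch_fns(config)
  if (is.null(x_init)) {
    x_init <- if (b$continuous) c(0, 0) else b$l_obs / 2
  }
  stopifnot(length(x_init) == 2)
  if (!b$continuous && (any(x_init < 0) || any(x_init > b$l_obs)))
    stop("`x_init` must lie within the observation channels")
  C <- actuator$compliance
  src <- actuator$rest_volume * actuator$dilatation
  tau0 <- time_constant(config, actuator, 0, x_init)
  if (is.null(dt)) {
    ramps <- waveform$segments$t1 - waveform$segments$t0
    ramps <- ramps[ramps > 0]
    dt <- min(tau0 / 100, if (length(ramps)) min(ramps) / 4 else Inf)
  }
  stopifnot(dt > 0)

  resist <- function(eps, vL, vR) {
    c(b$r_pump$left(eps) + b$r_len[1] * (x_init[1] + vL / b$area[1]),
      b$r_pump$right(eps) + b$r_len[2] * (x_init[2] + vR / b$area[2]))
  }

  deriv <- function(t, y, p) {
    eps <- p$eps0 + p$slope * (t - p$t0)
    r <- resist(eps, y[2], y[3])
    dP <- (-src * p$slope - y[1] * (1 / r[1] + 1 / r[2])) / C
    list(c(dP, y[1] / r[1], y[1] / r[2]))
  }

  y <- c(P = 0, vL = 0, vR = 0)
  pieces <- list(tibble::tibble(time = 0, strain = 0, pressure = 0,
                                v_left = 0, v_right = 0))
  halted <- FALSE
  seg <- waveform$segments
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    if (s$t1 == s$t0) {                      # ideal step: pressure jump
      y[1] <- y[1] - src * (s$eps1 - s$eps0) / C
      next
    }
    n <- max(2L, ceiling((s$t1 - s$t0) / dt) + 1L)
    times <- seq(s$t0, s$t1, length.out = n)
    p <- list(t0 = s$t0, eps0 = s$eps0, slope = (s$eps1 - s$eps0) / (s$t1 - s$t0))
    sol <- deSolve::ode(y = y, times = times, func = deriv, parms = p,
                        method = "rk4")
    eps_t <- p$eps0 + p$slope * (sol[, "time"] - p$t0)
    piece <- tibble::tibble(time = sol[, "time"], strain = eps_t,
                            pressure = sol[, "P"],
                            v_left = sol[, "vL"], v_right = sol[, "vR"])
    if (!b$continuous) {
      xl <- x_init[1] + piece$v_left / b$area[1]
      xr <- x_init[2] + piece$v_right / b$area[2]
      bad <- which(xl < 0 | xl > b$l_obs[1] | xr < 0 | xr > b$l_obs[2])
      if (length(bad)) {
        piece <- piece[seq_len(bad[1]), ]
        pieces[[length(pieces) + 1L]] <- piece[-1, ]
        halted <- TRUE
        warning(warningCondition(
          sprintf("meniscus left the observation channel at t = %.3f s; trace truncated",
                  piece$time[nrow(piece)]),
          class = "samp_dynamic_range"))
        break
      }
    }
    pieces[[length(pieces) + 1L]] <- piece[-1, ]   # drop duplicated boundary row
    y <- c(P = piece$pressure[n], vL = piece$v_left[n], vR = piece$v_right[n])
  }
  out <- dplyr::bind_rows(pieces)
  out$x_left <- x_init[1] + out$v_left / b$area[1]
  out$x_right <- x_init[2] + out$v_right / b$area[2]
  out <- out[, c("time", "strain", "pressure", "x_left", "x_right",
                 "v_left", "v_right")]
  cyc <- waveform$period * (0:waveform$cycles)
  structure(out, class = c("samp_trace", class(out)),
            config = config, actuator = actuator, waveform = waveform,
            v_total = actuator_stroke(actuator, waveform$amplitude),
            cycle_bounds = cyc, x_init = x_init, halted = halted)
}

#' Conservation residual of a simulation trace
#'
#' The quantity C P + V0 beta eps + V_L + V_R is conserved exactly by the
#' network equations; its excursion over the trace, relative to the stroke
#' volume, measures integrator consistency.
#'
#' @param trace A [simulate_pump()] trace.
#' @return Maximum absolute residual relative to the stroke volume.
#' @export
conservation_residual <- function(trace) {
  act <- attr(trace, "actuator")
  q <- act$compliance * trace$pressure +
    act$rest_volume * act$dilatation * trace$strain +
    trace$v_left + trace$v_right
  vt <- attr(trace, "v_total")
  if (vt == 0) vt <- 1
  max(abs(q - q[1])) / vt
}

#' Per-cycle pumping efficiency from a simulation trace
#'
#' For each completed strain cycle, the net right-to-left transported volume
#' ((delta V_left - delta V_right)/2 over the cycle) divided by the stroke
#' volume. Positive values mean right-to-left transport, matching the sign of
#' [pumping_efficiency()]; with full inter-cycle stabilization the values
#' approach the quasi-static PE.
#'
#' @param trace A [simulate_pump()] trace.
#' @param stroke_volume Stroke volume V_total in uL; defaults to the trace's.
#' @return A tibble with columns `cycle` and `pe`.
#' @export
per_cycle_pe <- function(trace, stroke_volume = NULL) {
  stopifnot(inherits(trace, "samp_trace"))
  if (is.null(stroke_volume)) stroke_volume <- attr(trace, "v_total")
  if (stroke_volume <= 0) stop("`stroke_volume` must be positive")
  bounds <- attr(trace, "cycle_bounds")
  t_end <- trace$time[nrow(trace)]
  complete <- which(bounds[-1] <= t_end + 1e-9)
  if (!length(complete)) stop("trace does not cover a full cycle")
  if (length(complete) < length(bounds) - 1)
    warning("trace ends mid-cycle; pumping efficiency computed over completed cycles only",
            call. = FALSE)
  idx <- vapply(bounds, function(tt) which.min(abs(trace$time - tt))[1], integer(1))
  pe <- vapply(complete, function(k) {
    dvl <- trace$v_left[idx[k + 1]] - trace$v_left[idx[k]]
    dvr <- trace$v_right[idx[k + 1]] - trace$v_right[idx[k]]
    (dvl - dvr) / 2 / stroke_volume
  }, numeric(1))
  tibble::tibble(cycle = complete, pe = pe)
}

#' Cumulative displacement linearity over many actuations
#'
#' Simulates `n_actuations` strain cycles and summarizes how linear the
#' cumulative net transported volume is in the actuation count. With
#' observation channels, pumping moves the menisci apart, the series
#' resistances of the two branches grow increasingly unequal, and the
#' per-cycle increments shrink — the cumulative series is sublinear. The
#' continuous design (no observation channel, meniscus-independent
#' resistances) produces a constant per-cycle increment and an essentially
#' perfect linear fit.
#'
#' @param config A [pump_config()].
#' @param actuator An [actuator()].
#' @param waveform A [strain_waveform()]; its `cycles` field is overridden by
#'   `n_actuations`.
#' @param n_actuations Number of strain cycles to simulate.
#' @param dt Integrator step passed to [simulate_pump()].
#' @return A tibble of class `samp_linearity` with columns `actuation`,
#'   `v_net_cum` (uL), `pe` (that cycle's efficiency), and attributes
#'   `r_squared` and `slope` (uL/actuation) of the linear fit.
#' @export
long_run_linearity <- function(config, actuator, waveform, n_actuations,
                               dt = NULL) {
  d <- waveform$durations
  wf <- strain_waveform(waveform$amplitude, ramp = d[["ramp"]],
                        hold = d[["hold"]], release = d[["release"]],
                        wait = d[["wait"]], cycles = n_actuations)
  tr <- withCallingHandlers(
    simulate_pump(config, actuator, wf, dt = dt),
    samp_dynamic_range = function(w) invokeRestart("muffleWarning"))
  pe <- suppressWarnings(per_cycle_pe(tr))
  vt <- attr(tr, "v_total")
  out <- tibble::tibble(actuation = pe$cycle,
                        v_net_cum = cumsum(pe$pe * vt),
                        pe = pe$pe)
  fit <- stats::lm(v_net_cum ~ actuation, data = out)
  r2 <- suppressWarnings(summary(fit))$r.squared
  structure(out, class = c("samp_linearity", class(out)),
            r_squared = r2, slope = unname(stats::coef(fit)[2]),
            halted = attr(tr, "halted"))
}

#' Plot a simulation trace
#'
#' @param object A [simulate_pump()] trace.
#' @param ... Unused.
#' @return A ggplot with pressure and meniscus-position panels over time.
#' @export
autoplot.samp_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("time", "pressure", "x_left", "x_right")],
    -"time", names_to = "signal", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~signal, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
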