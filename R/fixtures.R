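# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards. NULL seed leaves the RNG stream alone.
with_fixture_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic meniscus-displacement series
#'
#' Emulates a benchtop measurement of a pump with true per-cycle efficiency
#' `pe_true`: the low-AR side's displaced volume grows linearly at
#' `pe_true * v_total` per actuation and the high-AR side's falls at the same
#' rate, each read with independent Gaussian measurement noise of standard
#' deviation `sigma` (uL). [fit_pe()] applied to the output has expected
#' slope `pe_true`. Deterministic for a fixed `seed`.
#'
#' Default scales follow the on-body wrist measurements (about 0.01-0.02 uL
#' per actuation with a 1 uL stroke).
#'
#' @param n_actuations Number of actuations (>= 1). Default 10.
#' @param pe_true True pumping efficiency. Default 0.02.
#' @param sigma Measurement noise standard deviation in uL (>= 0).
#'   Default 0.002.
#' @param v_total Stroke volume in uL. Default 1.
#' @param strain Strain-amplitude metadata recorded on the series.
#' @param chip_id Chip label.
#' @param seed Integer seed; `NULL` draws from the current RNG stream.
#' @return A [meniscus_series()].
#' @export
make_meniscus_series <- function(n_actuations = 10, pe_true = 0.02,
                                 sigma = 0.002, v_total = 1,
                                 strain = NA_real_, chip_id = "synthetic-1",
                                 seed = NULL) {
  stopifnot(n_actuations >= 1, sigma >= 0, v_total > 0)
  n <- seq_len(n_actuations)
  with_fixture_seed(seed, {
    lar <- pe_true * v_total * n + stats::rnorm(n_actuations, 0, sigma)
    har <- -pe_true * v_total * n + stats::rnorm(n_actuations, 0, sigma)
    df <- tibble::tibble(
      chip_id = chip_id,
      side = rep(c("LAR", "HAR"), each = n_actuations),
      actuation = c(n, n),
      volume_uL = c(lar, har))
    meniscus_series(df, v_total = v_total, strain = strain)
  })
}

#' Synthetic principal-strain field
#'
#' A smooth strain field on a regular planar grid: both principal-strain
#' magnitudes are Gaussian bumps centred at `center` with length scale
#' `width`, and the first principal direction is uniform at `angle1`. With a
#' sensor footprint at the bump centre and orientation along the first
#' principal axis, the mean resultant strain approaches `peak_M1` as the
#' footprint shrinks relative to `width`. Point positions can be jittered
#' (seeded) to emulate an unstructured DIC point cloud.
#'
#' @param extent Field extent `c(x, y)` in mm. Default 40 x 40.
#' @param spacing Grid spacing in mm. Default 1.
#' @param center Bump centre `c(x, y)` in mm. Default field centre.
#' @param width Gaussian length scale in mm. Default 8.
#' @param peak_M1,peak_M2 Peak principal strain magnitudes. Defaults 0.08 and
#'   0.03, typical of large shoulder movements.
#' @param angle1 First principal direction in degrees. Default 0.
#' @param jitter Positional jitter standard deviation in mm (>= 0).
#'   Default 0.
#' @param seed Integer seed for the jitter; `NULL` uses the current stream.
#' @return A [strain_field()].
#' @export
make_strain_field <- function(extent = c(40, 40), spacing = 1,
                              center = extent / 2, width = 8,
                              peak_M1 = 0.08, peak_M2 = 0.03, angle1 = 0,
                              jitter = 0, seed = NULL) {
  stopifnot(spacing > 0, width > 0, jitter >= 0, peak_M1 >= 0, peak_M2 >= 0)
  g <- tidyr::expand_grid(x = seq(0, extent[1], by = spacing),
                          y = seq(0, extent[2], by = spacing))
  with_fixture_seed(seed, {
    if (jitter > 0) {
      g$x <- g$x + stats::rnorm(nrow(g), 0, jitter)
      g$y <- g$y + stats::rnorm(nrow(g), 0, jitter)
    }
    r2 <- (g$x - center[1])^2 + (g$y - center[2])^2
    bump <- exp(-r2 / (2 * width^2))
    strain_field(g$x, g$y, M1 = peak_M1 * bump, M2 = peak_M2 * bump,
                 angle1 = rep(angle1, nrow(g)))
  })
}
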