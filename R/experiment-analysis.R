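#' Meniscus-displacement measurement series
#'
#' Benchtop and on-body experiments record, after each actuation (or set of
#' actuations), the displaced liquid volume read from the meniscus position
#' on each side of the pump. The tidy schema is one row per (actuation,
#' side): columns `chip_id`, `side` (`"HAR"` or `"LAR"`), `actuation`
#' (non-negative integer, strictly increasing per side) and `volume_uL`
#' (signed displaced volume).
#'
#' @param data A data frame with the columns above.
#' @param v_total Actuator stroke volume V_total in uL; when present,
#'   displaced volumes can be normalized to V_net/V_total. `NA` leaves the
#'   series in raw-volume mode.
#' @param strain Strain amplitude metadata (optional).
#' @return A tibble of class `samp_series` with attributes `v_total` and
#'   `strain`.
#' @export
meniscus_series <- function(data, v_total = NA_real_, strain = NA_real_) {
  need <- c("chip_id", "side", "actuation", "volume_uL")
  if (!all(need %in% names(data)))
    stop("meniscus series needs columns: ", paste(need, collapse = ", "))
  data <- tibble::as_tibble(data)[, need]
  if (!all(data$side %in% c("HAR", "LAR")))
    stop('`side` must be "HAR" or "LAR"')
  if (any(data$actuation < 0)) stop("actuation counts must be non-negative")
  ok <- data |>
    dplyr::group_by(.data$chip_id, .data$side) |>
    dplyr::summarise(ok = !is.unsorted(.data$actuation, strictly = TRUE),
                     .groups = "drop")
  if (!all(ok$ok)) stop("actuation counts must be strictly increasing per side")
  structure(data, class = c("samp_series", class(data)),
            v_total = v_total, strain = strain)
}

#' Read / write a measurement CSV
#'
#' CSV schema: columns `chip_id`, `side`, `actuation`, `volume_uL`. Stroke
#' volume and strain metadata may be carried as constant extra columns
#' `v_total` and `strain`.
#'
#' @param path CSV file path.
#' @return [read_meniscus_series()] returns a [meniscus_series()];
#'   [write_meniscus_series()] invisibly returns the path.
#' @export
read_meniscus_series <- function(path) {
  df <- utils::read.csv(path)
  v_total <- if ("v_total" %in% names(df)) df$v_total[1] else NA_real_
  strain <- if ("strain" %in% names(df)) df$strain[1] else NA_real_
  meniscus_series(df, v_total = v_total, strain = strain)
}

#' @rdname read_meniscus_series
#' @param series A [meniscus_series()].
#' @export
write_meniscus_series <- function(series, path) {
  df <- as.data.frame(series)
  df$v_total <- attr(series, "v_total")
  df$strain <- attr(series, "strain")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Pumping efficiency from a measurement series
#'
#' Pools both sides of the pump (the high-AR side's volumes are sign-flipped,
#' since its net displacement mirrors the low-AR side's) and fits ordinary
#' least squares of normalized displacement V_net/V_total against actuation
#' count. The slope of that line is the measured per-actuation pumping
#' efficiency. Without stroke-volume metadata the fit is on raw volumes and
#' the slope is in uL per actuation.
#'
#' A constant response is reported as slope 0 with R^2 defined as 0 (no
#' variance explained), by convention.
#'
#' @param series A [meniscus_series()] (or data frame coercible to one).
#' @return An object of class `samp_pe_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `n`, `normalized`, and the underlying `lm` fit.
#' @export
fit_pe <- function(series) {
  if (!inherits(series, "samp_series")) series <- meniscus_series(series)
  v_total <- attr(series, "v_total")
  normalized <- is.finite(v_total)
  df <- dplyr::mutate(series,
    y = ifelse(.data$side == "HAR", -.data$volume_uL, .data$volume_uL))
  if (normalized) df$y <- df$y / v_total
  if (nrow(df) < 3) stop("need at least 3 measurements to fit")
  if (length(unique(df$actuation)) < 2) stop("actuation counts are constant; cannot fit")
  if (diff(range(df$y)) == 0) {
    fit <- stats::lm(y ~ actuation, data = df)
    res <- list(slope = 0, intercept = df$y[1], r_squared = 0, n = nrow(df),
                normalized = normalized, fit = fit)
    return(structure(res, class = "samp_pe_fit"))
  }
  fit <- stats::lm(y ~ actuation, data = df)
  res <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r_squared = suppressWarnings(summary(fit))$r.squared,
              n = nrow(df), normalized = normalized, fit = fit)
  structure(res, class = "samp_pe_fit")
}

#' @export
print.samp_pe_fit <- function(x, ...) {
  unit <- if (x$normalized) "per actuation (V_net/V_total)" else "uL per actuation"
  cat(sprintf("<samp_pe_fit> slope %.4g %s, R^2 = %.4f (n = %d)\n",
              x$slope, unit, x$r_squared, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pumping-efficiency fit
#'
#' @param x A [fit_pe()] object.
#' @param ... Unused.
#' @return One row per coefficient with `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.samp_pe_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = rownames(s), estimate = unname(s[, 1]),
                 std.error = unname(s[, 2]), statistic = unname(s[, 3]),
                 p.value = unname(s[, 4]))
}

#' Glance at a pumping-efficiency fit
#'
#' @param x A [fit_pe()] object.
#' @param ... Unused.
#' @return A one-row tibble with `slope`, `intercept`, `r.squared`,
#'   `sigma`, `nobs`.
#' @export
glance.samp_pe_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, sigma = suppressWarnings(summary(x$fit))$sigma,
                 nobs = x$n)
}

#' Pumping rate per actuation from per-set displacements
#'
#' On-body protocols record the cumulative displaced volume after each set of
#' repetitions; the per-actuation pumping rate is the per-set slope of that
#' series divided by the repetitions per set. A single set reduces to its
#' increment divided by the repetition count.
#'
#' @param set_displacements Cumulative displaced volumes (uL) after each set.
#' @param reps_per_set Repetitions per set (> 0). Default 10.
#' @return Pumping rate in uL per actuation.
#' @export
#' @examples
#' pumping_rate(cumsum(rep(0.11, 10)), reps_per_set = 10)  # 0.011
pumping_rate <- function(set_displacements, reps_per_set = 10) {
  if (!length(set_displacements)) stop("no displacement measurements supplied")
  if (reps_per_set <= 0) stop("`reps_per_set` must be positive")
  v <- as.numeric(set_displacements)
  if (length(v) == 1) return(v[1] / reps_per_set)
  sets <- seq_along(v)
  slope <- unname(stats::coef(stats::lm(v ~ sets))[2])
  slope / reps_per_set
}

#' Correlate pumping rates with mean resultant strain
#'
#' Pearson product-moment correlation between measured pumping rates and the
#' mean resultant strain each sensor experienced, plus the simple
#' least-squares line (whose R^2 equals r^2).
#'
#' @param rates Pumping rates (uL per actuation).
#' @param strains Mean resultant strains, same length (>= 3), non-constant.
#' @return An object of class `samp_correlation`: list with `r`, `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @export
correlate_rates <- function(rates, strains) {
  if (length(rates) != length(strains)) stop("`rates` and `strains` must have equal length")
  if (length(rates) < 3) stop("need at least 3 pairs")
  if (diff(range(rates)) == 0 || diff(range(strains)) == 0)
    stop("correlation is undefined for a constant vector")
  r <- stats::cor(strains, rates)
  fit <- stats::lm(rates ~ strains)
  structure(list(r = r, slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit))$r.squared, n = length(rates)),
            class = "samp_correlation")
}

#' @export
print.samp_correlation <- function(x, ...) {
  cat(sprintf("<samp_correlation> r = %.3f (R^2 = %.3f, n = %d)\n",
              x$r, x$r_squared, x$n))
  invisible(x)
}

#' @rdname correlate_rates
#' @param x A `samp_correlation`.
#' @param ... Unused.
#' @export
glance.samp_correlation <- function(x, ...) {
  tibble::tibble(r = x$r, r.squared = x$r_squared, slope = x$slope,
                 intercept = x$intercept, nobs = x$n)
}

#' Five-number box-plot summary
#'
#' Median, quartiles (linear interpolation between order statistics,
#' `quantile(type = 7)`) and whiskers at the sample minimum and maximum.
#'
#' @param values Numeric vector (>= 1 value).
#' @return A one-row tibble with `median`, `q1`, `q3`, `whisker_lo`,
#'   `whisker_hi`.
#' @export
#' @examples
#' box_stats(1:5)
box_stats <- function(values) {
  if (!length(values)) stop("`values` is empty")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(median = q[2], q1 = q[1], q3 = q[3],
                 whisker_lo = min(values), whisker_hi = max(values))
}
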