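#' Principal-strain field on a planar grid
#'
#' Digital image correlation of the skin surface yields, at each surface
#' point, the first and second principal Lagrangian strains: magnitudes `M1`,
#' `M2` and the direction of the first principal axis. The second principal
#' direction is taken perpendicular to the first, so the orthogonality of the
#' principal frame is exact by construction.
#'
#' @param x,y Point coordinates in mm.
#' @param M1,M2 First/second principal strain magnitudes (dimensionless).
#' @param angle1 Direction of the first principal axis in degrees
#'   (counter-clockwise from the +x axis).
#' @return A tibble of class `samp_strain_field` with columns `x`, `y`, `M1`,
#'   `M2`, `angle1`, and unit-direction columns `u1x`, `u1y`, `u2x`, `u2y`.
#' @export
strain_field <- function(x, y, M1, M2, angle1) {
  n <- length(x)
  stopifnot(length(y) == n, length(M1) == n, length(M2) == n, length(angle1) == n)
  th <- angle1 * pi / 180
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                        M1 = as.numeric(M1), M2 = as.numeric(M2),
                        angle1 = as.numeric(angle1),
                        u1x = cos(th), u1y = sin(th),
                        u2x = -sin(th), u2y = cos(th))
  structure(out, class = c("samp_strain_field", class(out)))
}

#' Read / write a strain-field point list
#'
#' CSV schema: columns `x`, `y`, `M1`, `M2`, `angle1` (degrees). DIC exports
#' are point clouds, so no grid structure is assumed.
#'
#' @param path CSV file path.
#' @return [read_strain_field()] returns a [strain_field()] tibble;
#'   [write_strain_field()] invisibly returns the path.
#' @export
read_strain_field <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "M1", "M2", "angle1")
  if (!all(need %in% names(df)))
    stop("strain-field CSV must have columns: ", paste(need, collapse = ", "))
  strain_field(df$x, df$y, df$M1, df$M2, df$angle1)
}

#' @rdname read_strain_field
#' @param field A [strain_field()].
#' @export
write_strain_field <- function(field, path) {
  utils::write.csv(field[, c("x", "y", "M1", "M2", "angle1")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Sensor footprint and orientation
#'
#' The device footprint on the skin: a closed region (circle or polygon) plus
#' the sensor orientation — the direction of the straight line orthogonal to
#' the device reservoirs, along which the resultant strain is evaluated.
#'
#' @param center Numeric length-2 `c(x, y)` in mm (circle center; for a
#'   polygon, used only for plotting).
#' @param radius Circle radius in mm (> 0); give either `radius` or
#'   `vertices`.
#' @param vertices Two-column matrix of polygon vertices in mm.
#' @param orientation Sensor orientation in degrees (counter-clockwise from
#'   +x).
#' @return An object of class `samp_footprint`.
#' @export
sensor_footprint <- function(center = c(0, 0), radius = NULL, vertices = NULL,
                             orientation = 0) {
  if (is.null(radius) == is.null(vertices))
    stop("give exactly one of `radius` or `vertices`")
  if (!is.null(radius) && (!is.numeric(radius) || radius <= 0))
    stop("`radius` must be a positive number (mm)")
  if (!is.null(vertices)) {
    vertices <- as.matrix(vertices)
    if (ncol(vertices) != 2 || nrow(vertices) < 3)
      stop("`vertices` must be a matrix with >= 3 rows and 2 columns")
  }
  th <- orientation * pi / 180
  structure(list(center = as.numeric(center), radius = radius,
                 vertices = vertices, orientation = orientation,
                 s_hat = c(cos(th), sin(th))),
            class = "samp_footprint")
}

#' @export
print.samp_footprint <- function(x, ...) {
  shape <- if (is.null(x$vertices))
    sprintf("circle r = %g mm at (%g, %g)", x$radius, x$center[1], x$center[2])
  else sprintf("polygon with %d vertices", nrow(x$vertices))
  cat(sprintf("<samp_footprint> %s, orientation %g deg\n", shape, x$orientation))
  invisible(x)
}

# Points on the outline count as inside (closed region). Polygon membership
# uses mgcv's even-odd test; boundary points there follow that routine's
# convention.
points_in_footprint <- function(footprint, x, y) {
  if (!is.null(footprint$radius)) {
    d2 <- (x - footprint$center[1])^2 + (y - footprint$center[2])^2
    d2 <= footprint$radius^2 * (1 + 1e-12)
  } else {
    mgcv::in.out(rbind(footprint$vertices, footprint$vertices[1, ]),
                 cbind(x, y))
  }
}

.normalize_unit <- function(v, name) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop(name, " must be a non-zero vector")
  if (abs(n - 1) > 1e-6)
    warning(sprintf("%s deviates from unit length by %.2e; normalizing", name, abs(n - 1)),
            call. = FALSE)
  v / n
}

#' Resultant strain along a sensor orientation
#'
#' Projects both principal directions onto the sensor orientation and sums
#' the magnitude-weighted projections:
#' \deqn{\epsilon_R = M_1 (\hat u_1 \cdot \hat s) + M_2 (\hat u_2 \cdot \hat s).}
#' The default keeps the projections signed, so compressive components along
#' the sensor axis reduce (and can negate) the resultant — matching devices
#' that pump backwards under compression. Set `rectify = TRUE` to sum
#' absolute projections instead.
#'
#' The sum is invariant under a simultaneous rotation of both principal
#' directions and the sensor orientation.
#'
#' @param M1,M2 Principal strain magnitudes.
#' @param u1,u2 Unit principal-direction vectors, length 2. Non-unit inputs
#'   are normalized (with a warning beyond 1e-6 deviation).
#' @param s Unit sensor-orientation vector, length 2.
#' @param rectify If `TRUE`, use absolute projections.
#' @return The scalar resultant strain.
#' @export
#' @examples
#' resultant_strain(0.08, c(1, 0), 0.03, c(0, 1), c(cos(pi/6), sin(pi/6)))
resultant_strain <- function(M1, u1, M2, u2, s, rectify = FALSE) {
  u1 <- .normalize_unit(u1, "u1"); u2 <- .normalize_unit(u2, "u2")
  s <- .normalize_unit(s, "s")
  p1 <- sum(u1 * s); p2 <- sum(u2 * s)
  if (rectify) M1 * abs(p1) + M2 * abs(p2) else M1 * p1 + M2 * p2
}

#' Pointwise resultant strain over a field
#'
#' @param field A [strain_field()].
#' @param s Either a [sensor_footprint()] (its orientation is used) or a
#'   length-2 direction vector / scalar angle in degrees.
#' @param rectify Passed to the projection; see [resultant_strain()].
#' @return The field tibble with an added `eps_R` column.
#' @export
field_resultant_strain <- function(field, s, rectify = FALSE) {
  stopifnot(inherits(field, "samp_strain_field"))
  if (inherits(s, "samp_footprint")) s <- s$s_hat
  if (length(s) == 1) s <- c(cos(s * pi / 180), sin(s * pi / 180))
  s <- .normalize_unit(s, "s")
  p1 <- field$u1x * s[1] + field$u1y * s[2]
  p2 <- field$u2x * s[1] + field$u2y * s[2]
  field$eps_R <- if (rectify) field$M1 * abs(p1) + field$M2 * abs(p2)
                 else field$M1 * p1 + field$M2 * p2
  field
}

#' Mean resultant strain over a sensor footprint
#'
#' Unweighted mean of the pointwise resultant strain over the field points
#' that fall inside the footprint (closed region: outline points count).
#'
#' @param field A [strain_field()].
#' @param footprint A [sensor_footprint()]; its orientation defines the
#'   projection axis.
#' @param rectify See [resultant_strain()].
#' @return The scalar mean resultant strain.
#' @export
mean_resultant_strain <- function(field, footprint, rectify = FALSE) {
  stopifnot(inherits(field, "samp_strain_field"),
            inherits(footprint, "samp_footprint"))
  inside <- points_in_footprint(footprint, field$x, field$y)
  if (!any(inside))
    stop("no strain-field points fall inside the sensor footprint (",
         format(footprint$center[1]), ", ", format(footprint$center[2]), ")")
  f <- field_resultant_strain(field, footprint, rectify = rectify)
  mean(f$eps_R[inside])
}

#' Plot a strain field with a sensor footprint
#'
#' @param object A [strain_field()].
#' @param footprint Optional [sensor_footprint()] drawn on top.
#' @param ... Unused.
#' @return A ggplot of M1 magnitudes with principal-direction glyphs.
#' @export
autoplot.samp_strain_field <- function(object, footprint = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$M1)) +
    ggplot2::scale_colour_viridis_c(name = "M1") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(footprint) && !is.null(footprint$radius)) {
    th <- seq(0, 2 * pi, length.out = 181)
    circ <- tibble::tibble(x = footprint$center[1] + footprint$radius * cos(th),
                           y = footprint$center[2] + footprint$radius * sin(th))
    p <- p + ggplot2::geom_path(data = circ, colour = "black")
  }
  p
}
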