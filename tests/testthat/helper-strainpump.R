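# Shared builders for test geometries and small protocols.

# Antisymmetric pumping pair: ARs `ar` and 1/ar with equal cross-sectional
# areas and equal lengths (the canonical benchtop design).
antisym_pump <- function(ar = 3, area = 1.2e5, length = 5000, ...) {
  w_har <- sqrt(area / ar)
  pump_config(left = channel(sqrt(area * ar), sqrt(area / ar), length),
              right = channel(w_har, sqrt(area * ar), length), ...)
}

# Pump with identical channels on both sides (no pumping expected).
symmetric_pump <- function(width = 300, height = 300, length = 5000, ...) {
  pump_config(left = channel(width, height, length),
              right = channel(width, height, length), ...)
}

# Unit-area channel of a given aspect ratio (dimensionless test units).
ar_channel <- function(ar, area = 1, length = 1) {
  channel(sqrt(area / ar), sqrt(area * ar), length)
}

# Network-solve flow divider, independent of flow_split(): impose Q_total,
# solve for the node pressure over the parallel pair, then per-branch flows.
divider_oracle <- function(R_a, R_b, Q_total) {
  P <- Q_total / (1 / R_a + 1 / R_b)
  c(P / R_a, P / R_b)
}

# Definition-level Pearson correlation (covariance form).
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Rotate a strain field and a footprint rigidly about the origin (degrees).
rotate_field <- function(field, angle_deg) {
  th <- angle_deg * pi / 180
  strain_field(x = field$x * cos(th) - field$y * sin(th),
               y = field$x * sin(th) + field$y * cos(th),
               M1 = field$M1, M2 = field$M2,
               angle1 = field$angle1 + angle_deg)
}

rotate_footprint <- function(fp, angle_deg) {
  th <- angle_deg * pi / 180
  rot <- function(p) c(p[1] * cos(th) - p[2] * sin(th),
                       p[1] * sin(th) + p[2] * cos(th))
  sensor_footprint(center = rot(fp$center), radius = fp$radius,
                   orientation = fp$orientation + angle_deg)
}
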