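test_that("flow divider: symmetry, arithmetic, and network-solve oracle", {
  expect_equal(flow_split(2, 2, 2), tibble::tibble(Q_a = 1, Q_b = 1))
  expect_equal(flow_split(1, 3, 4), tibble::tibble(Q_a = 3, Q_b = 1))
  expect_equal(flow_split(5, 9, 0), tibble::tibble(Q_a = 0, Q_b = 0))
  # lower resistance carries the larger flow; flows sum exactly
  set.seed(11)
  for (i in 1:25) {
    R <- stats::runif(2, 0.1, 50)
    Q <- stats::runif(1, -5, 5)
    got <- flow_split(R[1], R[2], Q)
    want <- divider_oracle(R[1], R[2], Q)
    expect_equal(c(got$Q_a, got$Q_b), want, tolerance = 1e-12)
    expect_equal(got$Q_a + got$Q_b, Q, tolerance = 1e-12)
    if (Q > 0 && R[1] < R[2]) expect_gt(got$Q_a, got$Q_b)
  }
  expect_error(flow_split(-1, 2, 1), "positive")
})

test_that("pumping efficiency of the antisymmetric AR 3 / (1/3) pair", {
  p <- antisym_pump(3)
  expect_equal(pumping_efficiency(p, 0.1, model = "approximate"), 0.0488,
               tolerance = 1e-2)
  expect_equal(pumping_efficiency(p, 0.1, model = "exact"), 0.0535,
               tolerance = 1e-2)
  # swapping the sides negates PE
  ps <- pump_config(left = p$right, right = p$left,
                    stroke_volume = p$stroke_volume, fluid = p$fluid)
  for (m in c("exact", "approximate"))
    expect_equal(pumping_efficiency(ps, 0.1, model = m),
                 -pumping_efficiency(p, 0.1, model = m), tolerance = 1e-12)
  # equal ARs on both sides (any areas): no pumping, exactly
  expect_identical(pumping_efficiency(symmetric_pump(), 0.1), 0)
  uneq <- pump_config(left = channel(300, 300, 5000),
                      right = channel(450, 450, 5000))
  expect_identical(pumping_efficiency(uneq, 0.08), 0)
})

test_that("PE magnitude grows with strain and shrinks with series load", {
  p <- antisym_pump(3)
  pes <- vapply(seq(0.01, 0.12, by = 0.01),
                function(e) abs(pumping_efficiency(p, e)), numeric(1))
  expect_true(all(diff(pes) > 0))
  # identical observation channels on both sides only dilute the asymmetry
  pe_with_obs <- vapply(c(0, 5000, 20000, 60000), function(L) {
    if (L == 0) return(abs(pumping_efficiency(antisym_pump(3), 0.1)))
    obs <- channel(500, 200, L)
    abs(pumping_efficiency(antisym_pump(3, obs_left = obs, obs_right = obs), 0.1))
  }, numeric(1))
  expect_true(all(diff(pe_with_obs) < 0))
})

test_that("per-cycle volume budget is equal and opposite across sides", {
  p <- antisym_pump(3, stroke_volume = 0.8)
  cyc <- net_volume_per_cycle(p, 0.1)
  expect_equal(sum(cyc$v_net), 0, tolerance = 1e-15)
  expect_equal(sum(cyc$v_plus), 0.8, tolerance = 1e-12)
  expect_equal(sum(cyc$v_minus), 0.8, tolerance = 1e-12)
  pe <- attr(cyc, "pe")
  expect_equal(cyc$v_net[cyc$role == "LAR"], pe * 0.8, tolerance = 1e-12)
  expect_equal(cyc$v_net[cyc$role == "HAR"], -pe * 0.8, tolerance = 1e-12)
  expect_gt(cyc$v_net[cyc$role == "LAR"], 0)   # transport toward the low-AR side
  # equal-AR config moves no net volume
  cyc0 <- net_volume_per_cycle(symmetric_pump(), 0.1)
  expect_equal(cyc0$v_net, c(0, 0))
})

test_that("PE from the divider difference equals brute-force volume splitting", {
  set.seed(23)
  for (i in 1:20) {
    dims <- stats::runif(4, 100, 900)
    v <- stats::runif(1, 0.2, 2)
    e <- stats::runif(1, 0.01, 0.12)
    p <- pump_config(left = channel(dims[1], dims[2], 5000),
                     right = channel(dims[3], dims[4], 5000),
                     stroke_volume = v)
    r0 <- c(hydraulic_resistance(p$left, p$fluid),
            hydraulic_resistance(p$right, p$fluid))
    r1 <- c(deformed_resistance(p$left, e, p$fluid),
            deformed_resistance(p$right, e, p$fluid))
    drawn <- flow_split(r1[1], r1[2], v)      # strained phase, from each side
    returned <- flow_split(r0[1], r0[2], v)   # released phase, back to each side
    pe_oracle <- (returned$Q_b - drawn$Q_b) * -1 / v  # right side net, sign: right->left
    expect_equal(pumping_efficiency(p, e), pe_oracle, tolerance = 1e-12)
  }
})

test_that("aspect-ratio sweep: diagonal, antisymmetry, corner maximum", {
  sw <- pe_sweep(0.1, 10, n_grid = 41, strain = 0.1, model = "approximate")
  expect_s3_class(sw, "samp_pe_sweep")
  expect_equal(nrow(sw), 41^2)
  diag <- sw$pe[sw$ar_left == sw$ar_right]
  expect_length(diag, 41)
  expect_true(all(diag == 0))
  # antisymmetric under transposition at equal areas
  key <- paste(signif(sw$ar_left, 12), signif(sw$ar_right, 12))
  tkey <- paste(signif(sw$ar_right, 12), signif(sw$ar_left, 12))
  expect_equal(sw$pe, -sw$pe[match(key, tkey)], tolerance = 1e-12)
  # grid max sits at the antisymmetric corner region and rounds to 0.06
  i <- which.max(abs(sw$pe))
  expect_equal(round(max(abs(sw$pe)), 2), 0.06)
  expect_gt(max(sw$ar_left[i], sw$ar_right[i]), 8)
  expect_error(pe_sweep(0.1, 10, n_grid = 1), "n_grid")
  expect_error(pe_sweep(10, 0.1), "ar_lo")
})

test_that("transport direction is high-AR to low-AR for clear asymmetry", {
  set.seed(7)
  for (m in c("exact", "approximate")) {
    for (i in 1:20) {
      ar_low <- stats::runif(1, 0.1, 0.4)
      ar_high <- stats::runif(1, 1.5, 10)
      flip <- i %% 2 == 0
      p <- pump_config(left = ar_channel(if (flip) ar_high else ar_low, 1e5, 5000),
                       right = ar_channel(if (flip) ar_low else ar_high, 1e5, 5000))
      pe <- pumping_efficiency(p, 0.1, model = m)
      # positive = right-to-left; transport must leave the high-AR side
      if (flip) expect_lt(pe, 0) else expect_gt(pe, 0)
    }
  }
})

test_that("larger right-side area lowers the peak PE and relaxes its AR", {
  eq <- pe_sweep(0.1, 10, n_grid = 41, strain = 0.1, model = "exact")
  sc <- pe_sweep(0.1, 10, n_grid = 41, strain = 0.1, model = "exact",
                 area_policy = "right_scaled", scale = 1.5)
  expect_lt(max(abs(sc$pe)), max(abs(eq$pe)))
  har_of <- function(s) {
    i <- which.max(abs(s$pe))
    max(s$ar_left[i], s$ar_right[i])
  }
  expect_lt(har_of(sc), har_of(eq))
})
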