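test_that("PE fit recovers exact and constant series", {
  n <- 0:10
  exact <- meniscus_series(
    tibble::tibble(chip_id = "c1", side = "LAR", actuation = n,
                   volume_uL = 0.01 * n),
    v_total = 1)
  fit <- fit_pe(exact)
  expect_equal(fit$slope, 0.01, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  const <- meniscus_series(
    tibble::tibble(chip_id = "c1", side = "LAR", actuation = n,
                   volume_uL = rep(0.3, 11)))
  fitc <- fit_pe(const)
  expect_identical(fitc$slope, 0)
  expect_identical(fitc$r_squared, 0)

  # HAR-side series are sign-flipped before pooling
  both <- meniscus_series(
    tibble::tibble(chip_id = "c1",
                   side = rep(c("LAR", "HAR"), each = 11),
                   actuation = c(n, n),
                   volume_uL = c(0.02 * n, -0.02 * n)),
    v_total = 2)
  expect_equal(fit_pe(both)$slope, 0.01, tolerance = 1e-12)

  expect_error(fit_pe(exact[1:2, ]), "at least 3")
  expect_error(meniscus_series(tibble::tibble(chip_id = "c", side = "LAR",
                                              actuation = c(2, 1),
                                              volume_uL = c(0, 0))),
               "strictly increasing")
})

test_that("tidy and glance expose the fit in broom form", {
  fit <- fit_pe(make_meniscus_series(seed = 2))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$estimate[td$term == "actuation"], fit$slope)
  gl <- glance(fit)
  expect_equal(gl$r.squared, fit$r_squared)
  expect_equal(gl$nobs, 20L)
})

test_that("noisy parameter recovery stays within propagated standard errors", {
  s <- make_meniscus_series(n_actuations = 10, pe_true = 0.02, sigma = 0.002,
                            seed = 31)
  fit <- fit_pe(s)
  se <- tidy(fit)$std.error[2]
  expect_lt(abs(fit$slope - 0.02), 3 * se)
})

test_that("pumping rate reduces per-set displacements per actuation", {
  expect_equal(pumping_rate(cumsum(rep(0.11, 10)), 10), 0.011, tolerance = 1e-12)
  expect_equal(pumping_rate(0.25, 10), 0.025)
  expect_equal(pumping_rate(rep(0, 5), 10), 0)
  expect_error(pumping_rate(numeric(0)), "no displacement")
  expect_error(pumping_rate(1, 0), "positive")
})

test_that("Pearson correlation matches the covariance-definition oracle", {
  x <- 1:6
  expect_equal(correlate_rates(2 * x, x)$r, 1)
  expect_equal(correlate_rates(-x + 10, x)$r, -1)
  set.seed(17)
  for (i in 1:20) {
    a <- stats::rnorm(8); b <- stats::rnorm(8)
    got <- correlate_rates(a, b)
    expect_equal(got$r, pearson_oracle(b, a), tolerance = 1e-12)
    expect_equal(got$r_squared, got$r^2, tolerance = 1e-12)
    # affine invariance
    expect_equal(correlate_rates(3 * a - 1, -2 * b + 5)$r, -got$r,
                 tolerance = 1e-12)
  }
  expect_error(correlate_rates(rep(1, 4), 1:4), "constant")
  expect_error(correlate_rates(1:3, 1:4), "equal length")
})

test_that("box summary uses interpolated quartiles and min/max whiskers", {
  b <- box_stats(c(1, 2, 3, 4, 5))
  expect_equal(unlist(b), c(median = 3, q1 = 2, q3 = 4,
                            whisker_lo = 1, whisker_hi = 5))
  b1 <- box_stats(7)
  expect_true(all(unlist(b1) == 7))
  # symmetric data: median equals mean
  v <- c(-2, -1, 0, 1, 2)
  expect_equal(box_stats(v)$median, mean(v))
  # order invariant on random draws
  set.seed(5)
  for (i in 1:10) {
    b <- box_stats(stats::rnorm(sample(3:50, 1)))
    expect_true(b$whisker_lo <= b$q1 && b$q1 <= b$median &&
                  b$median <= b$q3 && b$q3 <= b$whisker_hi)
  }
  expect_error(box_stats(numeric(0)), "empty")
})

test_that("measurement series round-trip through the CSV schema", {
  s <- make_meniscus_series(seed = 12, strain = 0.05)
  path <- withr::local_tempfile(fileext = ".csv")
  write_meniscus_series(s, path)
  s2 <- read_meniscus_series(path)
  expect_equal(as.data.frame(s2), as.data.frame(s))
  expect_equal(attr(s2, "v_total"), attr(s, "v_total"))
  expect_equal(attr(s2, "strain"), attr(s, "strain"))
  expect_equal(fit_pe(s2)$slope, fit_pe(s)$slope, tolerance = 1e-9)
})

test_that("noiseless transient run feeds through the fit without bias", {
  act <- actuator()
  p <- default_pump(continuous = TRUE)
  tau <- time_constant(p, act)
  # step strain with full relaxation so every cycle's increment is identical
  wf <- strain_waveform(0.05, ramp = 0, hold = 25 * tau, release = 0,
                        wait = 25 * tau)
  lin <- long_run_linearity(p, act, wf, 8, dt = 0.01)
  series <- meniscus_series(
    tibble::tibble(chip_id = "sim",
                   side = rep(c("LAR", "HAR"), each = nrow(lin)),
                   actuation = rep(lin$actuation, 2),
                   volume_uL = c(lin$v_net_cum, -lin$v_net_cum)),
    v_total = 1)
  fit <- fit_pe(series)
  expect_equal(fit$slope, mean(lin$pe), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})
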