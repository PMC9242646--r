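test_that("trace input returns both endpoints of every axis", {
  traces <- lapply(1:20, function(i)
    axis_trace(paste0("a", i), cbind(c(i, i + 30), c(5, 40))))
  pts <- detect_axis_endpoints(traces)
  expect_identical(nrow(pts), 40L)
  expect_equal(pts$x_px[1:2], c(1, 31))
})

test_that("image input recovers straight-axis termini to sub-pixel accuracy", {
  plane <- matrix(100, 80, 80)
  for (x in seq(10, 60, by = 0.5))
    plane <- adaptorquant:::add_gaussian_spot(plane, x, 10, 1000, 1.5)
  pts <- detect_axis_endpoints(plane)
  expect_identical(nrow(pts), 2L)
  got <- pts[order(pts$x_px), ]
  expect_lt(abs(got$x_px[1] - 10), 1)
  expect_lt(abs(got$x_px[2] - 60), 1)
  expect_lt(max(abs(got$y_px - 10)), 1)
})

test_that("closed-loop axes are flagged rather than dropped", {
  plane <- matrix(100, 80, 80)
  th <- seq(0, 2 * pi, length.out = 200)
  for (k in seq_along(th))
    plane <- adaptorquant:::add_gaussian_spot(plane, 40 + 20 * cos(th[k]),
                                              40 + 20 * sin(th[k]), 1000, 1.5)
  pts <- detect_axis_endpoints(plane)
  expect_identical(nrow(pts), 0L)
  expect_length(attr(pts, "flagged_loops"), 1)
})

test_that("focus measurement subtracts the local background", {
  flat <- matrix(100, 60, 60)
  m <- measure_focus(flat, c(30, 30), pixel_size = 0.16)
  expect_equal(m$corrected, 0)
  expect_error(measure_focus(flat, c(1, 1), pixel_size = 0.16), "out of bounds")
})

test_that("a Gaussian focus is recovered near its analytic aperture mean", {
  px <- 0.1
  sigma_um <- 0.13
  A <- 1000
  plane <- matrix(100, 80, 80)
  plane <- adaptorquant:::add_gaussian_spot(plane, 40, 40, A, sigma_um / px)
  R <- 2 * sigma_um
  m <- measure_focus(plane, c(40, 40), pixel_size = px, aperture_radius = R,
                     bg_inner = 0.5, bg_outer = 0.8)
  # analytic mean of A*exp(-r^2/2s^2) over a disk of radius R
  analytic <- A * 2 * sigma_um^2 * (1 - exp(-R^2 / (2 * sigma_um^2))) / R^2
  expect_lt(abs(m$corrected - analytic) / analytic, 0.10)
})

test_that("corrected intensities are offset-invariant, normalized are gain-invariant", {
  set.seed(7)
  plane <- matrix(100, 100, 100) + matrix(rnorm(1e4, 0, 3), 100, 100)
  plane <- adaptorquant:::add_gaussian_spot(plane, 30, 30, 500, 1.3)
  plane <- adaptorquant:::add_gaussian_spot(plane, 70, 70, 800, 1.3)
  pts <- data.frame(x_px = c(30, 70), y_px = c(30, 70))
  m0 <- measure_foci(plane, pts, 0.16)
  m_off <- measure_foci(plane + 55, pts, 0.16)
  expect_equal(m_off$corrected, m0$corrected, tolerance = 1e-10)
  ref <- data.frame(corrected = c(400, 600))
  n0 <- normalize_foci(m0, ref)
  m_gain <- measure_foci(2.5 * plane, pts, 0.16)
  n_gain <- normalize_foci(m_gain, data.frame(corrected = 2.5 * ref$corrected))
  expect_equal(n_gain$normalized, n0$normalized, tolerance = 1e-10)
})

test_that("normalization maps the reference set to mean one", {
  meas <- data.frame(corrected = c(10, 20, 30))
  out <- normalize_foci(meas, meas)
  expect_equal(mean(out$normalized), 1.0)
  frac <- data.frame(corrected = 0.73 * mean(meas$corrected))
  expect_equal(normalize_foci(frac, meas)$normalized, 0.73)
  expect_error(normalize_foci(meas, data.frame(corrected = numeric(0))),
               "empty reference")
  expect_error(normalize_foci(meas, data.frame(corrected = c(-5, 1))),
               "positive")
})

test_that("blot ratios and replicate summaries are exact", {
  expect_equal(blot_ratio(5000, 10000), 0.5)
  expect_equal(blot_ratio(7, 7), 1)
  trip <- blot_ratio(c(0.4, 0.5, 0.6), c(1, 1, 1))
  expect_equal(trip$mean, 0.5)
  expect_equal(trip$sem, sd(c(0.4, 0.5, 0.6)) / sqrt(3))
  expect_equal(trip$sem, 0.05773503, tolerance = 1e-6)
  expect_error(blot_ratio(1, 0), "positive")
})

test_that("simulated spreads recover the configured amplitude fraction", {
  bench <- foci_benchmark(0.5, seed = 31, n_cells = 3, n_foci = 12)
  expect_identical(bench$n_mutant_foci, 36L)
  expect_lt(abs(bench$mean_normalized - 0.5), 0.05)
})
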