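# Scan geometry, time delays, and the forward scattering models.

test_that("time delay is |r - a| / v, symmetric and guarded", {
  expect_equal(time_delay(c(0.01, 0.02), c(0.01, 0.02), 3e8), 0)
  # |r - a| = 0.15 m at 3e8 m/s
  expect_equal(time_delay(c(0.15, 0), c(0, 0), 3e8), 5e-10)
  # 3-4-5 triangle
  expect_equal(time_delay(c(0.03, 0.04), c(0, 0), 2e8), 2.5e-10)
  r <- c(0.02, -0.05); a <- c(-0.01, 0.03)
  expect_equal(time_delay(r, a, 2.2e8), time_delay(a, r, 2.2e8))
  expect_error(time_delay(r, a, 0), "positive")
  expect_error(time_delay(r, a, -1), "positive")
})

test_that("circular-arc constructor places equally spaced positions on the circle", {
  g <- circular_scan_geometry(8, radius_m = 0.12, arc_span_deg = 355,
                              start_angle_deg = 10)
  radii <- sqrt(rowSums(g$positions^2))
  expect_equal(radii, rep(0.12, 8))
  ang <- atan2(g$positions[, 2], g$positions[, 1]) * 180 / pi
  steps <- diff(ang %% 360)
  steps <- (steps + 360) %% 360
  expect_equal(steps, rep(355 / 7, 7))
  # derived speed from permittivity
  g2 <- circular_scan_geometry(4, avg_permittivity = 4)
  expect_equal(g2$speed, 299792458 / 2)
})

test_that("frequency axis and grid constructors enforce their invariants", {
  expect_error(frequency_axis(c(2e9, 1e9)), "increasing")
  expect_error(frequency_axis(c(1e9, Inf)), "finite")
  g <- image_grid(c(-0.08, 0.08), c(-0.04, 0.04), 16, 8)
  expect_equal(g$pixel_area, 0.01 * 0.01)
  expect_equal(g$domain_area, g$n_pixels * g$pixel_area)
  # regular lattice of pixel centres
  expect_equal(diff(g$x), rep(g$dx, g$n_x - 1))
  expect_equal(g$x[1], -0.08 + g$dx / 2)
  gr <- image_grid(n_x = 10, n_y = 10, roi_radius = 0.05)
  expect_equal(dim(gr$roi), c(10L, 10L))
  expect_true(gr$roi[5, 5] && !gr$roi[1, 1])
})

test_that("phase matrix entries are unit-modulus round-trip phasors", {
  g <- small_geometry(3)
  fa <- small_freqs(2)
  grid <- small_grid(4)
  pm <- phase_matrix(grid, g, fa)
  expect_equal(dim(pm), c(3L, 2L, 16L))
  expect_equal(Mod(pm), array(1, dim(pm)))
  # zero frequency: all entries equal 1
  pm0 <- phase_matrix(grid, g, frequency_axis(0))
  expect_equal(as.vector(pm0), rep(1 + 0i, length(pm0)))
  # scalar recomputation for a single entry
  p <- 7
  d <- sqrt(sum((grid$pixel_xy[p, ] - g$positions[2, ])^2))
  expect_equal(pm[2, 2, p],
               exp(-4i * pi * fa$frequencies[2] * d / g$speed))
  # memory guard points to streaming
  expect_error(phase_matrix(grid, g, fa, max_bytes = 10), "streaming")
})

test_that("forward model is the dA-weighted phase sum and is linear", {
  set.seed(11)
  g <- small_geometry(4)
  fa <- small_freqs(3)
  grid <- small_grid(6)
  expect_equal(forward_model(zero_profile(grid), g, fa)$values,
               matrix(0 + 0i, 4, 3))
  p1 <- rand_profile(grid); p2 <- rand_profile(grid)
  a <- 0.7 - 0.2i; b <- -1.1 + 0.4i
  comb <- reflectivity_profile(a * p1$values + b * p2$values, grid)
  expect_equal(forward_model(comb, g, fa)$values,
               a * forward_model(p1, g, fa)$values +
                 b * forward_model(p2, g, fa)$values,
               tolerance = 1e-12)
  # brute-force element check against the definition
  fw <- forward_model(p1, g, fa)$values
  aidx <- 3; kidx <- 2
  acc <- 0 + 0i
  for (p in seq_len(grid$n_pixels)) {
    tt <- time_delay(grid$pixel_xy[p, ], g$positions[aidx, ], g$speed)
    acc <- acc + grid$pixel_area * as.vector(p1$values)[p] *
      exp(-2i * pi * fa$frequencies[kidx] * 2 * tt)
  }
  expect_equal(fw[aidx, kidx], acc, tolerance = 1e-12)
  # precomputed phase path agrees with the streaming path
  ph <- bmsradar:::.forward_phase(grid, g, fa)
  expect_equal(forward_model(p1, g, fa, phase = ph)$values, fw,
               tolerance = 1e-12)
})

test_that("single-measurement closed-form profile reproduces the measurement exactly", {
  set.seed(21)
  g1 <- circular_scan_geometry(1, radius_m = 0.15)
  f1 <- frequency_axis(3.7e9)
  grid <- small_grid(9)
  s <- rand_complex(1)
  prof <- sigma_d_profile(s, g1, f1$frequencies, grid)
  fw <- forward_model(prof, g1, f1)
  expect_equal(fw$values[1, 1], s, tolerance = 1e-12)
})

test_that("dual-frequency DAS-derived profile leaves a nonzero residual", {
  set.seed(22)
  g1 <- circular_scan_geometry(1, radius_m = 0.15)
  f2 <- frequency_axis(c(2e9, 7e9))
  grid <- small_grid(9)
  s <- rand_complex(2)
  p0 <- sigma_d_profile(s[1], g1, f2$frequencies[1], grid)
  p1 <- sigma_d_profile(s[2], g1, f2$frequencies[2], grid)
  prof <- reflectivity_profile(p0$values + p1$values, grid)
  sp <- sparameter_set(matrix(s, 1, 2), g1, f2)
  expect_gt(orr_loss(prof, sp), 1e-6 * sum(Mod(s)^2))
})

test_that("second-order model matches closed forms and guards its cost", {
  g <- small_geometry(3)
  fa <- small_freqs(2)
  grid <- small_grid(5)
  expect_equal(forward_model_second_order(zero_profile(grid), g, fa)$values,
               matrix(0 + 0i, 3, 2))
  # single nonzero pixel: second-order term is dA^2 sigma^2 e^{-2pi j f [2 t(r0,a)]}
  set.seed(31)
  p0 <- 13
  sig <- rep(0 + 0i, grid$n_pixels); sig[p0] <- 1.3 - 0.4i
  prof <- reflectivity_profile(matrix(sig, grid$n_y, grid$n_x), grid)
  s2 <- forward_model_second_order(prof, g, fa)$values
  s1 <- forward_model(prof, g, fa)$values
  for (a in 1:3) for (k in 1:2) {
    tt <- time_delay(grid$pixel_xy[p0, ], g$positions[a, ], g$speed)
    expected <- grid$pixel_area^2 * sig[p0]^2 *
      exp(-2i * pi * fa$frequencies[k] * 2 * tt) # t(r0, r0) = 0
    expect_equal(s2[a, k] - s1[a, k], expected, tolerance = 1e-12)
  }
  # two-pixel profile vs independent quadruple-loop brute force
  sig <- rep(0 + 0i, grid$n_pixels)
  sig[c(4, 20)] <- rand_complex(2)
  prof <- reflectivity_profile(matrix(sig, grid$n_y, grid$n_x), grid)
  got <- forward_model_second_order(prof, g, fa)$values
  dA <- grid$pixel_area
  want <- matrix(0 + 0i, 3, 2)
  for (a in 1:3) for (k in 1:2) {
    f <- fa$frequencies[k]
    acc <- 0 + 0i
    for (p in seq_len(grid$n_pixels)) {
      tpa <- time_delay(grid$pixel_xy[p, ], g$positions[a, ], g$speed)
      acc <- acc + dA * sig[p] * exp(-2i * pi * f * 2 * tpa)
      inner <- 0 + 0i
      for (q in seq_len(grid$n_pixels)) {
        tqa <- time_delay(grid$pixel_xy[q, ], g$positions[a, ], g$speed)
        tpq <- time_delay(grid$pixel_xy[p, ], grid$pixel_xy[q, ], g$speed)
        inner <- inner + dA * sig[q] * exp(-2i * pi * f * (tqa + tpq))
      }
      acc <- acc + dA * sig[p] * exp(-2i * pi * f * tpa) * inner
    }
    want[a, k] <- acc
  }
  expect_equal(got, want, tolerance = 1e-10)
  # quadratic-cost guard
  big <- image_grid(n_x = 80, n_y = 80)
  expect_error(
    forward_model_second_order(zero_profile(big), g, fa, max_pixels = 100),
    "n_pixels\\^2")
})

test_that("reference subtraction is an element-wise difference with axis checks", {
  set.seed(41)
  g <- small_geometry(4); fa <- small_freqs(3)
  a <- rand_sparams(g, fa); b <- rand_sparams(g, fa)
  expect_equal(subtract_reference(a, a)$values, matrix(0 + 0i, 4, 3))
  zero <- sparameter_set(matrix(0 + 0i, 4, 3), g, fa)
  expect_equal(subtract_reference(a, zero)$values, a$values)
  expect_equal(subtract_reference(a, b)$values, a$values - b$values)
  g2 <- small_geometry(5)
  expect_error(subtract_reference(a, rand_sparams(g2, small_freqs(3))),
               "identical geometry")
})
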