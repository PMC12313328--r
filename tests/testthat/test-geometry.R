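geom <- channel_geometry()

test_that("width profile interpolates the nominal region widths", {
  expect_equal(width_profile(geom, 25), 25, tolerance = 0.25 / 25)
  expect_equal(width_profile(geom, 75), 50, tolerance = 0.5 / 50)
  expect_equal(width_profile(geom, 125), 25, tolerance = 0.25 / 25)
  # asymptotes to the effective inlet width far upstream/downstream
  expect_equal(width_profile(geom, -1e4), geom$inlet_effective_width)
  expect_equal(width_profile(geom, 1e4), geom$inlet_effective_width)
  expect_true(all(width_profile(geom, seq(-200, 400, by = 0.5)) > 0))
})

test_that("geometry constructor validates its inputs", {
  expect_error(channel_geometry(transition_scale = 0), "transition_scale")
  expect_error(channel_geometry(height = -1), "height")
  expect_error(width_profile(geom, Inf), "finite")
})

test_that("centreline velocity follows 1/width mass conservation", {
  v25 <- centerline_velocity(geom, 1, 25)
  v75 <- centerline_velocity(geom, 1, 75)
  expect_equal(v25 / v75, 2, tolerance = 0.05)
  expect_true(all(centerline_velocity(geom, 1, seq(-50, 200, 1)) > 0))
  expect_error(centerline_velocity(geom, 0, 10), "flow_rate")
  bad <- geom; bad$velocity_scale <- 0
  expect_error(centerline_velocity(bad, 1, 10), "velocity_scale")
})

test_that("a tracer crosses the 150 um channel in 25-35 frames at 11000 fps", {
  xg <- seq(0, 150, by = 0.02)
  v <- centerline_velocity(geom, 1, xg)
  transit <- sum(0.02 / v)
  frames <- transit * 11000
  expect_gte(frames, 25)
  expect_lte(frames, 35)
})

test_that("stress proxy has the cavity zero crossing near 75 um", {
  xg <- seq(50, 100, by = 0.01)
  s <- stress_proxy(geom, 1, xg)
  x0 <- xg[which.min(abs(s))]
  expect_equal(x0, 75, tolerance = 1 / 75)
  # maximum positive stress in R3 sits at the second constriction
  # entrance, ~25 um past the crossing
  xg3 <- seq(x0, 170, by = 0.01)
  s3 <- stress_proxy(geom, 1, xg3)
  x_max3 <- xg3[which.max(s3)]
  expect_gt(x_max3, 95)
  expect_lt(x_max3, 110)
})

test_that("stress proxy sign pattern matches the deformation narrative", {
  # +, ~0/-, - -> 0 -> +, then - again towards the outlet
  sgn_at <- function(x) sign(stress_proxy(geom, 1, x))
  expect_identical(sgn_at(2), 1)      # entering R1
  expect_identical(sgn_at(52), -1)    # entering the cavity
  expect_identical(sgn_at(98), 1)     # entering R2 (second constriction)
  expect_identical(sgn_at(152), -1)   # exiting to the outlet
  # ordered sign changes: exactly one crossing in the cavity
  xg <- seq(55, 95, by = 0.05)
  s <- stress_proxy(geom, 1, xg)
  expect_equal(sum(diff(sign(s)) != 0), 1)
})

test_that("stress proxy equals the numerical derivative of velocity", {
  xg <- seq(-30, 170, by = 2.5)
  h <- 1e-4
  num <- (centerline_velocity(geom, 1, xg + h) -
            centerline_velocity(geom, 1, xg - h)) / (2 * h)
  expect_equal(stress_proxy(geom, 1, xg), num, tolerance = 1e-6)
})

test_that("integral of dv/dx recovers the velocity difference", {
  xg <- seq(-30, 170, by = 0.01)
  s <- stress_proxy(geom, 1, xg)
  integral <- sum((s[-1] + s[-length(s)]) / 2 * diff(xg))
  expect_equal(integral,
               centerline_velocity(geom, 1, 170) -
                 centerline_velocity(geom, 1, -30),
               tolerance = 1e-6)
})
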