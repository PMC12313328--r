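geom <- channel_geometry()
acq <- acquisition_config()

one_cell <- function(gain, tau, radius = 6, entry = 0) {
  tibble::tibble(radius = radius, gain = gain, tau = tau, entry_time = entry)
}

test_that("zero gain yields no deformation at any frame", {
  tr <- simulate_trajectory(one_cell(0, 0.14), geom, acq)
  expect_true(all(tr$D_true == 1))
  expect_equal(tr$a, tr$b)
})

test_that("ellipse model conserves area and encodes D as axis ratio", {
  tr <- simulate_trajectory(one_cell(1.4e-4, 0.14), geom, acq)
  expect_equal(tr$a * tr$b, rep(36, nrow(tr)), tolerance = 1e-12)
  expect_equal(tr$a / tr$b, tr$D_true, tolerance = 1e-12)
})

test_that("vanishing relaxation time reaches the quasi-static response", {
  cell <- one_cell(1.4e-4, 1e-3)
  tr <- simulate_trajectory(cell, geom, acq, compression_ratio = 1)
  deq <- 1 + cell$gain * stress_proxy(geom, acq$flow_rate, tr$x)
  expect_lt(max(abs(tr$D_true - deq)), 0.01 * max(abs(deq)))
})

test_that("an explicitly insufficient step size is reported", {
  acq10 <- acquisition_config(substeps = 10)
  expect_error(
    simulate_trajectory(one_cell(1.4e-4, 1e-3), geom, acq10,
                        allow_substep_refinement = FALSE),
    "unstable"
  )
})

test_that("first-constriction deformation exceeds the second peak", {
  for (gain in c(0.9e-4, 1.4e-4, 2.1e-4)) {
    tr <- simulate_trajectory(one_cell(gain, 0.14), geom, acq)
    p1 <- max(tr$D_true[tr$x >= -30 & tr$x < 50])
    cav <- tr$x >= 50 & tr$x < 100
    base_x <- tr$x[cav][which.min(tr$D_true[cav])]
    p2 <- max(tr$D_true[tr$x >= base_x & tr$x <= 170])
    expect_gt(p1, p2)
  }
})

test_that("deformation grows with gain and relaxation slows with tau", {
  peaks <- sapply(c(0.5e-4, 1e-4, 1.5e-4, 2e-4), function(g) {
    tr <- simulate_trajectory(one_cell(g, 0.14), geom, acq)
    max(tr$D_true[tr$x < 50])
  })
  expect_true(all(diff(peaks) > 0))
  # larger tau -> shallower relaxation slope after the first peak
  slope_after_peak <- function(tau) {
    tr <- simulate_trajectory(one_cell(1.4e-4, tau), geom, acq)
    sr <- tr[tr$x > -30 & tr$x <= 170, ]
    pk <- which.max(sr$D_true[sr$x < 50])
    cav <- which(sr$x >= 50 & sr$x < 100)
    base <- cav[which.min(sr$D_true[cav])]
    stats::coef(stats::lm(D_true ~ x, sr[pk:base, ]))[["x"]]
  }
  expect_gt(abs(slope_after_peak(0.1)), abs(slope_after_peak(0.3)))
})

test_that("rendered discs have the right pixel area", {
  msk <- render_mask(list(x = 75, y = 0, a = 6, b = 6), acq, noise_sd = 0)
  area_px <- sum(mechanodc:::mask_logical(msk))
  expect_equal(area_px, pi * (6 / acq$pixel_size)^2,
               tolerance = 0.02)
})

test_that("rendering then refitting recovers the aspect ratio", {
  msk <- render_mask(list(x = 75, y = 0, a = 8, b = 4), acq, noise_sd = 0)
  fit <- fit_ellipse(msk, acq$pixel_size)
  expect_equal(fit$AR, 2, tolerance = 0.02)
  expect_equal(fit$a, 8, tolerance = 0.02)
  expect_equal(fit$b, 4, tolerance = 0.02)
})

test_that("mask rendering is deterministic under a fixed RNG state", {
  set.seed(9); m1 <- render_mask(list(x = 75, y = 0, a = 6, b = 6), acq, 0.5)
  set.seed(9); m2 <- render_mask(list(x = 75, y = 0, a = 6, b = 6), acq, 0.5)
  expect_identical(m1, m2)
  expect_error(render_mask(list(x = 75, y = 30, a = 6, b = 6), acq),
               "frame bounds")
})

test_that("noise-free mask area is conserved along a trajectory", {
  cfg <- phenotype_config("x", gain_mean = 1.4e-4, gain_sd = 0,
                          tau_mean = 0.14, tau_sd = 0,
                          boundary_noise_sd = 0)
  pop <- sample_population(cfg, 2, seed = 3, acq)
  ds <- generate_dataset(pop, geom, acq, seed = 3)
  for (id in pop$cell_id) {
    areas <- ds$detections$area[ds$detections$cell_id == id]
    expect_lt((max(areas) - min(areas)) / stats::median(areas), 0.03)
  }
})

test_that("datasets interleave cells and inject exact artifact counts", {
  ds <- small_dataset(n = 4, seed = 101)
  per_frame <- table(ds$detections$frame)
  expect_gt(max(per_frame), 1)  # overlapping transits share frames
  pop <- sample_population(default_phenotypes(), 10, seed = 11, acq)
  ds2 <- generate_dataset(pop, geom, acq,
                          artifact_config(impossible_fraction = 0.1),
                          seed = 11)
  expect_identical(sum(ds2$cells$is_artifact), 3L)  # round(0.1 * 30)
  expect_true(all(ds2$detections$x[ds2$detections$cell_id %in%
                                     ds2$cells$cell_id[ds2$cells$is_artifact]] > 25))
})

test_that("dataset generation is byte-identical under one seed", {
  pop <- sample_population(default_phenotypes(), 2, seed = 5, acq)
  d1 <- generate_dataset(pop, geom, acq, seed = 5)
  d2 <- generate_dataset(pop, geom, acq, seed = 5)
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
})
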