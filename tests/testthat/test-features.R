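geom <- channel_geometry()
acq <- acquisition_config()

test_that("moment ellipse fit recovers discs and axis-aligned ellipses", {
  expect_equal(fit_ellipse(raster_disc(30))$AR, 1, tolerance = 0.01)
  fit <- fit_ellipse(raster_ellipse(26, 13))
  expect_equal(fit$AR, 2, tolerance = 0.02)
  # brute-force second-moment oracle on the same raster
  idx <- which(raster_ellipse(26, 13), arr.ind = TRUE)
  mu20 <- mean((idx[, 2] - mean(idx[, 2]))^2) + 1 / 12
  mu02 <- mean((idx[, 1] - mean(idx[, 1]))^2) + 1 / 12
  expect_equal(fit$AR, sqrt(mu20 / mu02), tolerance = 1e-12)
  # rotating the shape 90 degrees swaps the channel-axis convention
  fit90 <- fit_ellipse(raster_ellipse(26, 13, angle = pi / 2))
  expect_equal(fit90$AR, 0.5, tolerance = 0.02)
})

test_that("ellipse fit rejects empty and fragmented masks", {
  expect_error(fit_ellipse(matrix(FALSE, 5, 5)), "empty")
  frag <- matrix(FALSE, 12, 12)
  frag[2:3, 2:3] <- TRUE; frag[9:10, 9:10] <- TRUE
  expect_error(fit_ellipse(frag), "components")
})

test_that("convex hull ratio matches an independent oracle", {
  expect_equal(convex_hull_ratio(raster_disc(25)), 1, tolerance = 0.01)
  expect_identical(convex_hull_ratio(matrix(TRUE, 1, 1)), 1)
  # crescent: disc of radius R bitten by a disc of radius 0.93 R centred on
  # its boundary; analytic hull/mask ratio from circular segment and lens
  # areas
  R <- 40; r <- 0.93 * R; d <- R
  size <- 2 * R + 9; cx <- (size + 1) / 2
  big <- raster_disc(R, size = size)
  bite <- outer(seq_len(size), seq_len(size),
                function(rr, cc) ((cc - cx - d)^2 + (rr - cx)^2) <= r^2)
  crescent <- big & !bite
  gamma <- acos(1 - r^2 / (2 * R^2))       # half-angle of the removed arc
  seg <- R^2 * (gamma - sin(gamma) * cos(gamma))
  d1 <- (d^2 - r^2 + R^2) / (2 * d)
  d2 <- d - d1
  lens <- R^2 * acos(d1 / R) - d1 * sqrt(R^2 - d1^2) +
    r^2 * acos(d2 / r) - d2 * sqrt(r^2 - d2^2)
  analytic <- (pi * R^2 - seg) / (pi * R^2 - lens)
  expect_gt(analytic, 1.25)
  expect_lt(analytic, 1.35)
  expect_equal(convex_hull_ratio(crescent), analytic, tolerance = 0.02)
  # pixel-count oracle via an independent point-in-polygon routine
  idx <- which(crescent, arr.ind = TRUE)
  hull <- grDevices::chull(idx[, 2], idx[, 1])
  grid <- expand.grid(r = seq_len(size), c = seq_len(size))
  inhull <- mgcv::in.out(cbind(c(idx[hull, 2], idx[hull[1], 2]),
                               c(idx[hull, 1], idx[hull[1], 1])),
                         cbind(grid$c, grid$r))
  oracle <- sum(inhull | crescent[cbind(grid$r, grid$c)]) / nrow(idx)
  expect_equal(convex_hull_ratio(crescent), oracle, tolerance = 0.005)
})

test_that("quality filters discard hull violations and radius outliers", {
  # 12 trajectories: 9 clean, 2 with one crescent frame, 1 radius outlier
  clean_masks <- rep(list(raster_disc(20)), 8)
  crescent <- {
    size <- 49; cx <- 25
    big <- raster_disc(20, size = size)
    bite <- outer(seq_len(size), seq_len(size),
                  function(r, c) ((c - cx - 20)^2 + (r - cx)^2) <= 18^2)
    big & !bite
  }
  expect_gt(convex_hull_ratio(crescent), 1.1)
  trajs <- c(
    lapply(1:9, function(i) disc_traj(20, n = 8)),
    lapply(1:2, function(i) {
      masks <- rep(list(raster_disc(20)), 8); masks[[4]] <- crescent
      make_shape_traj(masks)
    }),
    list(disc_traj(34, n = 8))  # far-out radius at ~4 population SD
  )
  names(trajs) <- sprintf("t%02d", 1:12)
  res <- apply_filters(trajs, acquisition = acq)
  expect_identical(length(res$kept), 9L)
  expect_setequal(res$discarded$reason, c("hull ratio", "radius outlier"))
  expect_identical(sum(res$discarded$reason == "hull ratio"), 2L)
  # order independence of the kept set
  perm <- sample(12)
  res2 <- apply_filters(trajs[perm], acquisition = acq)
  expect_setequal(names(res2$kept), names(res$kept))
  # all-clean set passes untouched
  res3 <- apply_filters(trajs[1:9], acquisition = acq)
  expect_identical(length(res3$kept), 9L)
})

test_that("a frame exactly at the hull threshold is kept", {
  tr <- disc_traj(20, n = 6)
  ratios <- vapply(tr$mask, convex_hull_ratio, numeric(1))
  res <- apply_filters(list(a = tr, b = disc_traj(20, n = 6)),
                       hull_threshold = max(ratios), acquisition = acq)
  expect_identical(length(res$kept), 2L)
})

test_that("region partition flags degenerate monotone series", {
  series <- tibble::tibble(x = seq(-30, 170, length.out = 40),
                           AR = seq(1, 2, length.out = 40))
  part <- partition_regions(series, geom)
  expect_true(part$degenerate)
})

test_that("relative deformability is baseline-anchored and shift-invariant", {
  series <- tibble::tibble(x = seq(-30, 170, length.out = 41),
                           AR = rep(1.2, 41))
  part <- partition_regions(series, geom)
  rd <- relative_deformability(series, part)
  expect_true(all(rd$rD == 0))
  expect_identical(rd$rD1, 0); expect_identical(rd$rD2, 0)
  # known sequence: rD1 by direct enumeration
  set.seed(4)
  ar <- 1 + 0.3 * exp(-((seq(-30, 170, length.out = 41) - 5) / 25)^2) +
    0.2 * exp(-((seq(-30, 170, length.out = 41) - 105) / 20)^2) +
    rnorm(41, 0, 0.005)
  s2 <- tibble::tibble(x = seq(-30, 170, length.out = 41), AR = ar)
  p2 <- partition_regions(s2, geom)
  rd2 <- relative_deformability(s2, p2)
  cavity <- s2$x >= 50 & s2$x < 100
  expect_equal(rd2$rD1,
               max(ar[p2$region == "R1"]) - min(ar[cavity]), tolerance = 1e-12)
  expect_equal(min(rd2$rD[cavity]), 0)
  # adding a constant to AR leaves rD unchanged
  s3 <- s2; s3$AR <- s3$AR + 0.37
  rd3 <- relative_deformability(s3, partition_regions(s3, geom))
  expect_equal(rd3$rD, rd2$rD, tolerance = 1e-12)
})

test_that("slope fitting is exact on lines and matches normal equations", {
  x <- seq(20, 60, length.out = 20)
  series <- tibble::tibble(x = x, AR = 1.5 - 8.71e-3 * x)
  expect_equal(fit_slope(series, 1, 20), -8.71e-3, tolerance = 1e-12)
  set.seed(2)
  series$AR <- series$AR + rnorm(20, 0, 0.01)
  xc <- series$x - mean(series$x)
  oracle <- sum(xc * series$AR) / sum(xc^2)
  expect_equal(fit_slope(series, 1, 20), oracle, tolerance = 1e-10)
  two <- tibble::tibble(x = c(1, 3), AR = c(1, 2))
  expect_identical(fit_slope(two, 1, 2), 0.5)
  expect_error(fit_slope(series, 5, 5), "2 points")
})

test_that("Hu moments are invariant to translation, scale and rotation", {
  coefs <- list(a = c(0.15, -0.08, 0.05, 0.02), b = c(-0.12, 0.06, -0.04, 0.03))
  base <- shape_moments(raster_blob(60, coefs))
  hu <- grep("^hu", names(base))
  shifted <- shape_moments(raster_blob(60, coefs, shift = c(17, -9),
                                       size = 2 * 75 + 40))
  expect_equal(shifted[hu], base[hu], tolerance = 1e-3)
  scaled <- shape_moments(raster_blob(60, coefs, scale = 2))
  expect_equal(scaled[hu], base[hu], tolerance = 1e-2)
  rotated <- shape_moments(raster_blob(60, coefs, angle = 37 * pi / 180))
  expect_equal(rotated[hu], base[hu], tolerance = 1e-2)
})

test_that("feature vectors have the documented base and extended sizes", {
  ds <- small_dataset(n = 4, seed = 101)
  tracked <- link_detections(ds$detections, 16)
  ct <- collect_trajectories(tracked, geom, ds$cells)
  fv <- derive_feature_vector(ct$trajectories[[1]], geom, acq)
  expect_identical(setdiff(names(fv), "degenerate"),
                   c("rD1", "rD2", "R2_slope", "R3_slope", "radius"))
  fv_ext <- derive_feature_vector(ct$trajectories[[1]], geom, acq,
                                  extended = TRUE)
  expect_identical(ncol(fv_ext) - ncol(fv), 30L)
  expect_true(all(is.finite(unlist(fv_ext[setdiff(names(fv_ext), "degenerate")]))))
  expect_gte(fv$rD1, 0); expect_gte(fv$rD2, 0)
})

test_that("zero-gain trajectories give zero deformability features", {
  cfg <- phenotype_config("flat", gain_mean = 0, gain_sd = 0,
                          tau_mean = 0.14, tau_sd = 0, boundary_noise_sd = 0)
  pop <- sample_population(cfg, 1, seed = 2, acq)
  ds <- generate_dataset(pop, geom, acq, seed = 2)
  fv <- derive_feature_vector(ds$detections, geom, acq)
  expect_lt(fv$rD1, 0.02)
  expect_lt(abs(fv$R2_slope), 5e-4)
})

test_that("padded sequences carry the four channels and a validity mask", {
  tr30 <- disc_traj(20, n = 30)
  tr50 <- disc_traj(20, n = 50)
  seqs <- prepare_sequences(list(a = tr30, b = tr50), geom, acq)
  expect_identical(dim(seqs$x), c(2L, 50L, 4L))
  expect_identical(sum(seqs$mask[1, ]), 30L)
  expect_true(all(seqs$x[1, 31:50, ] == 0))
  expect_identical(sum(seqs$mask[2, ]), 50L)
  expect_identical(dimnames(seqs$x)[[3]], c("AR", "perimeter", "rD", "area"))
  tr55 <- disc_traj(20, n = 55)
  expect_error(prepare_sequences(list(too_long = tr55), geom, acq),
               "too_long")
})

test_that("mask sequences materialise as (50, 96, 96, 2) tensors", {
  tr <- disc_traj(20, n = 30)
  ms <- prepare_mask_sequences(list(a = tr), geom, acq)
  tens <- mask_sequence_tensor(ms, 1)
  expect_identical(dim(tens), c(50L, 96L, 96L, 2L))
  ch1 <- tens[5, , , 1]; ch2 <- tens[5, , , 2]
  iou <- sum(ch1 & ch2) / sum(ch1 | ch2)
  expect_gte(iou, 0.95)
  expect_true(all(tens[31:50, , , ] == 0))
})
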