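geom <- channel_geometry()
acq <- acquisition_config()

test_that("a single clean cell yields one trajectory with every detection", {
  pop <- sample_population(default_phenotypes()[1, ], 1, seed = 8, acq)
  ds <- generate_dataset(pop, geom, acq, seed = 8)
  tracked <- link_detections(ds$detections, 16)
  expect_identical(length(unique(tracked$track_id)), 1L)
  expect_identical(nrow(tracked), nrow(ds$detections))
})

test_that("two staggered cells are linked exactly as an exhaustive oracle", {
  pop <- sample_population(default_phenotypes()[1:2, ], 1, seed = 12, acq)
  pop$entry_time <- c(0.001, 0.001 + 40 / acq$fps)  # 40-frame offset
  ds <- generate_dataset(pop, geom, acq, seed = 12)
  tracked <- link_detections(ds$detections, 16)
  # oracle: optimal frame-to-frame assignment by exhaustive enumeration of
  # the (at most 2x2) assignment alternatives, minimising total distance
  det <- dplyr::arrange(ds$detections, frame, x)
  frames <- unique(det$frame)
  oracle <- rep(NA_integer_, nrow(det))
  last_pos <- list(); next_id <- 0
  for (fr in frames) {
    rows <- which(det$frame == fr)
    k <- length(rows); m <- length(last_pos)
    best <- NULL; best_cost <- Inf
    perms <- if (m == 0) list(integer(0)) else
      lapply(seq_len(max(1, factorial(min(k, m)))), function(i) i)
    # enumerate all injective maps rows -> tracks (k, m <= 2)
    cand <- list()
    if (m >= 1 && k >= 1) {
      maps <- expand.grid(rep(list(0:m), k))
      for (r in seq_len(nrow(maps))) {
        mp <- as.integer(maps[r, ])
        if (anyDuplicated(mp[mp > 0])) next
        cost <- 0; feas <- TRUE
        for (j in seq_len(k)) {
          if (mp[j] > 0) {
            d <- sqrt((det$x[rows[j]] - last_pos[[mp[j]]]$x)^2 +
                        (det$y[rows[j]] - last_pos[[mp[j]]]$y)^2)
            if (d > 16 || det$x[rows[j]] - last_pos[[mp[j]]]$x < -1) {
              feas <- FALSE; break
            }
            cost <- cost + d
          } else cost <- cost + 1e3  # new track penalty
        }
        if (feas && cost < best_cost) { best_cost <- cost; best <- mp }
      }
    }
    if (is.null(best)) best <- rep(0L, k)
    new_last <- last_pos
    for (j in seq_len(k)) {
      if (best[j] > 0) {
        oracle[rows[j]] <- last_pos[[best[j]]]$id
        new_last[[best[j]]] <- list(x = det$x[rows[j]], y = det$y[rows[j]],
                                    id = last_pos[[best[j]]]$id)
      } else {
        next_id <- next_id + 1
        oracle[rows[j]] <- next_id
        new_last[[length(new_last) + 1]] <- list(x = det$x[rows[j]],
                                                 y = det$y[rows[j]],
                                                 id = next_id)
      }
    }
    last_pos <- new_last
  }
  tracked <- dplyr::arrange(tracked, frame, x)
  expect_identical(length(unique(tracked$track_id)), 2L)
  # same partition of detections as the oracle and as ground truth
  expect_true(all(tapply(oracle, tracked$track_id,
                         function(v) length(unique(v))) == 1))
  expect_true(all(tapply(tracked$cell_id, tracked$track_id,
                         function(v) length(unique(v))) == 1))
})

test_that("empty input produces empty output", {
  det <- tibble::tibble(frame = integer(), x = numeric(), y = numeric())
  out <- link_detections(det, 16)
  expect_identical(nrow(out), 0L)
  expect_true("track_id" %in% names(out))
})

test_that("mid-channel starts are rejected with a reason", {
  tr <- tibble::tibble(track_id = "t1",
                       frame = 1:20,
                       x = seq(60, 170, length.out = 20))
  val <- validate_trajectories(tr, geom)
  expect_false(val$keep)
  expect_identical(val$reason, "impossible start")
})

test_that("full-span trajectories are kept, truncated ones rejected", {
  full <- tibble::tibble(track_id = "a", frame = 1:40,
                         x = seq(-35, 172, length.out = 40))
  val <- validate_trajectories(full, geom)
  expect_true(val$keep)
  expect_true(is.na(val$reason))
  cut <- tibble::tibble(track_id = "b", frame = 1:30,
                        x = seq(-35, 90, length.out = 30))
  val2 <- validate_trajectories(cut, geom)
  expect_false(val2$keep)
  expect_identical(val2$reason, "incomplete span")
})

test_that("tracks plus discards account for all cells and artifacts", {
  pop <- sample_population(default_phenotypes(), 3, seed = 31, acq)
  ds <- generate_dataset(pop, geom, acq,
                         artifact_config(impossible_fraction = 0.2), seed = 31)
  tracked <- link_detections(ds$detections, 16)
  val <- validate_trajectories(tracked, geom)
  expect_identical(nrow(val), nrow(ds$cells))
  expect_identical(sum(!val$keep & val$reason == "impossible start"),
                   sum(ds$cells$is_artifact))
})
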