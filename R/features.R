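# Mechanotyping features from mask trajectories: shape series, R1-R4
# partition, relative deformability, relaxation/re-deformation slopes,
# optional region-wise moment descriptors, and model-ready sequences.

#' Per-frame shape series of one trajectory
#'
#' Fits an ellipse to every mask of a trajectory and returns the ordered
#' per-frame shape record used by all downstream features.
#'
#' @param traj Tibble of one cell's detections (columns `frame`, `mask`;
#'   optionally `t`), ordered or orderable by frame.
#' @param acquisition An [acquisition_config()] (pixel size, frame grid).
#' @return Tibble: `frame`, `x` (centroid, um), `AR`, `D` (= AR), `area`
#'   (um^2), `perimeter` (um), plus the mask list column.
#' @export
shape_series <- function(traj, acquisition = acquisition_config()) {
  stopifnot(is.data.frame(traj), nrow(traj) >= 1, "mask" %in% names(traj))
  traj <- dplyr::arrange(traj, .data$frame)
  px <- acquisition$pixel_size
  fits <- purrr::map(traj$mask, fit_ellipse, pixel_size = px,
                     check_connected = FALSE)
  # channel-axis centroids: dc_masks know their frame position, plain
  # matrices only their local pixel grid
  cx <- purrr::map_dbl(traj$mask, function(m) {
    if (inherits(m, "dc_mask")) mask_centroid_um(m, acquisition)[["x"]]
    else fit_ellipse(m, px, check_connected = FALSE)$centroid[["x"]]
  })
  tibble::tibble(
    frame = traj$frame,
    x = cx,
    AR = purrr::map_dbl(fits, "AR"),
    D = purrr::map_dbl(fits, "AR"),
    area = purrr::map_dbl(fits, "area"),
    perimeter = purrr::map_dbl(traj$mask, mask_perimeter_px) * px,
    mask = traj$mask
  )
}

#' Partition a shape series into the R1-R4 phases
#'
#' R1: deformation entering the first constriction (start to first peak);
#' R2: relaxation into the cavity (first peak to the cavity AR minimum);
#' R3: re-deformation entering the second constriction (cavity minimum to
#' second peak); R4: relaxation after it (second peak to end). The first
#' peak is the AR maximum before the cavity, the baseline is the AR
#' minimum over cavity frames, the second peak is the AR maximum
#' downstream of the baseline.
#'
#' @param series A [shape_series()] tibble (columns `x`, `AR`), covering
#'   the cavity.
#' @param geometry A [channel_geometry()] (region boundaries).
#' @return List: `peak1`, `baseline`, `peak2` (row indices), `region`
#'   (factor R1-R4 per row), `degenerate` (TRUE if R2 or R3 has < 2 rows).
#' @export
partition_regions <- function(series, geometry) {
  x <- series$x; ar <- series$AR
  if (any(diff(x) < -2)) {
    stop("series x positions are not ordered along the flow", call. = FALSE)
  }
  bounds <- step_positions(geometry)  # 0, 50, 100, 150
  cavity <- x >= bounds[2] & x < bounds[3]
  if (!any(cavity)) stop("series does not cover the cavity", call. = FALSE)
  win <- geometry$alignment_window
  pre <- x >= win[1] & x < bounds[2]
  if (!any(pre)) stop("series has no frames before the cavity", call. = FALSE)
  peak1 <- which(pre)[which.max(ar[pre])]
  baseline <- which(cavity)[which.min(ar[cavity])]
  post <- seq_along(x) >= baseline & x <= win[2]
  peak2 <- which(post)[which.max(ar[post])]
  region <- rep("R4", length(x))
  region[seq_len(peak1)] <- "R1"
  if (baseline > peak1) region[(peak1 + 1):baseline] <- "R2"
  if (peak2 > baseline) region[(baseline + 1):peak2] <- "R3"
  region <- factor(region, levels = c("R1", "R2", "R3", "R4"))
  list(peak1 = peak1, baseline = baseline, peak2 = peak2, region = region,
       degenerate = (baseline - peak1 <= 1) || (peak2 - baseline <= 1))
}

#' Relative deformability series
#'
#' rD(x) = AR(x) - min cavity AR, so rD = 0 at the cell's most relaxed
#' cavity shape and rD > 0 where it is stretched along the channel beyond
#' that. rD1 and rD2 are the maxima over the two deformation phases.
#'
#' @param series A [shape_series()] tibble.
#' @param partition Result of [partition_regions()] on the same series.
#' @return List: `rD` (vector, one per frame), `rD1`, `rD2`.
#' @export
relative_deformability <- function(series, partition) {
  base_ar <- series$AR[partition$baseline]
  rd <- series$AR - base_ar
  list(rD = rd,
       rD1 = max(rd[seq_len(partition$peak1)]),
       rD2 = max(rd[partition$baseline:partition$peak2]))
}

#' Least-squares slope of AR against axial position
#'
#' Ordinary least-squares slope of `AR` on `x` over a row range of a shape
#' series, in 1/um. The R2 slope (first peak to cavity baseline) describes
#' relaxation kinetics; the R3 slope (baseline to second peak) describes
#' re-deformation kinetics.
#'
#' @param series A [shape_series()] tibble.
#' @param start_idx,end_idx Inclusive row range (>= 2 rows).
#' @return Slope in 1/um.
#' @export
fit_slope <- function(series, start_idx, end_idx) {
  if (end_idx - start_idx < 1) stop("need at least 2 points for a slope", call. = FALSE)
  i <- start_idx:end_idx
  x <- series$x[i]; y <- series$AR[i]
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

#' Quality filters over a set of trajectories
#'
#' Discards a trajectory if any frame's convex-hull ratio exceeds
#' `hull_threshold` (strictly), or if its mean radius deviates from the
#' population mean radius by at least `radius_sd_limit` population
#' standard deviations. The radius rule is defined on the pooled set of
#' trajectories, so filtering is order-independent. Radii are derived from
#' the mask areas, r = sqrt(area / pi).
#'
#' @param trajectories Named list of trajectory tibbles (each with a
#'   `mask` column), e.g. `split(detections, detections$track_id)`.
#' @param hull_threshold Convex-hull ratio above which a frame flags the
#'   trajectory (default 1.1; a frame at exactly the threshold passes).
#' @param radius_sd_limit Number of population SDs at or beyond which the
#'   mean radius flags the trajectory (default 3).
#' @param acquisition An [acquisition_config()].
#' @return List: `kept` (list of trajectories), `discarded` (tibble
#'   `id`, `reason`), `counts` (tibble `reason`, `n`).
#' @export
apply_filters <- function(trajectories, hull_threshold = 1.1,
                          radius_sd_limit = 3,
                          acquisition = acquisition_config()) {
  stopifnot(is.list(trajectories), length(trajectories) >= 1)
  ids <- names(trajectories)
  if (is.null(ids)) ids <- as.character(seq_along(trajectories))
  px2 <- acquisition$pixel_size^2
  hull_bad <- purrr::map_lgl(trajectories, function(tr) {
    any(purrr::map_dbl(tr$mask, convex_hull_ratio) > hull_threshold)
  })
  mean_radius <- purrr::map_dbl(trajectories, function(tr) {
    mean(sqrt(purrr::map_dbl(tr$mask, ~ sum(mask_logical(.x))) * px2 / pi))
  })
  mu <- mean(mean_radius); sdv <- stats::sd(mean_radius)
  radius_bad <- if (is.na(sdv) || sdv == 0) {
    rep(FALSE, length(mean_radius))
  } else {
    abs(mean_radius - mu) >= radius_sd_limit * sdv
  }
  reason <- dplyr::case_when(
    hull_bad ~ "hull ratio",
    radius_bad ~ "radius outlier",
    TRUE ~ NA_character_
  )
  keep <- is.na(reason)
  list(
    kept = trajectories[keep],
    discarded = tibble::tibble(id = ids[!keep], reason = reason[!keep]),
    counts = dplyr::count(tibble::tibble(reason = reason[!keep]), .data$reason)
  )
}

#' Mechanotyping feature vector of one trajectory
#'
#' Base set: rD1, rD2 (dimensionless), R2 and R3 slopes (1/um) and mean
#' radius (um). With `extended = TRUE`, adds the normalised central and Hu
#' moments of the masks at the first peak (R1), the cavity baseline (R2)
#' and the second peak (R3): 30 additional values.
#'
#' @param traj A trajectory tibble (columns `frame`, `mask`).
#' @param geometry A [channel_geometry()].
#' @param acquisition An [acquisition_config()].
#' @param extended Include region-wise moment descriptors.
#' @return One-row tibble; degenerate partitions yield NA features with a
#'   `degenerate` flag.
#' @export
derive_feature_vector <- function(traj, geometry,
                                  acquisition = acquisition_config(),
                                  extended = FALSE) {
  series <- if (is.data.frame(traj) && all(c("AR", "x") %in% names(traj))) {
    traj
  } else {
    shape_series(traj, acquisition)
  }
  part <- partition_regions(series, geometry)
  rd <- relative_deformability(series, part)
  radius <- mean(sqrt(series$area / pi))
  if (part$degenerate) {
    out <- tibble::tibble(rD1 = NA_real_, rD2 = NA_real_,
                          R2_slope = NA_real_, R3_slope = NA_real_,
                          radius = radius, degenerate = TRUE)
  } else {
    out <- tibble::tibble(
      rD1 = rd$rD1, rD2 = rd$rD2,
      R2_slope = fit_slope(series, part$peak1, part$baseline),
      R3_slope = fit_slope(series, part$baseline, part$peak2),
      radius = radius, degenerate = FALSE
    )
  }
  if (extended) {
    anchors <- c(r1 = part$peak1, r2 = part$baseline, r3 = part$peak2)
    mm <- purrr::imap(anchors, function(i, nm) {
      v <- shape_moments(series$mask[[i]])
      stats::setNames(v, paste0(nm, "_", names(v)))
    })
    out <- dplyr::bind_cols(out, tibble::as_tibble(as.list(unlist(unname(mm)))))
  }
  out
}

#' Feature table for many trajectories
#'
#' Applies [derive_feature_vector()] to each trajectory and binds the
#' results, keyed by trajectory id (and phenotype label when present).
#'
#' @inheritParams derive_feature_vector
#' @param trajectories Named list of trajectory tibbles.
#' @return Tibble, one row per trajectory: `id`, optional `phenotype`,
#'   features.
#' @export
derive_features <- function(trajectories, geometry,
                            acquisition = acquisition_config(),
                            extended = FALSE) {
  ids <- names(trajectories)
  if (is.null(ids)) ids <- as.character(seq_along(trajectories))
  rows <- purrr::map(trajectories, derive_feature_vector, geometry = geometry,
                     acquisition = acquisition, extended = extended)
  out <- dplyr::bind_cols(tibble::tibble(id = ids), dplyr::bind_rows(rows))
  phen <- purrr::map_chr(trajectories, function(tr) {
    if ("phenotype" %in% names(tr)) tr$phenotype[1] else NA_character_
  })
  if (!all(is.na(phen))) out <- dplyr::mutate(out, phenotype = phen, .after = "id")
  out
}

#' Padded scalar sequences for recurrent models
#'
#' Builds the four per-frame channels (AR, perimeter, rD, area), clips each
#' trajectory to the alignment window, and post-pads with zeros to length
#' `max_len` with an explicit validity mask. Trajectories with more than
#' `max_len` in-window frames are an error.
#'
#' @param trajectories Named list of trajectory tibbles.
#' @param geometry A [channel_geometry()].
#' @param acquisition An [acquisition_config()].
#' @param max_len Padded sequence length (default 50).
#' @return A `dc_sequences`: list with `x` (array n x max_len x 4, channels
#'   AR, perimeter, rD, area), `mask` (n x max_len logical), `lengths`,
#'   `ids`, `phenotype` (NA when unknown).
#' @export
prepare_sequences <- function(trajectories, geometry,
                              acquisition = acquisition_config(),
                              max_len = 50) {
  ids <- names(trajectories)
  if (is.null(ids)) ids <- as.character(seq_along(trajectories))
  n <- length(trajectories)
  win <- geometry$alignment_window
  x <- array(0, c(n, max_len, 4),
             dimnames = list(NULL, NULL, c("AR", "perimeter", "rD", "area")))
  msk <- matrix(FALSE, n, max_len)
  lens <- integer(n)
  phen <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    series <- shape_series(trajectories[[i]], acquisition)
    part <- partition_regions(series, geometry)
    rd <- relative_deformability(series, part)$rD
    inwin <- series$x >= win[1] & series$x <= win[2]
    len <- sum(inwin)
    if (len > max_len) {
      stop(sprintf("trajectory '%s' has %d in-window frames (> %d)",
                   ids[i], len, max_len), call. = FALSE)
    }
    sel <- which(inwin)
    x[i, seq_len(len), 1] <- series$AR[sel]
    x[i, seq_len(len), 2] <- series$perimeter[sel]
    x[i, seq_len(len), 3] <- rd[sel]
    x[i, seq_len(len), 4] <- series$area[sel]
    msk[i, seq_len(len)] <- TRUE
    lens[i] <- len
    if ("phenotype" %in% names(trajectories[[i]])) {
      phen[i] <- trajectories[[i]]$phenotype[1]
    }
  }
  structure(list(x = x, mask = msk, lengths = lens, ids = ids,
                 phenotype = phen, max_len = max_len),
            class = "dc_sequences")
}

# place a mask crop centred in a crop x crop frame; error if it does not fit
center_mask_crop <- function(mask, crop) {
  m <- mask_logical(mask)
  idx <- which(m, arr.ind = TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  h <- r1 - r0 + 1; w <- c1 - c0 + 1
  if (h > crop || w > crop) stop("mask larger than crop", call. = FALSE)
  sub <- m[r0:r1, c0:c1, drop = FALSE]
  # centre on the centroid, clamped so the crop stays inside bounds
  cen_r <- mean(idx[, 1]); cen_c <- mean(idx[, 2])
  off_r <- max(1, min(crop - h + 1, round(crop / 2 - (cen_r - r0))))
  off_c <- max(1, min(crop - w + 1, round(crop / 2 - (cen_c - c0))))
  out <- matrix(FALSE, crop, crop)
  out[off_r:(off_r + h - 1), off_c:(off_c + w - 1)] <- sub
  out
}

# rasterise the fitted ellipse of a mask at the crop centre (channel 2)
rasterize_fit_ellipse <- function(fit, crop, pixel_size) {
  a_px <- fit$a / pixel_size; b_px <- fit$b / pixel_size
  th <- fit$orientation
  ctr <- (crop + 1) / 2
  g <- seq_len(crop) - ctr
  dx <- matrix(g, crop, crop, byrow = TRUE)
  dy <- matrix(g, crop, crop)
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / a_px)^2 + (v / b_px)^2 <= 1
}

# 4x4 (or pool x pool) average pooling by matrix projection
pool_matrix <- function(crop, pool) {
  stopifnot(crop %% pool == 0)
  out <- crop / pool
  P <- matrix(0, out, crop)
  for (i in seq_len(out)) P[i, ((i - 1) * pool + 1):(i * pool)] <- 1 / pool
  P
}

#' Padded two-channel mask-image sequences for convolutional-recurrent
#' models
#'
#' For every in-window frame: channel 1 is the binary mask centred in a
#' `crop` x `crop` frame; channel 2 is the rasterised moment-fit ellipse of
#' that mask. Sequences are post-padded with all-zero frames to `max_len`.
#' Full-resolution tensors are materialised on demand with
#' [mask_sequence_tensor()]; the object stores average-pooled frames
#' (factor `pool`) that the bundled sequence models consume.
#'
#' @inheritParams prepare_sequences
#' @param crop Crop side in pixels (default 96).
#' @param pool Average-pooling factor for the stored frames (default 4).
#' @return A `dc_mask_sequences`: `pooled` (list of T_i x (2*(crop/pool)^2)
#'   matrices), `mask` (n x max_len validity), `lengths`, `ids`,
#'   `phenotype`, plus geometry/acquisition context for materialisation.
#' @export
prepare_mask_sequences <- function(trajectories, geometry,
                                   acquisition = acquisition_config(),
                                   crop = 96, max_len = 50, pool = 4) {
  ids <- names(trajectories)
  if (is.null(ids)) ids <- as.character(seq_along(trajectories))
  n <- length(trajectories)
  win <- geometry$alignment_window
  P <- pool_matrix(crop, pool)
  side <- crop / pool
  pooled <- vector("list", n)
  msk <- matrix(FALSE, n, max_len)
  lens <- integer(n)
  phen <- rep(NA_character_, n)
  clipped <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- dplyr::arrange(trajectories[[i]], .data$frame)
    cx <- purrr::map_dbl(tr$mask, ~ mask_centroid_um(.x, acquisition)[["x"]])
    inwin <- cx >= win[1] & cx <= win[2]
    len <- sum(inwin)
    if (len > max_len) {
      stop(sprintf("trajectory '%s' has %d in-window frames (> %d)",
                   ids[i], len, max_len), call. = FALSE)
    }
    tr <- tr[inwin, , drop = FALSE]
    mat <- matrix(0, len, 2 * side^2)
    for (k in seq_len(len)) {
      ch1 <- center_mask_crop(tr$mask[[k]], crop)
      fit <- fit_ellipse(ch1, pixel_size = acquisition$pixel_size,
                         check_connected = FALSE)
      ch2 <- rasterize_fit_ellipse(fit, crop, acquisition$pixel_size)
      mat[k, ] <- c(P %*% ch1 %*% t(P), P %*% ch2 %*% t(P))
    }
    pooled[[i]] <- mat
    msk[i, seq_len(len)] <- TRUE
    lens[i] <- len
    clipped[[i]] <- tr
    if ("phenotype" %in% names(tr)) phen[i] <- tr$phenotype[1]
  }
  structure(list(pooled = pooled, mask = msk, lengths = lens, ids = ids,
                 phenotype = phen, crop = crop, pool = pool,
                 max_len = max_len, trajectories = clipped,
                 acquisition = acquisition),
            class = "dc_mask_sequences")
}

#' Materialise one trajectory's full-resolution image-sequence tensor
#'
#' @param ms A `dc_mask_sequences` from [prepare_mask_sequences()].
#' @param i Trajectory index.
#' @return Array (max_len, crop, crop, 2); padded frames are all zero.
#' @export
mask_sequence_tensor <- function(ms, i) {
  stopifnot(inherits(ms, "dc_mask_sequences"))
  tr <- ms$trajectories[[i]]
  out <- array(0, c(ms$max_len, ms$crop, ms$crop, 2))
  for (k in seq_len(ms$lengths[i])) {
    ch1 <- center_mask_crop(tr$mask[[k]], ms$crop)
    fit <- fit_ellipse(ch1, pixel_size = ms$acquisition$pixel_size,
                       check_connected = FALSE)
    out[k, , , 1] <- ch1
    out[k, , , 2] <- rasterize_fit_ellipse(fit, ms$crop, ms$acquisition$pixel_size)
  }
  out
}
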