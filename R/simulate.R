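# Synthetic trajectory and mask generation.
#
# Deformation model: a cell is an area-conserving ellipse whose aspect
# ratio D relaxes with first-order kinetics towards a stress-set
# equilibrium while being advected along the centreline,
#   dx/dt = v(x),   dD/dt = (D_eq(x) - D) / tau,
#   D_eq(x) = 1 + gain * [dv/dx]_+ + compression_ratio * gain * [dv/dx]_-,
# i.e. cells extend under positive velocity gradients and respond only
# weakly (ratio compression_ratio) to compressive ones, so they relax to a
# near-spherical shape in the cavity rather than deforming strongly in the
# perpendicular direction.

# ---- integrator -----------------------------------------------------------

# vectorised RK4 over many cells in cell-local time, starting at x_start.
# Returns list(t = substep times, x = steps x n matrix, D = steps x n).
integrate_cells <- function(gain, tau_ms, geometry, acquisition,
                            x_start = NULL, x_end = NULL,
                            compression_ratio = 0.06,
                            allow_substep_refinement = TRUE) {
  n <- length(gain)
  stopifnot(length(tau_ms) == n)
  if (is.null(x_start)) x_start <- geometry$alignment_window[1] - 10
  if (is.null(x_end)) x_end <- geometry$alignment_window[2] + 5
  tau_s <- tau_ms * 1e-3
  dt0 <- 1 / (acquisition$fps * acquisition$substeps)
  # RK4 on dD/dt = -(D - Deq)/tau is stable for dt/tau < 2.785; stay well inside
  required <- ceiling(dt0 / (0.5 * min(tau_s)))
  refine <- max(1L, required)
  if (refine > 1L && !allow_substep_refinement) {
    stop(sprintf(paste0("integration step %.3g s is unstable for tau = %.3g ms; ",
                        "increase substeps (need >= %d per frame)"),
                 dt0, min(tau_ms), acquisition$substeps * refine), call. = FALSE)
  }
  dt <- dt0 / refine
  v_fun <- function(x) centerline_velocity(geometry, acquisition$flow_rate, x)
  deq_fun <- function(x) {
    s <- stress_proxy(geometry, acquisition$flow_rate, x)
    1 + gain * pmax(s, 0) + compression_ratio * gain * pmin(s, 0)
  }
  # worst-case duration: slowest stretch is the inlet margin
  v_min <- min(v_fun(seq(x_start, x_end, length.out = 512)))
  max_steps <- ceiling((x_end - x_start) / (v_min * dt)) + 2L
  xs <- matrix(NA_real_, max_steps, n)
  ds <- matrix(NA_real_, max_steps, n)
  x <- rep(x_start, n); d <- rep(1, n)
  xs[1, ] <- x; ds[1, ] <- d
  step <- 1L
  while (any(x <= x_end) && step < max_steps) {
    k1x <- v_fun(x);            k1d <- (deq_fun(x) - d) / tau_s
    x2 <- x + dt / 2 * k1x
    k2x <- v_fun(x2);           k2d <- (deq_fun(x2) - (d + dt / 2 * k1d)) / tau_s
    x3 <- x + dt / 2 * k2x
    k3x <- v_fun(x3);           k3d <- (deq_fun(x3) - (d + dt / 2 * k2d)) / tau_s
    x4 <- x + dt * k3x
    k4x <- v_fun(x4);           k4d <- (deq_fun(x4) - (d + dt * k3d)) / tau_s
    x <- x + dt / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
    d <- d + dt / 6 * (k1d + 2 * k2d + 2 * k3d + k4d)
    step <- step + 1L
    xs[step, ] <- x; ds[step, ] <- d
  }
  if (any(!is.finite(d))) {
    stop("integration diverged; check gain/tau configuration", call. = FALSE)
  }
  list(t = (seq_len(step) - 1) * dt, x = xs[seq_len(step), , drop = FALSE],
       D = ds[seq_len(step), , drop = FALSE], dt = dt)
}

#' Simulate one cell's transit
#'
#' Integrates the advection/deformation dynamics for a single cell and
#' samples its true state at the acquisition frame times. The trajectory
#' starts upstream of the alignment window and ends past it, so a rendered
#' trajectory covers the full window.
#'
#' @param cell One-row tibble as returned by [sample_population()] (fields
#'   `radius`, `gain`, `tau`, `entry_time`; `entry_time` defaults to 0 if
#'   absent).
#' @param geometry A [channel_geometry()].
#' @param acquisition An [acquisition_config()].
#' @param compression_ratio Ratio of the response gain under compressive
#'   (negative) velocity gradients to the extensional gain.
#' @param allow_substep_refinement If `FALSE`, error instead of refining an
#'   unstable integration step.
#' @return A tibble with one row per frame: `frame` (global index), `t`
#'   (s), `x` (um), `D_true` (aspect ratio), semi-axes `a` (parallel) and
#'   `b` (perpendicular, um), satisfying a*b = radius^2 and a/b = D_true.
#' @export
simulate_trajectory <- function(cell, geometry, acquisition = acquisition_config(),
                                compression_ratio = 0.06,
                                allow_substep_refinement = TRUE) {
  stopifnot(nrow(cell) == 1)
  entry <- if ("entry_time" %in% names(cell)) cell$entry_time else 0
  path <- integrate_cells(cell$gain, cell$tau, geometry, acquisition,
                          compression_ratio = compression_ratio,
                          allow_substep_refinement = allow_substep_refinement)
  sample_path_frames(path, 1L, cell$radius, entry, acquisition)
}

# sample cell i of an integrate_cells() result at global frame times
sample_path_frames <- function(path, i, radius, entry_time, acquisition) {
  x_i <- path$x[, i]; d_i <- path$D[, i]
  keep <- is.finite(x_i)
  t_loc <- path$t[keep]; x_i <- x_i[keep]; d_i <- d_i[keep]
  t_end <- t_loc[length(t_loc)]
  j0 <- ceiling(entry_time * acquisition$fps)
  j1 <- floor((entry_time + t_end) * acquisition$fps)
  if (j1 < j0) return(empty_truth_tbl())
  j <- j0:j1
  u <- j / acquisition$fps - entry_time
  x_f <- stats::approx(t_loc, x_i, xout = u)$y
  d_f <- stats::approx(t_loc, d_i, xout = u)$y
  tibble::tibble(
    frame = as.integer(j), t = j / acquisition$fps,
    x = x_f, D_true = d_f,
    a = radius * sqrt(d_f), b = radius / sqrt(d_f)
  )
}

empty_truth_tbl <- function() {
  tibble::tibble(frame = integer(), t = numeric(), x = numeric(),
                 D_true = numeric(), a = numeric(), b = numeric())
}

# ---- mask rendering -------------------------------------------------------

# smooth periodic radial boundary perturbation, amplitude sd_px pixels
radial_noise_coefs <- function(sd_px, harmonics = 4) {
  if (sd_px <= 0) return(NULL)
  list(a = stats::rnorm(harmonics, 0, sd_px / sqrt(harmonics)),
       b = stats::rnorm(harmonics, 0, sd_px / sqrt(harmonics)))
}

#' Render a binary mask of an elliptical cell state
#'
#' Rasterises the ellipse with semi-axis `a` along the channel axis and `b`
#' perpendicular, centred at (`x`, `y`) um, onto the global pixel grid of
#' the acquisition frame. An optional smooth radial boundary perturbation
#' (truncated Fourier series, Gaussian coefficients, total amplitude
#' `noise_sd` pixels) emulates segmentation noise. Uses the current RNG
#' state, so it is deterministic under a fixed seed.
#'
#' @param state A one-row data frame (or list) with `x`, `a`, `b` in um and
#'   optionally `y` (default 0).
#' @param acquisition An [acquisition_config()].
#' @param noise_sd Boundary perturbation amplitude in pixels.
#' @return A `dc_mask`: list with `px` (raw matrix, rows = y, cols = x; 1 =
#'   inside), `origin` = c(row, col) 0-based offset of the crop in the full
#'   frame, and `pixel_size`.
#' @export
render_mask <- function(state, acquisition = acquisition_config(), noise_sd = 0) {
  px <- acquisition$pixel_size
  cx <- state$x; cy <- if (!is.null(state$y)) state$y else 0
  a <- state$a; b <- state$b
  stopifnot(a > 0, b > 0)
  W <- acquisition$frame_size[1]; H <- acquisition$frame_size[2]
  # pixel centres: col c -> frame_origin_x + (c - 0.5) px ; row r -> (r - (H+1)/2) px
  pad <- 3 * max(noise_sd, 1) * px
  c0 <- floor((cx - a - pad - acquisition$frame_origin_x) / px + 0.5)
  c1 <- ceiling((cx + a + pad - acquisition$frame_origin_x) / px + 0.5)
  r0 <- floor((cy - b - pad) / px + (H + 1) / 2)
  r1 <- ceiling((cy + b + pad) / px + (H + 1) / 2)
  if (r0 < 1 || r1 > H || c0 < 1 || c1 > W) {
    stop("ellipse exceeds frame bounds", call. = FALSE)
  }
  cols <- c0:c1; rows <- r0:r1
  xg <- acquisition$frame_origin_x + (cols - 0.5) * px - cx
  yg <- (rows - (H + 1) / 2) * px - cy
  dx <- matrix(xg, length(rows), length(cols), byrow = TRUE)
  dy <- matrix(yg, length(rows), length(cols))
  q <- sqrt((dx / a)^2 + (dy / b)^2)  # normalised elliptical radius
  if (noise_sd > 0) {
    nz <- radial_noise_coefs(noise_sd)
    theta <- atan2(dy, dx)
    delta <- matrix(0, nrow(q), ncol(q))
    for (m in seq_along(nz$a)) {
      delta <- delta + nz$a[m] * cos(m * theta) + nz$b[m] * sin(m * theta)
    }
    # boundary distance at angle theta (um), for converting px noise to q units
    rho <- 1 / sqrt((cos(theta) / a)^2 + (sin(theta) / b)^2)
    q <- q - delta * px / rho
  }
  inside <- q <= 1
  m <- matrix(as.raw(inside), nrow(inside), ncol(inside))
  structure(list(px = m, origin = c(r0 - 1L, c0 - 1L), pixel_size = px),
            class = "dc_mask")
}

# logical view of a dc_mask (or plain logical matrix)
mask_logical <- function(mask) {
  if (inherits(mask, "dc_mask")) {
    m <- mask$px
    out <- m != as.raw(0)
    dim(out) <- dim(m)
    out
  } else if (is.matrix(mask)) {
    mask != 0
  } else {
    stop("not a mask", call. = FALSE)
  }
}

# centroid (x, y) in um of a dc_mask on the global frame grid
mask_centroid_um <- function(mask, acquisition) {
  m <- mask_logical(mask)
  idx <- which(m, arr.ind = TRUE)
  px <- acquisition$pixel_size
  H <- acquisition$frame_size[2]
  row_g <- idx[, 1] + mask$origin[1]
  col_g <- idx[, 2] + mask$origin[2]
  c(x = acquisition$frame_origin_x + (mean(col_g) - 0.5) * px,
    y = (mean(row_g) - (H + 1) / 2) * px)
}

# carve a circular bite out of a mask boundary (concave-artifact frames)
make_concave <- function(mask, bite_frac = 0.6) {
  m <- mask_logical(mask)
  idx <- which(m, arr.ind = TRUE)
  cr <- mean(idx[, 1]); cc <- mean(idx[, 2])
  # bite centred on the rightmost boundary point
  bp <- idx[which.max(idx[, 2]), ]
  r_eq <- sqrt(nrow(idx) / pi)
  rb <- bite_frac * r_eq
  d2 <- (idx[, 1] - bp[1])^2 + (idx[, 2] - bp[2])^2
  m[idx[d2 <= rb^2, , drop = FALSE]] <- FALSE
  out <- mask
  out$px <- matrix(as.raw(m), nrow(m), ncol(m))
  out
}

# ---- dataset generation ---------------------------------------------------

#' Dataset artifact injection settings
#'
#' @param impossible_fraction Fraction of the population size injected as
#'   extra trajectories that first appear mid-channel (exercises the
#'   impossible-start filter). Count is `round(fraction * n_cells)`.
#' @param concave_fraction Fraction of cells that get one concave
#'   (crescent) mask frame (exercises the convex-hull filter).
#' @return An `dc_artifacts` list.
#' @export
artifact_config <- function(impossible_fraction = 0, concave_fraction = 0) {
  stopifnot(impossible_fraction >= 0, concave_fraction >= 0)
  structure(list(impossible_fraction = impossible_fraction,
                 concave_fraction = concave_fraction),
            class = "dc_artifacts")
}

#' Generate a synthetic mask dataset
#'
#' Integrates every cell in `population` through the channel, renders a
#' binary mask per frame on the shared acquisition clock (cells interleave
#' according to their entry times, so frames may contain several cells),
#' and optionally injects mid-channel-start trajectories and concave mask
#' frames. Fully deterministic given `seed` (per-cell noise streams are
#' keyed by `cell_seed` from [sample_population()]).
#'
#' @param population Tibble from [sample_population()].
#' @param geometry A [channel_geometry()].
#' @param acquisition An [acquisition_config()].
#' @param artifacts An [artifact_config()].
#' @param compression_ratio See [simulate_trajectory()].
#' @param seed Integer seed for artifact placement.
#' @return A `dc_dataset`: list with `detections` (tibble: `frame`, `t`,
#'   `cell_id` (ground truth), `x`, `y`, `area` in um^2, `mask` list
#'   column), `truth` (per cell per frame true state), `cells` (population
#'   incl. injected artifacts, with `is_artifact` flag), and the configs.
#' @export
generate_dataset <- function(population, geometry,
                             acquisition = acquisition_config(),
                             artifacts = artifact_config(),
                             compression_ratio = 0.06,
                             seed = 1) {
  stopifnot(is.data.frame(population), nrow(population) >= 1)
  set.seed(as.integer(seed))
  n <- nrow(population)
  cells <- population
  cells$is_artifact <- FALSE
  # injected impossible trajectories: clones that first appear mid-channel
  n_imp <- round(artifacts$impossible_fraction * n)
  if (n_imp > 0) {
    src <- cells[sample.int(n, n_imp, replace = TRUE), ]
    src$cell_id <- sprintf("artifact_%03d", seq_len(n_imp))
    src$entry_time <- max(cells$entry_time) +
      cumsum(stats::rexp(n_imp, acquisition$arrival_rate))
    src$cell_seed <- sample.int(.Machine$integer.max - 1L, n_imp)
    src$is_artifact <- TRUE
    src$start_x <- stats::runif(n_imp, 30, 120)
    cells <- dplyr::bind_rows(cells, src)
  }
  if (!"start_x" %in% names(cells)) cells$start_x <- NA_real_
  n_conc <- round(artifacts$concave_fraction * n)
  concave_ids <- if (n_conc > 0) sample(population$cell_id, n_conc) else character()
  cells$y_offset <- stats::rnorm(nrow(cells), 0, 0.8)

  path <- integrate_cells(cells$gain, cells$tau, geometry, acquisition,
                          compression_ratio = compression_ratio)
  det_list <- vector("list", nrow(cells))
  truth_list <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    tr <- sample_path_frames(path, i, ci$radius, ci$entry_time, acquisition)
    if (!is.na(ci$start_x)) tr <- tr[tr$x >= ci$start_x, , drop = FALSE]
    if (nrow(tr) == 0) next
    tr$y <- ci$y_offset
    set.seed(ci$cell_seed)
    concave_frame <- if (ci$cell_id %in% concave_ids) {
      tr$frame[max(2L, round(nrow(tr) * 0.35))]
    } else NA_integer_
    nf <- nrow(tr)
    masks <- vector("list", nf)
    cx <- cy <- ar <- rep(NA_real_, nf)
    ok <- rep(TRUE, nf)
    for (k in seq_len(nf)) {
      msk <- tryCatch(
        render_mask(list(x = tr$x[k], y = ci$y_offset, a = tr$a[k], b = tr$b[k]),
                    acquisition, noise_sd = ci$boundary_noise_sd),
        error = function(e) NULL
      )
      if (is.null(msk)) { ok[k] <- FALSE; next }
      if (!is.na(concave_frame) && tr$frame[k] == concave_frame) {
        msk <- make_concave(msk)
      }
      cen <- mask_centroid_um(msk, acquisition)
      masks[[k]] <- msk
      cx[k] <- cen[["x"]]; cy[k] <- cen[["y"]]
      ar[k] <- sum(mask_logical(msk)) * acquisition$pixel_size^2
    }
    det_list[[i]] <- tibble::tibble(
      frame = tr$frame[ok], t = tr$t[ok], cell_id = ci$cell_id,
      x = cx[ok], y = cy[ok], area = ar[ok], mask = masks[ok]
    )
    tr$cell_id <- ci$cell_id
    truth_list[[i]] <- tr[ok, , drop = FALSE]
  }
  detections <- dplyr::arrange(dplyr::bind_rows(det_list), .data$frame, .data$x)
  truth <- dplyr::bind_rows(truth_list)
  structure(
    list(detections = detections, truth = truth, cells = cells,
         geometry = geometry, acquisition = acquisition,
         artifacts = artifacts, seed = as.integer(seed)),
    class = "dc_dataset"
  )
}

#' @export
print.dc_dataset <- function(x, ...) {
  cat(sprintf("<dc_dataset> %d cells (%d injected artifacts), %d detections over %d frames\n",
              nrow(x$cells), sum(x$cells$is_artifact), nrow(x$detections),
              length(unique(x$detections$frame))))
  invisible(x)
}

#' Plot true deformation traces of a dataset
#'
#' @param object A `dc_dataset`.
#' @param n Maximum number of cells to draw.
#' @param ... Unused.
#' @return A ggplot of true aspect ratio vs axial position.
#' @export
autoplot.dc_dataset <- function(object, n = 50, ...) {
  ids <- utils::head(unique(object$truth$cell_id), n)
  df <- dplyr::inner_join(
    dplyr::filter(object$truth, .data$cell_id %in% ids),
    dplyr::select(object$cells, "cell_id", "phenotype"), by = "cell_id"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$D_true, group = .data$cell_id,
                                   colour = .data$phenotype)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "axial position x (um)", y = "aspect ratio (true)")
}
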