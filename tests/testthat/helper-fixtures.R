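# Shared fixtures, built in code. Expensive simulated datasets are cached
# in this environment so several test files can reuse them within one run.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# rasterise a disc on a pixel grid (continuous definition -> raster)
raster_disc <- function(r_px, size = 2 * ceiling(r_px) + 7,
                        cx = (size + 1) / 2, cy = (size + 1) / 2) {
  outer(seq_len(size), seq_len(size),
        function(r, c) ((c - cx)^2 + (r - cy)^2) <= r_px^2)
}

# rasterise an ellipse with semi-axes (a_px along x, b_px along y),
# rotated by `angle` radians
raster_ellipse <- function(a_px, b_px, angle = 0,
                           size = 2 * ceiling(max(a_px, b_px)) + 9,
                           cx = (size + 1) / 2, cy = (size + 1) / 2) {
  outer(seq_len(size), seq_len(size), function(r, c) {
    dx <- c - cx; dy <- r - cy
    u <- dx * cos(angle) + dy * sin(angle)
    v <- -dx * sin(angle) + dy * cos(angle)
    (u / a_px)^2 + (v / b_px)^2 <= 1
  })
}

# smooth asymmetric blob from a truncated Fourier radial function;
# translate/rotate/scale act on the continuous definition so the raster is
# an independent high-resolution oracle of the transformed shape
raster_blob <- function(r_px, coefs, angle = 0, scale = 1,
                        shift = c(0, 0), size = NULL) {
  rmax <- r_px * scale * (1 + sum(abs(unlist(coefs))) + 0.1)
  if (is.null(size)) size <- 2 * ceiling(rmax) + 11
  cx <- (size + 1) / 2 + shift[1]; cy <- (size + 1) / 2 + shift[2]
  outer(seq_len(size), seq_len(size), function(r, c) {
    dx <- c - cx; dy <- r - cy
    th <- atan2(dy, dx) - angle
    rho <- r_px * scale *
      (1 + Reduce(`+`, lapply(seq_along(coefs$a), function(m) {
        coefs$a[m] * cos(m * th) + coefs$b[m] * sin(m * th)
      })))
    dx^2 + dy^2 <= rho^2
  })
}

# wrap a logical matrix as a dc_mask positioned so its centroid sits near
# x_um on the default acquisition frame grid
as_dc_mask <- function(m, x_um, acq = acquisition_config(), row0 = 55L) {
  col0 <- as.integer(round((x_um - acq$frame_origin_x) / acq$pixel_size -
                             ncol(m) / 2))
  structure(list(px = matrix(as.raw(m), nrow(m), ncol(m)),
                 origin = c(row0, col0), pixel_size = acq$pixel_size),
            class = "dc_mask")
}

# synthetic trajectory of given per-frame shapes marching across the
# alignment window
make_shape_traj <- function(masks, x_from = -28, x_to = 168,
                            acq = acquisition_config()) {
  n <- length(masks)
  xs <- seq(x_from, x_to, length.out = n)
  tibble::tibble(
    frame = seq_len(n),
    mask = lapply(seq_len(n), function(i) as_dc_mask(masks[[i]], xs[i], acq))
  )
}

# trajectory of n identical discs (radius r_px)
disc_traj <- function(r_px = 20, n = 30, ...) {
  make_shape_traj(rep(list(raster_disc(r_px)), n), ...)
}

# small cached default dataset (3 phenotypes x n cells)
small_dataset <- function(n = 4, seed = 101) {
  cache_fixture(sprintf("small_ds_%d_%d", n, seed), function() {
    geom <- channel_geometry()
    acq <- acquisition_config()
    pop <- sample_population(default_phenotypes(), n, seed, acq)
    generate_dataset(pop, geom, acq, seed = seed)
  })
}

# two-phenotype (hl60 vs hl60d, morphology-matched) classification fixture:
# trajectories, features, sequences, mask sequences and the generating
# population. n_per_class cells per phenotype.
two_class_fixture <- function(n_per_class = 400, seed = 21) {
  cache_fixture(sprintf("two_class_%d_%d", n_per_class, seed), function() {
    geom <- channel_geometry()
    acq <- acquisition_config()
    cfg <- default_phenotypes()[1:2, ]
    pop <- sample_population(cfg, n_per_class, seed, acq)
    ds <- generate_dataset(pop, geom, acq, seed = seed)
    tracked <- link_detections(ds$detections, 16)
    ct <- collect_trajectories(tracked, geom, ds$cells)
    filt <- apply_filters(ct$trajectories, acquisition = acq)
    feats <- derive_features(filt$kept, geom, acq)
    list(geom = geom, acq = acq, configs = cfg, population = pop,
         dataset = ds, trajectories = filt$kept, features = feats)
  })
}

# binomial 95% confidence band around chance for a test set of size n
chance_band <- function(n) 0.5 + c(-1, 1) * 1.96 * sqrt(0.25 / n)
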