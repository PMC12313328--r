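#' Phenotype generative configuration
#'
#' One row per phenotype. Each cell of a phenotype draws its radius,
#' deformation gain and relaxation time from truncated normal distributions
#' with these means and standard deviations.
#'
#' The deformation gain `gain` (seconds) maps the local velocity gradient
#' dv/dx (1/s) to the equilibrium aspect ratio, AR_eq = 1 + gain * dv/dx;
#' the relaxation time `tau` (ms) sets how fast the cell approaches that
#' equilibrium. Neither is an estimate of a physical constant of any real
#' cell line; they are generative knobs chosen so the synthetic populations
#' reproduce the qualitative mechanotype ordering of
#' cytochalasin-D-treated > untreated > nocodazole-treated HL60-like cells
#' (higher gain / shorter tau = more deformable and faster responding).
#'
#' @param name Phenotype label.
#' @param gain_mean,gain_sd Deformation gain (s).
#' @param tau_mean,tau_sd Relaxation time (ms).
#' @param radius_mean,radius_sd Cell radius (um); `radius_sd` must be
#'   below `radius_mean / 3`.
#' @param boundary_noise_sd Mask boundary perturbation amplitude (pixels).
#' @param abundance Population fraction (abundances are normalised when a
#'   population is sampled).
#' @return A one-row tibble.
#' @export
phenotype_config <- function(name,
                             gain_mean, gain_sd,
                             tau_mean, tau_sd,
                             radius_mean = 6, radius_sd = 0.45,
                             boundary_noise_sd = 0.4,
                             abundance = 1) {
  if (gain_mean < 0) stop("gain_mean must be >= 0", call. = FALSE)
  if (tau_mean <= 0) stop("tau_mean must be > 0", call. = FALSE)
  if (radius_sd >= radius_mean / 3) {
    stop("radius_sd must be below radius_mean / 3", call. = FALSE)
  }
  if (abundance <= 0) stop("abundance must be positive", call. = FALSE)
  tibble::tibble(
    name = as.character(name),
    gain_mean = gain_mean, gain_sd = gain_sd,
    tau_mean = tau_mean, tau_sd = tau_sd,
    radius_mean = radius_mean, radius_sd = radius_sd,
    boundary_noise_sd = boundary_noise_sd,
    abundance = abundance
  )
}

#' Default three-phenotype population
#'
#' Emulates untreated HL60-like cells plus an actin-perturbed (more
#' deformable, faster-relaxing, "hl60d") and a microtubule-perturbed (less
#' deformable, slower, more variable, "hl60n") treatment, with near
#' identical radius distributions so that classification cannot lean on
#' size.
#'
#' @return A tibble with one row per phenotype (see [phenotype_config()]).
#' @export
default_phenotypes <- function() {
  dplyr::bind_rows(
    phenotype_config("hl60", gain_mean = 1.4e-4, gain_sd = 2.0e-5,
                     tau_mean = 0.14, tau_sd = 0.025),
    phenotype_config("hl60d", gain_mean = 2.1e-4, gain_sd = 2.5e-5,
                     tau_mean = 0.10, tau_sd = 0.018),
    phenotype_config("hl60n", gain_mean = 0.9e-4, gain_sd = 2.5e-5,
                     tau_mean = 0.19, tau_sd = 0.040, radius_sd = 0.55)
  )
}

check_phenotype_configs <- function(configs) {
  need <- c("name", "gain_mean", "gain_sd", "tau_mean", "tau_sd",
            "radius_mean", "radius_sd", "boundary_noise_sd", "abundance")
  if (!is.data.frame(configs) || !all(need %in% names(configs))) {
    stop("phenotype configs must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(configs$gain_mean < 0) || any(configs$tau_mean <= 0) ||
      any(configs$radius_mean <= 0) || any(configs$abundance <= 0)) {
    stop("invalid phenotype config values", call. = FALSE)
  }
  if (any(configs$radius_sd >= configs$radius_mean / 3)) {
    stop("radius_sd must be below radius_mean / 3", call. = FALSE)
  }
  if (anyDuplicated(configs$name)) stop("duplicate phenotype names", call. = FALSE)
  invisible(configs)
}

#' Acquisition configuration
#'
#' Frame rate, optics and flow settings of the virtual high-speed camera.
#' Defaults mirror a 11000 fps recording at 0.26 um/pixel with a field of
#' view that covers the full channel plus margins, at a core flow rate of
#' 1 uL/min.
#'
#' @param fps Frame rate (frames per second).
#' @param pixel_size Pixel size (um/pixel).
#' @param frame_size Field of view in pixels, c(width, height).
#' @param frame_origin_x x-position (um) of the left edge of the frame.
#' @param flow_rate Core flow rate (uL/min).
#' @param substeps Integrator substeps per frame interval (>= 10 advised).
#' @param arrival_rate Mean cell arrivals per second (sets how often two
#'   cells share a frame).
#' @return A `dc_acquisition` object.
#' @export
acquisition_config <- function(fps = 11000, pixel_size = 0.26,
                               frame_size = c(880, 140),
                               frame_origin_x = -45,
                               flow_rate = 1, substeps = 10,
                               arrival_rate = 400) {
  if (fps <= 0 || pixel_size <= 0) {
    stop("fps and pixel_size must be positive", call. = FALSE)
  }
  if (substeps < 1) stop("substeps must be >= 1", call. = FALSE)
  structure(
    list(fps = fps, pixel_size = pixel_size,
         frame_size = as.integer(frame_size),
         frame_origin_x = frame_origin_x,
         flow_rate = flow_rate, substeps = as.integer(substeps),
         arrival_rate = arrival_rate),
    class = "dc_acquisition"
  )
}

#' @export
print.dc_acquisition <- function(x, ...) {
  cat(sprintf("<dc_acquisition> %g fps, %g um/px, frame %dx%d px, %g uL/min\n",
              x$fps, x$pixel_size, x$frame_size[1], x$frame_size[2], x$flow_rate))
  invisible(x)
}

# truncated-at-zero normal draws (redraw; sd may be 0)
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Sample a synthetic cell population
#'
#' Draws per-cell generative parameters for each phenotype. Deterministic
#' given `seed`; each cell also receives a private `cell_seed` so that
#' downstream stochastic steps (mask noise) are reproducible per cell
#' regardless of processing order.
#'
#' @param configs Phenotype configuration tibble (rows as in
#'   [phenotype_config()]).
#' @param n_per_phenotype Cells per phenotype; a single number or one per
#'   config row.
#' @param seed Integer seed.
#' @param acquisition Acquisition config (sets arrival rate for entry
#'   times).
#' @return A tibble with one row per cell: `cell_id`, `phenotype`,
#'   `radius` (um), `gain` (s), `tau` (ms), `entry_time` (s), `cell_seed`.
#' @export
sample_population <- function(configs, n_per_phenotype, seed,
                              acquisition = acquisition_config()) {
  check_phenotype_configs(configs)
  if (any(n_per_phenotype < 1)) stop("n_per_phenotype must be >= 1", call. = FALSE)
  n <- rep_len(as.integer(n_per_phenotype), nrow(configs))
  set.seed(as.integer(seed))
  cells <- purrr::pmap_dfr(
    cbind(configs, .n = n),
    function(name, gain_mean, gain_sd, tau_mean, tau_sd, radius_mean,
             radius_sd, boundary_noise_sd, abundance, .n) {
      tibble::tibble(
        phenotype = name,
        radius = rtruncnorm_pos(.n, radius_mean, radius_sd),
        gain = pmax(0, stats::rnorm(.n, gain_mean, gain_sd)),
        tau = rtruncnorm_pos(.n, tau_mean, tau_sd),
        boundary_noise_sd = boundary_noise_sd
      )
    }
  )
  total <- nrow(cells)
  # exponential inter-arrival times; cells enter in a random phenotype order
  ord <- sample.int(total)
  gaps <- stats::rexp(total, rate = acquisition$arrival_rate)
  entry <- cumsum(gaps)
  cells <- cells[ord, ]
  cells$entry_time <- entry
  cells$cell_id <- sprintf("cell_%04d", seq_len(total))
  cells$cell_seed <- sample.int(.Machine$integer.max - 1L, total)
  stopifnot(all(is.finite(cells$radius)), all(is.finite(cells$gain)),
            all(is.finite(cells$tau)))
  dplyr::select(cells, "cell_id", "phenotype", "radius", "gain", "tau",
                "entry_time", "boundary_noise_sd", "cell_seed")
}
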