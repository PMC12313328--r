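#' Undulating channel geometry
#'
#' Defines the constriction-cavity-constriction channel: three consecutive
#' sub-regions (defaults 50/50/50 um long and 25/50/25 um wide, 20 um high)
#' preceded by a wide inlet and followed by a wide outlet. The axial
#' coordinate x is in micrometres, x = 0 at the entrance of the first
#' constriction and increasing along the flow direction, so under defaults
#' the cavity spans x in [50, 100).
#'
#' `transition_scale` is the 10-90% width (um) of the smooth logistic step
#' between neighbouring region widths. `velocity_scale` is the dimensionless
#' factor relating centreline velocity to the plug-flow estimate
#' flow_rate / (width x height); its default is calibrated so that a tracer
#' at the default flow rate crosses the alignment window in about 46 frames
#' at 11000 fps (about 27 frames over the 150 um channel proper).
#'
#' @param region_lengths Lengths (um) of the three sub-regions.
#' @param region_widths Widths (um) of the three sub-regions.
#' @param height Channel height (um).
#' @param inlet_effective_width Effective centreline width (um) used for
#'   x < 0 and past the outlet.
#' @param transition_scale 10-90% width (um) of each logistic width step.
#' @param alignment_window Axial interval (um) that a usable trajectory
#'   must cover; also the interval sequences are clipped to.
#' @param velocity_scale Dimensionless centreline velocity factor.
#' @param velocity_transition_scale 10-90% width (um) of the velocity
#'   (not width) transitions: the centreline flow develops over a length
#'   comparable to the channel width, so the velocity profile is smoother
#'   than the wall geometry. Gives the smooth V-shaped dv/dx profile
#'   through the cavity with its zero crossing at the cavity midpoint.
#' @return A `dc_geometry` object (list with the fields above).
#' @examples
#' geom <- channel_geometry()
#' width_profile(geom, c(25, 75, 125))
#' @export
channel_geometry <- function(region_lengths = c(50, 50, 50),
                             region_widths = c(25, 50, 25),
                             height = 20,
                             inlet_effective_width = 80,
                             transition_scale = 10,
                             alignment_window = c(-30, 170),
                             velocity_scale = 2.58,
                             velocity_transition_scale = 22) {
  stopifnot(length(region_lengths) == 3, length(region_widths) == 3)
  if (any(region_lengths <= 0) || any(region_widths <= 0)) {
    stop("region lengths and widths must be positive", call. = FALSE)
  }
  if (transition_scale <= 0) stop("transition_scale must be positive", call. = FALSE)
  if (velocity_transition_scale <= 0) {
    stop("velocity_transition_scale must be positive", call. = FALSE)
  }
  if (height <= 0) stop("height must be positive", call. = FALSE)
  if (inlet_effective_width <= 0) stop("inlet_effective_width must be positive", call. = FALSE)
  stopifnot(length(alignment_window) == 2, alignment_window[1] < alignment_window[2])
  structure(
    list(
      region_lengths = as.numeric(region_lengths),
      region_widths = as.numeric(region_widths),
      height = as.numeric(height),
      inlet_effective_width = as.numeric(inlet_effective_width),
      transition_scale = as.numeric(transition_scale),
      alignment_window = as.numeric(alignment_window),
      velocity_scale = as.numeric(velocity_scale),
      velocity_transition_scale = as.numeric(velocity_transition_scale)
    ),
    class = "dc_geometry"
  )
}

#' @export
print.dc_geometry <- function(x, ...) {
  cat("<dc_geometry>\n")
  cat(sprintf("  regions: %s um long, %s um wide, height %g um\n",
              paste(x$region_lengths, collapse = "/"),
              paste(x$region_widths, collapse = "/"), x$height))
  cat(sprintf("  inlet/outlet effective width: %g um, transition 10-90%% width: %g um\n",
              x$inlet_effective_width, x$transition_scale))
  cat(sprintf("  alignment window: [%g, %g] um, velocity scale: %g\n",
              x$alignment_window[1], x$alignment_window[2], x$velocity_scale))
  invisible(x)
}

# x-positions of the width steps: inlet->R1, R1->cavity, cavity->R2, R2->outlet
step_positions <- function(geometry) {
  cumsum(c(0, geometry$region_lengths))
}

#' Smooth channel width profile
#'
#' Continuously differentiable interpolation of the stepped width profile:
#' a sum of logistic steps at the four region boundaries, each with 10-90%
#' transition width `transition_scale`.
#'
#' @param geometry A [channel_geometry()].
#' @param x Axial position(s), um. Vectorised.
#' @return Width(s) in um, same length as `x`.
#' @export
width_profile <- function(geometry, x) {
  stopifnot(inherits(geometry, "dc_geometry"))
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  smooth_width(geometry, x, geometry$transition_scale)
}

# logistic-step width interpolation at a given 10-90% transition width
smooth_width <- function(geometry, x, width_10_90) {
  s <- width_10_90 / (2 * log(9))  # logistic scale parameter
  pos <- step_positions(geometry)
  w_levels <- c(geometry$inlet_effective_width, geometry$region_widths,
                geometry$inlet_effective_width)
  w <- rep(w_levels[1], length(x))
  for (i in seq_along(pos)) {
    w <- w + (w_levels[i + 1] - w_levels[i]) * stats::plogis(x, pos[i], s)
  }
  w
}

# d(width)/dx of smooth_width
smooth_width_deriv <- function(geometry, x, width_10_90) {
  s <- width_10_90 / (2 * log(9))
  pos <- step_positions(geometry)
  w_levels <- c(geometry$inlet_effective_width, geometry$region_widths,
                geometry$inlet_effective_width)
  dw <- rep(0, length(x))
  for (i in seq_along(pos)) {
    p <- stats::plogis(x, pos[i], s)
    dw <- dw + (w_levels[i + 1] - w_levels[i]) * p * (1 - p) / s
  }
  dw
}

#' Centreline velocity profile
#'
#' One-dimensional mass-conservation velocity
#' v(x) = velocity_scale * flow_rate / (width(x) * height), converted to
#' um/s. Fastest in the narrow regions, slowest in the wide inlet/outlet.
#'
#' @inheritParams width_profile
#' @param flow_rate Core flow rate in uL/min; must be positive.
#' @return Velocity in um/s.
#' @export
centerline_velocity <- function(geometry, flow_rate, x) {
  stopifnot(inherits(geometry, "dc_geometry"))
  if (!is.numeric(flow_rate) || length(flow_rate) != 1 || !is.finite(flow_rate) ||
      flow_rate <= 0) {
    stop("flow_rate must be a single positive number (uL/min)", call. = FALSE)
  }
  if (geometry$velocity_scale <= 0) {
    stop("velocity_scale must be positive", call. = FALSE)
  }
  q_um3_s <- flow_rate * 1e9 / 60  # uL/min -> um^3/s
  w_v <- smooth_width(geometry, x, geometry$velocity_transition_scale)
  geometry$velocity_scale * q_um3_s / (w_v * geometry$height)
}

#' Axial velocity gradient (shear-stress proxy)
#'
#' Analytic derivative dv/dx of [centerline_velocity()]; the centreline
#' velocity gradient is proportional to the shear stress a transiting cell
#' experiences. Positive entering each constriction, negative entering the
#' cavity and outlet, with a single zero crossing in the middle of the
#' cavity (x ~ 75 um under defaults).
#'
#' @inheritParams centerline_velocity
#' @return dv/dx in 1/s.
#' @export
stress_proxy <- function(geometry, flow_rate, x) {
  stopifnot(inherits(geometry, "dc_geometry"))
  # v = c / w_v(x)  =>  dv/dx = -v w_v'(x) / w_v(x)
  v <- centerline_velocity(geometry, flow_rate, x)
  sc <- geometry$velocity_transition_scale
  -v * smooth_width_deriv(geometry, x, sc) / smooth_width(geometry, x, sc)
}

#' Plot the channel width, velocity and stress profiles
#'
#' @param object A `dc_geometry`.
#' @param flow_rate Flow rate in uL/min.
#' @param ... Unused.
#' @return A ggplot object with the three profiles as facets.
#' @export
autoplot.dc_geometry <- function(object, flow_rate = 1, ...) {
  x <- seq(object$alignment_window[1], object$alignment_window[2], by = 0.25)
  df <- tibble::tibble(
    x = rep(x, 3),
    value = c(width_profile(object, x),
              centerline_velocity(object, flow_rate, x) / 1000,
              stress_proxy(object, flow_rate, x)),
    profile = rep(c("width (um)", "velocity (mm/s)", "dv/dx (1/s)"),
                  each = length(x))
  )
  df$profile <- factor(df$profile,
                       levels = c("width (um)", "velocity (mm/s)", "dv/dx (1/s)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~profile, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "axial position x (um)", y = NULL)
}
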