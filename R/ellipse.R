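# Mask geometry: moment ellipse fits, convex-hull ratio, image moments.
# Masks are dc_mask objects (raw matrix + frame origin) or plain logical
# matrices; rows index y, columns index x (the channel axis).

mask_points <- function(mask) {
  m <- mask_logical(mask)
  if (!any(m)) stop("empty mask", call. = FALSE)
  which(m, arr.ind = TRUE)  # (row = y, col = x) pixel indices
}

# raw image moments about the pixel-centre origin, up to order 3
raw_moments <- function(idx) {
  x <- idx[, 2]; y <- idx[, 1]
  n <- nrow(idx)
  xb <- mean(x); yb <- mean(y)
  dx <- x - xb; dy <- y - yb
  list(
    n = n, xbar = xb, ybar = yb,
    mu20 = sum(dx^2) / n + 1 / 12,  # +1/12: variance of a unit square pixel
    mu02 = sum(dy^2) / n + 1 / 12,
    mu11 = sum(dx * dy) / n,
    mu30 = sum(dx^3) / n,
    mu21 = sum(dx^2 * dy) / n,
    mu12 = sum(dx * dy^2) / n,
    mu03 = sum(dy^3) / n
  )
}

# flood-fill connectivity check (8-connected), on the mask bounding box
is_single_component <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) <= 1) return(TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  sub <- m[r0:r1, c0:c1, drop = FALSE]
  nr <- nrow(sub); nc <- ncol(sub)
  sel <- matrix(FALSE, nr, nc)
  seed <- which(sub)[1]
  sel[seed] <- TRUE
  repeat {
    grown <- sel
    grown[-1, ] <- grown[-1, ] | sel[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | sel[-1, ]
    grown[, -1] <- grown[, -1] | sel[, -nc]
    grown[, -nc] <- grown[, -nc] | sel[, -1]
    grown[-1, -1] <- grown[-1, -1] | sel[-nr, -nc]
    grown[-nr, -nc] <- grown[-nr, -nc] | sel[-1, -1]
    grown[-1, -nc] <- grown[-1, -nc] | sel[-nr, -1]
    grown[-nr, -1] <- grown[-nr, -1] | sel[-1, -nc]
    grown <- grown & sub
    if (all(grown == sel)) break
    sel <- grown
  }
  sum(sel) == sum(sub)
}

#' Fit an ellipse to a binary mask by its image moments
#'
#' Centroid from the first moments; semi-axes and orientation from the
#' eigen-decomposition of the second central moment matrix (a solid ellipse
#' with semi-axes a, b has eigenvalues a^2/4, b^2/4). The aspect ratio AR
#' is the ratio of the fitted ellipse's extent along the channel axis (x)
#' to its extent perpendicular (y), so AR = 1 for a disc, AR > 1 for a cell
#' stretched along the flow and AR < 1 for a compressed one.
#'
#' @param mask A `dc_mask` or logical matrix (rows = y, cols = x).
#' @param pixel_size Pixel size in um/pixel.
#' @param check_connected Verify the mask is a single 8-connected
#'   component (skipped in bulk pipelines where the source guarantees it).
#' @return A `dc_ellipse`: list with `centroid` (x, y in um, frame
#'   coordinates for a `dc_mask`, local otherwise), semi-axes `a` >= `b`
#'   (um), `orientation` (radians, major axis vs channel axis), `AR`,
#'   `area` (um^2).
#' @export
fit_ellipse <- function(mask, pixel_size = 1, check_connected = TRUE) {
  idx <- mask_points(mask)
  if (check_connected && !is_single_component(mask_logical(mask))) {
    stop("mask has multiple connected components", call. = FALSE)
  }
  mom <- raw_moments(idx)
  cov <- matrix(c(mom$mu20, mom$mu11, mom$mu11, mom$mu02), 2, 2)
  eig <- eigen(cov, symmetric = TRUE)
  ax <- 2 * sqrt(pmax(eig$values, 0)) * pixel_size
  orientation <- atan2(eig$vectors[2, 1], eig$vectors[1, 1])
  # fold orientation into (-pi/2, pi/2]
  if (orientation > pi / 2) orientation <- orientation - pi
  if (orientation <= -pi / 2) orientation <- orientation + pi
  # extents of the fitted ellipse projected on the channel (x) and
  # perpendicular (y) directions: ext_u = 2 sqrt(u' C u)
  ar <- sqrt(mom$mu20 / mom$mu02)
  cen <- c(x = mom$xbar * pixel_size, y = mom$ybar * pixel_size)
  if (inherits(mask, "dc_mask")) {
    cen <- c(x = cen[["x"]] + mask$origin[2] * pixel_size,
             y = cen[["y"]] + mask$origin[1] * pixel_size)
  }
  structure(
    list(centroid = cen, a = ax[1], b = ax[2], orientation = orientation,
         AR = ar, area = mom$n * pixel_size^2),
    class = "dc_ellipse"
  )
}

#' @export
print.dc_ellipse <- function(x, ...) {
  cat(sprintf("<dc_ellipse> a=%.3g b=%.3g um, AR=%.3f, theta=%.2f rad\n",
              x$a, x$b, x$AR, x$orientation))
  invisible(x)
}

#' Convex hull to mask area ratio
#'
#' Ratio of the pixel area of the mask's convex hull to the mask's own
#' pixel area. Near 1 for convex shapes; segmentation failures (concave
#' bites, merged debris) push it up. The hull area is the number of pixel
#' centres inside or on the hull polygon of the mask's pixel centres,
#' counted exactly with Pick's theorem (lattice polygon: points = area +
#' boundary/2 + 1).
#'
#' @param mask A `dc_mask` or logical matrix.
#' @return Ratio >= 1 (dimensionless).
#' @export
convex_hull_ratio <- function(mask) {
  m <- mask_logical(mask)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask", call. = FALSE)
  if (nrow(idx) <= 3) return(1)
  hull <- grDevices::chull(idx[, 2], idx[, 1])
  vx <- idx[hull, 2]; vy <- idx[hull, 1]
  k <- length(vx)
  if (k < 3) return(1)  # collinear mask
  nx <- c(vx[-1], vx[1]); ny <- c(vy[-1], vy[1])
  area2 <- abs(sum(vx * ny - nx * vy))          # twice the shoelace area
  boundary_pts <- sum(mapply(gcd_int, abs(nx - vx), abs(ny - vy)))
  hull_pixels <- area2 / 2 + boundary_pts / 2 + 1
  hull_pixels / nrow(idx)
}

gcd_int <- function(a, b) {
  while (b != 0) { tmp <- b; b <- a %% b; a <- tmp }
  a
}

#' Central and Hu moments of a mask
#'
#' Normalised central moments of inertia (eta20, eta11, eta02) plus Hu's
#' seven moment invariants, which are invariant to translation, scale and
#' rotation of the shape. Used as region-wise morphology descriptors.
#'
#' @param mask A `dc_mask` or logical matrix.
#' @return Named numeric vector: `mu20n`, `mu11n`, `mu02n`, `hu1` ... `hu7`.
#' @export
shape_moments <- function(mask) {
  idx <- mask_points(mask)
  mom <- raw_moments(idx)
  n <- mom$n
  eta <- function(mu, p, q) mu * n / n^(1 + (p + q) / 2)  # mu here is per-pixel
  n20 <- eta(mom$mu20, 2, 0); n02 <- eta(mom$mu02, 0, 2); n11 <- eta(mom$mu11, 1, 1)
  n30 <- eta(mom$mu30, 3, 0); n03 <- eta(mom$mu03, 0, 3)
  n21 <- eta(mom$mu21, 2, 1); n12 <- eta(mom$mu12, 1, 2)
  s1 <- n30 + n12; s2 <- n21 + n03
  d1 <- n30 - 3 * n12; d2 <- 3 * n21 - n03
  c(
    mu20n = n20, mu11n = n11, mu02n = n02,
    hu1 = n20 + n02,
    hu2 = (n20 - n02)^2 + 4 * n11^2,
    hu3 = d1^2 + d2^2,
    hu4 = s1^2 + s2^2,
    hu5 = d1 * s1 * (s1^2 - 3 * s2^2) + d2 * s2 * (3 * s1^2 - s2^2),
    hu6 = (n20 - n02) * (s1^2 - s2^2) + 4 * n11 * s1 * s2,
    hu7 = d2 * s1 * (s1^2 - 3 * s2^2) - d1 * s2 * (3 * s1^2 - s2^2)
  )
}

# crack-boundary perimeter of a mask in pixels: number of pixel edges
# between inside and outside (or the image border)
mask_perimeter_px <- function(mask) {
  m <- mask_logical(mask)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  inner <- pad[2:(nr + 1), 2:(nc + 1)]
  sum(inner & !pad[1:nr, 2:(nc + 1)]) +
    sum(inner & !pad[3:(nr + 2), 2:(nc + 1)]) +
    sum(inner & !pad[2:(nr + 1), 1:nc]) +
    sum(inner & !pad[2:(nr + 1), 3:(nc + 2)])
}
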