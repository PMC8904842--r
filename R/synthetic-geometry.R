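# Ring and marker phantoms for residual-strain parameter recovery.

#' Ring phantom specification
#'
#' Defines an opened-ring phantom whose true opening angle is known. The
#' midline is a circular arc of radius `mid_radius` spanning a central angle
#' of 360 - 2 * alpha_true degrees (the opening-angle convention: an uncut
#' ring has alpha = 0 and central angle 360, a flat strip has alpha = 180 and
#' central angle 0). For `alpha_true` > 180 the formula gives a negative
#' central angle; such phantoms are supported as contours only, using the
#' absolute value (an arc bent the other way), and cannot be rendered.
#'
#' @param alpha_true opening angle (degrees), in [0, 360).
#' @param mid_radius midline radius of the arc (um).
#' @param wall_thickness wall band thickness (um), used when rendering.
#' @param points_per_contour contour sample count.
#' @param pixel_size um per pixel for rendered images (NULL: no rendering).
#' @param jitter_sd Gaussian point jitter (um).
#' @param seed RNG seed.
#' @return An object of class `ring_phantom`.
#' @export
ring_phantom <- function(alpha_true, mid_radius = 1000, wall_thickness = 150,
                         points_per_contour = 200L, pixel_size = NULL,
                         jitter_sd = 0, seed = NULL) {
  if (!is.numeric(alpha_true) || alpha_true < 0 || alpha_true >= 360)
    stop_field("alpha_true", "must lie in [0, 360)")
  check_positive(mid_radius, "mid_radius")
  check_positive(wall_thickness, "wall_thickness")
  check_nonneg(jitter_sd, "jitter_sd")
  if (points_per_contour < 10L)
    stop_field("points_per_contour", "needs >= 10 points")
  if (!is.null(pixel_size)) check_positive(pixel_size, "pixel_size")
  structure(list(alpha_true = alpha_true, mid_radius = mid_radius,
                 wall_thickness = wall_thickness,
                 points_per_contour = as.integer(points_per_contour),
                 pixel_size = pixel_size, jitter_sd = jitter_sd, seed = seed),
            class = "ring_phantom")
}

#' Generate a ring midline contour (and optionally a rendered image)
#'
#' Produces ordered midline points on a circular arc of central angle
#' 360 - 2 * alpha_true degrees. `alpha_true` = 180 is the flat-strip limit
#' (a straight segment whose length equals the closed-ring circumference);
#' `alpha_true` = 0 gives a closed circle (contour flagged closed). When
#' `pixel_size` is set, a binary raster of the wall band (logical matrix,
#' rows = y, columns = x, `pixel_size` stored as an attribute) is also
#' returned.
#'
#' @param ph a [ring_phantom()].
#' @return List with `contour` (a [ring_contour()]), `alpha_true`, and
#'   `image` (binary matrix or NULL).
#' @export
gen_ring_contour <- function(ph) {
  stopifnot(inherits(ph, "ring_phantom"))
  ca <- (360 - 2 * ph$alpha_true) * pi / 180   # central angle, radians
  n <- ph$points_per_contour
  closed <- ph$alpha_true == 0
  if (abs(ca) < 1e-9) {
    len <- 2 * pi * ph$mid_radius   # flat strip: circumference preserved
    pts <- cbind(seq(-len / 2, len / 2, length.out = n), 0)
  } else {
    th <- seq(-abs(ca) / 2, abs(ca) / 2, length.out = n)
    pts <- ph$mid_radius * cbind(cos(th), sin(th))
  }
  pts <- with_seed(ph$seed, {
    if (ph$jitter_sd > 0)
      pts + matrix(stats::rnorm(2L * n, 0, ph$jitter_sd), ncol = 2L)
    else pts
  })
  img <- NULL
  if (!is.null(ph$pixel_size)) {
    if (ph$alpha_true > 180)
      stop("phantoms with alpha_true > 180 are contour-only", call. = FALSE)
    img <- render_ring_image(ph)
  }
  list(contour = ring_contour(pts, closed = closed), alpha_true = ph$alpha_true,
       image = img)
}

#' Render a ring phantom as a binary wall-band image
#'
#' Pixels whose distance to the (noise-free) midline arc is at most half the
#' wall thickness are set TRUE. Rows index y, columns x; the `pixel_size`
#' attribute records um/pixel.
#'
#' @param ph a [ring_phantom()] with `pixel_size` set and
#'   `alpha_true <= 180`.
#' @return Logical matrix with attributes `pixel_size` and `origin_um`.
#' @export
render_ring_image <- function(ph) {
  stopifnot(inherits(ph, "ring_phantom"))
  if (is.null(ph$pixel_size)) stop_field("pixel_size", "must be set to render")
  ps <- ph$pixel_size
  R <- ph$mid_radius; halfw <- ph$wall_thickness / 2
  ca <- (360 - 2 * ph$alpha_true) * pi / 180
  margin <- halfw + 4 * ps
  if (abs(ca) < 1e-9) {
    len <- 2 * pi * R
    x0 <- -len / 2 - margin; x1 <- len / 2 + margin
    y0 <- -halfw - margin; y1 <- halfw + margin
  } else {
    x0 <- -R - margin; x1 <- R + margin
    y0 <- -R - margin; y1 <- R + margin
  }
  xs <- seq(x0, x1, by = ps)
  ys <- seq(y0, y1, by = ps)
  px <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  py <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  if (abs(ca) < 1e-9) {
    len <- 2 * pi * R
    img <- abs(py) <= halfw & abs(px) <= len / 2
  } else {
    r <- sqrt(px^2 + py^2)
    th <- atan2(py, px)
    # flat (radial-cut) end caps: the band exists only within the arc span
    img <- abs(th) <= abs(ca) / 2 & abs(r - R) <= halfw
  }
  attr(img, "pixel_size") <- ps
  attr(img, "origin_um") <- c(x0, y0)
  img
}

#' Marker phantom specification
#'
#' @param lambda_true per-segment pre-stretch values (all >= 1).
#' @param exvivo_spacing distance between adjacent ex-vivo markers (um).
#' @param coordinate_noise_sd Gaussian jitter on marker coordinates (um).
#' @param seed RNG seed.
#' @return An object of class `marker_phantom`.
#' @export
marker_phantom <- function(lambda_true, exvivo_spacing = 10000,
                           coordinate_noise_sd = 0, seed = NULL) {
  if (length(lambda_true) < 1L || any(lambda_true < 1))
    stop_field("lambda_true", "needs >= 1 segment, all values >= 1")
  check_positive(exvivo_spacing, "exvivo_spacing")
  check_nonneg(coordinate_noise_sd, "coordinate_noise_sd")
  structure(list(lambda_true = lambda_true, n_segments = length(lambda_true),
                 exvivo_spacing = exvivo_spacing,
                 coordinate_noise_sd = coordinate_noise_sd, seed = seed),
            class = "marker_phantom")
}

#' Generate paired in-situ / ex-vivo marker traces
#'
#' Ex-vivo markers are equally spaced along a straight line; the in-situ
#' distance between markers i and i+1 is `exvivo_spacing * lambda_true[i]`.
#'
#' @param ph a [marker_phantom()].
#' @return List with `in_situ` and `ex_vivo` [marker_trace()] objects and
#'   `lambda_true`.
#' @export
gen_marker_traces <- function(ph) {
  stopifnot(inherits(ph, "marker_phantom"))
  n <- ph$n_segments + 1L
  ex_x <- seq(0, by = ph$exvivo_spacing, length.out = n)
  in_x <- cumsum(c(0, ph$exvivo_spacing * ph$lambda_true))
  ex <- cbind(ex_x, 0)
  ins <- cbind(in_x, 0)
  if (ph$coordinate_noise_sd > 0) {
    jit <- with_seed(ph$seed,
                     matrix(stats::rnorm(4L * n, 0, ph$coordinate_noise_sd),
                            ncol = 4L))
    ins <- ins + jit[, 1:2]
    ex <- ex + jit[, 3:4]
  }
  list(in_situ = marker_trace(ins, label = "in_situ"),
       ex_vivo = marker_trace(ex, label = "ex_vivo"),
       lambda_true = ph$lambda_true)
}
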