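# Stained-section phantoms with exact ground truth for every histological
# quantity: nuclei (count, area, aspect), fiber pixel fractions, and layer
# geometry. Pixels are painted in optical-density space by mixing the stain
# vectors, so color deconvolution is exactly invertible on the phantom.

#' Annular-sector ROI polygon inside the media band
#'
#' @param cx,cy vessel centre (pixels).
#' @param r_in,r_out sector radii (pixels), `r_out > r_in > 0`.
#' @param theta1,theta2 sector angular range (degrees).
#' @param n vertices per arc.
#' @return Two-column polygon matrix (x, y), ordered.
#' @export
roi_sector <- function(cx, cy, r_in, r_out, theta1 = -45, theta2 = 45,
                       n = 60L) {
  if (r_out <= r_in || r_in <= 0) stop_field("r_out", "need r_out > r_in > 0")
  t1 <- theta1 * pi / 180; t2 <- theta2 * pi / 180
  th <- seq(t1, t2, length.out = n)
  outer <- cbind(cx + r_out * cos(th), cy + r_out * sin(th))
  inner <- cbind(cx + r_in * cos(rev(th)), cy + r_in * sin(rev(th)))
  rbind(outer, inner)
}

#' Histology phantom specification
#'
#' Defines a synthetic stained cross-section: a white lumen and background,
#' a media band painted with elastin-like and collagen-like stain at exact
#' pixel fractions, a paler adventitia band, and dark non-overlapping
#' elliptical nuclei inside the ROI. All defaults describe a full-size rat
#' thoracic aorta (internal diameter 1610 um, external 2089 um, intima-media
#' thickness 121.4 um); smaller phantoms are convenient for fine-resolution
#' nuclei work.
#'
#' @param inner_diameter,outer_diameter lumen and outer vessel diameters
#'   (um).
#' @param media_outer_diameter diameter of the media-adventitia border (um);
#'   default `inner_diameter + 2 * 121.4`.
#' @param pixel_size um per pixel.
#' @param n_nuclei nuclei to place inside the ROI.
#' @param nucleus_mean_area mean nucleus area (um^2).
#' @param nucleus_aspect major/minor axis ratio (>= 1).
#' @param elastin_fraction,collagen_fraction target positive-pixel fractions
#'   within the ROI (their sum plus the nuclei fraction must stay below 1).
#' @param stain_matrix a [stain_matrix()].
#' @param roi_theta ROI sector half-angle (degrees, default 45).
#' @param seed RNG seed.
#' @return An object of class `histology_phantom`.
#' @export
histology_phantom <- function(inner_diameter = 1610, outer_diameter = 2089,
                              media_outer_diameter = inner_diameter + 2 * 121.4,
                              pixel_size = 2, n_nuclei = 150,
                              nucleus_mean_area = 24, nucleus_aspect = 2,
                              elastin_fraction = 0.2566,
                              collagen_fraction = 0.1653,
                              stain_matrix = default_stain_matrix(),
                              roi_theta = 45, seed = NULL) {
  check_positive(inner_diameter, "inner_diameter")
  if (outer_diameter <= inner_diameter)
    stop_field("outer_diameter", "must exceed inner_diameter")
  if (media_outer_diameter <= inner_diameter ||
      media_outer_diameter >= outer_diameter)
    stop_field("media_outer_diameter",
               "must lie between inner and outer diameters")
  check_positive(pixel_size, "pixel_size")
  if (n_nuclei < 0) stop_field("n_nuclei", "must be >= 0")
  check_positive(nucleus_mean_area, "nucleus_mean_area")
  if (nucleus_aspect < 1) stop_field("nucleus_aspect", "must be >= 1")
  if (elastin_fraction < 0 || collagen_fraction < 0 ||
      elastin_fraction + collagen_fraction > 1)
    stop_field("elastin_fraction",
               "fractions must be >= 0 and sum to at most 1")
  structure(list(inner_diameter = inner_diameter,
                 outer_diameter = outer_diameter,
                 media_outer_diameter = media_outer_diameter,
                 pixel_size = pixel_size, n_nuclei = as.integer(n_nuclei),
                 nucleus_mean_area = nucleus_mean_area,
                 nucleus_aspect = nucleus_aspect,
                 elastin_fraction = elastin_fraction,
                 collagen_fraction = collagen_fraction,
                 stain_matrix = stain_matrix, roi_theta = roi_theta,
                 seed = seed),
            class = "histology_phantom")
}

# OD "paint" strengths; fiber pixels stay above the 0.15 positivity cutoff
# while remaining clearly lighter in grayscale than the nuclei, so Otsu
# isolates nuclei rather than fibers
PAINT <- list(media_base = c(elastin = 0.05, collagen = 0.05, residual = 0),
              elastin = c(elastin = 0.30, collagen = 0.03, residual = 0),
              collagen = c(elastin = 0.03, collagen = 0.30, residual = 0),
              adventitia = c(elastin = 0, collagen = 0.06, residual = 0),
              nucleus = c(elastin = 0.10, collagen = 0, residual = 1.30))

#' Generate a stained-section phantom with exact ground truth
#'
#' Renders the annular section (white lumen/background, painted media,
#' pale adventitia), places `n_nuclei` non-overlapping elliptical nuclei of
#' prescribed mean area and aspect ratio at random positions/orientations in
#' the ROI, and paints exact counts of elastin- and collagen-positive pixels
#' among the remaining ROI pixels so that the positive fractions match the
#' prescription to within one pixel. Colors are composed in OD space from
#' the phantom's stain matrix.
#'
#' @param ph a [histology_phantom()].
#' @return List with `image` (a [histology_image()]) and `truth`: nuclei
#'   count/centroids/areas (um^2), painted `elastin_mask` / `collagen_mask`,
#'   prescribed fractions, analytic layer perimeters (um), ROI polygon and
#'   ROI area (um^2).
#' @export
gen_histology_image <- function(ph) {
  stopifnot(inherits(ph, "histology_phantom"))
  ps <- ph$pixel_size
  r_in <- ph$inner_diameter / 2 / ps
  r_med <- ph$media_outer_diameter / 2 / ps
  r_out <- ph$outer_diameter / 2 / ps
  half <- ceiling(r_out + 6)
  n_px <- 2L * half + 1L
  cx <- half + 1; cy <- half + 1
  # matrices are h x w with rows = y, columns = x
  dx <- matrix(rep(seq_len(n_px), each = n_px), n_px) - cx   # col j == j
  dy <- matrix(rep(seq_len(n_px), times = n_px), n_px) - cy  # row i == i
  r <- sqrt(dx^2 + dy^2)
  media <- r >= r_in & r < r_med
  advent <- r >= r_med & r <= r_out

  margin <- 0.08 * (r_med - r_in)
  roi <- roi_sector(cx, cy, r_in + margin, r_med - margin,
                    -ph$roi_theta, ph$roi_theta)
  mask <- roi_mask(roi, c(n_px, n_px)) & media

  with_seed(ph$seed, {
    # --- nuclei placement (non-overlapping ellipses, bounded retries) ---
    nuc_mask <- matrix(FALSE, n_px, n_px)
    centroids <- matrix(NA_real_, ph$n_nuclei, 2L)
    areas_px <- integer(ph$n_nuclei)
    a_um <- sqrt(ph$nucleus_mean_area * ph$nucleus_aspect / pi)
    b_um <- a_um / ph$nucleus_aspect
    a_px <- a_um / ps; b_px <- b_um / ps
    cand <- which(mask, arr.ind = TRUE)
    # keep full ellipses inside the ROI band
    ok_c <- cand[points_in_polygon(cand[, 2L], cand[, 1L],
                                   roi[, 1L], roi[, 2L]), , drop = FALSE]
    placed <- 0L
    tries <- 0L
    fails <- 0L
    max_tries <- 400L * max(ph$n_nuclei, 1L)
    taken <- matrix(FALSE, n_px, n_px)   # dilated occupancy
    while (placed < ph$n_nuclei && tries < max_tries && fails < 2000L) {
      tries <- tries + 1L
      fails <- fails + 1L
      k <- sample.int(nrow(ok_c), 1L)
      yc <- ok_c[k, 1L]; xc <- ok_c[k, 2L]
      th <- stats::runif(1, 0, pi)
      # bounding box check on the dilated occupancy grid
      rad <- ceiling(a_px) + 1L
      ys_w <- max(1L, yc - rad):min(n_px, yc + rad)
      xs_w <- max(1L, xc - rad):min(n_px, xc + rad)
      if (any(taken[ys_w, xs_w])) next
      wy <- matrix(rep(ys_w, times = length(xs_w)), length(ys_w)) - yc
      wx <- matrix(rep(xs_w, each = length(ys_w)), length(ys_w)) - xc
      u <- wx * cos(th) + wy * sin(th)
      v <- -wx * sin(th) + wy * cos(th)
      ell <- (u / a_px)^2 + (v / b_px)^2 <= 1
      sub_mask <- mask[ys_w, xs_w, drop = FALSE]
      if (any(ell & !sub_mask)) next   # must lie fully inside the ROI media
      placed <- placed + 1L
      fails <- 0L
      nm <- matrix(FALSE, length(ys_w), length(xs_w))
      nm[ell] <- TRUE
      nuc_mask[ys_w, xs_w] <- nuc_mask[ys_w, xs_w] | nm
      taken[ys_w, xs_w] <- taken[ys_w, xs_w] |
        ((u / (a_px + 1.5))^2 + (v / (b_px + 1.5))^2 <= 1)
      centroids[placed, ] <- c(xc, yc)
      areas_px[placed] <- sum(ell)
    }
    if (placed < ph$n_nuclei)
      stop("could not place ", ph$n_nuclei, " non-overlapping nuclei; ",
           "achieved ", placed, call. = FALSE)

    # --- exact-count fiber painting among non-nucleus ROI pixels ---
    n_roi <- sum(mask)
    paintable <- which(mask & !nuc_mask)
    n_el <- round(ph$elastin_fraction * n_roi)
    n_co <- round(ph$collagen_fraction * n_roi)
    if (n_el + n_co > length(paintable))
      stop("fiber fractions plus nuclei exceed the ROI area", call. = FALSE)
    pick <- sample(paintable, n_el + n_co)
    el_mask <- matrix(FALSE, n_px, n_px); el_mask[pick[seq_len(n_el)]] <- TRUE
    co_mask <- matrix(FALSE, n_px, n_px)
    if (n_co > 0) co_mask[pick[n_el + seq_len(n_co)]] <- TRUE

    # --- compose optical densities and convert to RGB ---
    sm <- ph$stain_matrix
    od_of <- function(w) as.numeric(sm %*% c(w[["elastin"]], w[["collagen"]],
                                             w[["residual"]]))
    od <- array(0, dim = c(n_px, n_px, 3L))
    assign_od <- function(od, where, w) {
      v <- od_of(w)
      for (k in 1:3) {
        ch <- od[, , k]
        ch[where] <- v[k]
        od[, , k] <- ch
      }
      od
    }
    od <- assign_od(od, media, PAINT$media_base)
    od <- assign_od(od, advent, PAINT$adventitia)
    od <- assign_od(od, el_mask, PAINT$elastin)
    od <- assign_od(od, co_mask, PAINT$collagen)
    od <- assign_od(od, nuc_mask, PAINT$nucleus)
    rgb <- round(255 * 10^(-od))

    img <- histology_image(rgb, pixel_size = ps, roi = roi)
    truth <- list(
      n_nuclei = placed,
      nucleus_centroids = centroids,
      nucleus_areas = areas_px * ps^2,
      nucleus_aspect = ph$nucleus_aspect,
      nuclei_mask = nuc_mask,
      elastin_mask = el_mask, collagen_mask = co_mask,
      elastin_fraction = n_el / n_roi,
      collagen_fraction = n_co / n_roi,
      roi = roi, roi_area_um2 = n_roi * ps^2,
      nuclei_density = placed / (n_roi * ps^2 / 1e6),
      luminal_P = pi * ph$inner_diameter,
      medial_P = pi * ph$media_outer_diameter,
      adventitial_P = pi * ph$outer_diameter)
    list(image = img, truth = truth)
  })
}
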