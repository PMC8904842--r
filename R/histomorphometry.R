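# Histological quantification: stain deconvolution, nuclei morphometry and
# perimeter-based vessel geometry. Images are 8-bit RGB arrays
# (rows = y, columns = x, third dimension = R,G,B in 0..255); EBImage is used
# for blurring, distance transform and watershed, with transposition at the
# boundary (EBImage stores x first).

to_ebi <- function(m) EBImage::Image(t(m))
from_ebi <- function(im) t(EBImage::imageData(im))

#' Histology image container
#'
#' @param rgb numeric array `h x w x 3`, 8-bit scale (0..255).
#' @param pixel_size um per pixel, > 0.
#' @param roi region-of-interest polygon: two-column matrix of (x, y) pixel
#'   coordinates (1-based, y down), closed implicitly.
#' @return An object of class `histology_image`.
#' @export
histology_image <- function(rgb, pixel_size, roi) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop_field("rgb", "must be an h x w x 3 array")
  check_positive(pixel_size, "pixel_size")
  roi <- as.matrix(roi)
  if (ncol(roi) != 2L || nrow(roi) < 3L)
    stop_field("roi", "must be a polygon with >= 3 vertices")
  if (abs(polygon_area(roi)) <= 0)
    stop_field("roi", "polygon area must be positive")
  structure(list(rgb = rgb, pixel_size = pixel_size, roi = roi),
            class = "histology_image")
}

# shoelace area (pixel^2)
polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# logical mask of pixels (centers) inside the polygon, image h x w
roi_mask <- function(poly, dims) {
  h <- dims[1L]; w <- dims[2L]
  xs <- rep(seq_len(w), each = h)
  ys <- rep(seq_len(h), times = w)
  matrix(points_in_polygon(xs, ys, poly[, 1L], poly[, 2L]), h, w)
}

#' Default stain vectors for elastin-stained sections
#'
#' Unit optical-density (OD) RGB triples used by the phantom generator and as
#' a fallback for deconvolution: a dark elastin-like stain, a pink
#' collagen-like counterstain and a residual vector. Real analyses should
#' supply the stain matrix measured for their own staining batch via
#' [stain_matrix()].
#'
#' @return A 3 x 3 matrix, one unit-norm OD column per stain
#'   (`elastin`, `collagen`, `residual`), rows R, G, B.
#' @export
default_stain_matrix <- function() {
  stain_matrix(elastin = c(0.650, 0.704, 0.286),
               collagen = c(0.072, 0.990, 0.105),
               residual = c(0.268, 0.570, 0.776))
}

#' Build and validate a stain matrix
#'
#' @param elastin,collagen,residual length-3 OD vectors (R, G, B); each is
#'   normalized to unit Euclidean norm.
#' @return A 3 x 3 matrix with stains in columns; condition number must be
#'   below 1e6.
#' @export
stain_matrix <- function(elastin, collagen, residual) {
  m <- cbind(elastin = elastin, collagen = collagen, residual = residual)
  if (nrow(m) != 3L) stop_field("stain_matrix", "vectors must have 3 components")
  nrm <- sqrt(colSums(m^2))
  if (any(nrm <= 0)) stop_field("stain_matrix", "zero stain vector")
  m <- sweep(m, 2L, nrm, "/")
  if (kappa(m) >= 1e6)
    stop_field("stain_matrix", "singular or near-singular (condition >= 1e6)")
  m
}

#' Grayscale + Gaussian blur preprocessing of a histology image
#'
#' Converts to luminance (ITU-R BT.601 weights 0.299/0.587/0.114, scaled to
#' 0..1), applies a Gaussian blur and masks pixels outside the ROI polygon.
#'
#' @param image a [histology_image()].
#' @param blur_sigma Gaussian blur sigma in pixels (default 2; 0 skips the
#'   blur).
#' @return List with `gray` (matrix in 0..1, blurred) and `mask` (logical
#'   ROI matrix); pixels outside the ROI are NA in `gray`.
#' @export
preprocess_histology <- function(image, blur_sigma = 2) {
  stopifnot(inherits(image, "histology_image"))
  check_nonneg(blur_sigma, "blur_sigma")
  dims <- dim(image$rgb)[1:2]
  if (any(image$roi[, 1L] < 1) || any(image$roi[, 1L] > dims[2L]) ||
      any(image$roi[, 2L] < 1) || any(image$roi[, 2L] > dims[1L]))
    stop("ROI polygon extends outside the image bounds", call. = FALSE)
  gray <- (0.299 * image$rgb[, , 1L] + 0.587 * image$rgb[, , 2L] +
             0.114 * image$rgb[, , 3L]) / 255
  if (blur_sigma > 0)
    gray <- from_ebi(EBImage::gblur(to_ebi(gray), sigma = blur_sigma))
  mask <- roi_mask(image$roi, dims)
  gray[!mask] <- NA_real_
  list(gray = gray, mask = mask)
}

# Otsu threshold on a numeric vector in [0, 1]
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  h <- tabulate(pmin(pmax(floor(values * n_bins) + 1L, 1L), n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  (which.max(sb) - 0.5) / n_bins
}

#' Segment cell nuclei in a preprocessed ROI
#'
#' Thresholds the blurred grayscale ROI (Otsu by default; nuclei are the dark
#' class), separates touching nuclei by distance-transform watershed, and
#' filters objects by area.
#'
#' @param prep output of [preprocess_histology()].
#' @param pixel_size um per pixel.
#' @param min_area,max_area object area filter in um^2 (defaults 5 and 200).
#' @param threshold fixed grayscale threshold in 0..1 (NULL: Otsu on the
#'   in-ROI values).
#' @return Integer label matrix (0 = background), one label per nucleus.
#' @export
segment_nuclei <- function(prep, pixel_size, min_area = 5, max_area = 200,
                           threshold = NULL) {
  check_positive(pixel_size, "pixel_size")
  vals <- prep$gray[prep$mask]
  if (length(vals) == 0L)
    return(matrix(0L, nrow(prep$gray), ncol(prep$gray)))
  thr <- if (is.null(threshold)) otsu_threshold(vals) else threshold
  nmask <- !is.na(prep$gray) & prep$gray < thr & prep$mask
  if (!any(nmask))
    return(matrix(0L, nrow(prep$gray), ncol(prep$gray)))
  dm <- EBImage::distmap(to_ebi(nmask * 1))
  ws <- EBImage::watershed(dm, tolerance = 1)
  labels <- from_ebi(ws)
  sizes <- tabulate(labels[labels > 0])
  area_um2 <- sizes * pixel_size^2
  keep <- which(area_um2 >= min_area & area_um2 <= max_area)
  out <- matrix(0L, nrow(labels), ncol(labels))
  if (length(keep)) {
    relab <- integer(max(labels))
    relab[keep] <- seq_along(keep)
    pos <- labels > 0
    out[pos] <- relab[labels[pos]]
  }
  out
}

#' Morphometric statistics of segmented nuclei
#'
#' Per-object area (pixel count x pixel_size^2), moment-based major-axis
#' length (4 sqrt of the largest eigenvalue of the pixel-coordinate
#' covariance, which equals the major axis for a filled ellipse) and the
#' particle-analysis roundness 4 Area / (pi major_axis^2), which is 1 for a
#' disc and b/a for an ellipse with semi-axes a > b. Density is the object
#' count per mm^2 of ROI.
#'
#' @param labels integer label matrix from [segment_nuclei()].
#' @param pixel_size um per pixel.
#' @param roi_area_um2 ROI area in um^2 (e.g. `sum(mask) * pixel_size^2`).
#' @return An object of class `nuclei_measurements`: per-nucleus `area`
#'   (um^2), `major_axis` (um), `roundness`, plus `count`, `density`
#'   (count/mm^2), `mean_area`, `mean_roundness`.
#' @export
nuclei_stats <- function(labels, pixel_size, roi_area_um2) {
  check_positive(pixel_size, "pixel_size")
  check_positive(roi_area_um2, "roi_area_um2")
  n <- max(labels)
  if (n == 0L)
    return(structure(list(area = numeric(0), major_axis = numeric(0),
                          roundness = numeric(0), count = 0L, density = 0,
                          mean_area = NA_real_, mean_roundness = NA_real_),
                     class = "nuclei_measurements"))
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  area_px <- tabulate(lab, n)
  major <- vapply(seq_len(n), function(k) {
    pts <- idx[lab == k, , drop = FALSE]
    if (nrow(pts) < 2L) return(2 * sqrt(1 / pi))  # single pixel ~ tiny disc
    cv <- stats::cov(pts) * (nrow(pts) - 1L) / nrow(pts)  # population moments
    4 * sqrt(max(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0))
  }, 1)
  area <- area_px * pixel_size^2
  major_um <- major * pixel_size
  roundness <- pmin(4 * area / (pi * major_um^2), 1)
  structure(list(area = area, major_axis = major_um, roundness = roundness,
                 count = n, density = n / (roi_area_um2 / 1e6),
                 mean_area = mean(area), mean_roundness = mean(roundness)),
            class = "nuclei_measurements")
}

#' Color deconvolution into stain concentration maps
#'
#' Converts each pixel to optical density, OD = -log10(max(I, 1)/255) per
#' channel, and solves OD = stain_matrix %*% concentrations, clipping
#' negative concentrations to zero.
#'
#' @param rgb `h x w x 3` array in 0..255 (or a [histology_image()]).
#' @param stains a [stain_matrix()] (default [default_stain_matrix()]).
#' @return Named list of concentration matrices (`elastin`, `collagen`,
#'   `residual`).
#' @export
deconvolve_stains <- function(rgb, stains = default_stain_matrix()) {
  if (inherits(rgb, "histology_image")) rgb <- rgb$rgb
  if (kappa(stains) >= 1e6) stop("singular stain matrix", call. = FALSE)
  od <- -log10(pmax(rgb, 1) / 255)
  h <- dim(od)[1L]; w <- dim(od)[2L]
  odm <- rbind(as.vector(od[, , 1L]), as.vector(od[, , 2L]),
               as.vector(od[, , 3L]))
  conc <- solve(stains, odm)
  conc[conc < 0] <- 0
  out <- lapply(1:3, function(k) matrix(conc[k, ], h, w))
  names(out) <- colnames(stains)
  out
}

#' Fiber area fractions from concentration maps
#'
#' A pixel is stain-positive when its concentration exceeds `threshold`; the
#' fiber fraction is the percentage of ROI pixels that are positive.
#'
#' @param maps list from [deconvolve_stains()].
#' @param mask logical ROI matrix.
#' @param threshold concentration cutoff (default 0.15).
#' @return List with `elastin_pct` and `collagen_pct` (0..100).
#' @export
fiber_fractions <- function(maps, mask, threshold = 0.15) {
  n_roi <- sum(mask)
  if (n_roi == 0L) return(list(elastin_pct = 0, collagen_pct = 0))
  list(elastin_pct = 100 * sum(maps$elastin[mask] > threshold) / n_roi,
       collagen_pct = 100 * sum(maps$collagen[mask] > threshold) / n_roi)
}

#' Vessel morphometry from layer perimeters
#'
#' Estimates diameters from measured perimeters assuming effective
#' circularity (d = P / pi): internal diameter from the luminal perimeter,
#' external from the adventitial; intima-media thickness =
#' (d_medial - d_luminal)/2, adventitia thickness =
#' (d_adventitial - d_medial)/2, media/lumen ratio = d_medial / d_luminal,
#' and wall cross-section area = pi/4 (d_adventitial^2 - d_luminal^2).
#'
#' @param luminal_P,medial_P,adventitial_P layer perimeters (um), strictly
#'   increasing in that order.
#' @return An object of class `morphometry`: `internal_diameter`,
#'   `external_diameter`, `intima_media_thickness`, `adventitia_thickness`,
#'   `media_lumen_ratio`, `cross_section_area` (um / um^2).
#' @examples
#' morphometry_from_perimeters(pi * 1000, pi * 1240, pi * 1300)
#' @export
morphometry_from_perimeters <- function(luminal_P, medial_P, adventitial_P) {
  if (!(adventitial_P > medial_P && medial_P > luminal_P && luminal_P > 0))
    stop("perimeters must satisfy adventitial > medial > luminal > 0",
         call. = FALSE)
  d_lum <- luminal_P / pi
  d_med <- medial_P / pi
  d_adv <- adventitial_P / pi
  structure(list(
    internal_diameter = d_lum,
    external_diameter = d_adv,
    intima_media_thickness = (d_med - d_lum) / 2,
    adventitia_thickness = (d_adv - d_med) / 2,
    media_lumen_ratio = d_med / d_lum,
    cross_section_area = pi / 4 * (d_adv^2 - d_lum^2)),
    class = "morphometry")
}

#' Trace luminal, medial and adventitial perimeters from a section image
#'
#' Segments a single annular vessel cross-section: wall pixels are those
#' darker than the near-white background; the lumen is the enclosed
#' background component; the media is the darker (stained) class within the
#' wall, separated from the paler adventitia by Otsu's threshold. Layer
#' perimeters are computed from the enclosed areas via the circle-equivalent
#' relation P = 2 sqrt(pi A), which is far less biased on rasters than
#' summing boundary steps for the near-circular sections this operation
#' expects.
#'
#' @param image a [histology_image()] (the ROI is not used here).
#' @param bg_level grayscale level above which a pixel counts as background
#'   (default 0.96).
#' @param min_media_frac smallest credible media share of the wall area,
#'   used by the recursive threshold search (default 0.25).
#' @return List with `luminal_P`, `medial_P`, `adventitial_P` in um.
#' @export
trace_perimeters <- function(image, bg_level = 0.96, min_media_frac = 0.25) {
  stopifnot(inherits(image, "histology_image"))
  ps <- image$pixel_size
  gray <- (0.299 * image$rgb[, , 1L] + 0.587 * image$rgb[, , 2L] +
             0.114 * image$rgb[, , 3L]) / 255
  wall <- gray < bg_level
  lab_wall <- from_ebi(EBImage::bwlabel(to_ebi(wall * 1)))
  n_wall <- max(lab_wall)
  if (n_wall != 1L)
    stop("expected a single annular vessel wall, found ", n_wall,
         " components", call. = FALSE)
  lab_bg <- from_ebi(EBImage::bwlabel(to_ebi((!wall) * 1)))
  border_labs <- unique(c(lab_bg[1L, ], lab_bg[nrow(lab_bg), ],
                          lab_bg[, 1L], lab_bg[, ncol(lab_bg)]))
  holes <- setdiff(unique(lab_bg[lab_bg > 0]), border_labs)
  if (length(holes) != 1L)
    stop("image is not a single annulus: found ", length(holes),
         " enclosed lumina", call. = FALSE)
  a_lum <- sum(lab_bg == holes) * ps^2
  # separate the pale adventitia from the (possibly stain-mottled) media:
  # cluster wall grays into up to three levels and cut between the two
  # brightest centres, so dark stain speckle inside the media cannot hijack
  # the split the way a plain bimodal threshold can
  # the media is the substantial dark fraction of the wall; dark stain
  # speckle can hijack a single Otsu split, so re-split the bright class
  # until the dark class is a plausible media (>= min_media_frac of wall)
  pool <- gray[wall]
  if (length(unique(pool)) < 2L)
    stop("wall grayscale is uniform: cannot separate media from adventitia",
         call. = FALSE)
  n_wall_px <- length(pool)
  thr <- otsu_threshold(pool)
  for (it in 1:4) {
    if (sum(gray[wall] < thr) / n_wall_px >= min_media_frac) break
    upper <- pool[pool >= thr]
    if (length(unique(upper)) < 2L) break
    thr <- otsu_threshold(upper)
  }
  media <- wall & gray < thr
  a_media <- sum(media) * ps^2
  a_wall <- sum(wall) * ps^2
  p_of_area <- function(a) 2 * sqrt(pi * a)
  list(luminal_P = p_of_area(a_lum),
       medial_P = p_of_area(a_lum + a_media),
       adventitial_P = p_of_area(a_lum + a_wall))
}
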