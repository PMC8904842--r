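#' Marker trace
#'
#' Ordered 2-D coordinates (in micrometres, after scale-bar calibration) of
#' ink markers placed along an artery, photographed in situ (before excision)
#' or ex vivo (after excision and retraction).
#'
#' @param points two-column matrix of x/y coordinates (um).
#' @param scale um-per-pixel factor already applied (metadata only).
#' @param label `"in_situ"` or `"ex_vivo"`.
#' @return An object of class `marker_trace`.
#' @export
marker_trace <- function(points, scale = 1, label = c("in_situ", "ex_vivo")) {
  label <- match.arg(label)
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 2L)
    stop_field("points", "must be a 2-column matrix with >= 2 rows")
  if (any(sqrt(rowSums(diff(points)^2)) == 0))
    stop_field("points", "consecutive markers must be distinct")
  structure(list(points = points, scale = scale, label = label),
            class = "marker_trace")
}

#' Longitudinal pre-stretch from paired marker traces
#'
#' An artery retracts when excised; the longitudinal pre-stretch of segment i
#' is the ratio of the in-situ inter-marker distance to the ex-vivo distance,
#' lambda_i = d_insitu_i / d_exvivo_i (>= 1 for a retracting vessel).
#' Segments are binned into proximal / middle / distal thirds by their
#' normalized midpoint position along the in-situ trace; the thirds follow
#' the 0-33.3% / 33.6-66.6% / 66.6-100% convention, positions falling in the
#' 33.3-33.6% gap being assigned to the middle third.
#'
#' @param in_situ,ex_vivo [marker_trace()] objects with the same marker
#'   count, ordered proximal to distal.
#' @return A list of class `prestretch_map`: `segment_lambdas`,
#'   `region_bins` (factor: proximal/middle/distal) and `region_means`.
#' @examples
#' ex <- marker_trace(cbind(seq(0, 40000, 10000), 0), label = "ex_vivo")
#' ins <- marker_trace(cbind(seq(0, 60000, 15000), 0), label = "in_situ")
#' compute_prestretch(ins, ex)$segment_lambdas   # all 1.5
#' @export
compute_prestretch <- function(in_situ, ex_vivo) {
  stopifnot(inherits(in_situ, "marker_trace"), inherits(ex_vivo, "marker_trace"))
  n <- nrow(in_situ$points)
  if (nrow(ex_vivo$points) != n)
    stop("marker counts differ between traces", call. = FALSE)
  d_in <- sqrt(rowSums(diff(in_situ$points)^2))
  d_ex <- sqrt(rowSums(diff(ex_vivo$points)^2))
  if (any(d_ex <= 0)) stop("non-positive ex-vivo marker distance", call. = FALSE)
  lam <- d_in / d_ex
  s <- cumsum(c(0, d_in))
  mid <- (s[-length(s)] + s[-1L]) / 2 / s[length(s)]
  bins <- cut(mid, breaks = c(-Inf, 0.333, 0.666, Inf),
              labels = c("proximal", "middle", "distal"))
  means <- tapply(lam, bins, mean)
  structure(list(segment_lambdas = lam, region_bins = bins,
                 region_means = means),
            class = "prestretch_map")
}

#' Ring contour
#'
#' Ordered midline coordinates (um) of an arterial ring after a radial cut
#' (an open arc) or before it (closed).
#'
#' @param points two-column matrix of ordered midline coordinates (um).
#' @param closed logical; TRUE for an uncut ring.
#' @return An object of class `ring_contour`.
#' @export
ring_contour <- function(points, closed = FALSE) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 10L)
    stop_field("points", "must be a 2-column matrix with >= 10 rows")
  s <- arc_length(points)
  if (s[length(s)] <= 0) stop_field("points", "zero total arc length")
  structure(list(points = points, closed = isTRUE(closed)),
            class = "ring_contour")
}

#' Opening angle of a cut arterial ring
#'
#' After a radial cut a ring springs open, releasing circumferential residual
#' strain. The opening angle alpha is the interior angle at the midpoint of
#' the opened ring's perimeter between the two rays joining that midpoint to
#' the cut ends. Under this convention an unopened ring gives alpha near 0
#' and a ring that springs fully flat gives 180 degrees: for a circular arc
#' of central angle 2 phi the angle at the arc midpoint is 180 - phi degrees,
#' so alpha = 180 - (central angle)/2.
#'
#' @param contour a [ring_contour()]; must be open (cut) and ordered along
#'   the arc.
#' @return An object of class `opening_angle_result`: `alpha` (degrees),
#'   `endpoint_1`, `endpoint_2`, `perimeter_midpoint`.
#' @examples
#' th <- seq(-pi / 2, pi / 2, length.out = 200)   # semicircle: 2 phi = 180
#' opening_angle(ring_contour(1000 * cbind(cos(th), sin(th))))$alpha  # 90
#' @export
opening_angle <- function(contour) {
  stopifnot(inherits(contour, "ring_contour"))
  pts <- contour$points
  s <- arc_length(pts)
  total <- s[length(s)]
  gap <- sqrt(sum((pts[1L, ] - pts[nrow(pts), ])^2))
  if (contour$closed || gap < 0.02 * total)
    stop("contour is closed (no cut detected); opening angle undefined",
         call. = FALSE)
  e1 <- pts[1L, ]
  e2 <- pts[nrow(pts), ]
  midpt <- point_at_arclength(pts, total / 2)
  v1 <- e1 - midpt
  v2 <- e2 - midpt
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 * total || n2 < 1e-9 * total)
    stop("degenerate contour: perimeter midpoint coincides with an endpoint",
         call. = FALSE)
  cosang <- sum(v1 * v2) / (n1 * n2)
  alpha <- acos(min(max(cosang, -1), 1)) * 180 / pi
  structure(list(alpha = alpha, endpoint_1 = e1, endpoint_2 = e2,
                 perimeter_midpoint = midpt),
            class = "opening_angle_result")
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' alpha_C = k/(k-1) * (1 - sum_i var(item_i) / var(sum of items)), with
#' sample variances over rows. Used here to quantify the reliability of
#' repeated opening-angle measurements (samples = rings, items = the three
#' repeat measurements).
#'
#' @param measurements numeric matrix, `n_samples x k_items`, no missing
#'   cells, `n_samples >= 2`, `k_items >= 2`.
#' @return Cronbach's alpha (<= 1).
#' @examples
#' m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2)  # identical items
#' cronbach_alpha(m)   # exactly 1
#' @export
cronbach_alpha <- function(measurements) {
  m <- as.matrix(measurements)
  if (any(is.na(m))) stop_field("measurements", "must have no missing cells")
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop_field("measurements", "needs >= 2 samples and >= 2 items")
  k <- ncol(m)
  item_vars <- apply(m, 2L, stats::var)
  total_var <- stats::var(rowSums(m))
  if (total_var <= .Machine$double.eps)
    stop("total score variance is zero; Cronbach's alpha undefined",
         call. = FALSE)
  k / (k - 1) * (1 - sum(item_vars) / total_var)
}

#' Repeatability report for triplicate opening-angle measurements
#'
#' Computes the per-sample standard deviation of the replicate measurements,
#' the study-wide maximum and minimum SD, and Cronbach's alpha across
#' replicate positions (requires >= 2 samples; reported as NA with a flag
#' otherwise).
#'
#' @param replicate_alphas numeric matrix, `n_samples x k_replicates`
#'   (k >= 2), one row per ring specimen.
#' @return A list of class `reliability_report`: `per_sample_sd`, `max_sd`,
#'   `min_sd`, `cronbach_alpha`, `n_samples`, `n_items`,
#'   `alpha_available`.
#' @export
repeatability <- function(replicate_alphas) {
  m <- as.matrix(replicate_alphas)
  if (nrow(m) < 1L || ncol(m) < 2L)
    stop_field("replicate_alphas", "needs >= 1 sample with >= 2 replicates")
  sds <- apply(m, 1L, stats::sd)
  alpha_ok <- nrow(m) >= 2L
  a <- if (alpha_ok) cronbach_alpha(m) else NA_real_
  structure(list(per_sample_sd = sds, max_sd = max(sds), min_sd = min(sds),
                 cronbach_alpha = a, n_samples = nrow(m), n_items = ncol(m),
                 alpha_available = alpha_ok),
            class = "reliability_report")
}
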