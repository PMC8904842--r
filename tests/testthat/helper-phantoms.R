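# Shared fixtures, all generated in code.

default_gt <- function(...) {
  tensile_ground_truth(E1_true = 14, E2_true = 3100, lambda_a = 2.2,
                       lambda_b = 3.0, lambda_r_true = 4.4, ...)
}

# a small RGB image containing n_pairs of touching dark disc pairs on a
# white background, for watershed checks
touching_pairs_image <- function(n_pairs, radius = 10, gap_frac = 1.5,
                                 seed = 1) {
  set.seed(seed)
  size <- ceiling(sqrt(n_pairs) * 12 * radius) + 40L
  img <- matrix(1, size, size)
  centers <- list()
  placed <- 0L
  tries <- 0L
  while (placed < n_pairs && tries < 20000L) {
    tries <- tries + 1L
    cx <- runif(1, 4 * radius, size - 4 * radius)
    cy <- runif(1, 4 * radius, size - 4 * radius)
    ok <- all(vapply(centers, function(p)
      sqrt(sum((p - c(cx, cy))^2)) > 5.5 * radius, TRUE))
    if (!ok) next
    placed <- placed + 1L
    centers[[placed]] <- c(cx, cy)
  }
  stopifnot(placed == n_pairs)
  dx <- matrix(rep(seq_len(size), each = size), size)
  dy <- matrix(rep(seq_len(size), times = size), size)
  for (p in centers) {
    th <- runif(1, 0, pi)
    off <- gap_frac * radius * c(cos(th), sin(th)) / 2
    for (s in c(-1, 1)) {
      c1 <- p + s * off
      img[sqrt((dx - c1[1])^2 + (dy - c1[2])^2) <= radius] <- 0.2
    }
  }
  rgb <- array(255 * img, dim = c(size, size, 3))
  roi <- cbind(c(2, size - 1, size - 1, 2), c(2, 2, size - 1, size - 1))
  list(image = histology_image(rgb, pixel_size = 1, roi = roi),
       n_true = 2L * n_pairs)
}

# label matrix containing one filled disc and one 2:1 ellipse
disc_ellipse_labels <- function(radius = 30) {
  size <- 8L * radius
  labs <- matrix(0L, size, size)
  dx <- matrix(rep(seq_len(size), each = size), size)
  dy <- matrix(rep(seq_len(size), times = size), size)
  labs[sqrt((dx - 2 * radius)^2 + (dy - 2 * radius)^2) <= radius] <- 1L
  a <- radius * sqrt(2); b <- a / 2   # same area as the disc, aspect 2
  labs[((dx - 5.5 * radius) / a)^2 + ((dy - 5 * radius) / b)^2 <= 1] <- 2L
  labs
}
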