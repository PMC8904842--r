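# Internal validation and numeric helpers shared across modules.

#' @keywords internal
#' @noRd
stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_field(field, "must be a single positive finite number")
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_field(field, "must be a single non-negative finite number")
  invisible(x)
}

# centered moving average; edge windows shrink symmetrically so that
# linear trends pass through unchanged
moving_average <- function(x, window = 5L) {
  n <- length(x)
  if (window <= 1L || n < window) return(x)
  half <- window %/% 2L
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    out[i] <- (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
  }
  out
}

# cumulative arc length of an ordered 2-column coordinate matrix
arc_length <- function(pts) {
  d <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(d))
}

# linear interpolation of a point at a given arc-length position
point_at_arclength <- function(pts, s_target) {
  s <- arc_length(pts)
  i <- findInterval(s_target, s, rightmost.closed = TRUE)
  i <- max(1L, min(i, nrow(pts) - 1L))
  if (s[i + 1L] == s[i]) return(pts[i, ])
  f <- (s_target - s[i]) / (s[i + 1L] - s[i])
  pts[i, ] + f * (pts[i + 1L, ] - pts[i, ])
}

# even-odd rule point-in-polygon, vectorised over query points
points_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]
    xj <- poly_x[j]; yj <- poly_y[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
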