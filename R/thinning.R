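# Binary image thinning and midline extraction for the ring-opening test.
# Zhang-Suen thinning reduces the wall band to a 1-pixel skeleton; the
# midline is then the longest geodesic path between skeleton endpoints.

# shift a matrix by (dr, dc), zero-padding
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Zhang-Suen binary thinning
#'
#' Iteratively peels a binary shape down to its 1-pixel-wide skeleton using
#' the two-subiteration Zhang-Suen scheme.
#'
#' @param img logical or 0/1 matrix.
#' @param max_iter safety cap on iterations (default 500).
#' @return Logical matrix of skeleton pixels.
#' @export
thin_binary <- function(img, max_iter = 500L) {
  m <- matrix(as.integer(as.logical(img)), nrow(img), ncol(img))
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours P2..P9 clockwise from north
      p2 <- shift_mat(m, 1, 0);  p3 <- shift_mat(m, 1, -1)
      p4 <- shift_mat(m, 0, -1); p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1);  p9 <- shift_mat(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) a <- a + (seqs[[i]] == 0L & seqs[[i + 1L]] == 1L)
      if (sub == 1L) {
        c1 <- p2 * p4 * p6
        c2 <- p4 * p6 * p8
      } else {
        c1 <- p2 * p4 * p8
        c2 <- p2 * p6 * p8
      }
      del <- m == 1L & b >= 2L & b <= 6L & a == 1L & c1 == 0L & c2 == 0L
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# 8-connected neighbours of skeleton pixel k (row-major index into subset)
skeleton_graph <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  n <- nrow(idx)
  key <- idx[, 1L] + (idx[, 2L] - 1L) * nrow(skel)
  lookup <- new.env(hash = TRUE, size = n)
  for (k in seq_len(n)) assign(as.character(key[k]), k, envir = lookup)
  adj <- vector("list", n)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (k in seq_len(n)) {
    nb <- integer(0)
    for (o in seq_len(nrow(offs))) {
      r <- idx[k, 1L] + offs$dr[o]; c <- idx[k, 2L] + offs$dc[o]
      if (r >= 1 && r <= nrow(skel) && c >= 1 && c <= ncol(skel) && skel[r, c]) {
        kk <- get(as.character(r + (c - 1L) * nrow(skel)), envir = lookup)
        nb <- c(nb, kk)
      }
    }
    adj[[k]] <- nb
  }
  list(coords = idx, adj = adj)
}

# BFS from `from`; returns distances and parents
bfs_path <- function(adj, from) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  parent <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) if (is.na(dist[w])) {
      dist[w] <- dist[v] + 1L
      parent[w] <- v
      queue <- c(queue, w)
    }
  }
  list(dist = dist, parent = parent)
}

#' Opening angle from a binary ring image
#'
#' Extracts the wall-band midline of a photographed (or rendered) opened ring
#' and delegates to [opening_angle()]. The image must contain exactly one
#' connected wall band with one radial cut: the band is thinned to a
#' skeleton, the midline is taken as the longest geodesic path between
#' skeleton endpoints (which also prunes short thinning spurs), lightly
#' smoothed to suppress rasterization zigzag, and converted to micrometre
#' coordinates.
#'
#' @param image logical/0-1 matrix (rows = y, columns = x), e.g. from
#'   [render_ring_image()] or a thresholded photograph.
#' @param pixel_size um per pixel.
#' @return An [opening_angle()] result.
#' @export
opening_angle_from_image <- function(image, pixel_size) {
  check_positive(pixel_size, "pixel_size")
  img <- matrix(as.logical(image), nrow(image), ncol(image))
  if (!any(img)) stop("image contains no foreground", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(t(img * 1)))
  n_comp <- max(lab)
  if (n_comp != 1L)
    stop("expected exactly one connected wall band, found ", n_comp,
         call. = FALSE)
  skel <- thin_binary(img)
  g <- skeleton_graph(skel)
  deg <- lengths(g$adj)
  ends <- which(deg == 1L)
  if (length(ends) == 0L)
    stop("no cut detected: the ring midline forms a closed loop",
         call. = FALSE)
  # longest geodesic between endpoints (double BFS)
  b1 <- bfs_path(g$adj, ends[1L])
  a <- ends[which.max(b1$dist[ends])]
  b2 <- bfs_path(g$adj, a)
  b <- ends[which.max(b2$dist[ends])]
  path <- b
  while (!is.na(b2$parent[path[1L]])) path <- c(b2$parent[path[1L]], path)
  pts_px <- g$coords[path, , drop = FALSE]
  # near a flat cut the skeleton forks towards the cap corners; trim each
  # path end by the wall half-width (peak of the distance transform) so only
  # clean midline remains
  halfw_px <- max(EBImage::distmap(EBImage::Image(t(img * 1))))
  n_trim <- min(ceiling(halfw_px) + 2L, floor(0.2 * nrow(pts_px)))
  if (n_trim > 0L && nrow(pts_px) > 2L * n_trim + 20L)
    pts_px <- pts_px[(n_trim + 1L):(nrow(pts_px) - n_trim), , drop = FALSE]
  # (x, y) = (column, row)
  xy <- cbind(pts_px[, 2L], pts_px[, 1L])
  w <- min(15L, 2L * (nrow(xy) %/% 8L) + 1L)
  xy <- cbind(moving_average(xy[, 1L], w), moving_average(xy[, 2L], w))

  fg <- which(img, arr.ind = TRUE)
  fg_xy <- cbind(fg[, 2L], fg[, 1L])
  ctr0 <- colMeans(fg_xy)
  ev <- eigen(stats::cov(fg_xy))$vectors
  fg_uv <- sweep(fg_xy, 2L, ctr0) %*% ev        # u = major (chord) axis
  u_ext <- diff(range(fg_uv[, 1L]))
  v_ext <- diff(range(fg_uv[, 2L]))
  if ((v_ext - 2 * halfw_px) / u_ext < 0.15) {
    # shallow arc (or flat strip): sagitta small relative to the chord. The
    # midline is the per-column mid-depth of the band in the principal
    # frame, fitted with a quadratic; this is immune to thinning artefacts
    # at the stubby cut ends and restores the eroded extent.
    nb <- 40L
    bins <- cut(fg_uv[, 1L], breaks = nb)
    cnt <- tapply(fg_uv[, 2L], bins, length)
    vmid <- tapply(fg_uv[, 2L], bins, function(v) (min(v) + max(v)) / 2)
    umid <- tapply(fg_uv[, 1L], bins, mean)
    keep <- !is.na(cnt) & cnt >= 3L
    qf <- stats::lm.fit(cbind(1, umid[keep], umid[keep]^2),
                        vmid[keep])$coefficients
    # bins truncated by the tilted cut faces deviate from the quadratic;
    # refit without them
    for (it in 1:2) {
      res <- vmid[keep] - (qf[1L] + qf[2L] * umid[keep] + qf[3L] * umid[keep]^2)
      s <- stats::mad(res)
      if (s <= 0) break
      keep2 <- keep
      keep2[keep][abs(res) > 2.5 * s] <- FALSE
      if (sum(keep2) < 10L || all(keep2 == keep)) break
      keep <- keep2
      qf <- stats::lm.fit(cbind(1, umid[keep], umid[keep]^2),
                          vmid[keep])$coefficients
    }
    us <- seq(min(fg_uv[, 1L]), max(fg_uv[, 1L]), length.out = 400L)
    mid_uv <- cbind(us, qf[1L] + qf[2L] * us + qf[3L] * us^2)
    pts <- sweep(mid_uv %*% t(ev), 2L, ctr0, FUN = "+") * pixel_size
    return(opening_angle(ring_contour(pts)))
  }
  # otherwise: circumcircle through the path ends and midpoint
  A <- xy[1L, ]; B <- xy[nrow(xy), ]; M <- xy[round(nrow(xy) / 2), ]
  d <- 2 * (A[1L] * (M[2L] - B[2L]) + M[1L] * (B[2L] - A[2L]) +
              B[1L] * (A[2L] - M[2L]))
  a2 <- sum(A^2); m2 <- sum(M^2); b2 <- sum(B^2)
  ctr <- c(a2 * (M[2L] - B[2L]) + m2 * (B[2L] - A[2L]) + b2 * (A[2L] - M[2L]),
           a2 * (B[1L] - M[1L]) + m2 * (A[1L] - B[1L]) + b2 * (M[1L] - A[1L])) / d
  R_fit <- sqrt(sum((A - ctr)^2))
  # a radial cut lies at constant polar angle about the arc centre, so the
  # angular extremes of the foreground pixels locate the cut ends to ~1 px
  mid_xy <- xy[round(nrow(xy) / 2), ]
  th0 <- atan2(mid_xy[2L] - ctr[2L], mid_xy[1L] - ctr[1L])
  th_fg <- atan2(fg[, 1L] - ctr[2L], fg[, 2L] - ctr[1L]) - th0
  th_fg <- (th_fg + pi) %% (2 * pi) - pi
  th_lo <- min(th_fg); th_hi <- max(th_fg)
  if (th_hi - th_lo > 1.95 * pi)
    stop("no cut detected: wall band spans the full circle", call. = FALSE)
  th_seq <- seq(th_lo, th_hi, length.out = max(200L, nrow(xy))) + th0
  arc <- cbind(ctr[1L] + R_fit * cos(th_seq),
               ctr[2L] + R_fit * sin(th_seq)) * pixel_size
  opening_angle(ring_contour(arc))
}
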