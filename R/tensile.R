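#' Uniaxial tensile record
#'
#' Container for one uniaxial tensile test: specimen reference dimensions and
#' the recorded jaw displacement / load series. Dimensions are the unloaded
#' gauge length `l0`, width `w0` and thickness `e0` in mm; displacement is in
#' mm, force in N.
#'
#' @param l0,w0,e0 specimen gauge length, width and thickness (mm), all > 0.
#' @param displacement non-decreasing jaw displacement series (mm), starting
#'   at 0.
#' @param force load series (N), non-negative, same length as `displacement`.
#' @param specimen_id optional specimen label.
#' @return An object of class `tensile_record`.
#' @export
tensile_record <- function(l0, w0, e0, displacement, force,
                           specimen_id = NA_character_) {
  check_positive(l0, "l0"); check_positive(w0, "w0"); check_positive(e0, "e0")
  if (length(displacement) != length(force))
    stop_field("force", "must have the same length as `displacement`")
  if (length(displacement) < 10L)
    stop_field("displacement", "needs at least 10 samples")
  if (any(!is.finite(displacement)) || any(!is.finite(force)))
    stop_field("displacement/force", "must be finite")
  if (displacement[1L] != 0)
    stop_field("displacement", "must start at 0")
  if (any(diff(displacement) < 0))
    stop_field("displacement", "must be non-decreasing (jaw reversal not supported)")
  if (any(force < 0))
    stop_field("force", "must be non-negative")
  structure(
    list(l0 = l0, w0 = w0, e0 = e0,
         displacement = as.numeric(displacement),
         force = as.numeric(force),
         specimen_id = specimen_id),
    class = "tensile_record")
}

#' Stretch from gauge length and displacement
#'
#' lambda_i = (l0 + Delta_i) / l0, so the series starts at 1 for zero
#' displacement.
#'
#' @param l0 gauge length (mm), > 0.
#' @param displacement non-decreasing displacement series (mm).
#' @return Numeric stretch series (dimensionless).
#' @examples
#' compute_stretch(10, c(0, 5))   # 1.0 1.5
#' @export
compute_stretch <- function(l0, displacement) {
  check_positive(l0, "l0")
  if (any(displacement < 0))
    stop_field("displacement", "negative displacement (jaw reversal) not supported")
  if (any(diff(displacement) < 0))
    stop_field("displacement", "must be non-decreasing")
  (l0 + displacement) / l0
}

#' Cauchy stress under incompressibility
#'
#' For an incompressible specimen in uniaxial extension the deformed
#' cross-section is (w0 e0)/lambda, so the Cauchy (true) stress is
#' sigma = F / (w0 e0) * lambda. Inputs in N and mm give N/mm^2 (MPa);
#' the result is reported in kPa.
#'
#' @param force load series (N).
#' @param w0,e0 reference width and thickness (mm), > 0.
#' @param stretch stretch series aligned with `force`.
#' @return Cauchy stress series (kPa).
#' @examples
#' compute_cauchy_stress(0.1, w0 = 2, e0 = 0.5, stretch = 2)  # 200 kPa
#' @export
compute_cauchy_stress <- function(force, w0, e0, stretch) {
  check_positive(w0, "w0"); check_positive(e0, "e0")
  if (length(force) != length(stretch))
    stop_field("stretch", "must align with `force`")
  force / (w0 * e0) * stretch * 1000
}

#' Stress-stretch curve
#'
#' @param stretch strictly increasing stretch series starting at 1.
#' @param stress Cauchy stress series (kPa), same length.
#' @return An object of class `stress_stretch_curve`.
#' @export
stress_stretch_curve <- function(stretch, stress) {
  if (length(stretch) != length(stress))
    stop_field("stress", "must have the same length as `stretch`")
  if (length(stretch) < 3L)
    stop_field("stretch", "needs at least 3 samples")
  if (any(diff(stretch) <= 0))
    stop_field("stretch", "must be strictly increasing")
  if (abs(stretch[1L] - 1) > 1e-9)
    stop_field("stretch", "must start at 1")
  structure(list(stretch = as.numeric(stretch), stress = as.numeric(stress)),
            class = "stress_stretch_curve")
}

#' Convert a tensile record to a stress-stretch curve
#'
#' @param record a [tensile_record()].
#' @return A [stress_stretch_curve()].
#' @export
as_stress_stretch <- function(record) {
  stopifnot(inherits(record, "tensile_record"))
  lam <- compute_stretch(record$l0, record$displacement)
  sig <- compute_cauchy_stress(record$force, record$w0, record$e0, lam)
  keep <- c(TRUE, diff(lam) > 0)   # collapse dwell samples at equal stretch
  stress_stretch_curve(lam[keep], sig[keep])
}

# R^2 of a plain line fit on a subset
window_r2 <- function(x, y) {
  if (length(x) < 3L) return(NA_real_)
  sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
  if (sxx * syy <= .Machine$double.eps) return(1)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  min(sxy^2 / (sxx * syy), 1)
}

# Rolling robust estimate of the local noise level of `raw`, from the
# high-frequency residual raw - smoothed. The residual of a centered moving
# average of window w has variance sigma^2 (1 - 1/w); correct for that.
local_noise <- function(raw, smoothed, smooth_window = 5L, win = 21L) {
  d <- abs(raw - smoothed)
  n <- length(d)
  half <- win %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- stats::median(d[lo:hi])
  }
  out / 0.6745 / sqrt(1 - 1 / smooth_window)
}

# One-sided boundary walk. Starting from an anchor window at the near end of
# (x, y), repeatedly fits a line on the trusted part of the accepted window
# and accepts the next sample while it stays within `dev_mult` local noise
# levels of the prediction. The walk stops only when `consec` confirmation
# samples, spaced `spacing` apart so their smoothed noise is essentially
# independent, all exceed the threshold. Returns the index of the last
# accepted sample and the threshold in force there (for curvature-based
# creep correction by the caller).
boundary_walk <- function(x, y, tau, start, dev_mult = 3, consec = 3L,
                          spacing = 5L, guard = 0.8) {
  m <- length(x)
  j <- start
  while (j < m) {
    j0 <- max(start, floor(guard * j))
    probe <- j + 1L + spacing * (seq_len(consec) - 1L)
    probe <- probe[probe <= m]
    fit <- stats::lm.fit(cbind(1, x[seq_len(j0)]), y[seq_len(j0)])
    pred <- fit$coefficients[1L] + fit$coefficients[2L] * x[probe]
    dev <- abs(y[probe] - pred)
    thr <- dev_mult * tau[probe]
    if (length(probe) == consec && all(dev > thr)) break
    j <- j + 1L
  }
  list(stop = j, threshold = dev_mult * tau[min(j + 1L, m)])
}

# local curvature |d2 sigma / d lambda2| from a quadratic fit around index i
local_curvature <- function(x, y, i, half_win = 15L) {
  lo <- max(1L, i - half_win); hi <- min(length(x), i + half_win)
  if (hi - lo < 5L) return(0)
  xx <- x[lo:hi] - x[i]
  fit <- stats::lm.fit(cbind(1, xx, xx^2), y[lo:hi])
  abs(2 * fit$coefficients[3L])
}

#' Segment the four zones of an arterial stress-stretch curve
#'
#' Arterial tissue in uniaxial extension shows a low-stiffness linear zone, a
#' stiffening transition ("elbow"), a high-stiffness nearly linear zone and a
#' failure zone. This locates the end of the first linear zone (`lambda_a`)
#' and the start of the final linear zone (`lambda_b`) by expanding-window
#' line fits from each end of the pre-rupture curve: a walk accepts samples
#' while they stay within a few local noise levels of the line predicted from
#' the already-accepted window, so each boundary is the last stretch at which
#' the curve is still statistically consistent with its terminal linear zone.
#' Because a smooth stiffening onset only exceeds a noise threshold some way
#' into the transition, the stop position is de-biased by the predicted creep
#' sqrt(2 tau / kappa) (threshold tau, local curvature kappa). The stress
#' series is smoothed by a short moving average before segmentation; the
#' local noise level is estimated from the high-frequency residual, so both
#' additive and proportional noise are handled without a noise model.
#'
#' A degenerate flag is raised when the two walks meet (sharp elbow: both
#' boundaries at the meeting point) or cross over the whole domain (a single
#' straight line with no distinct stiffening; both boundaries are then set to
#' the mid-domain stretch).
#'
#' @param curve a [stress_stretch_curve()].
#' @param smooth_window moving-average window (samples) applied to stress
#'   before segmentation (default 5).
#' @param min_points anchor window size for the walks (default 8).
#' @param dev_mult acceptance threshold in local-noise units (default 3).
#' @param consec consecutive out-of-band samples required to stop a walk
#'   (default 3).
#' @return A list of class `zone_boundaries` with `lambda_a`, `lambda_b`,
#'   `degenerate` and `fit_diagnostics` (R^2 of a line fit on each outer
#'   zone).
#' @export
segment_zones <- function(curve, smooth_window = 5L, min_points = 8L,
                          dev_mult = 3, consec = 3L) {
  stopifnot(inherits(curve, "stress_stretch_curve"))
  sm_all <- moving_average(curve$stress, smooth_window)
  i_max <- which.max(sm_all)          # smoothed argmax: robust to end spikes
  lam <- curve$stretch[seq_len(i_max)]
  raw <- curve$stress[seq_len(i_max)]
  sig <- moving_average(raw, smooth_window)
  m <- length(lam)
  if (m < 3L * min_points)
    stop("too few pre-rupture samples to segment zones", call. = FALSE)

  ns <- local_noise(raw, sig, smooth_window)
  scale <- max(abs(sig))
  if (stats::median(ns) < 1e-7 * scale) {
    # effectively noise-free: walk on the raw series so the moving average
    # does not smear the boundaries by half a window
    sig <- raw
    tau <- rep(1e-9 * scale, m)
  } else {
    tau <- pmax(ns / sqrt(smooth_window), 1e-9 * scale)
  }

  anchor <- max(min_points, 12L, as.integer(round(0.08 * m)))
  fwd <- boundary_walk(lam, sig, tau, start = anchor,
                       dev_mult = dev_mult, consec = consec,
                       spacing = smooth_window)
  bwd <- boundary_walk(rev(-lam), rev(sig), rev(tau), start = anchor,
                       dev_mult = dev_mult, consec = consec,
                       spacing = smooth_window)
  ia <- fwd$stop
  jb <- m - bwd$stop + 1L

  # creep de-bias: a C1 transition crosses the noise band ~sqrt(2 tau/kappa)
  # past the true boundary
  step <- stats::median(diff(lam))
  creep <- function(i, thr) {
    kap <- local_curvature(lam, sig, i)
    if (kap <= 0) return(0)
    min(sqrt(2 * thr / kap), 0.25 * (lam[jb] - lam[ia] + step))
  }
  lambda_a <- lam[ia]
  lambda_b <- lam[jb]
  if (jb > ia) {
    lambda_a <- max(lam[min_points], lambda_a - creep(ia, fwd$threshold))
    lambda_b <- min(lam[m - min_points + 1L],
                    lambda_b + creep(jb, bwd$threshold))
  }

  degenerate <- FALSE
  if (jb <= ia) {
    if (jb <= anchor + 1L && ia >= m - anchor) {
      # both walks crossed the whole curve: single straight line
      degenerate <- TRUE
      lambda_a <- lambda_b <- lam[(1L + m) %/% 2L]
    } else {
      # walks met at a sharp elbow: place both at the line intersection
      f1 <- stats::lm.fit(cbind(1, lam[seq_len(max(ia - consec, min_points))]),
                          sig[seq_len(max(ia - consec, min_points))])$coefficients
      i2 <- min(jb + consec, m - min_points + 1L):m
      f2 <- stats::lm.fit(cbind(1, lam[i2]), sig[i2])$coefficients
      cross <- if (abs(f2[2L] - f1[2L]) > 1e-12)
        (f1[1L] - f2[1L]) / (f2[2L] - f1[2L]) else (lam[ia] + lam[jb]) / 2
      cross <- min(max(cross, lam[1L]), lam[m])
      lambda_a <- lambda_b <- cross
      degenerate <- TRUE
    }
    ia <- max(which(lam <= lambda_a + 1e-12))
    jb <- min(which(lam >= lambda_b - 1e-12))
  }
  structure(list(lambda_a = unname(lambda_a), lambda_b = unname(lambda_b),
                 degenerate = degenerate,
                 fit_diagnostics = c(
                   r2_zone1 = window_r2(lam[seq_len(ia)], sig[seq_len(ia)]),
                   r2_zone3 = window_r2(lam[jb:m], sig[jb:m]))),
            class = "zone_boundaries")
}

#' Transition ("elbow") point of the stress-stretch curve
#'
#' The transition point is the midpoint between the end of the low-stiffness
#' zone and the start of the high-stiffness zone:
#' lambda_t = (lambda_a + lambda_b)/2 and
#' sigma_t = (sigma(lambda_a) + sigma(lambda_b))/2, with stresses linearly
#' interpolated on the curve.
#'
#' @param curve a [stress_stretch_curve()].
#' @param zones a `zone_boundaries` from [segment_zones()].
#' @return Named numeric vector `c(lambda_t =, sigma_t =)` (kPa for stress).
#' @export
transition_point <- function(curve, zones) {
  stopifnot(inherits(curve, "stress_stretch_curve"),
            inherits(zones, "zone_boundaries"))
  s_a <- stats::approx(curve$stretch, curve$stress, zones$lambda_a,
                       rule = 2)$y
  s_b <- stats::approx(curve$stretch, curve$stress, zones$lambda_b,
                       rule = 2)$y
  c(lambda_t = (zones$lambda_a + zones$lambda_b) / 2,
    sigma_t = (s_a + s_b) / 2)
}

#' Low- and high-strain tangent moduli
#'
#' Ordinary least-squares slopes of stress versus stretch on the first linear
#' zone (`[1, lambda_a]`, giving `E1`) and the final linear zone
#' (`[lambda_b, lambda at max stress]`, giving `E2`), both on the raw
#' (unsmoothed) curve.
#'
#' @inheritParams transition_point
#' @param min_points minimum samples required in each zone (default 5).
#' @return Named numeric vector `c(E1 =, E2 =)` in kPa.
#' @export
fit_slopes <- function(curve, zones, min_points = 5L) {
  stopifnot(inherits(curve, "stress_stretch_curve"),
            inherits(zones, "zone_boundaries"))
  i_max <- which.max(moving_average(curve$stress, 5L))
  in1 <- which(curve$stretch <= zones$lambda_a + 1e-12)
  in2 <- which(curve$stretch >= zones$lambda_b - 1e-12 &
                 seq_along(curve$stretch) <= i_max)
  if (length(in1) < min_points)
    stop("fewer than ", min_points, " samples in the low-strain zone",
         call. = FALSE)
  if (length(in2) < min_points)
    stop("fewer than ", min_points, " samples in the high-strain zone",
         call. = FALSE)
  e1 <- stats::lm.fit(cbind(1, curve$stretch[in1]),
                      curve$stress[in1])$coefficients[2L]
  e2 <- stats::lm.fit(cbind(1, curve$stretch[in2]),
                      curve$stress[in2])$coefficients[2L]
  if (e2 < e1)
    warning("fitted E2 < E1: curve is not physiologically shaped",
            call. = FALSE)
  c(E1 = unname(e1), E2 = unname(e2))
}

#' Rupture (breaking) point detection
#'
#' A sample qualifies as the breaking point when the stress within the next
#' `lookahead` samples falls by more than `drop_frac` of its value; among
#' qualifying samples the one of maximum stress is returned. When no sample
#' qualifies (e.g. the test stopped before failure) the last sample is
#' returned with `ruptured = FALSE`.
#'
#' @param curve a [stress_stretch_curve()].
#' @param drop_frac minimum relative stress drop identifying failure
#'   (default 0.2).
#' @param lookahead number of following samples inspected for the drop
#'   (default 5).
#' @return List with `lambda_r`, `sigma_r` (kPa) and logical `ruptured`.
#' @export
detect_rupture <- function(curve, drop_frac = 0.2, lookahead = 5L) {
  stopifnot(inherits(curve, "stress_stretch_curve"))
  sig <- curve$stress
  n <- length(sig)
  if (n == 0L) stop("empty curve", call. = FALSE)
  floor_after <- rep(Inf, n)
  run <- Inf
  for (i in n:1) {                       # min of the next `lookahead` samples
    if (i < n) run <- min(sig[i + 1L],
                          if (i + lookahead <= n) {
                            min(sig[(i + 1L):(i + lookahead)])
                          } else min(sig[(i + 1L):n]))
    floor_after[i] <- if (i < n) run else Inf
  }
  cand <- which(floor_after < (1 - drop_frac) * sig & sig > 0)
  if (length(cand) == 0L)
    return(list(lambda_r = curve$stretch[n], sigma_r = sig[n],
                ruptured = FALSE))
  i_r <- cand[which.max(sig[cand])]
  list(lambda_r = curve$stretch[i_r], sigma_r = sig[i_r], ruptured = TRUE)
}

#' Strain energy density by Simpson's rule
#'
#' Integrates the stress-stretch curve from lambda = 1 to `lambda_end` with
#' composite Simpson's rule on a uniform grid (the curve is resampled by
#' linear interpolation, so experimental non-uniform sampling is supported).
#' Stress in kPa integrated over dimensionless stretch gives energy per unit
#' reference volume in uJ/mm^3 (numerically equal to kPa).
#'
#' @param curve a [stress_stretch_curve()].
#' @param lambda_end upper integration limit (>= 1, within the curve domain).
#' @param n_grid number of resampling nodes (default 1001; forced odd so the
#'   interval count is even as Simpson's rule requires).
#' @return Strain energy density (uJ/mm^3).
#' @examples
#' lam <- seq(1, 3, length.out = 1001)
#' cv <- stress_stretch_curve(lam, 100 * (lam - 1))
#' strain_energy(cv, 3)   # 200 = k (lambda_end - 1)^2 / 2
#' @export
strain_energy <- function(curve, lambda_end, n_grid = 1001L) {
  stopifnot(inherits(curve, "stress_stretch_curve"))
  if (!is.finite(lambda_end) || lambda_end < 1)
    stop_field("lambda_end", "must be >= 1")
  if (lambda_end > max(curve$stretch) + 1e-9)
    stop_field("lambda_end", "outside the curve domain")
  if (lambda_end == 1) return(0)
  if (n_grid %% 2L == 0L) n_grid <- n_grid + 1L
  grid <- seq(1, lambda_end, length.out = n_grid)
  f <- stats::approx(curve$stretch, curve$stress, grid, rule = 2)$y
  h <- (lambda_end - 1) / (n_grid - 1L)
  idx <- seq_len(n_grid)
  w <- ifelse(idx %% 2L == 0L, 4, 2)
  w[c(1L, n_grid)] <- 1
  sum(w * f) * h / 3
}

#' Full tensile analysis of one specimen
#'
#' Composes the tensile operations: converts the record to a Cauchy
#' stress-stretch curve, segments the four zones, fits the low- and
#' high-strain moduli, locates the transition and rupture points, and
#' integrates the strain energies up to the transition stretch (`Et`) and the
#' rupture stretch (`Er`). When the record ends before failure, `lambda_r` /
#' `sigma_r` report the last sample and `Er` is `NA` (flagged via
#' `ruptured = FALSE`).
#'
#' @param record a [tensile_record()].
#' @param smooth_window,min_points passed to [segment_zones()] /
#'   [fit_slopes()].
#' @param drop_frac,lookahead passed to [detect_rupture()].
#' @param n_grid passed to [strain_energy()].
#' @return An object of class `mechanical_parameters`: a list with `E1`,
#'   `E2` (kPa), `lambda_t`, `sigma_t` (kPa), `lambda_r`, `sigma_r` (kPa),
#'   `Et`, `Er` (uJ/mm^3), plus `ruptured`, `degenerate` and
#'   `fit_diagnostics`.
#' @export
analyze_tensile <- function(record, smooth_window = 5L,
                            min_points = 5L, drop_frac = 0.2,
                            lookahead = 5L, n_grid = 1001L) {
  curve <- as_stress_stretch(record)
  zones <- segment_zones(curve, smooth_window = smooth_window,
                         min_points = min_points)
  slopes <- fit_slopes(curve, zones, min_points = min_points)
  tp <- transition_point(curve, zones)
  rp <- detect_rupture(curve, drop_frac = drop_frac, lookahead = lookahead)
  et <- strain_energy(curve, tp[["lambda_t"]], n_grid = n_grid)
  er <- if (rp$ruptured)
    strain_energy(curve, rp$lambda_r, n_grid = n_grid) else NA_real_
  structure(
    list(E1 = slopes[["E1"]], E2 = slopes[["E2"]],
         lambda_t = tp[["lambda_t"]], sigma_t = tp[["sigma_t"]],
         lambda_r = rp$lambda_r, sigma_r = rp$sigma_r,
         Et = et, Er = er,
         ruptured = rp$ruptured, degenerate = zones$degenerate,
         fit_diagnostics = zones$fit_diagnostics,
         specimen_id = record$specimen_id),
    class = "mechanical_parameters")
}

#' @export
print.mechanical_parameters <- function(x, ...) {
  cat("Tensile mechanical parameters",
      if (!is.na(x$specimen_id)) paste0("(", x$specimen_id, ")"), "\n")
  cat(sprintf("  E1 = %.3g kPa   E2 = %.4g kPa\n", x$E1, x$E2))
  cat(sprintf("  transition: lambda_t = %.3f, sigma_t = %.4g kPa\n",
              x$lambda_t, x$sigma_t))
  cat(sprintf("  rupture:    lambda_r = %.3f, sigma_r = %.4g kPa%s\n",
              x$lambda_r, x$sigma_r,
              if (!x$ruptured) " [no rupture detected]" else ""))
  cat(sprintf("  energies:   Et = %.4g, Er = %s uJ/mm^3\n",
              x$Et, if (is.na(x$Er)) "NA" else sprintf("%.4g", x$Er)))
  invisible(x)
}
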