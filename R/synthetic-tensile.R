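# Synthetic tensile curves with closed-form ground truth.
#
# The noise-free stress-stretch curve is piecewise:
#   zone 1: sigma = E1 (lambda - 1)                 on [1, lambda_a]
#   zone 2: monotone cubic Hermite bridge           on [lambda_a, lambda_b]
#   zone 3: sigma = sigma_b + E2 (lambda - lambda_b) on [lambda_b, lambda_r]
#   zone 4: linear drop to 5% of sigma_r over 2% stretch, then flat
# The Hermite end value sigma_b = sigma_a + (E1+E2)/2 (lambda_b - lambda_a)
# makes the bridge slope ratio m/Delta lie in (0, 2), which satisfies the
# Fritsch-Carlson monotonicity condition, so the bridge is monotone and C1.
# All ground-truth energies are exact piecewise-polynomial integrals.

# run expr with a temporarily seeded RNG, restoring the caller's state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialise a RNG state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Ground-truth parameter set for a synthetic tensile curve
#'
#' Defines the noise-free four-zone stress-stretch curve a synthetic tensile
#' record is built from: a linear low-stiffness zone of slope `E1_true` up to
#' `lambda_a`, a smooth monotone C1 (cubic Hermite) stiffening transition up
#' to `lambda_b`, a linear high-stiffness zone of slope `E2_true` up to the
#' rupture stretch `lambda_r_true`, and a modelled post-rupture stress drop.
#'
#' @param E1_true,E2_true low- and high-strain slopes (kPa), `E2 > E1 > 0`.
#' @param lambda_a,lambda_b,lambda_r_true end of zone 1, start of zone 3 and
#'   rupture stretch; `1 < lambda_a <= lambda_b < lambda_r_true`
#'   (`lambda_a == lambda_b` gives the degenerate sharp-elbow bilinear curve).
#' @param l0,w0,e0 specimen dimensions (mm).
#' @param noise_sd additive Gaussian stress noise, sd in kPa.
#' @param noise_frac proportional Gaussian stress noise, sd as a fraction of
#'   the local noise-free stress (0 disables; may be combined with
#'   `noise_sd`).
#' @param n_points samples per curve.
#' @param seed RNG seed (NULL uses the current RNG state).
#' @return A validated list of class `tensile_ground_truth`.
#' @export
tensile_ground_truth <- function(E1_true = 14, E2_true = 3100,
                                 lambda_a = 2.2, lambda_b = 3.0,
                                 lambda_r_true = 4.4,
                                 l0 = 10, w0 = 4, e0 = 0.18,
                                 noise_sd = 0, noise_frac = 0,
                                 n_points = 500L, seed = NULL) {
  check_positive(E1_true, "E1_true")
  if (E2_true <= E1_true) stop_field("E2_true", "must exceed E1_true")
  if (!(1 < lambda_a)) stop_field("lambda_a", "must exceed 1")
  if (lambda_b < lambda_a) stop_field("lambda_b", "must be >= lambda_a")
  if (lambda_r_true <= lambda_b)
    stop_field("lambda_r_true", "must exceed lambda_b")
  check_positive(l0, "l0"); check_positive(w0, "w0"); check_positive(e0, "e0")
  check_nonneg(noise_sd, "noise_sd"); check_nonneg(noise_frac, "noise_frac")
  if (n_points < 20L) stop_field("n_points", "needs at least 20 samples")
  structure(list(E1_true = E1_true, E2_true = E2_true, lambda_a = lambda_a,
                 lambda_b = lambda_b, lambda_r_true = lambda_r_true,
                 l0 = l0, w0 = w0, e0 = e0, noise_sd = noise_sd,
                 noise_frac = noise_frac, n_points = as.integer(n_points),
                 seed = seed),
            class = "tensile_ground_truth")
}

# noise-free stress at arbitrary stretch for a ground-truth parameter set
true_stress <- function(gt, lambda) {
  E1 <- gt$E1_true; E2 <- gt$E2_true
  la <- gt$lambda_a; lb <- gt$lambda_b; lr <- gt$lambda_r_true
  sa <- E1 * (la - 1)
  h <- lb - la
  sb <- sa + (E1 + E2) / 2 * h
  sr <- sb + E2 * (lr - lb)
  out <- numeric(length(lambda))
  z1 <- lambda <= la
  out[z1] <- E1 * (lambda[z1] - 1)
  z2 <- lambda > la & lambda < lb
  if (any(z2) && h > 0) {
    t <- (lambda[z2] - la) / h
    h00 <- 2 * t^3 - 3 * t^2 + 1
    h10 <- t^3 - 2 * t^2 + t
    h01 <- -2 * t^3 + 3 * t^2
    h11 <- t^3 - t^2
    out[z2] <- h00 * sa + h10 * h * E1 + h01 * sb + h11 * h * E2
  }
  z3 <- lambda >= lb & lambda <= lr
  out[z3] <- sb + E2 * (lambda[z3] - lb)
  z4 <- lambda > lr
  if (any(z4)) {
    lam_end <- lr * 1.02
    frac <- pmin((lambda[z4] - lr) / (lam_end - lr), 1)
    out[z4] <- sr - frac * 0.95 * sr
  }
  pmax(out, 0)
}

# exact integral of the noise-free stress from lambda = 1 to x (x <= lambda_r)
true_energy <- function(gt, x) {
  E1 <- gt$E1_true; E2 <- gt$E2_true
  la <- gt$lambda_a; lb <- gt$lambda_b
  sa <- E1 * (la - 1)
  h <- lb - la
  sb <- sa + (E1 + E2) / 2 * h
  e <- 0
  x1 <- min(x, la)
  e <- e + E1 * (x1 - 1)^2 / 2
  if (x > la && h > 0) {
    s <- min((x - la) / h, 1)
    H00 <- s^4 / 2 - s^3 + s
    H10 <- s^4 / 4 - 2 * s^3 / 3 + s^2 / 2
    H01 <- -s^4 / 2 + s^3
    H11 <- s^4 / 4 - s^3 / 3
    e <- e + h * (H00 * sa + H10 * h * E1 + H01 * sb + H11 * h * E2)
  }
  if (x > lb) {
    d <- x - lb
    e <- e + sb * d + E2 * d^2 / 2
  }
  e
}

#' Generate a synthetic tensile record with known mechanical parameters
#'
#' Samples the four-zone ground-truth curve of `gt` uniformly in stretch from
#' 1 to 4% past rupture, adds the configured stress noise, and back-computes
#' the force series by inverting the Cauchy-stress relation
#' (F = sigma w0 e0 / lambda). The returned `truth` element carries the exact
#' parameters an ideal analysis should recover: the transition point is the
#' zone-2 midpoint (`lambda_t = (lambda_a + lambda_b)/2`,
#' `sigma_t = (sigma(lambda_a) + sigma(lambda_b))/2`) and the strain energies
#' `Et`, `Er` are exact integrals of the noise-free piecewise-polynomial
#' curve.
#'
#' @param gt a [tensile_ground_truth()].
#' @return List with `record` (a [tensile_record()]) and `truth` (named list:
#'   E1, E2, lambda_t, sigma_t, lambda_r, sigma_r, Et, Er).
#' @examples
#' out <- gen_tensile_record(tensile_ground_truth(seed = 1))
#' out$truth$lambda_t   # 2.6 for the default lambda_a = 2.2, lambda_b = 3.0
#' @export
gen_tensile_record <- function(gt) {
  stopifnot(inherits(gt, "tensile_ground_truth"))
  lam <- seq(1, gt$lambda_r_true * 1.04, length.out = gt$n_points)
  sig0 <- true_stress(gt, lam)
  sig <- with_seed(gt$seed, {
    noise <- 0
    if (gt$noise_sd > 0) noise <- noise + stats::rnorm(length(lam), 0, gt$noise_sd)
    if (gt$noise_frac > 0)
      noise <- noise + stats::rnorm(length(lam), 0, gt$noise_frac * pmax(sig0, 0))
    sig0 + noise
  })
  force <- pmax(sig / 1000 * gt$w0 * gt$e0 / lam, 0)
  record <- tensile_record(gt$l0, gt$w0, gt$e0,
                           displacement = (lam - 1) * gt$l0,
                           force = force)
  sa <- gt$E1_true * (gt$lambda_a - 1)
  sb <- sa + (gt$E1_true + gt$E2_true) / 2 * (gt$lambda_b - gt$lambda_a)
  lambda_t <- (gt$lambda_a + gt$lambda_b) / 2
  truth <- list(
    E1 = gt$E1_true, E2 = gt$E2_true,
    lambda_t = lambda_t, sigma_t = (sa + sb) / 2,
    lambda_r = gt$lambda_r_true,
    sigma_r = sb + gt$E2_true * (gt$lambda_r_true - gt$lambda_b),
    Et = true_energy(gt, lambda_t),
    Er = true_energy(gt, gt$lambda_r_true))
  list(record = record, truth = truth)
}

#' Generate a synthetic cohort of tensile records from group-level means
#'
#' Draws per-animal mechanical parameters from normal distributions centred
#' on the group means with between-animal SD = SEM * sqrt(n_ref) (the
#' reference tables report mean +/- SEM at n_ref = 6), builds a ground-truth
#' curve per animal and samples a tensile record from it. Zone boundaries are
#' placed symmetrically around the drawn transition stretch
#' (`lambda_a = lambda_t - half_width`, `lambda_b = lambda_t + half_width`).
#'
#' @param means data frame like [reference_mechanics()] (columns `group`,
#'   `E1`, `E1_sem`, `E2`, `E2_sem`, `lambda_t`, `lambda_t_sem`, `lambda_r`,
#'   `lambda_r_sem`).
#' @param n_per_group animals per group (default 6).
#' @param seed RNG seed for the whole cohort.
#' @param noise_sd,noise_frac measurement noise passed to each record.
#' @param n_points samples per curve.
#' @param half_width half-width of the stiffening transition in stretch units
#'   (default 0.4).
#' @param n_ref reference sample size behind the printed SEMs (default 6).
#' @return List of per-animal entries, each with `group`, `animal`, `record`
#'   and `truth`.
#' @export
gen_tensile_cohort <- function(means = reference_mechanics(),
                               n_per_group = 6L, seed = NULL,
                               noise_sd = 0, noise_frac = 0,
                               n_points = 400L, half_width = 0.4,
                               n_ref = 6L) {
  with_seed(seed, {
    out <- list()
    for (g in seq_len(nrow(means))) {
      for (a in seq_len(n_per_group)) {
        sdv <- function(p) means[[paste0(p, "_sem")]][g] * sqrt(n_ref)
        E1 <- max(stats::rnorm(1, means$E1[g], sdv("E1")), 1)
        E2 <- max(stats::rnorm(1, means$E2[g], sdv("E2")), E1 * 5)
        lt <- max(stats::rnorm(1, means$lambda_t[g], sdv("lambda_t")),
                  1 + half_width + 0.15)
        lr <- max(stats::rnorm(1, means$lambda_r[g], sdv("lambda_r")),
                  lt + half_width + 0.2)
        gt <- tensile_ground_truth(
          E1_true = E1, E2_true = E2,
          lambda_a = lt - half_width, lambda_b = lt + half_width,
          lambda_r_true = lr, noise_sd = noise_sd, noise_frac = noise_frac,
          n_points = n_points, seed = NULL)
        rec <- gen_tensile_record(gt)
        out[[length(out) + 1L]] <- list(group = means$group[g], animal = a,
                                        record = rec$record,
                                        truth = rec$truth)
      }
    }
    out
  })
}
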