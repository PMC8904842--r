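# Uniaxial tensile mechanics: stress/stretch conversion, zone segmentation,
# transition/rupture extraction and strain energies.

test_that("stretch and Cauchy stress follow their defining relations", {
  expect_equal(compute_stretch(10, c(0, 5)), c(1, 1.5))
  expect_equal(compute_stretch(20, c(0, 10, 20, 30)), c(1, 1.5, 2, 2.5))
  expect_error(compute_stretch(10, c(0, -1)), "jaw reversal")

  expect_equal(compute_cauchy_stress(0, 2, 0.5, 1), 0)
  expect_equal(compute_cauchy_stress(0.1, 2, 0.5, 2), 200)
  expect_equal(compute_cauchy_stress(0.05, 1, 1, 1), 50)
  expect_error(compute_cauchy_stress(1, 0, 1, 1), "w0")
})

test_that("stress scales linearly with force (incompressibility relation)", {
  out <- gen_tensile_record(default_gt(n_points = 200))
  rec <- out$record
  rec3 <- tensile_record(rec$l0, rec$w0, rec$e0, rec$displacement,
                         3 * rec$force)
  c1 <- as_stress_stretch(rec)
  c3 <- as_stress_stretch(rec3)
  expect_equal(c3$stress, 3 * c1$stress)
  expect_equal(strain_energy(c3, 3), 3 * strain_energy(c1, 3))
})

test_that("noise-free zone boundaries are recovered within 0.05", {
  out <- gen_tensile_record(default_gt(n_points = 500))
  z <- segment_zones(as_stress_stretch(out$record))
  expect_lt(abs(z$lambda_a - 2.2), 0.05)
  expect_lt(abs(z$lambda_b - 3.0), 0.05)
  expect_false(z$degenerate)
})

test_that("a sharp bilinear elbow collapses both boundaries to the elbow", {
  lam <- seq(1, 4, length.out = 300)
  sig <- ifelse(lam < 2.5, 14 * (lam - 1), 14 * 1.5 + 3100 * (lam - 2.5))
  z <- segment_zones(stress_stretch_curve(lam, sig))
  step <- diff(lam)[1]
  expect_lt(abs(z$lambda_a - 2.5), 3 * step + 1e-9)
  expect_lt(abs(z$lambda_b - 2.5), 3 * step + 1e-9)
})

test_that("a single straight line raises the degenerate flag", {
  lam <- seq(1, 4, length.out = 300)
  z <- segment_zones(stress_stretch_curve(lam, 14 * (lam - 1)))
  expect_true(z$degenerate)
})

test_that("transition point is the zone midpoint with interpolated stress", {
  lam <- seq(1, 4, length.out = 301)
  sig <- 100 * (lam - 1)   # sigma(2) = 100, sigma(3) = 200 on a known line
  cv <- stress_stretch_curve(lam, sig)
  z <- structure(list(lambda_a = 2, lambda_b = 3, degenerate = FALSE,
                      fit_diagnostics = c(r2_zone1 = 1, r2_zone3 = 1)),
                 class = "zone_boundaries")
  tp <- transition_point(cv, z)
  expect_equal(tp[["lambda_t"]], 2.5)
  expect_equal(tp[["sigma_t"]], 150)
})

test_that("slopes are exact on noise-free linear zones", {
  lam <- seq(1, 4, length.out = 400)
  sig <- ifelse(lam < 2.5, 14 * (lam - 1), 14 * 1.5 + 3100 * (lam - 2.5))
  z <- segment_zones(stress_stretch_curve(lam, sig))
  sl <- fit_slopes(stress_stretch_curve(lam, sig), z)
  expect_equal(unname(sl["E1"]), 14, tolerance = 1e-6)
  expect_equal(unname(sl["E2"]), 3100, tolerance = 1e-6)
})

test_that("concave curves warn about E2 < E1 but still return values", {
  lam <- seq(1, 4, length.out = 300)
  sig <- ifelse(lam < 2.5, 3100 * (lam - 1), 3100 * 1.5 + 14 * (lam - 2.5))
  cv <- stress_stretch_curve(lam, sig)
  z <- segment_zones(cv)
  expect_warning(sl <- fit_slopes(cv, z), "E2 < E1")
  expect_true(sl["E2"] < sl["E1"])
})

test_that("rupture detection finds the drop and flags truncated tests", {
  out <- gen_tensile_record(default_gt(n_points = 500))
  cv <- as_stress_stretch(out$record)
  rp <- detect_rupture(cv)
  expect_true(rp$ruptured)
  step <- diff(cv$stretch)[1]
  expect_lt(abs(rp$lambda_r - 4.4), 2 * step)

  # strictly increasing curve: no rupture
  lam <- seq(1, 3, length.out = 100)
  rp2 <- detect_rupture(stress_stretch_curve(lam, 50 * (lam - 1)^2))
  expect_false(rp2$ruptured)
  expect_equal(rp2$lambda_r, 3)
})

test_that("with two maxima, the one followed by a >20% drop is chosen", {
  # first local max higher but followed by a shallow dip; second followed by
  # a deep drop. Brute-force oracle: scan all samples for the drop condition
  # and take the qualifying maximum.
  lam <- seq(1, 5, length.out = 200)
  sig <- 100 * sin((lam - 1) * 1.2) + 100
  sig[lam > 4] <- sig[lam > 4] * seq(1, 0.2, length.out = sum(lam > 4))
  cv <- stress_stretch_curve(lam, sig)
  rp <- detect_rupture(cv, drop_frac = 0.2, lookahead = 5)
  oracle <- {
    n <- length(sig)
    cand <- which(vapply(seq_len(n - 1), function(i) {
      win <- sig[(i + 1):min(i + 5, n)]
      min(win) < 0.8 * sig[i]
    }, TRUE))
    cand[which.max(sig[cand])]
  }
  expect_equal(rp$lambda_r, lam[oracle])
})

test_that("Simpson energy matches closed forms and is exact for cubics", {
  lam <- seq(1, 2, length.out = 1001)
  expect_equal(strain_energy(stress_stretch_curve(lam, rep(5, 1001)), 2), 5)

  lam3 <- seq(1, 3, length.out = 1001)
  expect_equal(strain_energy(stress_stretch_curve(lam3, 100 * (lam3 - 1)), 3),
               200)

  # cubic sampled on the integration grid: Simpson is exact for cubics
  f <- function(x) 2 + 3 * x - x^2 + 0.5 * x^3
  F <- function(x) 2 * x + 1.5 * x^2 - x^3 / 3 + x^4 / 8
  lam_end <- 2.5
  grid <- seq(1, lam_end, length.out = 1001)
  cv <- stress_stretch_curve(grid, f(grid))
  expect_equal(strain_energy(cv, lam_end, n_grid = 1001),
               F(lam_end) - F(1), tolerance = 1e-12)

  expect_error(strain_energy(cv, 0.5), "lambda_end")
})

test_that("Simpson and trapezoid agree within 0.5% on the synthetic curve", {
  out <- gen_tensile_record(default_gt(n_points = 800))
  cv <- as_stress_stretch(out$record)
  simpson <- strain_energy(cv, 4.4)
  grid <- seq(1, 4.4, length.out = 1001)
  y <- approx(cv$stretch, cv$stress, grid)$y
  trap <- sum(diff(grid) * (head(y, -1) + tail(y, -1)) / 2)
  expect_lt(abs(simpson - trap) / trap, 0.005)
})

test_that("full analysis recovers all parameters within 2% without noise", {
  out <- gen_tensile_record(default_gt(n_points = 500))
  p <- analyze_tensile(out$record)
  tr <- out$truth
  for (par in c("E1", "E2", "lambda_t", "sigma_t", "lambda_r", "sigma_r",
                "Et", "Er")) {
    expect_lt(abs(p[[par]] - tr[[par]]) / abs(tr[[par]]), 0.02,
              label = paste("relative error of", par))
  }
  expect_true(p$Et <= p$Er)
})

test_that("noisy seeded records recover the moduli", {
  out <- gen_tensile_record(default_gt(noise_frac = 0.05, n_points = 500,
                                       seed = 7))
  p <- suppressWarnings(analyze_tensile(out$record))
  expect_lt(abs(p$E1 - 14) / 14, 0.10)
  expect_lt(abs(p$E2 - 3100) / 3100, 0.10)
  step <- 4.4 * 1.04 / 499
  expect_lt(abs(p$lambda_r - 4.4), 3 * step)

  # additive-noise example: high-strain modulus within 5%
  out2 <- gen_tensile_record(default_gt(noise_sd = 20, n_points = 500,
                                        seed = 11))
  p2 <- suppressWarnings(analyze_tensile(out2$record))
  expect_lt(abs(p2$E2 - 3100) / 3100, 0.05)
})

test_that("a record truncated before rupture reports Et but flags Er", {
  out <- gen_tensile_record(default_gt(n_points = 500))
  rec <- out$record
  keep <- seq_len(floor(0.75 * length(rec$force)))   # stop inside zone 3
  rec_tr <- tensile_record(rec$l0, rec$w0, rec$e0, rec$displacement[keep],
                           rec$force[keep])
  p <- analyze_tensile(rec_tr)
  expect_false(p$ruptured)
  expect_true(is.finite(p$Et))
  expect_true(is.na(p$Er))
})

test_that("tensile CSV round-trips through the reader", {
  out <- gen_tensile_record(default_gt(n_points = 60))
  path <- tempfile(fileext = ".csv")
  write_tensile_csv(out$record, path)
  rec2 <- read_tensile_csv(path)
  expect_equal(rec2$l0, out$record$l0)
  expect_equal(rec2$force, out$record$force, tolerance = 1e-12)
  expect_equal(rec2$displacement, out$record$displacement, tolerance = 1e-12)
})
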