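# Pre-stretch, opening angle and measurement reliability.

test_that("pre-stretch ratios and region binning follow the definitions", {
  ex <- marker_trace(cbind(seq(0, 40000, 10000), 0), label = "ex_vivo")
  ins <- marker_trace(cbind(seq(0, 60000, 15000), 0), label = "in_situ")
  pm <- compute_prestretch(ins, ex)
  expect_equal(pm$segment_lambdas, rep(1.5, 4))

  same <- compute_prestretch(
    marker_trace(ex$points, label = "in_situ"), ex)
  expect_equal(same$segment_lambdas, rep(1, 4))

  g <- gen_marker_traces(marker_phantom(lambda_true = c(1.2, 1.3, 1.5)))
  pm2 <- compute_prestretch(g$in_situ, g$ex_vivo)
  expect_equal(pm2$segment_lambdas, c(1.2, 1.3, 1.5))
  expect_equal(as.character(pm2$region_bins),
               c("proximal", "middle", "distal"))

  expect_error(compute_prestretch(
    marker_trace(cbind(0:3, 0), label = "in_situ"), ex), "marker counts")
})

test_that("pre-stretch is invariant to a common scale but not to one-sided", {
  g <- gen_marker_traces(marker_phantom(lambda_true = c(1.2, 1.4)))
  s <- 3.7
  both <- compute_prestretch(
    marker_trace(s * g$in_situ$points, label = "in_situ"),
    marker_trace(s * g$ex_vivo$points, label = "ex_vivo"))
  expect_equal(both$segment_lambdas, c(1.2, 1.4))
  one <- compute_prestretch(
    marker_trace(s * g$in_situ$points, label = "in_situ"), g$ex_vivo)
  expect_equal(one$segment_lambdas, s * c(1.2, 1.4))
})

test_that("opening angle matches the arc oracle alpha = 180 - phi", {
  # for an arc of central angle 2 phi, the angle at the arc midpoint between
  # rays to the ends is arccos(-cos phi) = 180 - phi degrees
  for (ca in c(20, 90, 180, 270, 350)) {
    g <- gen_ring_contour(ring_phantom(alpha_true = 180 - ca / 2,
                                       points_per_contour = 400))
    expect_lt(abs(opening_angle(g$contour)$alpha - (180 - ca / 2)), 0.1)
  }
  # straight contour: collinear rays
  strip <- ring_contour(cbind(seq(0, 1000, length.out = 50), 0))
  expect_equal(opening_angle(strip)$alpha, 180)
})

test_that("opening angle is invariant to rigid motion and scaling", {
  g <- gen_ring_contour(ring_phantom(alpha_true = 72, points_per_contour = 300))
  base <- opening_angle(g$contour)$alpha
  th <- 0.83
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pts <- 2.5 * g$contour$points %*% Rm + matrix(c(123, -45), 300, 2,
                                                byrow = TRUE)
  expect_equal(opening_angle(ring_contour(pts))$alpha, base,
               tolerance = 1e-10)
})

test_that("closed and degenerate contours are rejected", {
  g0 <- gen_ring_contour(ring_phantom(alpha_true = 0))
  expect_error(opening_angle(g0$contour), "closed")
})

test_that("image-based opening angle recovers rendered phantoms", {
  ph <- ring_phantom(alpha_true = 120, mid_radius = 1000,
                     wall_thickness = 150, pixel_size = 4)
  res <- opening_angle_from_image(render_ring_image(ph), 4)
  expect_lt(abs(res$alpha - 120), 2)

  strip <- ring_phantom(alpha_true = 180, mid_radius = 500,
                        wall_thickness = 150, pixel_size = 4)
  expect_lt(abs(opening_angle_from_image(render_ring_image(strip), 4)$alpha -
                  180), 2)

  closed <- ring_phantom(alpha_true = 0, mid_radius = 600,
                         wall_thickness = 120, pixel_size = 4)
  expect_error(opening_angle_from_image(render_ring_image(closed), 4),
               "no cut")
})

test_that("Cronbach's alpha matches its closed forms", {
  # identical items: sum of item variances = k sigma^2, total = k^2 sigma^2
  m <- matrix(rep(c(10, 25, 40, 55), 3), ncol = 3)
  expect_equal(cronbach_alpha(m), 1)

  # worked 4 x 3 matrix against an independent brute-force evaluation
  m2 <- matrix(c(12, 15, 11, 18,
                 14, 16, 10, 20,
                 11, 17, 13, 17), ncol = 3)
  k <- 3
  brute <- (k / (k - 1)) *
    (1 - (var(m2[, 1]) + var(m2[, 2]) + var(m2[, 3])) /
       var(m2[, 1] + m2[, 2] + m2[, 3]))
  expect_equal(cronbach_alpha(m2), brute)

  # independent items: alpha near 0 at large n
  set.seed(101)
  m3 <- matrix(rnorm(10000 * 3), ncol = 3)
  expect_lt(abs(cronbach_alpha(m3)), 0.05)

  expect_error(cronbach_alpha(matrix(1, 4, 3)), "variance")
  expect_error(cronbach_alpha(matrix(1:3, ncol = 1)), "items")
})

test_that("alpha is at most 1 over random matrices and shifted items", {
  set.seed(77)
  for (i in 1:25) {
    m <- matrix(rnorm(5 * 3, sd = runif(1, 0.5, 3)), ncol = 3) +
      rnorm(5, sd = 2)   # shared sample effect
    expect_lte(cronbach_alpha(m), 1)
  }
  # items identical up to per-item shifts: exactly 1
  base <- c(3, 9, 1, 7, 5)
  m <- cbind(base, base + 2, base - 1)
  expect_equal(cronbach_alpha(m), 1)
})

test_that("repeatability summarizes triplicates and flags single samples", {
  m <- matrix(c(100, 100, 100,
                80, 90, 100), nrow = 2, byrow = TRUE)
  r <- repeatability(m)
  expect_equal(r$per_sample_sd[1], 0)
  expect_equal(r$per_sample_sd[2], 10)
  expect_equal(r$min_sd, 0)

  ident <- repeatability(matrix(rep(c(50, 70, 90), each = 3), ncol = 3,
                                byrow = TRUE))
  expect_equal(ident$per_sample_sd, rep(0, 3))
  expect_equal(ident$cronbach_alpha, 1)

  single <- repeatability(matrix(c(10, 12, 14), nrow = 1))
  expect_false(single$alpha_available)
  expect_true(is.na(single$cronbach_alpha))

  # known replicate noise is recovered by the mean per-sample SD
  set.seed(42)
  tru <- runif(50, 20, 160)
  trip <- tru + matrix(rnorm(150, 0, 10), 50, 3)
  rr <- repeatability(trip)
  expect_lt(abs(mean(rr$per_sample_sd) - 10) / 10, 0.2)
})

test_that("triplicate angle CSV reshapes to the repeatability matrix", {
  dat <- data.frame(sample_id = rep(c("r1", "r2"), each = 3),
                    replicate = rep(1:3, 2),
                    alpha_deg = c(100, 104, 98, 55, 57, 53))
  path <- tempfile(fileext = ".csv")
  write.csv(dat, path, row.names = FALSE)
  m <- read_angles_csv(path)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(unname(m["r1", ]), c(100, 104, 98))
})
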