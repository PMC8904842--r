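# Generator contracts: determinism, invariants and documented limit cases.

test_that("tensile generation is deterministic and validates inputs", {
  a <- gen_tensile_record(default_gt(noise_frac = 0.05, seed = 3))
  b <- gen_tensile_record(default_gt(noise_frac = 0.05, seed = 3))
  expect_identical(a$record$force, b$record$force)

  c1 <- gen_tensile_record(default_gt(n_points = 100))
  c2 <- gen_tensile_record(default_gt(n_points = 100))
  expect_identical(c1$record$force, c2$record$force)  # zero noise: any seed

  expect_error(tensile_ground_truth(E1_true = -1), "E1_true")
  expect_error(tensile_ground_truth(E2_true = 10), "E2_true")
  expect_error(tensile_ground_truth(lambda_a = 0.9), "lambda_a")
  expect_error(tensile_ground_truth(lambda_b = 2.0, lambda_a = 2.2),
               "lambda_b")
})

test_that("ground-truth transition point is the zone midpoint", {
  out <- gen_tensile_record(default_gt())
  expect_equal(out$truth$lambda_t, 2.6)

  # degenerate sharp elbow: transition equals the elbow point
  gt <- tensile_ground_truth(lambda_a = 2.5, lambda_b = 2.5)
  out2 <- gen_tensile_record(gt)
  expect_equal(out2$truth$lambda_t, 2.5)
  expect_equal(out2$truth$sigma_t, 14 * 1.5)
})

test_that("noise-free curves are monotone non-decreasing before rupture", {
  for (gt in list(default_gt(), tensile_ground_truth(
    E1_true = 8, E2_true = 1711, lambda_a = 2.7, lambda_b = 3.5,
    lambda_r_true = 4.4))) {
    out <- gen_tensile_record(gt)
    cv <- as_stress_stretch(out$record)
    pre <- cv$stretch <= gt$lambda_r_true
    expect_true(all(diff(cv$stress[pre]) >= -1e-9))
  }
})

test_that("generator energies match high-resolution quadrature", {
  gt <- default_gt()
  out <- gen_tensile_record(gt)
  lam <- seq(1, 4.4, length.out = 20001)
  sig <- vasomech:::true_stress(gt, lam)
  trap <- sum(diff(lam) * (head(sig, -1) + tail(sig, -1)) / 2)
  expect_equal(out$truth$Er, trap, tolerance = 1e-6)
})

test_that("ring contours honour the opening-angle geometry", {
  # alpha 90: semicircular arc, recovered by the analysis within 0.1 degree
  g <- gen_ring_contour(ring_phantom(alpha_true = 90, points_per_contour = 300))
  s <- vasomech:::arc_length(g$contour$points)
  expect_equal(max(s), 1000 * pi, tolerance = 1e-3)  # half circumference
  expect_lt(abs(opening_angle(g$contour)$alpha - 90), 0.1)

  # alpha 180: straight strip
  g180 <- gen_ring_contour(ring_phantom(alpha_true = 180))
  spread <- apply(g180$contour$points, 2, function(v) diff(range(v)))
  expect_equal(min(spread), 0)

  # alpha 0: closed circle
  g0 <- gen_ring_contour(ring_phantom(alpha_true = 0))
  expect_true(g0$contour$closed)

  # determinism under jitter
  j1 <- gen_ring_contour(ring_phantom(alpha_true = 120, jitter_sd = 5, seed = 4))
  j2 <- gen_ring_contour(ring_phantom(alpha_true = 120, jitter_sd = 5, seed = 4))
  expect_identical(j1$contour$points, j2$contour$points)
})

test_that("marker traces encode the prescribed per-segment stretches", {
  g <- gen_marker_traces(marker_phantom(lambda_true = rep(1.5, 3),
                                        exvivo_spacing = 10000))
  d_in <- sqrt(rowSums(diff(g$in_situ$points)^2))
  expect_equal(d_in, rep(15000, 3))

  g1 <- gen_marker_traces(marker_phantom(lambda_true = rep(1, 4)))
  expect_equal(diff(g1$in_situ$points[, 1]), diff(g1$ex_vivo$points[, 1]))

  ja <- gen_marker_traces(marker_phantom(rep(1.3, 5),
                                         coordinate_noise_sd = 20, seed = 9))
  jb <- gen_marker_traces(marker_phantom(rep(1.3, 5),
                                         coordinate_noise_sd = 20, seed = 9))
  expect_identical(ja$in_situ$points, jb$in_situ$points)
})

test_that("CCRC generator matches the 4PL closed form", {
  gt <- ccrc_ground_truth(bottom = 10, top = 90, log_ec50 = -6, hill = 1,
                          doses = c(1e-8, 1e-7, 1e-6, 1e-5, 1e-4))
  g <- gen_ccrc(gt)
  expect_equal(g$responses[3], 50)          # dose = EC50: midpoint
  expect_equal(g$responses[5], 90, tolerance = 0.01)  # near top asymptote
  expect_error(ccrc_ground_truth(top = 0, bottom = 0), "top")
})

test_that("histology phantom paints exact fractions and places all nuclei", {
  ph <- histology_phantom(inner_diameter = 400, outer_diameter = 580,
                          media_outer_diameter = 520, pixel_size = 1,
                          n_nuclei = 20, elastin_fraction = 0.25,
                          collagen_fraction = 0.10, seed = 5)
  g <- gen_histology_image(ph)
  # painted mask covers the prescribed fraction of ROI pixels (pixel_size 1)
  expect_equal(sum(g$truth$elastin_mask) / g$truth$roi_area_um2, 0.25,
               tolerance = 0.01)
  expect_equal(g$truth$n_nuclei, 20)
  # nuclei do not overlap painted fiber pixels
  expect_false(any(g$truth$elastin_mask & g$truth$nuclei_mask))

  # analytic luminal perimeter is a circle circumference
  expect_equal(g$truth$luminal_P, pi * 400)

  # determinism
  g2 <- gen_histology_image(ph)
  expect_identical(g$image$rgb, g2$image$rgb)

  # impossible nucleus packing errors out with the achieved count
  ph_bad <- histology_phantom(inner_diameter = 400, outer_diameter = 580,
                              media_outer_diameter = 520, pixel_size = 1,
                              n_nuclei = 5000, seed = 5)
  expect_error(gen_histology_image(ph_bad), "non-overlapping")
})

test_that("phantom ground truth round-trips through the JSON sidecar", {
  truth <- list(alpha_true = 120, mid_radius = 1000,
                lambda_true = c(1.2, 1.3, 1.5))
  path <- tempfile(fileext = ".json")
  write_truth_json(truth, path)
  back <- read_truth_json(path)
  expect_equal(back$alpha_true, 120)
  expect_equal(back$lambda_true, c(1.2, 1.3, 1.5))
})
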