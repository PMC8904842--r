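# Stain deconvolution, nuclei morphometry and vessel geometry.

test_that("deconvolution inverts OD mixing to machine precision", {
  sm <- default_stain_matrix()
  px <- function(w) array(255 * 10^(-as.numeric(sm %*% w)), dim = c(1, 1, 3))
  white <- deconvolve_stains(array(255, dim = c(1, 1, 3)), sm)
  expect_equal(white$elastin[1, 1], 0)
  expect_equal(white$collagen[1, 1], 0)

  pure <- deconvolve_stains(px(c(1, 0, 0)), sm)
  expect_equal(pure$elastin[1, 1], 1, tolerance = 1e-6)
  expect_lt(abs(pure$collagen[1, 1]), 1e-6)

  mixed <- deconvolve_stains(px(c(0.3, 0.7, 0)), sm)
  expect_equal(mixed$elastin[1, 1], 0.3, tolerance = 1e-6)
  expect_equal(mixed$collagen[1, 1], 0.7, tolerance = 1e-6)
  expect_lt(abs(mixed$residual[1, 1]), 1e-6)

  expect_error(stain_matrix(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1)), "singular")
})

test_that("deconvolution tolerates additive RGB noise within 5%", {
  sm <- default_stain_matrix()
  set.seed(8)
  n <- 500
  conc <- cbind(runif(n, 0.2, 0.8), runif(n, 0.1, 0.6), 0)
  od <- conc %*% t(sm)
  rgb0 <- 255 * 10^(-od)
  rgb <- array(NA_real_, dim = c(n, 1, 3))
  for (k in 1:3) rgb[, 1, k] <- rgb0[, k] + rnorm(n, 0, 3)
  maps <- deconvolve_stains(rgb, sm)
  rel <- abs(maps$elastin[, 1] - conc[, 1]) / conc[, 1]
  expect_lt(median(rel), 0.05)
})

test_that("preprocessing preserves uniform images and impulse mass", {
  rgb <- array(200, dim = c(64, 64, 3))
  roi <- cbind(c(2, 63, 63, 2), c(2, 2, 63, 63))
  hi <- histology_image(rgb, 1, roi)
  prep <- preprocess_histology(hi, blur_sigma = 2)
  vals <- prep$gray[prep$mask]
  expect_lt(diff(range(vals)), 1e-6)

  prep0 <- preprocess_histology(hi, blur_sigma = 0)
  expect_equal(unique(as.vector(prep0$gray[prep0$mask])), 200 / 255)

  # impulse: blur redistributes but conserves total mass (away from edges)
  rgb2 <- array(255, dim = c(65, 65, 3))
  rgb2[33, 33, ] <- 0
  hi2 <- histology_image(rgb2, 1, roi = cbind(c(2, 64, 64, 2), c(2, 2, 64, 64)))
  p2 <- preprocess_histology(hi2, blur_sigma = 2)
  deficit <- sum(1 - p2$gray[p2$mask])
  expect_equal(deficit, 1, tolerance = 0.01)

  expect_error(preprocess_histology(
    histology_image(rgb, 1, cbind(c(-5, 63, 63, -5), c(2, 2, 63, 63)))),
    "outside")
})

test_that("moment-based roundness is 1 for discs and b/a for ellipses", {
  labs <- disc_ellipse_labels(radius = 30)
  st <- nuclei_stats(labs, pixel_size = 1, roi_area_um2 = sum(labs >= 0))
  expect_equal(st$count, 2L)
  expect_lt(abs(st$roundness[1] - 1), 0.05)
  expect_lt(abs(st$roundness[2] - 0.5), 0.05)
  # major axis of the disc is its diameter
  expect_equal(st$major_axis[1], 60, tolerance = 0.05)
})

test_that("density is count over ROI area", {
  labs <- matrix(0L, 100, 100)
  labs[10:12, 10:12] <- 1L
  labs[50:52, 50:52] <- 2L
  st <- nuclei_stats(labs, pixel_size = 1, roi_area_um2 = 0.01 * 1e6)
  expect_equal(st$density, 200)   # 2 nuclei in 0.01 mm^2
})

test_that("watershed separates touching disc pairs", {
  tp <- touching_pairs_image(2, radius = 10, seed = 3)
  prep <- preprocess_histology(tp$image, blur_sigma = 1)
  labs <- segment_nuclei(prep, 1, min_area = 5, max_area = 2000)
  expect_equal(max(labs), tp$n_true)

  # blank ROI: zero labels, not an error
  blank <- histology_image(array(255, dim = c(50, 50, 3)), 1,
                           cbind(c(2, 49, 49, 2), c(2, 2, 49, 49)))
  labs0 <- segment_nuclei(preprocess_histology(blank, 1), 1)
  expect_equal(max(labs0), 0L)
})

test_that("watershed recovers at least 95% of nuclei over seeded images", {
  counts <- vapply(1:20, function(s) {
    tp <- touching_pairs_image(6, radius = 9, gap_frac = 1.5, seed = s)
    prep <- preprocess_histology(tp$image, blur_sigma = 1)
    labs <- segment_nuclei(prep, 1, min_area = 5, max_area = 1000)
    max(labs) / tp$n_true
  }, 1)
  expect_gte(mean(counts), 0.95)
})

test_that("fiber fractions are exact on phantoms and monotone in threshold", {
  ph <- histology_phantom(inner_diameter = 400, outer_diameter = 580,
                          media_outer_diameter = 520, pixel_size = 1,
                          n_nuclei = 10, elastin_fraction = 0.40,
                          collagen_fraction = 0.20, seed = 11)
  g <- gen_histology_image(ph)
  prep <- preprocess_histology(g$image, blur_sigma = 0.8)
  maps <- deconvolve_stains(g$image)
  ff <- fiber_fractions(maps, prep$mask)
  expect_lt(abs(ff$elastin_pct - 40), 1)
  expect_lt(abs(ff$collagen_pct - 20), 1)

  # monotone non-increasing in the positivity threshold
  pcts <- vapply(c(0.05, 0.15, 0.25, 0.35),
                 function(t) fiber_fractions(maps, prep$mask, t)$elastin_pct, 1)
  expect_true(all(diff(pcts) <= 0))

  # blank ROI
  blank <- matrix(FALSE, 10, 10)
  expect_equal(fiber_fractions(maps, blank)$elastin_pct, 0)
})

test_that("morphometry formulas are exact and scale-equivariant", {
  m <- morphometry_from_perimeters(pi * 1000, pi * 1240, pi * 1300)
  expect_equal(m$internal_diameter, 1000)
  expect_equal(m$external_diameter, 1300)
  expect_equal(m$intima_media_thickness, 120)
  expect_equal(m$adventitia_thickness, 30)
  expect_equal(m$media_lumen_ratio, 1.24)
  expect_equal(m$cross_section_area, pi / 4 * (1300^2 - 1000^2))

  c_ <- 2.5
  m2 <- morphometry_from_perimeters(c_ * pi * 1000, c_ * pi * 1240,
                                    c_ * pi * 1300)
  expect_equal(m2$internal_diameter, c_ * m$internal_diameter)
  expect_equal(m2$cross_section_area, c_^2 * m$cross_section_area)

  expect_error(morphometry_from_perimeters(10, 5, 20), "perimeters")
})

test_that("reference group means imply the printed media/lumen geometry", {
  # internal diameter 1610 um and intima-media thickness 121.4 um give a
  # media/lumen ratio of (1610 + 2 * 121.4) / 1610, close to (but not
  # exactly, because of per-animal averaging) the tabulated 1.165
  hm <- reference_histology()
  nn <- hm[hm$group == "NN", ]
  implied <- (nn$internal_diameter + 2 * nn$intima_media_thickness) /
    nn$internal_diameter
  expect_equal(implied, 1.1508, tolerance = 1e-4)
  expect_lt(abs(implied - nn$media_lumen_ratio) / nn$media_lumen_ratio, 0.013)
})

test_that("perimeter tracing recovers phantom geometry within 2%", {
  ph <- histology_phantom(inner_diameter = 1600, outer_diameter = 2100,
                          pixel_size = 2, n_nuclei = 0, seed = 1)
  g <- gen_histology_image(ph)
  tp <- trace_perimeters(g$image)
  expect_lt(abs(tp$luminal_P - pi * 1600) / (pi * 1600), 0.02)
  expect_lt(abs(tp$adventitial_P - pi * 2100) / (pi * 2100), 0.02)
  expect_lt(abs(tp$medial_P - g$truth$medial_P) / g$truth$medial_P, 0.02)

  # doubling the pixel size doubles the reported perimeters
  img2 <- histology_image(g$image$rgb, pixel_size = 4, roi = g$image$roi)
  tp2 <- trace_perimeters(img2)
  expect_equal(tp2$luminal_P, 2 * tp$luminal_P)

  # non-annular image errors
  flat <- histology_image(array(120, dim = c(60, 60, 3)), 1,
                          cbind(c(2, 59, 59, 2), c(2, 2, 59, 59)))
  expect_error(trace_perimeters(flat), "annul")
})
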