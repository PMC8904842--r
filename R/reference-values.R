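#' Reference group-level means for intermittent hypobaric hypoxia cohorts
#'
#' Group means and standard errors (n = 6 animals per group) that define the
#' study conditions the synthetic cohort generators emulate: a normobaric
#' normoxia control group (`NN`), a short-term intermittent hypobaric hypoxia
#' group (`STH`, 4 exposure cycles) and a long-term group (`LTH`, 10 cycles)
#' of adult rat thoracic aorta.
#'
#' `reference_mechanics()` returns the uniaxial tensile parameters per group:
#' low-strain modulus `E1` (kPa), high-strain modulus `E2` (kPa), transition
#' stretch `lambda_t` and stress `sigma_t` (kPa), rupture stretch `lambda_r`
#' and stress `sigma_r` (kPa), and strain energies at transition (`Et`) and
#' rupture (`Er`) in uJ/mm^3.
#'
#' `reference_histology()` returns per-group vessel morphometry (diameters,
#' thickness, media/lumen ratio), nuclei statistics (density in count/mm^2,
#' size in um^2, roundness) and elastin/collagen area percentages.
#'
#' @return A data frame with one row per group (`group` column) and one
#'   column per parameter mean, plus matching `<param>_sem` columns.
#' @examples
#' reference_mechanics()
#' reference_histology()$elastin_pct
#' @export
reference_mechanics <- function() {
  data.frame(
    group    = c("NN", "STH", "LTH"),
    E1       = c(13.88, 16.78, 8.01),
    E1_sem   = c(3.12, 3.85, 1.46),
    E2       = c(3102, 4913, 1711),
    E2_sem   = c(707, 633, 304),
    lambda_t = c(2.61, 3.06, 3.09),
    lambda_t_sem = c(0.14, 0.06, 0.25),
    sigma_t  = c(277.41, 496.95, 508.64),
    sigma_t_sem = c(64.06, 8.19, 228.91),
    lambda_r = c(3.80, 4.46, 4.40),
    lambda_r_sem = c(0.19, 0.18, 0.35),
    sigma_r  = c(4272, 6595, 5143),
    sigma_r_sem = c(1168, 511, 1647),
    Et       = c(124.64, 218.61, 261.14),
    Et_sem   = c(35.18, 17.80, 114.76),
    Er       = c(2149, 5731, 3322),
    Er_sem   = c(648, 1614, 1071),
    stringsAsFactors = FALSE
  )
}

#' @rdname reference_mechanics
#' @export
reference_histology <- function() {
  data.frame(
    group = c("NN", "STH", "LTH"),
    internal_diameter = c(1610, 1892, 1962),
    internal_diameter_sem = c(112, 56, 73),
    external_diameter = c(2089, 2367, 2399),
    external_diameter_sem = c(96, 74, 48),
    intima_media_thickness = c(121.4, 128.1, 120.8),
    intima_media_thickness_sem = c(10.12, 9.77, 10.93),
    media_lumen_ratio = c(1.165, 1.153, 1.123),
    media_lumen_ratio_sem = c(0.01, 0.01, 0.01),
    nuclei_density = c(2287, 2110, 1985),
    nuclei_density_sem = c(153, 90, 81),
    nuclei_size = c(23.97, 21.59, 21.7),
    nuclei_size_sem = c(1.08, 0.83, 0.51),
    nuclei_roundness = c(0.45, 0.47, 0.435),
    nuclei_roundness_sem = c(0.01, 0.01, 0.01),
    elastin_pct = c(25.66, 40.69, 24.95),
    elastin_pct_sem = c(0.69, 3.08, 1.10),
    collagen_pct = c(16.53, 21.39, 13.24),
    collagen_pct_sem = c(1.94, 2.92, 1.41),
    stringsAsFactors = FALSE
  )
}
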