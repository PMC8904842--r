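# Plain-text interchange formats: tensile records, contours/traces,
# dose-response tables, triplicate angles and ground-truth sidecar JSON.

#' Read and write tensile records as CSV
#'
#' Format: two header lines with the specimen dimensions
#' (`l0_mm,w0_mm,e0_mm` then their values), followed by a
#' `displacement_mm,force_N` table.
#'
#' @param record a [tensile_record()].
#' @param path file path.
#' @return `read_tensile_csv` returns a [tensile_record()];
#'   `write_tensile_csv` returns the path invisibly.
#' @export
write_tensile_csv <- function(record, path) {
  stopifnot(inherits(record, "tensile_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("l0_mm,w0_mm,e0_mm",
               paste(record$l0, record$w0, record$e0, sep = ",")), con)
  utils::write.csv(data.frame(displacement_mm = record$displacement,
                              force_N = record$force),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tensile_csv
#' @export
read_tensile_csv <- function(path) {
  hdr <- utils::read.csv(path, nrows = 1L)
  dat <- utils::read.csv(path, skip = 2L)
  tensile_record(l0 = hdr$l0_mm, w0 = hdr$w0_mm, e0 = hdr$e0_mm,
                 displacement = dat$displacement_mm, force = dat$force_N,
                 specimen_id = basename(path))
}

#' Read and write 2-D contours / marker traces as CSV (x_um, y_um)
#'
#' @param points two-column coordinate matrix (um) or an object with a
#'   `points` element ([ring_contour()], [marker_trace()]).
#' @param path file path.
#' @return `read_contour_csv` returns a coordinate matrix.
#' @export
write_contour_csv <- function(points, path) {
  if (is.list(points) && !is.null(points$points)) points <- points$points
  utils::write.csv(data.frame(x_um = points[, 1L], y_um = points[, 2L]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  dat <- utils::read.csv(path)
  as.matrix(dat[, c("x_um", "y_um")])
}

#' Read a dose-response table (agent, dose_M, tension_mN_per_mm)
#'
#' @param path CSV path.
#' @return Data frame with `agent`, `dose_M`, `tension_mN_per_mm`.
#' @export
read_ccrc_csv <- function(path) {
  dat <- utils::read.csv(path)
  need <- c("agent", "dose_M", "tension_mN_per_mm")
  if (!all(need %in% names(dat)))
    stop("CCRC CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  dat
}

#' Read triplicate opening-angle measurements (long format)
#'
#' Columns `sample_id, replicate, alpha_deg`; returns the wide
#' samples-by-replicates matrix expected by [repeatability()].
#'
#' @param path CSV path.
#' @return Numeric matrix, one row per sample.
#' @export
read_angles_csv <- function(path) {
  dat <- utils::read.csv(path)
  need <- c("sample_id", "replicate", "alpha_deg")
  if (!all(need %in% names(dat)))
    stop("angles CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  wide <- stats::reshape(dat, idvar = "sample_id", timevar = "replicate",
                         direction = "wide")
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}

#' Write / read a ground-truth sidecar JSON
#'
#' Generators attach exact ground truth to every synthetic artifact; the
#' sidecar makes that truth portable next to the data file. Matrices are
#' stored as nested arrays and restored on read.
#'
#' @param truth named list of ground-truth values.
#' @param path JSON path (conventionally `<artifact>.truth.json`).
#' @return `read_truth_json` returns the list.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a histology image as PNG
#'
#' @param image a [histology_image()] or `h x w x 3` array in 0..255.
#' @param path PNG path.
#' @export
write_histology_png <- function(image, path) {
  if (inherits(image, "histology_image")) image <- image$rgb
  EBImage::writeImage(EBImage::Image(aperm(image / 255, c(2, 1, 3)),
                                     colormode = "Color"), path)
  invisible(path)
}

#' @rdname write_histology_png
#' @param pixel_size,roi see [histology_image()].
#' @export
read_histology_png <- function(path, pixel_size, roi) {
  im <- EBImage::readImage(path)
  arr <- aperm(EBImage::imageData(im), c(2, 1, 3)) * 255
  histology_image(arr, pixel_size = pixel_size, roi = roi)
}
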