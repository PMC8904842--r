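# Study-level orchestration: group summaries, relative differences, and the
# synthetic end-to-end study runner.

#' Signed relative difference between group means
#'
#' 100 (comparison - reference) / reference. Full precision is returned in
#' `percent`; `percent_rounded` carries the value rounded for report text
#' (nearest integer by default).
#'
#' @param reference_mean reference group mean (non-zero).
#' @param comparison_mean comparison group mean.
#' @param digits rounding for the report value (default 0).
#' @return List of class `relative_difference`: `percent`,
#'   `percent_rounded`, `reference_mean`, `comparison_mean`.
#' @examples
#' relative_difference(25.66, 40.69)$percent_rounded   # +59%
#' relative_difference(40.69, 24.95)$percent_rounded   # -39%
#' @export
relative_difference <- function(reference_mean, comparison_mean, digits = 0) {
  if (!is.finite(reference_mean) || reference_mean == 0)
    stop_field("reference_mean", "must be non-zero and finite")
  pct <- 100 * (comparison_mean - reference_mean) / reference_mean
  structure(list(percent = pct, percent_rounded = round(pct, digits),
                 reference_mean = reference_mean,
                 comparison_mean = comparison_mean),
            class = "relative_difference")
}

#' @export
print.relative_difference <- function(x, ...) {
  cat(sprintf("%+g%% (%g -> %g)\n", x$percent_rounded, x$reference_mean,
              x$comparison_mean))
  invisible(x)
}

#' Group mean and standard error
#'
#' Mean and SEM = SD/sqrt(n) per group. A single observation yields SEM 0
#' with `n = 1` flagged, keeping report tables rectangular.
#'
#' @param values named list of numeric vectors, one per group, or a single
#'   numeric vector.
#' @return Data frame with `group`, `mean`, `sem`, `n`.
#' @examples
#' group_summary(list(NN = c(1, 2, 3)))   # mean 2, sem 0.577
#' @export
group_summary <- function(values) {
  if (is.numeric(values)) values <- list(group = values)
  if (any(lengths(values) < 1L)) stop("empty group", call. = FALSE)
  out <- data.frame(
    group = names(values),
    mean = vapply(values, mean, 1),
    sem = vapply(values, function(v)
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0, 1),
    n = lengths(values),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Default synthetic study configuration
#'
#' Describes a three-group (NN/STH/LTH, n = 6) synthetic study whose
#' generating parameters are the reference group means: tensile curves from
#' [reference_mechanics()], ring phantoms with group-level opening angles,
#' and concentration-response records per group. Pass the result (optionally
#' edited) to [run_study()].
#'
#' @param seed study RNG seed.
#' @param n_per_group animals per group.
#' @param stages character vector among `"tensile"`, `"ring"`, `"ccrc"`,
#'   `"histology"`.
#' @param noise_frac proportional stress noise for tensile records.
#' @param output_dir optional directory for report files.
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1L, n_per_group = 6L,
                         stages = c("tensile", "ring", "ccrc"),
                         noise_frac = 0, output_dir = NULL) {
  stages <- match.arg(stages, c("tensile", "ring", "ccrc", "histology"),
                      several.ok = TRUE)
  structure(list(
    seed = as.integer(seed), n_per_group = as.integer(n_per_group),
    stages = stages, noise_frac = noise_frac, output_dir = output_dir,
    groups = c("NN", "STH", "LTH"),
    tensile = list(means = reference_mechanics(), n_points = 400L),
    # group-level mean opening angles (degrees) for ring phantoms
    ring = list(alpha = c(NN = 100, STH = 55, LTH = 50), alpha_sd = 8,
                points_per_contour = 250L, jitter_sd = 2),
    ccrc = list(log_ec50 = c(NN = -6.6, STH = -6.6, LTH = -6.9), hill = 1.4,
                top = 100, bottom = 0, noise_sd = 3,
                doses = 10^seq(-9, -3, length.out = 8)),
    histology = list(means = reference_histology(), pixel_size = 1,
                     inner_diameter = 500, media_outer_diameter = 650,
                     outer_diameter = 720, n_nuclei = 40)),
    class = "study_config")
}

#' Run a synthetic study end to end
#'
#' Generates a full cohort from the configured group-level means, runs every
#' enabled analysis stage per animal, and aggregates group summaries and the
#' key relative differences. Per-animal failures are caught, counted and
#' excluded rather than aborting the run.
#'
#' @param config a [study_config()].
#' @return A list of class `study_report`: `seed`, `groups`, per-stage group
#'   summary data frames, `relative_differences` (data frame) and
#'   `failures`. When `config$output_dir` is set, the report is also written
#'   as JSON plus one CSV per summary table.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  report <- list(seed = config$seed, groups = config$groups,
                 stages = config$stages, failures = character(0))

  if ("tensile" %in% config$stages) {
    cohort <- gen_tensile_cohort(means = config$tensile$means,
                                 n_per_group = config$n_per_group,
                                 seed = config$seed,
                                 noise_frac = config$noise_frac,
                                 n_points = config$tensile$n_points)
    vals <- list()
    for (an in cohort) {
      p <- tryCatch(suppressWarnings(analyze_tensile(an$record)),
                    error = function(e) {
                      report$failures <<- c(report$failures, paste0(
                        "tensile/", an$group, "/", an$animal, ": ",
                        conditionMessage(e)))
                      NULL
                    })
      if (is.null(p)) next
      vals[[length(vals) + 1L]] <- data.frame(
        group = an$group, E1 = p$E1, E2 = p$E2, lambda_t = p$lambda_t,
        sigma_t = p$sigma_t, lambda_r = p$lambda_r, sigma_r = p$sigma_r,
        Et = p$Et, Er = p$Er)
    }
    tens <- do.call(rbind, vals)
    report$tensile <- do.call(rbind, lapply(
      setdiff(names(tens), "group"),
      function(par) {
        gs <- group_summary(split(tens[[par]], tens$group)[config$groups])
        cbind(parameter = par, gs)
      }))
  }

  if ("ring" %in% config$stages) {
    rc <- config$ring
    alphas <- with_seed(config$seed + 1L, {
      lapply(config$groups, function(g) {
        a_animal <- pmin(pmax(stats::rnorm(config$n_per_group,
                                           rc$alpha[[g]], rc$alpha_sd), 2), 178)
        vapply(a_animal, function(a) {
          ct <- gen_ring_contour(ring_phantom(
            alpha_true = a, points_per_contour = rc$points_per_contour,
            jitter_sd = rc$jitter_sd))
          opening_angle(ct$contour)$alpha
        }, 1)
      })
    })
    names(alphas) <- config$groups
    report$ring <- cbind(parameter = "opening_angle", group_summary(alphas))
  }

  if ("ccrc" %in% config$stages) {
    cc <- config$ccrc
    fits <- with_seed(config$seed + 2L, {
      lapply(config$groups, function(g) {
        lapply(seq_len(config$n_per_group), function(i) {
          rec <- gen_ccrc(ccrc_ground_truth(
            bottom = cc$bottom, top = cc$top, log_ec50 = cc$log_ec50[[g]],
            hill = cc$hill, doses = cc$doses, noise_sd = cc$noise_sd))
          fit_ccrc(rec$doses, rec$responses)
        })
      })
    })
    names(fits) <- config$groups
    report$ccrc <- do.call(rbind, lapply(config$groups, function(g) {
      s <- summarize_ccrc_group(fits[[g]])
      data.frame(group = g, pd2_mean = s$pd2$mean, pd2_sem = s$pd2$sem,
                 emax_mean = s$emax$mean, emax_sem = s$emax$sem,
                 n = s$pd2$n, n_excluded = s$n_excluded)
    }))
  }

  if ("histology" %in% config$stages) {
    hc <- config$histology
    hm <- hc$means
    rows <- list()
    for (g in seq_along(config$groups)) {
      grp <- config$groups[g]
      ph <- histology_phantom(
        inner_diameter = hc$inner_diameter,
        outer_diameter = hc$outer_diameter,
        media_outer_diameter = hc$media_outer_diameter,
        pixel_size = hc$pixel_size, n_nuclei = hc$n_nuclei,
        nucleus_mean_area = hm$nuclei_size[hm$group == grp],
        elastin_fraction = hm$elastin_pct[hm$group == grp] / 100,
        collagen_fraction = hm$collagen_pct[hm$group == grp] / 100,
        seed = config$seed + 10L + g)
      gen <- gen_histology_image(ph)
      prep <- preprocess_histology(gen$image, blur_sigma = 0.8)
      maps <- deconvolve_stains(gen$image)
      ff <- fiber_fractions(maps, prep$mask)
      labs <- segment_nuclei(prep, hc$pixel_size)
      st <- nuclei_stats(labs, hc$pixel_size,
                         sum(prep$mask) * hc$pixel_size^2)
      rows[[g]] <- data.frame(group = grp, elastin_pct = ff$elastin_pct,
                              collagen_pct = ff$collagen_pct,
                              nuclei_density = st$density,
                              nuclei_mean_area = st$mean_area)
    }
    report$histology <- do.call(rbind, rows)
    el <- stats::setNames(report$histology$elastin_pct,
                          report$histology$group)
    report$relative_differences <- data.frame(
      parameter = "elastin_pct",
      reference = c("NN", "STH"),
      comparison = c("STH", "LTH"),
      percent = c(relative_difference(el[["NN"]], el[["STH"]])$percent,
                  relative_difference(el[["STH"]], el[["LTH"]])$percent))
  }

  if ("tensile" %in% config$stages) {
    e2 <- report$tensile[report$tensile$parameter == "E2", ]
    rd <- data.frame(
      parameter = "E2",
      reference = c("NN", "STH"),
      comparison = c("STH", "LTH"),
      percent = c(
        relative_difference(e2$mean[e2$group == "NN"],
                            e2$mean[e2$group == "STH"])$percent,
        relative_difference(e2$mean[e2$group == "STH"],
                            e2$mean[e2$group == "LTH"])$percent))
    report$relative_differences <- rbind(report$relative_differences, rd)
  }

  class(report) <- "study_report"
  if (!is.null(config$output_dir)) write_study_report(report, config$output_dir)
  report
}

#' Write a study report to disk
#'
#' JSON report plus one CSV per summary table.
#'
#' @param report a `study_report` from [run_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the JSON path.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in intersect(c("tensile", "ring", "ccrc", "histology",
                          "relative_differences"), names(report))) {
    utils::write.csv(report[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE)
  }
  path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Synthetic study report (seed ", x$seed, ")\n", sep = "")
  for (tab in intersect(c("tensile", "ring", "ccrc", "histology",
                          "relative_differences"), names(x))) {
    cat("\n--", tab, "--\n")
    print(x[[tab]], digits = 4)
  }
  if (length(x$failures))
    cat("\nfailures:\n", paste(" -", x$failures, collapse = "\n"), "\n")
  invisible(x)
}
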