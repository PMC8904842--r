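#' Wall tension from wire-myograph force
#'
#' A mounted ring segment spans the two wires with two wall strips, so the
#' conventional wall tension is force / (2 x segment length). The divisor is
#' configurable because some laboratories normalize per single wall.
#'
#' @param force measured force (mN); may be a series.
#' @param segment_length mounted segment length (mm), > 0.
#' @param walls number of wall strips spanning the wires (default 2).
#' @return Wall tension (mN/mm).
#' @examples
#' wall_tension(8, 2)        # 2 mN/mm
#' wall_tension(8, 2, walls = 1)  # 4 mN/mm
#' @export
wall_tension <- function(force, segment_length, walls = 2) {
  check_positive(segment_length, "segment_length")
  check_positive(walls, "walls")
  force / (walls * segment_length)
}

#' Basal wall tension equivalent to a transmural pressure (Laplace)
#'
#' For a thin-walled cylinder the wall tension equivalent to transmural
#' pressure P at internal radius r is T = P r. With P in mmHg
#' (1 mmHg = 0.133322 kPa) and r in mm, T is returned in mN/mm
#' (1 kPa x mm = 1 mN/mm). Used to set the myograph basal tension to a
#' physiological operating pressure (e.g. 80 mmHg).
#'
#' @param pressure transmural pressure (mmHg), >= 0.
#' @param internal_diameter vessel internal diameter (mm), > 0.
#' @return Target basal wall tension (mN/mm).
#' @examples
#' laplace_basal_tension(80, 1.6)   # 8.533 mN/mm
#' @export
laplace_basal_tension <- function(pressure, internal_diameter) {
  check_nonneg(pressure, "pressure")
  check_positive(internal_diameter, "internal_diameter")
  pressure * 0.133322 * internal_diameter / 2
}

#' Contraction as percentage of maximal potassium contraction
#'
#' %Kmax_i = 100 (T_i - basal) / (Kmax - basal).
#'
#' @param tensions wall tension series (mN/mm).
#' @param kmax_tension tension at maximal K+ contraction (mN/mm).
#' @param basal_tension resting tension (mN/mm).
#' @return %Kmax series.
#' @export
normalize_contraction <- function(tensions, kmax_tension, basal_tension) {
  if (kmax_tension <= basal_tension)
    stop_field("kmax_tension", "must exceed basal_tension")
  100 * (tensions - basal_tension) / (kmax_tension - basal_tension)
}

#' Relaxation as percentage of preconstriction
#'
#' %Rmax_i = 100 (T_pre - T_i) / (T_pre - basal): 0% at the preconstriction
#' plateau, 100% at complete relaxation back to basal tension. The standard
#' protocol preconstricts with 1e-6 M phenylephrine before the vasodilator
#' series.
#'
#' @param tensions wall tension series (mN/mm).
#' @param preconstriction_tension plateau tension after preconstriction
#'   (mN/mm).
#' @param basal_tension resting tension (mN/mm).
#' @return %Rmax (percent relaxation) series.
#' @export
normalize_relaxation <- function(tensions, preconstriction_tension,
                                 basal_tension) {
  if (preconstriction_tension <= basal_tension)
    stop_field("preconstriction_tension", "must exceed basal_tension")
  100 * (preconstriction_tension - tensions) /
    (preconstriction_tension - basal_tension)
}

# four-parameter logistic in log10 dose
fpl <- function(logc, bottom, top, logec50, hill) {
  bottom + (top - bottom) / (1 + 10^((logec50 - logc) * hill))
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares fit of R(c) = bottom + (top - bottom) /
#' (1 + 10^((logEC50 - log10 c) hill)) by Levenberg-Marquardt with
#' multi-start initialization over a logEC50 grid and hill in {0.5, 1, 2}
#' (signs flipped for descending responses). pD2 = -logEC50. The maximal
#' response is the fitted top parameter by default, or the largest observed
#' response with `emax = "observed"`.
#'
#' When `reference_span` is given (typically the preconstriction tension for
#' relaxation curves) and the fitted span is below 10% of it, the response is
#' flagged abolished and pD2 is withheld (NA), mirroring the handling of
#' preparations with no measurable dose effect.
#'
#' @param doses molar concentrations, strictly increasing, >= 4 points
#'   spanning >= 2 log units.
#' @param responses response at each dose (any consistent units).
#' @param emax `"fitted"` (default) or `"observed"`.
#' @param reference_span optional reference response span for the
#'   abolished-response rule.
#' @param abolished_frac span fraction below which the response is declared
#'   abolished (default 0.1).
#' @return An object of class `ccrc_fit`: `ec50`, `pd2`, `emax`, `hill`,
#'   `bottom`, `top`, `rss`, `converged`, `abolished`.
#' @examples
#' d <- 10^seq(-9, -3, by = 1)
#' r <- 100 / (1 + 10^((-6 - log10(d)) * 1))
#' fit_ccrc(d, r)$pd2    # 6
#' @export
fit_ccrc <- function(doses, responses, emax = c("fitted", "observed"),
                     reference_span = NULL, abolished_frac = 0.1) {
  emax <- match.arg(emax)
  if (length(doses) != length(responses))
    stop_field("responses", "must align with doses")
  if (length(doses) < 4L)
    stop_field("doses", "needs >= 4 dose points")
  if (any(doses <= 0) || any(diff(doses) <= 0))
    stop_field("doses", "must be positive and strictly increasing")
  logc <- log10(doses)
  if (diff(range(logc)) < 2)
    stop_field("doses", "must span >= 2 log units")
  if (stats::sd(responses) <= .Machine$double.eps * max(1, abs(mean(responses))))
    stop("responses are constant: no dose effect to fit", call. = FALSE)

  ascending <- stats::cor(logc, responses) >= 0
  span <- diff(range(responses))
  b0 <- if (ascending) min(responses) else max(responses)
  t0 <- if (ascending) max(responses) else min(responses)
  starts <- expand.grid(
    logec50 = stats::quantile(logc, c(0.25, 0.5, 0.75), names = FALSE),
    hill = c(0.5, 1, 2))
  df <- data.frame(logc = logc, y = responses)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ fpl(logc, bottom, top, logec50, hill), data = df,
        start = list(bottom = b0, top = t0,
                     logec50 = starts$logec50[i], hill = starts$hill[i]),
        lower = c(-Inf, -Inf, min(logc) - 3, 0.05),
        upper = c(Inf, Inf, max(logc) + 3, 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss,
                   converged = fit$convInfo$isConv %||% TRUE)
  }
  if (is.null(best))
    return(structure(list(ec50 = NA_real_, pd2 = NA_real_, emax = NA_real_,
                          hill = NA_real_, bottom = NA_real_, top = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          abolished = FALSE),
                     class = "ccrc_fit"))
  cf <- stats::coef(best$fit)
  fitted_span <- abs(cf[["top"]] - cf[["bottom"]])
  abolished <- !is.null(reference_span) &&
    fitted_span < abolished_frac * abs(reference_span)
  pd2 <- if (abolished) NA_real_ else -cf[["logec50"]]
  structure(list(
    ec50 = 10^cf[["logec50"]],
    pd2 = pd2,
    emax = if (emax == "fitted") cf[["top"]] else
      if (stats::cor(logc, responses) >= 0) max(responses) else min(responses),
    hill = cf[["hill"]], bottom = cf[["bottom"]], top = cf[["top"]],
    rss = best$rss, converged = isTRUE(best$converged),
    abolished = abolished),
    class = "ccrc_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ccrc_fit <- function(x, ...) {
  cat("4PL concentration-response fit\n")
  if (x$abolished) cat("  response abolished; pD2 not assessed\n")
  cat(sprintf("  pD2 = %s  (EC50 = %.3g M)\n",
              if (is.na(x$pd2)) "NA" else sprintf("%.3f", x$pd2), x$ec50))
  cat(sprintf("  bottom = %.3g, top = %.3g, hill = %.3g, rss = %.3g%s\n",
              x$bottom, x$top, x$hill, x$rss,
              if (!x$converged) "  [not converged]" else ""))
  invisible(x)
}

#' Group summary of concentration-response fits
#'
#' Mean and SEM of pD2 and the maximal response over a group of per-animal
#' fits. Non-converged fits are excluded and counted; abolished responses
#' contribute their maximal response but no pD2 ("not assessed").
#'
#' @param fits list of [fit_ccrc()] results (>= 2 animals).
#' @return List with `pd2` (mean, sem, n), `emax` (mean, sem, n),
#'   `n_excluded`, `n_abolished`.
#' @export
summarize_ccrc_group <- function(fits) {
  stopifnot(length(fits) >= 2L, all(vapply(fits, inherits, TRUE, "ccrc_fit")))
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (!any(conv)) stop("all fits failed to converge", call. = FALSE)
  ok <- fits[conv]
  pd2 <- vapply(ok, function(f) f$pd2, 1)
  em <- vapply(ok, function(f) f$emax, 1)
  msem <- function(x) {
    x <- x[!is.na(x)]
    list(mean = mean(x),
         sem = if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0,
         n = length(x))
  }
  list(pd2 = msem(pd2), emax = msem(em),
       n_excluded = sum(!conv),
       n_abolished = sum(vapply(ok, function(f) isTRUE(f$abolished), TRUE)))
}

#' Ground truth for a synthetic concentration-response record
#'
#' @param bottom,top response asymptotes (`top != bottom`).
#' @param log_ec50 log10 of the EC50 (M).
#' @param hill slope factor.
#' @param doses molar concentrations, strictly increasing.
#' @param noise_sd additive Gaussian response noise.
#' @param seed RNG seed.
#' @return An object of class `ccrc_ground_truth`.
#' @export
ccrc_ground_truth <- function(bottom = 0, top = 100, log_ec50 = -6, hill = 1,
                              doses = 10^seq(-9, -3, by = 0.75),
                              noise_sd = 0, seed = NULL) {
  if (top == bottom) stop_field("top", "must differ from bottom")
  if (any(doses <= 0) || any(diff(doses) <= 0))
    stop_field("doses", "must be positive and strictly increasing")
  check_nonneg(noise_sd, "noise_sd")
  structure(list(bottom = bottom, top = top, log_ec50 = log_ec50,
                 hill = hill, doses = doses, noise_sd = noise_sd,
                 seed = seed),
            class = "ccrc_ground_truth")
}

#' Generate a synthetic concentration-response record
#'
#' Responses follow the four-parameter logistic
#' bottom + (top - bottom)/(1 + 10^((log_ec50 - log10 dose) hill)) plus
#' additive Gaussian noise.
#'
#' @param gt a [ccrc_ground_truth()].
#' @return List with `doses`, `responses` and `truth` (pd2, emax, hill,
#'   bottom, top).
#' @export
gen_ccrc <- function(gt) {
  stopifnot(inherits(gt, "ccrc_ground_truth"))
  mu <- fpl(log10(gt$doses), gt$bottom, gt$top, gt$log_ec50, gt$hill)
  resp <- with_seed(gt$seed, mu + if (gt$noise_sd > 0)
    stats::rnorm(length(mu), 0, gt$noise_sd) else 0)
  list(doses = gt$doses, responses = resp,
       truth = list(pd2 = -gt$log_ec50, emax = gt$top, hill = gt$hill,
                    bottom = gt$bottom, top = gt$top))
}
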