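#' Welch two-sample t-test
#'
#' Two-sample t-test assuming normal distributions with unknown and
#' unequal variances (Welch-Satterthwaite degrees of freedom), two-tailed,
#' no multiplicity correction. Thin wrapper around [stats::t.test()]
#' returning the group descriptives alongside the test.
#'
#' @param a,b numeric samples (each `n >= 2`).
#' @param measure optional label.
#' @param alpha significance level.
#' @return List of class `group_comparison`: `measure`, `mean_a`, `sd_a`,
#'   `n_a`, `mean_b`, `sd_b`, `n_b`, `t`, `df`, `p`, `significant`.
#' @export
welch_t <- function(a, b, measure = NULL, alpha = 0.05) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 non-missing values", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  structure(list(
    measure = measure,
    mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
    mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, significant = tt$p.value < alpha
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (!is.null(x$measure)) cat(x$measure, "\n")
  cat(sprintf("  %.3f (%.3f) vs %.3f (%.3f): t(%.1f) = %.3f, p = %.4g%s\n",
              x$mean_a, x$sd_a, x$mean_b, x$sd_b, x$df, x$t, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Paired t-test
#'
#' Two-tailed paired t-test on the within-participant differences
#' (`after - before`), `df = n - 1`. A zero-variance nonzero shift is a
#' degenerate case and is flagged (`t` infinite, `p = 0`).
#'
#' @param before,after numeric vectors of equal length (pairs with missing
#'   values are dropped).
#' @return List with `mean_diff`, `t`, `df`, `p`, `n`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  ok <- !is.na(before) & !is.na(after)
  before <- before[ok]
  after <- after[ok]
  if (length(before) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- after - before
  if (stats::sd(d) == 0) {
    ## degenerate: constant shift
    return(list(mean_diff = mean(d),
                t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                df = length(d) - 1,
                p = if (mean(d) == 0) 1 else 0,
                n = length(d), degenerate = mean(d) != 0))
  }
  tt <- stats::t.test(after, before, paired = TRUE)
  list(mean_diff = mean(d), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, n = length(d),
       degenerate = FALSE)
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties. The two-sided p-value uses the
#' t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom; for small samples (`n <= 10`) without ties an exact p-value is
#' available via `exact = TRUE`.
#'
#' @param x,y numeric vectors (pairs with missing values dropped).
#' @param exact use the exact null distribution (small n, no ties).
#' @return List with `rho`, `p`, `n`; `rho` is `NA` (flagged by
#'   `undefined = TRUE`) when either variable has zero rank variance.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(rho = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact,
                    alternative = "two.sided")
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = n, undefined = FALSE)
}

#' NASA-TLX total workload score
#'
#' Mean of the six items (each on the 1-21 tick scale) rescaled to
#' 0-100%: 0% when every item is at 1, 100% when every item is at 21.
#'
#' @param items numeric vector of six item scores in `[1, 21]` (mental,
#'   physical, temporal, performance, effort, frustration).
#' @return Total workload percentage.
#' @export
tlx_total <- function(items) {
  if (length(items) != 6) stop("expected six TLX items", call. = FALSE)
  if (any(is.na(items)) || any(items < 1) || any(items > 21)) {
    stop("TLX items must lie in [1, 21]", call. = FALSE)
  }
  100 * (mean(items) - 1) / 20
}

## "mean (sd)" cell formatting used by the report tables
fmt_cell <- function(m, s, digits = 2) {
  if (is.na(m)) return("-")
  sprintf(paste0("%.", digits, "f (%.", digits, "f)"), m, s)
}

## one report row comparing a measure between groups
report_row <- function(measure, control, glaucoma, digits = 2) {
  ok <- sum(!is.na(control)) >= 2 && sum(!is.na(glaucoma)) >= 2
  if (!ok) {
    return(data.frame(measure = measure, control = "-", glaucoma = "-",
                      p = NA_real_, significant = NA))
  }
  w <- welch_t(control, glaucoma, measure)
  data.frame(
    measure = measure,
    control = fmt_cell(w$mean_a, w$sd_a, digits),
    glaucoma = fmt_cell(w$mean_b, w$sd_b, digits),
    p = w$p,
    significant = w$significant
  )
}

#' Build the study-style report tables
#'
#' Produces the five summary tables of the analysis from a
#' [cohort_metrics()] data frame: participant descriptives, driving
#' measures, letter-task measures, eye-scanning measures (participants
#' failing the gaze-quality criterion are dropped), and the correlation
#' matrix between patients' quadrant sensitivity loss and letter
#' performance. Group comparisons use Welch's t-test at `alpha`.
#'
#' @param metrics a [cohort_metrics()] result.
#' @param alpha significance level for marking comparisons.
#' @return Named list of data frames: `descriptives`, `driving`,
#'   `letters`, `eye_scanning`, `correlations`.
#' @export
build_report <- function(metrics, alpha = 0.05) {
  ctl <- metrics[metrics$group == "control", ]
  gla <- metrics[metrics$group == "glaucoma", ]

  descriptives <- rbind(
    report_row("Percentage of IVF points < 25 dB",
               ctl$ivf_pct_below, gla$ivf_pct_below, 1),
    report_row("Mean deviation OD (dB)", ctl$md_od, gla$md_od),
    report_row("Mean deviation OS (dB)", ctl$md_os, gla$md_os),
    report_row("Mean TLX workload (S1-S4) (%)", ctl$tlx_mean, gla$tlx_mean, 1)
  )

  driving <- rbind(
    report_row("SDLP, non-obstacle periods (S1-S4) (m)",
               ctl$sdlp, gla$sdlp),
    report_row("Steering Activity-high, non-obstacle periods (S1-S4) (deg/s)",
               ctl$sa_high_nonobst, gla$sa_high_nonobst),
    report_row("Steering Activity-high, obstacle periods (S3,S4) (deg/s)",
               ctl$sa_high_obst, gla$sa_high_obst),
    report_row("Steering Activity-low, non-obstacle periods (S1-S4) (deg/s)",
               ctl$sa_low_nonobst, gla$sa_low_nonobst),
    report_row("Steering Activity-low, obstacle periods (S3,S4) (deg/s)",
               ctl$sa_low_obst, gla$sa_low_obst),
    report_row("Longitudinal distance to obstacle (LongDtO) (S3,S4) (m)",
               ctl$long_dto, gla$long_dto, 1),
    report_row("Lateral position to obstacle (LatDtO) (S3,S4) (m)",
               ctl$lat_dto, gla$lat_dto)
  )

  letters <- rbind(
    report_row("Letter Reaction Time (LRT) (S2,S4) (s)",
               ctl$lrt_s, gla$lrt_s),
    report_row("Number of letter misses (S2,S4)",
               ctl$misses, gla$misses)
  )

  ctl_eye <- ctl[!ctl$eye_excluded, ]
  gla_eye <- gla[!gla$eye_excluded, ]
  eye_scanning <- rbind(
    report_row("Gaze directed at top (S1-S4) (% of time)",
               ctl_eye$dwell_top, gla_eye$dwell_top),
    report_row("Gaze directed at bottom (S1-S4) (% of time)",
               ctl_eye$dwell_bottom, gla_eye$dwell_bottom),
    report_row("Number of fixations per second (S1-S4)",
               ctl_eye$fixation_rate, gla_eye$fixation_rate),
    report_row("Mean saccade amplitude (S1-S4) (mm)",
               ctl_eye$saccade_amp, gla_eye$saccade_amp, 0)
  )
  attr(eye_scanning, "n_control") <- nrow(ctl_eye)
  attr(eye_scanning, "n_glaucoma") <- nrow(gla_eye)

  correlations <- if (nrow(gla) >= 5) {
    letter_vf_correlations(gla)
  } else {
    NULL
  }

  list(descriptives = descriptives, driving = driving, letters = letters,
       eye_scanning = eye_scanning, correlations = correlations)
}

#' Write report tables to CSV
#'
#' @param report a [build_report()] result.
#' @param outdir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report)) {
    if (is.null(report[[nm]])) next
    utils::write.csv(report[[nm]],
                     file.path(outdir, paste0("table_", nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(outdir)
}
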