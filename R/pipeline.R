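#' Per-participant metrics for a whole cohort
#'
#' Runs the complete measurement battery on every participant of a
#' (synthetic or file-loaded) cohort and returns one row per participant:
#' visual-field summaries (quadrant loss for the integrated, worse-eye and
#' better-eye fields, MDs, overall % of integrated-field points below
#' 25 dB), driving measures aggregated as in the study tables (non-obstacle
#' measures averaged over S1-S4, obstacle measures over S3-S4), letter
#' misses and pooled mean LRT over S2+S4, eye-scanning measures averaged
#' over the available sessions with the gaze-quality exclusion flag, and
#' mean TLX workload.
#'
#' @param cohort a [generate_cohort()] result.
#' @param gaze_sessions sessions to use for the eye-scanning measures
#'   (all four by default; a subset speeds up large simulation studies).
#' @param exclusion_threshold removed-data fraction above which a
#'   participant is excluded from eye-scanning analyses.
#' @param viewing_distance_mm viewing distance for the fixation detector.
#' @param regions screen regions for [region_dwell()].
#' @return Data frame with one row per participant.
#' @export
cohort_metrics <- function(cohort,
                           gaze_sessions = c("S1", "S2", "S3", "S4"),
                           exclusion_threshold = 0.6,
                           viewing_distance_mm = 780,
                           regions = default_screen_regions()) {
  course <- cohort$course
  rows <- lapply(cohort$participants, function(p) {
    ql_ivf <- quadrant_loss(p$ivf)
    bw <- better_worse_eye(p$vf_od, p$vf_os)
    ql_worse <- quadrant_loss(bw$worse)
    ql_better <- quadrant_loss(bw$better)

    dm <- lapply(names(p$traces), function(s) {
      session_driving_metrics(p$traces[[s]], course, s)
    })
    names(dm) <- names(p$traces)
    get <- function(field, sessions) {
      mean(vapply(sessions, function(s) dm[[s]][[field]], numeric(1)))
    }
    obst_sessions <- intersect(c("S3", "S4"), names(dm))

    sc2 <- score_letters(p$events$S2$letters, p$events$S2$voice_events)
    sc4 <- score_letters(p$events$S4$letters, p$events$S4$voice_events)
    ls <- session_letter_summary(sc2, sc4)

    eye <- list(excluded = NA, dwell_top = NA_real_,
                dwell_bottom = NA_real_, fixation_rate = NA_real_,
                saccade_amp = NA_real_)
    use <- if (is.null(p$gaze)) character(0) else
      intersect(gaze_sessions, names(p$gaze))
    if (length(use) > 0) {
      cleans <- lapply(p$gaze[use], preprocess_gaze)
      eye$excluded <- gaze_excluded(cleans, exclusion_threshold)
      per <- lapply(cleans, function(cg) {
        fx <- detect_fixations(cg, viewing_distance_mm = viewing_distance_mm)
        dw <- region_dwell(cg, regions)
        c(top = unname(dw["top"]), bottom = unname(dw["bottom"]),
          rate = fixation_rate(fx, cg), amp = saccade_amplitude(fx))
      })
      m <- do.call(rbind, per)
      eye$dwell_top <- mean(m[, "top"], na.rm = TRUE)
      eye$dwell_bottom <- mean(m[, "bottom"], na.rm = TRUE)
      eye$fixation_rate <- mean(m[, "rate"], na.rm = TRUE)
      eye$saccade_amp <- mean(m[, "amp"], na.rm = TRUE)
    }

    tlx_sessions <- apply(p$tlx, 1, tlx_total)

    data.frame(
      id = p$profile$id,
      group = p$profile$group,
      scotoma_pattern = p$profile$scotoma_pattern,
      md_od = attr(p$vf_od, "md_db"),
      md_os = attr(p$vf_os, "md_db"),
      ivf_pct_below = 100 * mean(p$ivf$sensitivity_db < 25),
      ivf_UL = ql_ivf["UL"], ivf_UR = ql_ivf["UR"],
      ivf_LL = ql_ivf["LL"], ivf_LR = ql_ivf["LR"],
      worse_UL = ql_worse["UL"], worse_UR = ql_worse["UR"],
      worse_LL = ql_worse["LL"], worse_LR = ql_worse["LR"],
      better_UL = ql_better["UL"], better_UR = ql_better["UR"],
      better_LL = ql_better["LL"], better_LR = ql_better["LR"],
      sdlp = get("sdlp_nonobstacle", names(dm)),
      sa_high_nonobst = get("sa_high_nonobstacle", names(dm)),
      sa_high_obst = get("sa_high_obstacle", obst_sessions),
      sa_low_nonobst = get("sa_low_nonobstacle", names(dm)),
      sa_low_obst = get("sa_low_obstacle", obst_sessions),
      long_dto = get("long_dto_mean", obst_sessions),
      lat_dto = get("lat_dto_mean", obst_sessions),
      collisions = sum(vapply(obst_sessions,
                              function(s) dm[[s]]$collisions, integer(1))),
      misses = ls$n_misses,
      lrt_s = ls$mean_lrt_s,
      eye_excluded = eye$excluded,
      dwell_top = eye$dwell_top,
      dwell_bottom = eye$dwell_bottom,
      fixation_rate = eye$fixation_rate,
      saccade_amp = eye$saccade_amp,
      tlx_mean = mean(tlx_sessions),
      tlx_s1 = tlx_sessions[1], tlx_s2 = tlx_sessions[2],
      tlx_s3 = tlx_sessions[3], tlx_s4 = tlx_sessions[4],
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}

#' Run the full simulate-measure-report pipeline
#'
#' Convenience wrapper: generate a synthetic cohort, compute every
#' per-participant metric, and build the report tables.
#'
#' @param rng_seed master seed.
#' @param outdir optional directory for the report CSVs.
#' @param ... passed to [generate_cohort()].
#' @return List with `cohort`, `metrics`, `report`.
#' @export
run_pipeline <- function(rng_seed = 1, outdir = NULL, ...) {
  cohort <- generate_cohort(rng_seed = rng_seed, ...)
  metrics <- cohort_metrics(cohort)
  report <- build_report(metrics)
  if (!is.null(outdir)) write_report(report, outdir)
  list(cohort = cohort, metrics = metrics, report = report)
}
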