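short_course <- course_spec(session_duration_s = 60)

test_that("generated visual fields follow the scotoma pattern", {
  p <- participant_profile("V1", "glaucoma", scotoma_pattern = "both_upper",
                           scotoma_depth_db = 25, scotoma_coverage = 1,
                           scotoma_secondary_coverage = 0,
                           diffuse_loss_db = 0)
  vfs <- generate_visual_fields(p, 5)
  for (vf in vfs) {
    upper <- vf$y_deg > 0 & !vf$blind_spot
    lower <- vf$y_deg < 0 & !vf$blind_spot
    expect_lt(mean(vf$sensitivity_db[upper]), 12)
    expect_gt(mean(vf$sensitivity_db[lower]), 25)
  }
  ## a deep scotoma floors at zero, never below
  expect_true(all(vfs$od$sensitivity_db >= 0))
  ## MD is clearly negative for the damaged field
  expect_lt(attr(vfs$od, "md_db"), -5)
})

test_that("control fields are healthy and reproducible", {
  p <- participant_profile("V2", "control")
  a <- generate_visual_fields(p, 9)
  b <- generate_visual_fields(p, 9)
  expect_identical(a, b)
  expect_false(identical(a, generate_visual_fields(p, 10)))
  ## expected share of points below 25 dB stays under 5%
  share <- mean(vapply(1:20, function(s) {
    vfs <- generate_visual_fields(p, 100 + s)
    ivf <- integrate_fields(vfs$od, vfs$os)
    mean(ivf$sensitivity_db < 25)
  }, numeric(1)))
  expect_lt(share, 0.05)
})

test_that("pattern-specific integrated fields: fellow-eye coverage works", {
  ## one healthy eye keeps the IVF healthy for single-eye scotomas
  p1 <- participant_profile("V3", "glaucoma", scotoma_pattern = "left_eye_only",
                            scotoma_coverage = 1,
                            scotoma_secondary_coverage = 0,
                            diffuse_loss_db = 0)
  vfs1 <- generate_visual_fields(p1, 21)
  ivf1 <- integrate_fields(vfs1$od, vfs1$os)
  expect_lt(mean(ivf1$sensitivity_db < 25), 0.1)
  ## alternated defects also leave the IVF mostly intact
  p2 <- participant_profile("V4", "glaucoma", scotoma_pattern = "alternated",
                            scotoma_coverage = 1,
                            scotoma_secondary_coverage = 0,
                            diffuse_loss_db = 0)
  vfs2 <- generate_visual_fields(p2, 22)
  ivf2 <- integrate_fields(vfs2$od, vfs2$os)
  expect_lt(mean(ivf2$sensitivity_db < 25), 0.1)
  ## bilateral upper defects push upper-quadrant IVF loss high
  p3 <- participant_profile("V5", "glaucoma", scotoma_pattern = "both_upper",
                            scotoma_coverage = 1,
                            scotoma_secondary_coverage = 0,
                            diffuse_loss_db = 0)
  vfs3 <- generate_visual_fields(p3, 23)
  ql <- quadrant_loss(integrate_fields(vfs3$od, vfs3$os))
  expect_gt(min(ql[c("UL", "UR")]), 60)
  expect_lt(max(ql[c("LL", "LR")]), 30)
})

test_that("the driver model is deterministic and avoids obstacles", {
  p <- participant_profile("D1", "control")
  co <- course_spec()
  expect_identical(simulate_drive(p, co, "S1", 7),
                   simulate_drive(p, co, "S1", 7))
  tr <- simulate_drive(p, co, "S3", 8)
  ## trace structure: 60 Hz, monotone distance, inside the road
  expect_equal(nrow(tr), 278 * 60)
  expect_equal(diff(tr$t)[1], 1 / 60, tolerance = 1e-12)
  expect_true(all(diff(tr$s_m) > 0))
  expect_true(all(tr$y_m > -1.8 & tr$y_m < 5.4))
  ## crosses into the left lane (y > 1.8) before each of the nine obstacles
  for (pos in co$obstacle_positions_m) {
    approach <- tr$y_m[tr$s_m >= pos - 150 & tr$s_m <= pos]
    expect_gt(max(approach), 1.8)
  }
  ## lateral clearance at every obstacle is at least 1.6 m
  lats <- vapply(co$obstacle_positions_m, function(s) lat_dto(tr, s),
                 numeric(1))
  expect_true(all(lats >= 1.6))
  ## non-obstacle session stays near the right-lane centre
  tr1 <- simulate_drive(p, co, "S1", 8)
  expect_lt(max(abs(tr1$y_m)), 1.8)
})

test_that("steering activity grows with the steering noise gain", {
  co <- short_course
  sa_for <- function(gain) {
    mean(vapply(1:6, function(s) {
      p <- participant_profile("D2", "control", steering_noise_gain = gain)
      tr <- simulate_drive(p, co, "S1", 400 + s)
      steering_activity(lowpass(tr$steer_deg, 0.5))
    }, numeric(1)))
  }
  sa <- vapply(c(0.5, 1, 2), sa_for, numeric(1))
  expect_true(all(diff(sa) > 0))
})

test_that("letter detection follows the integrated-field sensitivities", {
  p <- participant_profile("L1", "glaucoma", scotoma_pattern = "both_upper",
                           detection_threshold_db = 15)
  ## logistic miss model at the defaults (slope 2.5 dB)
  expect_gt(1 - plogis((15 - 30) / 2.5), 0.95)   # healthy point: detect
  expect_gt(plogis((15 - 0) / 2.5), 0.9)         # absolute scotoma: miss
  ## simulated responses: letters into a deep upper scotoma are missed
  vfs <- generate_visual_fields(
    participant_profile("L2", "glaucoma", scotoma_pattern = "both_upper",
                        scotoma_coverage = 1, diffuse_loss_db = 0), 31)
  ivf <- integrate_fields(vfs$od, vfs$os)
  sch <- generate_letter_schedule(letter_schedule_spec(), 3)
  ev <- simulate_letter_responses(p, ivf, sch, 32)
  det <- ev$detail
  in_scotoma <- det$sensitivity_db < 10
  expect_gt(mean(!det$detected[in_scotoma]), 0.8)
  expect_gt(mean(det$detected[det$sensitivity_db > 25]), 0.8)
  ## voice events live inside the session and scoring closes the loop
  expect_true(all(ev$voice_events >= sch$onset_s[1]))
  sc <- score_letters(ev$letters, ev$voice_events)
  expect_equal(sc$n_misses, sum(!det$detected))
})

test_that("gaze concentrates near the focus of expansion with blink gaps", {
  p <- participant_profile("Z1", "control")
  g <- simulate_gaze(p, NULL, rng_seed = 41, duration_s = 120)
  expect_equal(nrow(g), 120 * 60)
  ## blink/dropout gap count is near the Poisson expectation
  runs <- rle(g$valid)
  n_gaps <- sum(!runs$values)
  expected <- p$blink_rate_hz * 120 + 0.01 * 120
  expect_gt(n_gaps, expected * 0.4)
  expect_lt(n_gaps, expected * 1.8)
  ## scanning is horizontal-dominant around the anchor: vertical spread
  ## stays within ~3 degrees for most samples, horizontal within ~20
  ok <- g$valid
  mm3deg <- 3 * 780 * pi / 180
  expect_gt(mean(abs(g$y_mm[ok] - p$eye_point[2]) < mm3deg), 0.5)
  expect_gt(mean(abs(g$x_mm[ok] - p$eye_point[1]) < 300), 0.6)
  expect_gt(sd(g$x_mm[ok]), sd(g$y_mm[ok]))
  ## and hardly ever into the top/bottom screen bands
  expect_lt(mean(g$y_mm[ok] > 616) * 100, 5)
  expect_lt(mean(g$y_mm[ok] < 154) * 100, 5)
})

test_that("cohort generation is reproducible and validates pattern counts", {
  a <- generate_cohort(n_control = 2, n_glaucoma = 3,
                       pattern_counts = c(both_upper = 2, both_lower = 1),
                       course = short_course, rng_seed = 7,
                       gaze_sessions = NULL)
  b <- generate_cohort(n_control = 2, n_glaucoma = 3,
                       pattern_counts = c(both_upper = 2, both_lower = 1),
                       course = short_course, rng_seed = 7,
                       gaze_sessions = NULL)
  expect_identical(a$participants, b$participants)
  expect_equal(length(a$participants), 5)
  expect_error(generate_cohort(n_glaucoma = 3,
                               pattern_counts = c(both_upper = 1)),
               "sum to n_glaucoma")
  ## control-only cohort
  ctl <- generate_cohort(n_control = 2, n_glaucoma = 0,
                         pattern_counts = c(), course = short_course,
                         rng_seed = 8, gaze_sessions = NULL)
  expect_true(all(vapply(ctl$participants,
                         function(p) p$profile$scotoma_pattern,
                         character(1)) == "none"))
  ## default pattern counts match the emulated cohort structure
  expect_equal(sum(eval(formals(generate_cohort)$pattern_counts)), 23)
})

test_that("TLX ratings follow the group session trends", {
  p_pat <- participant_profile("T1", "glaucoma", tlx_base_pct = 17,
                               tlx_trend_pct = 4.5)
  m <- simulate_tlx(p_pat, 6)
  expect_true(all(m >= 1 & m <= 21))
  totals <- apply(m, 1, tlx_total)
  ## increasing trend over the four sessions for patients (on average)
  many <- rowMeans(vapply(1:20, function(s) {
    apply(simulate_tlx(p_pat, s), 1, tlx_total)
  }, numeric(4)))
  expect_gt(many[4], many[1])
})

test_that("cohort files are written in the documented layout", {
  ch <- generate_cohort(n_control = 1, n_glaucoma = 1,
                        pattern_counts = c(both_upper = 1),
                        course = short_course, rng_seed = 9,
                        gaze_sessions = "S1")
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  p1 <- file.path(dir, "P01")
  expect_true(all(file.exists(file.path(
    p1, c("trace_S1.csv", "trace_S4.csv", "gaze_S1.csv", "events_S2.csv",
          "events_S4.csv", "vf_od.csv", "vf_os.csv", "tlx.csv",
          "profile.json")))))
  ## traces round-trip
  tr <- read_session_trace(file.path(p1, "trace_S1.csv"))
  expect_equal(tr$y_m, ch$participants[[1]]$traces$S1$y_m, tolerance = 1e-9)
})
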