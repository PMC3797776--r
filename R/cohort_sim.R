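#' Default group effect configuration
#'
#' Group-level parameter distributions for the synthetic cohort. The
#' defaults emulate the study conditions the analysis is designed for:
#' controls steer smoothly and detect nearly all letters; glaucoma
#' patients carry a scotoma pattern, steer more actively (both below and
#' above 0.5 Hz), respond more slowly to letters, and report increasing
#' workload as tasks are added, while lane keeping, obstacle clearance and
#' eye-scanning are matched between groups.
#'
#' All values are means (with `*_sd` spreads) of per-participant draws.
#'
#' @return Named list with one sublist per group (`control`, `glaucoma`)
#'   plus shared simulator constants.
#' @export
default_effect_config <- function() {
  list(
    control = list(
      steering_noise_gain = 1.0, steering_noise_gain_sd = 0.12,
      kp_scale = 1.0,
      scotoma_depth_db = 0, scotoma_coverage = 0,
      scotoma_secondary_coverage = 0,
      diffuse_loss_db = 0.3, diffuse_loss_sd = 0.3,
      detection_threshold_db = 14, detection_threshold_sd = 1,
      rt_base_s = 0.85, rt_base_sd = 0.08,
      p_poor_tracking = 0.08,
      tlx_base_pct = 26, tlx_trend_pct = -1, tlx_between_sd = 10
    ),
    glaucoma = list(
      steering_noise_gain = 1.22, steering_noise_gain_sd = 0.18,
      kp_scale = 1.25,
      scotoma_depth_db = 25, scotoma_depth_sd = 4,
      scotoma_coverage = 0.85,
      scotoma_secondary_coverage = 0.3, scotoma_secondary_sd = 0.12,
      diffuse_loss_db = 2.5, diffuse_loss_sd = 1.5,
      detection_threshold_db = 14, detection_threshold_sd = 1,
      rt_base_s = 1.05, rt_base_sd = 0.12,
      p_poor_tracking = 0.3,
      tlx_base_pct = 17, tlx_trend_pct = 4.5, tlx_between_sd = 8
    ),
    shared = list(
      avoidance_initiation_m = 118, avoidance_initiation_sd = 10,
      rt_ecc_slope_s_per_deg = 0.008,
      rt_loss_gain_s_per_db = 0.012,
      rt_noise_meanlog = log(0.10), rt_noise_sdlog = 0.5,
      blink_rate_hz = 0.2,
      eye_point = c(250, 300, 780),
      field_margin_deg = 21,
      margin_floor_db = 20
    )
  )
}

#' Synthetic participant profile
#'
#' Per-participant latent parameters of the simulator: the scotoma pattern
#' and depth shaping the visual fields, steering-noise and control gains of
#' the driver model, letter-detection threshold and reaction-time
#' parameters, gaze/tracking quality, and workload trend.
#'
#' @param id participant identifier.
#' @param group `"control"` or `"glaucoma"`.
#' @param scotoma_pattern one of `"none"`, `"left_eye_only"`,
#'   `"right_eye_only"`, `"alternated"`, `"both_upper"`, `"both_lower"`.
#' @param ... named profile parameters (see [default_effect_config()] for
#'   the full set and defaults).
#' @return Object of class `participant_profile`.
#' @export
participant_profile <- function(id, group = c("control", "glaucoma"),
                                scotoma_pattern = "none", ...) {
  group <- match.arg(group)
  patterns <- c("none", "left_eye_only", "right_eye_only", "alternated",
                "both_upper", "both_lower")
  if (!scotoma_pattern %in% patterns) {
    stop("unknown scotoma pattern: ", scotoma_pattern, call. = FALSE)
  }
  if (group == "control" && scotoma_pattern != "none") {
    stop("controls must have scotoma pattern 'none'", call. = FALSE)
  }
  cfg <- default_effect_config()
  shared <- cfg$shared
  grp <- cfg[[group]]
  p <- list(
    id = id, group = group, scotoma_pattern = scotoma_pattern,
    scotoma_depth_db = grp$scotoma_depth_db,
    scotoma_coverage = grp$scotoma_coverage,
    scotoma_secondary_coverage = grp$scotoma_secondary_coverage %||% 0,
    diffuse_loss_db = grp$diffuse_loss_db,
    alternated_upper_eye = "OD",
    steering_noise_gain = grp$steering_noise_gain,
    kp_scale = grp$kp_scale,
    avoidance_initiation_m = shared$avoidance_initiation_m,
    detection_threshold_db = grp$detection_threshold_db,
    rt_base_s = grp$rt_base_s,
    rt_ecc_slope_s_per_deg = shared$rt_ecc_slope_s_per_deg,
    rt_loss_gain_s_per_db = shared$rt_loss_gain_s_per_db,
    rt_noise_meanlog = shared$rt_noise_meanlog,
    rt_noise_sdlog = shared$rt_noise_sdlog,
    blink_rate_hz = shared$blink_rate_hz,
    poor_tracking = FALSE,
    eye_point = shared$eye_point,
    tlx_base_pct = grp$tlx_base_pct,
    tlx_trend_pct = grp$tlx_trend_pct
  )
  dots <- list(...)
  p[names(dots)] <- dots
  if (p$scotoma_depth_db < 0 || p$steering_noise_gain < 0 ||
      p$blink_rate_hz < 0 || p$avoidance_initiation_m <= 0) {
    stop("rates and gains must be non-negative", call. = FALSE)
  }
  structure(p, class = "participant_profile")
}

#' @export
print.participant_profile <- function(x, ...) {
  cat("Participant", x$id, "-", x$group,
      if (x$scotoma_pattern != "none") paste0("(", x$scotoma_pattern, ")"),
      "\n")
  invisible(x)
}

## normal-field sensitivity model: gentle eccentricity decline around 31 dB
normal_sensitivity <- function(ecc_deg) 31 - 0.1 * ecc_deg

#' Generate a pair of monocular visual fields
#'
#' Builds both eyes' 24-2 fields for a profile: a normal baseline (about
#' 30 dB with a mild eccentricity decline plus measurement noise) minus a
#' small diffuse loss, with the profile's scotoma pattern subtracting
#' `scotoma_depth_db` (plus per-location depth jitter, floored at 0 dB)
#' from a random `scotoma_coverage` share of the locations in the
#' pattern's predominant hemifield(s)/eye(s). Because glaucomatous damage
#' is usually bilateral, locations outside the predominant region are
#' additionally affected with probability `scotoma_secondary_coverage`,
#' which reproduces the strongly negative mean deviations in both eyes and
#' the high integrated-field loss percentages typical of such cohorts.
#' The mean deviation is the mean departure of the generated sensitivities
#' from the noiseless baseline.
#'
#' @param profile a [participant_profile()].
#' @param rng_seed integer seed.
#' @return List with elements `od` and `os` ([visual_field()] objects).
#' @export
generate_visual_fields <- function(profile, rng_seed) {
  with_seed(rng_seed, {
    make_eye <- function(eye) {
      g <- build_grid_24_2(eye)
      ecc <- sqrt(g$x_deg^2 + g$y_deg^2)
      base <- normal_sensitivity(ecc)
      sens <- base + stats::rnorm(nrow(g), 0, 1.8) - profile$diffuse_loss_db
      ## hemifield membership of the scotoma for this eye
      affected <- rep(FALSE, nrow(g))
      pat <- profile$scotoma_pattern
      upper <- g$y_deg > 0
      if (pat == "left_eye_only" && eye == "OS") affected[] <- TRUE
      if (pat == "right_eye_only" && eye == "OD") affected[] <- TRUE
      if (pat == "both_upper") affected <- upper
      if (pat == "both_lower") affected <- !upper
      if (pat == "alternated") {
        affected <- if (eye == profile$alternated_upper_eye) upper else !upper
      }
      p_hit <- ifelse(affected, profile$scotoma_coverage,
                      profile$scotoma_secondary_coverage)
      hit <- stats::runif(nrow(g)) < p_hit
      depth <- profile$scotoma_depth_db + stats::rnorm(nrow(g), 0, 3)
      sens[hit] <- sens[hit] - pmax(depth[hit], 0)
      sens <- pmax(sens, 0)
      md <- mean((sens - base)[!g$blind_spot])
      visual_field(eye, sens, md)
    }
    list(od = make_eye("OD"), os = make_eye("OS"))
  })
}

## unit-variance band-limited noise: white noise through a cascade of two
## first-order low-pass filters with corner frequency fc, rescaled to sd 1
band_noise <- function(n, fc_hz, dt) {
  a <- exp(-2 * pi * fc_hz * dt)
  x <- stats::filter(stats::filter(stats::rnorm(n), a, method = "recursive"),
                     a, method = "recursive")
  x <- as.numeric(x)
  x / stats::sd(x)
}

## trapezoidal avoidance target: ramp from 0 to avoid_y over ramp_m metres
## starting init_m before the obstacle, hold past it, ramp back down
avoidance_target <- function(s, pos, init_m, ramp_m, avoid_y, hold_m, return_m) {
  up <- (s - (pos - init_m)) / ramp_m
  down <- 1 - (s - (pos + hold_m)) / return_m
  pmax(0, pmin(1, pmin(up, down))) * avoid_y
}

#' Simulate one driving session
#'
#' Closed-loop kinematic driver model standing in for the human: the
#' vehicle moves along the course at the automatic speed profile while a
#' proportional-derivative steering controller tracks a target lateral
#' position - the right-lane centre, ramping over to the left lane along a
#' trapezoidal profile that starts `avoidance_initiation_m` before each
#' obstacle (obstacle sessions only) and returns after it. Band-limited
#' noise enters twice: a slow wander of the tracked target common to
#' everyone (imperfect lane keeping) and two-band steering-wheel noise
#' scaled by the profile's `steering_noise_gain` (steering style; the
#' 0.18 Hz band feeds the low-pass steering-activity measure, the 0.8 Hz
#' band the high-pass one). Lateral position is clipped at the road edges.
#'
#' The fixed gains and noise scales are calibrated so that a default
#' control-group profile produces steering activity near 1.9 deg/s (2 Hz
#' filter) and 1.0 deg/s (0.5 Hz filter) outside obstacle windows, SDLP
#' near 0.4 m, obstacle commitment around 50 m before the obstacle and
#' lateral clearance above 3 m with no collisions.
#'
#' @param profile a [participant_profile()].
#' @param course a [course_spec()].
#' @param session_id `"S1"`..`"S4"`; obstacles are active in S3 and S4.
#' @param rng_seed integer seed.
#' @param fs sampling frequency, Hz.
#' @param avoid_ramp_m length of the lane-change ramp, metres.
#' @param avoid_y_m lateral offset held while passing an obstacle, metres.
#' @param hold_after_m metres past the obstacle before the return ramp.
#' @param return_ramp_m length of the return ramp, metres.
#' @return Session trace data frame `t`, `s_m`, `y_m`, `steer_deg`
#'   (positive = left), 60 Hz, spanning the session.
#' @export
simulate_drive <- function(profile, course, session_id, rng_seed,
                           fs = DEFAULT_FS, avoid_ramp_m = 55,
                           avoid_y_m = 3.15, hold_after_m = 15,
                           return_ramp_m = 90) {
  stopifnot(session_id %in% c("S1", "S2", "S3", "S4"))
  with_seed(rng_seed, {
    dt <- 1 / fs
    n <- round(course$session_duration_s * fs)
    t <- (seq_len(n) - 1) * dt
    s <- position_at_time(course, t)
    v <- c(diff(s) / dt, course$cruise_speed_mps)
    ## vehicle steering-to-heading gain: v / (wheelbase * steering ratio)
    k_h <- v / (2.7 * 16)

    ## target lane: slow wander + obstacle avoidance ramps
    wander_a <- exp(-dt / 8)
    target <- as.numeric(stats::filter(
      stats::rnorm(n, 0, 0.24 * sqrt(1 - wander_a^2)),
      wander_a, method = "recursive"))
    if (session_id %in% c("S3", "S4")) {
      av <- rep(0, n)
      for (pos in course$obstacle_positions_m) {
        av <- pmax(av, avoidance_target(s, pos,
                                        profile$avoidance_initiation_m,
                                        avoid_ramp_m, avoid_y_m,
                                        hold_after_m, return_ramp_m))
      }
      target <- target + av
    }

    ## two-band steering noise (degrees at the wheel)
    noise_deg <- profile$steering_noise_gain *
      (0.42 * band_noise(n, 0.8, dt) + 1.95 * band_noise(n, 0.18, dt))

    kp <- 0.09 * profile$kp_scale    # rad wheel per m of error
    kd <- 0.101                      # rad wheel per m/s
    y_edge_low <- -course$lane_width_m / 2 + 0.05
    y_edge_high <- course$lane_width_m * 1.5 - 0.05

    y <- numeric(n)
    steer <- numeric(n)
    yi <- 0
    vy <- 0
    theta <- 0
    for (i in seq_len(n)) {
      st <- kp * (target[i] - yi) - kd * vy + noise_deg[i] * pi / 180
      st <- max(min(st, 1.5 * pi), -1.5 * pi)
      theta <- theta + k_h[i] * st * dt
      theta <- max(min(theta, 0.35), -0.35)
      vy <- v[i] * sin(theta)
      yi <- yi + vy * dt
      if (yi > y_edge_high) { yi <- y_edge_high; theta <- min(theta, 0); vy <- 0 }
      if (yi < y_edge_low) { yi <- y_edge_low; theta <- max(theta, 0); vy <- 0 }
      y[i] <- yi
      steer[i] <- st * 180 / pi
    }
    data.frame(t = t, s_m = s, y_m = y, steer_deg = steer)
  })
}

## visual-direction of screen points from the eye point, gaze at the FOE
screen_to_field_deg <- function(x_mm, y_mm, eye_point) {
  data.frame(
    h_deg = atan2(x_mm - eye_point[1], eye_point[3]) * 180 / pi,
    v_deg = atan2(y_mm - eye_point[2], eye_point[3]) * 180 / pi
  )
}

## integrated-field sensitivity seen towards each (h, v) direction;
## directions beyond the field margin fall back to the floor value
ivf_sensitivity_at <- function(ivf, h_deg, v_deg, field_margin_deg,
                               margin_floor_db) {
  ecc <- sqrt(h_deg^2 + v_deg^2)
  sens <- numeric(length(h_deg))
  for (i in seq_along(h_deg)) {
    if (ecc[i] > field_margin_deg) {
      sens[i] <- margin_floor_db
    } else {
      d2 <- (ivf$x_deg - h_deg[i])^2 + (ivf$y_deg - v_deg[i])^2
      sens[i] <- ivf$sensitivity_db[which.min(d2)]
    }
  }
  sens
}

#' Simulate letter responses
#'
#' Detection model for the peripheral letter task. Gaze is taken to rest
#' at the focus of expansion, so each letter's visual-field direction is
#' its screen direction from the eye point; the integrated-field
#' sensitivity nearest that direction (a configurable floor beyond the
#' field margin) drives a logistic miss probability in
#' `(threshold - sensitivity)`. Detected letters get a voice event at
#' onset + base RT + eccentricity slope + a letter-level loss-dependent
#' slowing + a participant-level slowing proportional to the mean
#' sensitivity loss over the within-margin letter directions (severely
#' affected fields slow every response) + a lognormal noise term;
#' responses falling outside the response window become misses.
#'
#' @param profile a [participant_profile()].
#' @param ivf the participant's [integrate_fields()] result.
#' @param schedule a [generate_letter_schedule()] data frame.
#' @param rng_seed integer seed.
#' @param logistic_slope_db scale of the logistic miss curve, dB.
#' @param response_window_s response window after onset, seconds.
#' @param field_margin_deg integrated-field margin, degrees.
#' @param margin_floor_db sensitivity assumed beyond the margin, dB.
#' @param rt_field_slow_s_per_db participant-level slowing per dB of mean
#'   within-margin sensitivity loss (relative to 25 dB), seconds.
#' @return List of class `event_log`: `letters` (the schedule),
#'   `voice_events` (sorted timestamps), and a `detail` data frame with
#'   the per-letter sensitivity, eccentricity and detection flag.
#' @export
simulate_letter_responses <- function(profile, ivf, schedule, rng_seed,
                                      logistic_slope_db = 2.5,
                                      response_window_s = 5,
                                      field_margin_deg = 21,
                                      margin_floor_db = 20,
                                      rt_field_slow_s_per_db = 0.02) {
  with_seed(rng_seed, {
    dir <- screen_to_field_deg(schedule$x_mm, schedule$y_mm,
                               profile$eye_point)
    ecc <- sqrt(dir$h_deg^2 + dir$v_deg^2)
    sens <- ivf_sensitivity_at(ivf, dir$h_deg, dir$v_deg,
                               field_margin_deg, margin_floor_db)
    p_miss <- stats::plogis((profile$detection_threshold_db - sens) /
                              logistic_slope_db)
    n <- nrow(schedule)
    missed <- stats::runif(n) < p_miss
    in_margin <- ecc <= field_margin_deg
    field_slow <- rt_field_slow_s_per_db *
      mean(pmax(0, 25 - sens[in_margin]))
    rt <- profile$rt_base_s + field_slow +
      profile$rt_ecc_slope_s_per_deg * ecc +
      profile$rt_loss_gain_s_per_db * pmax(0, 25 - sens) +
      stats::rlnorm(n, profile$rt_noise_meanlog, profile$rt_noise_sdlog)
    missed <- missed | rt > response_window_s
    voice <- schedule$onset_s[!missed] + rt[!missed]
    structure(list(
      letters = schedule,
      voice_events = sort(voice),
      detail = data.frame(letter_id = schedule$letter_id,
                          eccentricity_deg = ecc,
                          sensitivity_db = sens,
                          p_miss = p_miss,
                          detected = !missed)
    ), class = "event_log")
  })
}

#' Simulate a gaze stream
#'
#' Gaze concentrates near the focus of expansion: the stream is a sequence
#' of fixation targets (horizontal-dominant scatter around the anchor,
#' occasional glances elsewhere on the screen), brief excursions toward
#' displayed letters with a return to the previous target, plus small
#' within-fixation jitter. Blinks (Poisson, `blink_rate_hz`) and tracking
#' dropouts mark samples invalid; profiles flagged `poor_tracking` get
#' long dropout episodes.
#'
#' @param profile a [participant_profile()].
#' @param schedule letter schedule for letter-task sessions, or `NULL`.
#' @param rng_seed integer seed.
#' @param duration_s session duration, seconds.
#' @param fs sampling frequency, Hz.
#' @param screen_mm screen size `c(width, height)`, millimetres.
#' @param shift_rate_hz rate of fixation-target shifts.
#' @param glance_prob probability that a shift is a full-screen glance.
#' @return Gaze data frame `t`, `x_mm`, `y_mm`, `valid`.
#' @export
simulate_gaze <- function(profile, schedule = NULL, rng_seed,
                          duration_s = 278, fs = DEFAULT_FS,
                          screen_mm = c(1090, 770),
                          shift_rate_hz = 0.35, glance_prob = 0.03) {
  with_seed(rng_seed, {
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    anchor <- profile$eye_point[1:2]
    clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

    ## fixation-target shift times
    n_shift <- stats::rpois(1, shift_rate_hz * duration_s)
    shift_t <- sort(stats::runif(n_shift, 0, duration_s))
    draw_target <- function(k) {
      glance <- stats::runif(k) < glance_prob
      x <- ifelse(glance, stats::runif(k, 0, screen_mm[1]),
                  clamp(anchor[1] + stats::rnorm(k, 0, 260),
                        0, screen_mm[1]))
      y <- ifelse(glance, stats::runif(k, 0, screen_mm[2]),
                  clamp(anchor[2] + stats::rnorm(k, 0, 45),
                        0, screen_mm[2]))
      cbind(x, y)
    }
    targets <- draw_target(n_shift + 1)
    idx <- findInterval(t, shift_t) + 1
    tx <- targets[idx, 1]
    ty <- targets[idx, 2]

    ## excursions toward displayed letters, then back
    if (!is.null(schedule) && nrow(schedule) > 0) {
      go <- stats::runif(nrow(schedule)) < 0.8
      for (i in which(go)) {
        from <- schedule$onset_s[i] + 0.25
        sel <- t >= from & t <= from + 0.5
        tx[sel] <- schedule$x_mm[i]
        ty[sel] <- schedule$y_mm[i]
      }
    }

    ## within-fixation jitter
    a <- exp(-1 / (0.2 * fs))
    jit <- function() as.numeric(stats::filter(
      stats::rnorm(n, 0, 5 * sqrt(1 - a^2)), a, method = "recursive"))
    x <- clamp(tx + jit(), 0, screen_mm[1])
    y <- clamp(ty + jit(), 0, screen_mm[2])

    ## blinks and dropouts
    valid <- rep(TRUE, n)
    mark_invalid <- function(valid, starts, durs) {
      for (i in seq_along(starts)) {
        sel <- t >= starts[i] & t <= starts[i] + durs[i]
        valid[sel] <- FALSE
      }
      valid
    }
    nb <- stats::rpois(1, profile$blink_rate_hz * duration_s)
    valid <- mark_invalid(valid, stats::runif(nb, 0, duration_s),
                          stats::runif(nb, 0.1, 0.3))
    drop_rate <- if (isTRUE(profile$poor_tracking)) 0.1 else 0.01
    drop_mean <- if (isTRUE(profile$poor_tracking)) 8 else 2
    nd <- stats::rpois(1, drop_rate * duration_s)
    valid <- mark_invalid(valid, stats::runif(nd, 0, duration_s),
                          stats::rlnorm(nd, log(drop_mean), 0.5))
    x[!valid] <- NA_real_
    y[!valid] <- NA_real_
    data.frame(t = t, x_mm = x, y_mm = y, valid = valid)
  })
}

#' Simulate NASA-TLX ratings for the four sessions
#'
#' Each session's six items scatter around a participant-level workload
#' that follows the group's linear session trend; items are rounded to the
#' 1-21 tick scale.
#'
#' @param profile a [participant_profile()].
#' @param rng_seed integer seed.
#' @return 4 x 6 matrix of item scores (sessions x items).
#' @export
simulate_tlx <- function(profile, rng_seed) {
  with_seed(rng_seed, {
    items <- c("mental", "physical", "temporal", "performance",
               "effort", "frustration")
    m <- matrix(NA_real_, 4, 6, dimnames = list(paste0("S", 1:4), items))
    for (s in 1:4) {
      pct <- profile$tlx_base_pct + profile$tlx_trend_pct * (s - 1)
      raw <- 1 + 20 * pct / 100 + stats::rnorm(6, 0, 1.5)
      m[s, ] <- pmin(pmax(round(raw), 1), 21)
    }
    m
  })
}

#' Generate a synthetic cohort
#'
#' Builds complete participant records - visual fields and integrated
#' field, four session traces (obstacles active in S3/S4), letter event
#' logs for S2/S4 (the same preprogrammed schedule in both, as in the
#' protocol), gaze streams for all sessions, and TLX ratings - for a
#' control group and a glaucoma group with configurable scotoma-pattern
#' counts and effect sizes. All randomness flows from `rng_seed` through
#' one sub-seed draw per participant stream.
#'
#' @param n_control,n_glaucoma group sizes.
#' @param pattern_counts named integer vector of scotoma-pattern counts
#'   over `left_eye_only`, `right_eye_only`, `alternated`, `both_upper`,
#'   `both_lower`; must sum to `n_glaucoma`. The recruitment counts of the
#'   emulated protocol were 4/7/5/6/3 over 25 patients of whom two
#'   withdrew before testing; the default analysed cohort of 23 trims one
#'   patient from each of the two largest strata.
#' @param effect_config see [default_effect_config()].
#' @param course a [course_spec()].
#' @param schedule_spec a [letter_schedule_spec()].
#' @param rng_seed master seed.
#' @param gaze_sessions sessions for which gaze streams are simulated
#'   (gaze is the most expensive component; pass a subset or `NULL` for
#'   replicate studies that do not need all of it).
#' @return Object of class `cohort`: list with `participants` (each a
#'   list `profile`, `vf_od`, `vf_os`, `ivf`, `traces`, `events`, `gaze`,
#'   `tlx`), the shared `schedule`, `course`, and `seed`.
#' @export
generate_cohort <- function(n_control = 12, n_glaucoma = 23,
                            pattern_counts = c(left_eye_only = 4,
                                               right_eye_only = 6,
                                               alternated = 5,
                                               both_upper = 5,
                                               both_lower = 3),
                            effect_config = default_effect_config(),
                            course = course_spec(),
                            schedule_spec = letter_schedule_spec(),
                            rng_seed = 1,
                            gaze_sessions = c("S1", "S2", "S3", "S4")) {
  if (n_glaucoma > 0 && sum(pattern_counts) != n_glaucoma) {
    stop("pattern counts must sum to n_glaucoma", call. = FALSE)
  }
  n_total <- n_control + n_glaucoma
  ## 1 seed for the schedule + 12 per participant
  seeds <- split_seed(rng_seed, 1 + 12 * n_total)
  schedule <- generate_letter_schedule(schedule_spec, seeds[1])
  groups <- c(rep("control", n_control), rep("glaucoma", n_glaucoma))
  patterns <- c(rep("none", n_control),
                rep(names(pattern_counts), pattern_counts))
  participants <- vector("list", n_total)
  for (k in seq_len(n_total)) {
    sk <- seeds[1 + (k - 1) * 12 + 1:12]
    grp <- groups[k]
    cfg <- effect_config[[grp]]
    shared <- effect_config$shared
    profile <- with_seed(sk[1], {
      participant_profile(
        id = sprintf("P%02d", k), group = grp,
        scotoma_pattern = patterns[k],
        scotoma_depth_db = max(0, stats::rnorm(1, cfg$scotoma_depth_db,
                                               cfg$scotoma_depth_sd %||% 0)),
        scotoma_coverage = cfg$scotoma_coverage,
        scotoma_secondary_coverage = min(1, max(0, stats::rnorm(
          1, cfg$scotoma_secondary_coverage %||% 0,
          cfg$scotoma_secondary_sd %||% 0))),
        diffuse_loss_db = max(0, stats::rnorm(1, cfg$diffuse_loss_db,
                                              cfg$diffuse_loss_sd %||% 0)),
        alternated_upper_eye = sample(c("OD", "OS"), 1),
        steering_noise_gain = max(0.1, stats::rnorm(1, cfg$steering_noise_gain,
                                                    cfg$steering_noise_gain_sd)),
        kp_scale = cfg$kp_scale,
        avoidance_initiation_m = max(60, stats::rnorm(1,
                                                      shared$avoidance_initiation_m,
                                                      shared$avoidance_initiation_sd)),
        detection_threshold_db = stats::rnorm(1, cfg$detection_threshold_db,
                                              cfg$detection_threshold_sd),
        rt_base_s = max(0.3, stats::rnorm(1, cfg$rt_base_s, cfg$rt_base_sd)),
        rt_ecc_slope_s_per_deg = shared$rt_ecc_slope_s_per_deg,
        rt_loss_gain_s_per_db = shared$rt_loss_gain_s_per_db,
        rt_noise_meanlog = shared$rt_noise_meanlog,
        rt_noise_sdlog = shared$rt_noise_sdlog,
        blink_rate_hz = shared$blink_rate_hz,
        poor_tracking = stats::runif(1) < cfg$p_poor_tracking,
        eye_point = shared$eye_point,
        tlx_base_pct = max(0, stats::rnorm(1, cfg$tlx_base_pct,
                                           cfg$tlx_between_sd)),
        tlx_trend_pct = cfg$tlx_trend_pct
      )
    })
    vfs <- generate_visual_fields(profile, sk[2])
    ivf <- integrate_fields(vfs$od, vfs$os)
    traces <- list(
      S1 = simulate_drive(profile, course, "S1", sk[3]),
      S2 = simulate_drive(profile, course, "S2", sk[4]),
      S3 = simulate_drive(profile, course, "S3", sk[5]),
      S4 = simulate_drive(profile, course, "S4", sk[6])
    )
    events <- list(
      S2 = simulate_letter_responses(profile, ivf, schedule, sk[7]),
      S4 = simulate_letter_responses(profile, ivf, schedule, sk[8])
    )
    gaze <- if (length(gaze_sessions) > 0) {
      gseed <- c(S1 = sk[9], S2 = sk[10], S3 = sk[11], S4 = sk[12])
      out <- lapply(gaze_sessions, function(s) {
        simulate_gaze(profile,
                      if (s %in% c("S2", "S4")) schedule else NULL,
                      gseed[[s]],
                      duration_s = course$session_duration_s)
      })
      names(out) <- gaze_sessions
      out
    } else {
      NULL
    }
    tlx <- simulate_tlx(profile, sk[9] + 1)
    participants[[k]] <- list(profile = profile, vf_od = vfs$od,
                              vf_os = vfs$os, ivf = ivf, traces = traces,
                              events = events, gaze = gaze, tlx = tlx)
  }
  structure(list(participants = participants, schedule = schedule,
                 course = course, seed = rng_seed),
            class = "cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort <- function(x, ...) {
  grp <- vapply(x$participants, function(p) p$profile$group, character(1))
  cat("Synthetic cohort:", sum(grp == "control"), "controls,",
      sum(grp == "glaucoma"), "glaucoma patients (seed", x$seed, ")\n")
  invisible(x)
}

#' Write a cohort to per-participant CSV directories
#'
#' Creates one directory per participant containing `trace_S1..4.csv`,
#' `gaze_S1..4.csv` (when simulated), `events_S2.csv`, `events_S4.csv`,
#' `vf_od.csv`, `vf_os.csv`, `tlx.csv` and `profile.json`, plus a cohort
#' `manifest.json`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- character(0)
  for (p in cohort$participants) {
    pid <- p$profile$id
    ids <- c(ids, pid)
    pd <- file.path(dir, pid)
    dir.create(pd, showWarnings = FALSE)
    for (s in names(p$traces)) {
      write_session_trace(p$traces[[s]],
                          file.path(pd, paste0("trace_", s, ".csv")))
    }
    if (!is.null(p$gaze)) {
      for (s in names(p$gaze)) {
        write_gaze_stream(p$gaze[[s]],
                          file.path(pd, paste0("gaze_", s, ".csv")))
      }
    }
    for (s in names(p$events)) {
      write_event_log(p$events[[s]]$letters, p$events[[s]]$voice_events,
                      file.path(pd, paste0("events_", s, ".csv")))
    }
    write_visual_field(p$vf_od, file.path(pd, "vf_od.csv"))
    write_visual_field(p$vf_os, file.path(pd, "vf_os.csv"))
    utils::write.csv(as.data.frame(p$tlx), file.path(pd, "tlx.csv"))
    jsonlite::write_json(unclass(p$profile), file.path(pd, "profile.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(seed = cohort$seed, participants = ids),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
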