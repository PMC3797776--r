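#' Course specification for the simulator highway
#'
#' Deterministic description of the experimental course: a two-lane highway
#' of fixed length driven at an automatically maintained cruise speed, with
#' nine static obstacles placed in the right lane. The vehicle accelerates
#' automatically and reaches cruise speed early in the session; only
#' steering is under the driver's control.
#'
#' @param length_m course length in metres.
#' @param lane_width_m lane width in metres.
#' @param n_lanes number of lanes.
#' @param session_duration_s session duration in seconds.
#' @param cruise_speed_mps cruise speed in metres per second (100 km/h).
#' @param cruise_reached_s time at which the acceleration phase ends.
#' @param obstacle_positions_m longitudinal positions of the static
#'   obstacles, metres from the start, strictly increasing.
#' @param obstacle_window_before_m,obstacle_window_after_m extent of the
#'   obstacle analysis window before/after each obstacle, metres.
#' @param accel_distance_m distance covered during the acceleration phase.
#'   The default is chosen so that, combined with the cruise speed, the
#'   vehicle reaches the first obstacle (350 m) at 19.7 s.
#' @return An object of class `course_spec`.
#' @export
course_spec <- function(length_m = 7534,
                        lane_width_m = 3.6,
                        n_lanes = 2,
                        session_duration_s = 278,
                        cruise_speed_mps = 100 / 3.6,
                        cruise_reached_s = 17,
                        obstacle_positions_m = c(350, 1171, 1521, 2125,
                                                 3193, 3563, 6095, 6395, 7262),
                        obstacle_window_before_m = 150,
                        obstacle_window_after_m = 200,
                        accel_distance_m = 350 - 2.7 * 100 / 3.6) {
  stopifnot(
    length_m > 0, lane_width_m > 0, n_lanes >= 1,
    session_duration_s > 0, cruise_speed_mps > 0,
    cruise_reached_s > 0, cruise_reached_s < session_duration_s,
    obstacle_window_before_m >= 0, obstacle_window_after_m >= 0,
    accel_distance_m > 0,
    accel_distance_m < cruise_speed_mps * cruise_reached_s
  )
  if (is.unsorted(obstacle_positions_m, strictly = TRUE)) {
    stop("obstacle positions must be strictly increasing", call. = FALSE)
  }
  if (any(obstacle_positions_m <= 0) || any(obstacle_positions_m >= length_m)) {
    stop("obstacle positions must lie inside the course", call. = FALSE)
  }
  structure(
    list(
      length_m = length_m,
      lane_width_m = lane_width_m,
      n_lanes = n_lanes,
      session_duration_s = session_duration_s,
      cruise_speed_mps = cruise_speed_mps,
      cruise_reached_s = cruise_reached_s,
      obstacle_positions_m = obstacle_positions_m,
      obstacle_window_before_m = obstacle_window_before_m,
      obstacle_window_after_m = obstacle_window_after_m,
      accel_distance_m = accel_distance_m
    ),
    class = "course_spec"
  )
}

#' @export
print.course_spec <- function(x, ...) {
  cat("Simulator course:", x$length_m, "m,", x$n_lanes, "lanes of",
      x$lane_width_m, "m\n")
  cat("Cruise", round(x$cruise_speed_mps * 3.6, 1), "km/h reached at",
      x$cruise_reached_s, "s; session", x$session_duration_s, "s\n")
  cat("Obstacles at:", paste(x$obstacle_positions_m, collapse = ", "), "m\n")
  invisible(x)
}

#' Default acceleration profile
#'
#' Cumulative distance covered during the automatic acceleration phase.
#' The profile is a two-phase speed ramp: linear increase from standstill to
#' cruise speed over the first `t1` seconds, cruise afterwards, with `t1`
#' chosen so the total distance at the end of the acceleration phase equals
#' `accel_distance_m`. The resulting ramp is steep early on; only
#' cruise-phase arithmetic is used for validation, so the in-ramp shape is a
#' modelling convention.
#'
#' @param spec a [course_spec()].
#' @return A monotone function of time (seconds) returning metres.
#' @export
default_accel_profile <- function(spec) {
  vc <- spec$cruise_speed_mps
  tc <- spec$cruise_reached_s
  d <- spec$accel_distance_m
  ## d = vc*(tc - t1/2)  =>  t1 = 2*(tc - d/vc)
  t1 <- 2 * (tc - d / vc)
  stopifnot(t1 > 0, t1 <= tc)
  function(t) {
    ifelse(t <= t1,
           vc * t^2 / (2 * t1),
           vc * t1 / 2 + vc * (t - t1))
  }
}

#' Longitudinal position at a given time
#'
#' Position along the course under the automatic speed profile: an
#' acceleration phase up to `cruise_reached_s`, then constant cruise speed.
#'
#' @param spec a [course_spec()].
#' @param t time(s) in seconds, non-negative; vectorised.
#' @param accel_profile monotone distance function on the acceleration
#'   phase; defaults to [default_accel_profile()].
#' @return Position(s) in metres.
#' @export
position_at_time <- function(spec, t, accel_profile = default_accel_profile(spec)) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  tc <- spec$cruise_reached_s
  d_tc <- accel_profile(tc)
  ifelse(t <= tc,
         accel_profile(t),
         d_tc + (t - tc) * spec$cruise_speed_mps)
}

#' Time at which an obstacle is encountered
#'
#' Cruise-phase arithmetic anchored on one known (time, position) pair:
#' the obstacle is reached `(position difference)/cruise speed` seconds
#' after the reference.
#'
#' @param spec a [course_spec()].
#' @param obstacle_index 1-based obstacle index.
#' @param reference numeric vector `c(time_s, position_m)`, a known point in
#'   the cruise phase at or before the obstacle.
#' @return Encounter time in seconds.
#' @export
encounter_time <- function(spec, obstacle_index, reference) {
  stopifnot(length(reference) == 2, obstacle_index >= 1,
            obstacle_index <= length(spec$obstacle_positions_m))
  if (reference[1] < spec$cruise_reached_s) {
    stop("reference time must be in the cruise phase", call. = FALSE)
  }
  pos <- spec$obstacle_positions_m[obstacle_index]
  if (pos < reference[2]) {
    stop("obstacle lies before the reference position", call. = FALSE)
  }
  reference[1] + (pos - reference[2]) / spec$cruise_speed_mps
}

#' Obstacle analysis windows
#'
#' One longitudinal interval per obstacle, from `obstacle_window_before_m`
#' before to `obstacle_window_after_m` after. `merged` additionally returns
#' the overlap-merged union used to delimit non-obstacle periods.
#'
#' @param spec a [course_spec()].
#' @param merged if `TRUE`, merge overlapping windows.
#' @return Data frame with `start_m` and `end_m` columns.
#' @export
obstacle_windows <- function(spec, merged = FALSE) {
  w <- data.frame(
    start_m = spec$obstacle_positions_m - spec$obstacle_window_before_m,
    end_m = spec$obstacle_positions_m + spec$obstacle_window_after_m
  )
  if (merged) {
    m <- merge_intervals(w$start_m, w$end_m)
    w <- data.frame(start_m = m$start, end_m = m$end)
  }
  w
}

#' Letter schedule specification
#'
#' The peripheral letter task projects letters at preprogrammed screen
#' coordinates: each letter stays on for a fixed display duration and the
#' gap between a letter's disappearance and the next letter's appearance is
#' drawn uniformly from `gap_range_s`. (The alternative onset-to-onset
#' reading of the inter-letter interval would make consecutive letters
#' overlap the 4 s display and is therefore not used.)
#'
#' The default 25 screen positions form a 5 x 5 grid in visual-angle space
#' whose extreme eccentricities, seen from the default eye point, are
#' -6.4 deg (leftmost) to 36.1 deg (rightmost) horizontally and -2.9 deg
#' (lowest) to 16.8 deg (highest) vertically.
#'
#' @param n_letters letters per session.
#' @param n_positions number of distinct screen positions.
#' @param first_onset_s onset of the first letter, seconds.
#' @param display_duration_s time a letter stays visible, seconds.
#' @param gap_range_s length-2 numeric, uniform range of the gap between a
#'   letter's offset and the next onset, seconds.
#' @param session_duration_s session length the schedule must fit in.
#' @param positions_mm data frame with `x_mm`, `y_mm` screen coordinates
#'   (origin: screen bottom-left) of the candidate positions.
#' @param eye_point numeric `c(x_mm, y_mm, distance_mm)`: the gaze origin in
#'   screen coordinates plus perpendicular viewing distance. The screen
#'   point `(x_mm, y_mm)` is the focus of expansion.
#' @return An object of class `letter_schedule_spec`.
#' @export
letter_schedule_spec <- function(n_letters = 32,
                                 n_positions = 25,
                                 first_onset_s = 6,
                                 display_duration_s = 4,
                                 gap_range_s = c(3, 6),
                                 session_duration_s = 278,
                                 positions_mm = NULL,
                                 eye_point = c(250, 300, 780)) {
  stopifnot(n_letters >= 1, n_positions >= 1, first_onset_s >= 0,
            display_duration_s > 0, length(gap_range_s) == 2,
            gap_range_s[1] <= gap_range_s[2], gap_range_s[1] >= 0,
            length(eye_point) == 3, eye_point[3] > 0)
  min_span <- first_onset_s + n_letters * display_duration_s +
    (n_letters - 1) * gap_range_s[1]
  if (min_span > session_duration_s) {
    stop("letter schedule cannot fit in the session", call. = FALSE)
  }
  if (is.null(positions_mm)) {
    positions_mm <- default_letter_positions(eye_point, n_positions)
  }
  stopifnot(nrow(positions_mm) == n_positions,
            all(c("x_mm", "y_mm") %in% names(positions_mm)))
  structure(
    list(
      n_letters = n_letters,
      n_positions = n_positions,
      first_onset_s = first_onset_s,
      display_duration_s = display_duration_s,
      gap_range_s = gap_range_s,
      session_duration_s = session_duration_s,
      positions_mm = positions_mm,
      eye_point = eye_point
    ),
    class = "letter_schedule_spec"
  )
}

#' Default letter positions
#'
#' 5 x 5 grid in visual-angle space spanning -6.4..36.1 deg horizontally and
#' -2.9..16.8 deg vertically (the letter-eccentricity extremes estimated at
#' the default eye point), mapped to screen millimetres through the eye
#' point.
#'
#' @param eye_point `c(x_mm, y_mm, distance_mm)` gaze origin.
#' @param n_positions must currently be 25.
#' @return Data frame with `position_id`, `x_mm`, `y_mm`, `h_deg`, `v_deg`.
#' @export
default_letter_positions <- function(eye_point = c(250, 300, 780),
                                     n_positions = 25) {
  stopifnot(n_positions == 25)
  h <- seq(-6.4, 36.1, length.out = 5)
  v <- seq(-2.9, 16.8, length.out = 5)
  grid <- expand.grid(h_deg = h, v_deg = v)
  data.frame(
    position_id = seq_len(nrow(grid)),
    x_mm = eye_point[1] + eye_point[3] * tan(grid$h_deg * pi / 180),
    y_mm = eye_point[2] + eye_point[3] * tan(grid$v_deg * pi / 180),
    h_deg = grid$h_deg,
    v_deg = grid$v_deg
  )
}

#' Generate a letter schedule
#'
#' Draws onset times (first onset fixed, subsequent gaps uniform in
#' `gap_range_s` between offset and next onset) and assigns screen
#' positions so that every preprogrammed position is used at least once.
#' Schedules whose final offset would exceed the session duration are
#' resampled.
#'
#' @param spec a [letter_schedule_spec()].
#' @param rng_seed integer seed; the same seed reproduces the schedule.
#' @param max_tries resampling attempts before giving up.
#' @return Data frame with `letter_id`, `onset_s`, `offset_s`,
#'   `position_id`, `x_mm`, `y_mm`.
#' @export
generate_letter_schedule <- function(spec, rng_seed, max_tries = 1000) {
  with_seed(rng_seed, {
    for (i in seq_len(max_tries)) {
      gaps <- stats::runif(spec$n_letters - 1,
                           spec$gap_range_s[1], spec$gap_range_s[2])
      onsets <- spec$first_onset_s +
        c(0, cumsum(gaps + spec$display_duration_s))
      offsets <- onsets + spec$display_duration_s
      if (offsets[spec$n_letters] <= spec$session_duration_s) {
        ## every position at least once, remainder uniform
        extra <- spec$n_letters - spec$n_positions
        ids <- c(seq_len(spec$n_positions),
                 if (extra > 0) sample.int(spec$n_positions, extra,
                                           replace = TRUE))
        ids <- sample(ids)
        pos <- spec$positions_mm[ids, , drop = FALSE]
        return(data.frame(
          letter_id = seq_len(spec$n_letters),
          onset_s = onsets,
          offset_s = offsets,
          position_id = ids,
          x_mm = pos$x_mm,
          y_mm = pos$y_mm
        ))
      }
    }
    stop("could not fit a letter schedule in the session", call. = FALSE)
  })
}

#' Serialise / restore a course and letter schedule
#'
#' @param spec a `course_spec` or `letter_schedule_spec`.
#' @param path file path.
#' @return `write_course_json` returns `path` invisibly; `read_course_json`
#'   returns the restored `course_spec`.
#' @export
write_course_json <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_course_json
#' @export
read_course_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(course_spec, x[names(x) %in% names(formals(course_spec))])
}
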