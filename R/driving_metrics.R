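#' Zero-phase Butterworth low-pass filter
#'
#' Second-order Butterworth filter applied forward and backward
#' (`signal::filtfilt`), giving zero phase shift. Because the filter runs
#' twice, the gain at the cutoff frequency is 0.5 (the squared single-pass
#' -3 dB point), which is accounted for in the tests.
#'
#' @param x uniformly sampled numeric series.
#' @param cutoff_hz cutoff frequency, Hz (0.5 and 2 for steering, 20 for
#'   gaze).
#' @param fs sampling frequency, Hz.
#' @return Filtered series of the same length.
#' @export
lowpass <- function(x, cutoff_hz, fs = DEFAULT_FS) {
  stopifnot(cutoff_hz > 0, cutoff_hz < fs / 2)
  ## require several settling times of the slowest pole
  min_len <- ceiling(6 * fs / cutoff_hz)
  if (length(x) < min_len) {
    stop("series too short for a ", cutoff_hz, " Hz filter (need >= ",
         min_len, " samples)", call. = FALSE)
  }
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Steering activity
#'
#' Average speed of the steering wheel angle: the mean absolute time
#' derivative of the (filtered) steering angle over the selected samples.
#' The derivative uses central finite differences; samples within
#' `edge_trim_s` of the series boundaries are excluded to suppress filter
#' transients.
#'
#' @param steer_deg filtered steering angle series, degrees.
#' @param mask logical sample-inclusion mask (same length), or `NULL` for
#'   all samples.
#' @param fs sampling frequency, Hz.
#' @param edge_trim_s boundary exclusion, seconds.
#' @return Steering activity in deg/s.
#' @export
steering_activity <- function(steer_deg, mask = NULL, fs = DEFAULT_FS,
                              edge_trim_s = 0.5) {
  n <- length(steer_deg)
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(length(mask) == n)
  trim <- round(edge_trim_s * fs)
  interior <- rep(FALSE, n)
  if (n > 2 * trim + 2) interior[(trim + 2):(n - trim - 1)] <- TRUE
  sel <- mask & interior
  if (sum(sel) < fs) stop("mask selects less than 1 s of samples",
                          call. = FALSE)
  rate <- rep(NA_real_, n)
  idx <- 2:(n - 1)
  rate[idx] <- (steer_deg[idx + 1] - steer_deg[idx - 1]) * fs / 2
  mean(abs(rate[sel]))
}

#' Standard deviation of lateral position (SDLP)
#'
#' Sample standard deviation (n - 1 denominator) of the lateral position
#' over the selected samples; the conventional lane-keeping ("swerving")
#' measure.
#'
#' @param y_m lateral position series, metres.
#' @param mask logical inclusion mask or `NULL`.
#' @param fs sampling frequency, Hz.
#' @param min_duration_s minimum masked duration, seconds.
#' @return SDLP in metres.
#' @export
sdlp <- function(y_m, mask = NULL, fs = DEFAULT_FS, min_duration_s = 10) {
  if (is.null(mask)) mask <- rep(TRUE, length(y_m))
  stopifnot(length(mask) == length(y_m))
  if (sum(mask) < min_duration_s * fs) {
    stop("mask selects less than ", min_duration_s, " s of samples",
         call. = FALSE)
  }
  stats::sd(y_m[mask])
}

## linear interpolation of y at longitudinal position s0
interp_at_s <- function(s, y, s0) {
  stats::approx(s, y, xout = s0, ties = "ordered")$y
}

#' Longitudinal distance to obstacle (LongDtO)
#'
#' Distance between the obstacle and the vehicle at the moment the vehicle
#' committed to the left lane: the last upward crossing of the road centre
#' line (y = `road_center_y`) within the approach window after which the
#' vehicle stays left of the centre line until the obstacle. Higher values
#' mean an earlier reaction. Returns `NA` when the vehicle never committed
#' (e.g., stayed in the right lane).
#'
#' @param trace a session trace (data frame with `s_m`, `y_m`).
#' @param obstacle_s obstacle longitudinal position, metres.
#' @param road_center_y lateral position of the road centre relative to the
#'   right-lane centre, metres (half a lane width).
#' @param window_before_m approach window length, metres.
#' @return Distance in metres, or `NA` if undefined.
#' @export
long_dto <- function(trace, obstacle_s, road_center_y = 1.8,
                     window_before_m = 150) {
  if (obstacle_s < min(trace$s_m) || obstacle_s > max(trace$s_m)) {
    stop("obstacle outside the trace span", call. = FALSE)
  }
  sel <- trace$s_m >= (obstacle_s - window_before_m) & trace$s_m <= obstacle_s
  s <- trace$s_m[sel]
  y <- trace$y_m[sel]
  n <- length(y)
  if (n < 2) return(NA_real_)
  up <- which(y[-n] < road_center_y & y[-1] >= road_center_y)
  if (length(up) == 0) return(NA_real_)
  i <- up[length(up)]
  ## committed: left of centre from the crossing through the obstacle
  y_at_obs <- interp_at_s(trace$s_m, trace$y_m, obstacle_s)
  if (any(y[(i + 1):n] < road_center_y) || y_at_obs < road_center_y) {
    return(NA_real_)
  }
  s_cross <- s[i] + (road_center_y - y[i]) / (y[i + 1] - y[i]) * (s[i + 1] - s[i])
  obstacle_s - s_cross
}

#' Lateral distance to obstacle (LatDtO)
#'
#' Absolute lateral distance between vehicle and obstacle centre at the
#' moment of passing (vehicle longitudinal position = obstacle position).
#' Obstacles sit at the right-lane centre (y = 0), so this is |y| at the
#' obstacle, linearly interpolated between samples.
#'
#' @param trace session trace with `s_m`, `y_m`.
#' @param obstacle_s obstacle position, metres.
#' @param obstacle_y obstacle lateral position, metres.
#' @return Distance in metres.
#' @export
lat_dto <- function(trace, obstacle_s, obstacle_y = 0) {
  if (obstacle_s < min(trace$s_m) || obstacle_s > max(trace$s_m)) {
    stop("obstacle outside the trace span", call. = FALSE)
  }
  abs(interp_at_s(trace$s_m, trace$y_m, obstacle_s) - obstacle_y)
}

#' Collision detection
#'
#' A collision with an obstacle is flagged when, at any sample where the
#' vehicle and the obstacle overlap longitudinally (centre distance at most
#' half the summed lengths), the lateral distance between the two centres
#' is strictly less than 1.6 m (contact implied from the car's width).
#'
#' @param trace session trace with `s_m`, `y_m`.
#' @param obstacle_positions_m obstacle positions, metres.
#' @param car_length_m vehicle length, metres.
#' @param obstacle_length_m obstacle length(s), metres; recycled.
#' @param lateral_threshold_m collision threshold, metres (strict `<`).
#' @param obstacle_y obstacle lateral position, metres.
#' @return List with `flags` (logical per obstacle) and `count`.
#' @export
detect_collisions <- function(trace, obstacle_positions_m,
                              car_length_m = 4.5,
                              obstacle_length_m = 4.5,
                              lateral_threshold_m = 1.6,
                              obstacle_y = 0) {
  obstacle_length_m <- rep_len(obstacle_length_m,
                               length(obstacle_positions_m))
  flags <- vapply(seq_along(obstacle_positions_m), function(i) {
    half <- (car_length_m + obstacle_length_m[i]) / 2
    sel <- abs(trace$s_m - obstacle_positions_m[i]) <= half
    any(abs(trace$y_m[sel] - obstacle_y) < lateral_threshold_m)
  }, logical(1))
  list(flags = flags, count = sum(flags))
}

#' All driving metrics for one session
#'
#' Applies the full driving-performance battery to one session trace:
#' steering activity from the 2 Hz ("high") and 0.5 Hz ("low") filtered
#' steering angle, inside and outside the obstacle windows (the windows are
#' applied in every session, whether or not obstacles were present), SDLP
#' over non-obstacle periods, and - for obstacle sessions S3/S4 -
#' per-obstacle LongDtO, LatDtO and collision flags.
#'
#' @param trace session trace (data frame `t`, `s_m`, `y_m`, `steer_deg`).
#' @param course a [course_spec()].
#' @param session_id `"S1"`..`"S4"`.
#' @param fs sampling frequency, Hz.
#' @param obstacle_length_m obstacle length(s) for collision detection.
#' @return List of class `driving_metrics`: scalar metrics plus
#'   per-obstacle vectors (`NA` entries where LongDtO is undefined, with
#'   `n_long_dto_undefined` counting them).
#' @export
session_driving_metrics <- function(trace, course, session_id,
                                    fs = DEFAULT_FS,
                                    obstacle_length_m = 4.5) {
  stopifnot(session_id %in% c("S1", "S2", "S3", "S4"))
  win <- obstacle_windows(course, merged = TRUE)
  in_obst <- in_intervals(trace$s_m, data.frame(start = win$start_m,
                                                end = win$end_m))
  steer_high <- lowpass(trace$steer_deg, 2, fs)
  steer_low <- lowpass(trace$steer_deg, 0.5, fs)
  obstacles_active <- session_id %in% c("S3", "S4")
  per_obstacle <- NULL
  collisions <- NA_integer_
  long_mean <- NA_real_
  lat_mean <- NA_real_
  n_undef <- NA_integer_
  if (obstacles_active) {
    pos <- course$obstacle_positions_m
    longs <- vapply(pos, function(p) long_dto(trace, p,
                                              course$lane_width_m / 2),
                    numeric(1))
    lats <- vapply(pos, function(p) lat_dto(trace, p), numeric(1))
    col <- detect_collisions(trace, pos,
                             obstacle_length_m = obstacle_length_m)
    per_obstacle <- data.frame(obstacle = seq_along(pos),
                               position_m = pos,
                               long_dto_m = longs,
                               lat_dto_m = lats,
                               collision = col$flags)
    collisions <- col$count
    n_undef <- sum(is.na(longs))
    long_mean <- if (all(is.na(longs))) NA_real_ else mean(longs, na.rm = TRUE)
    lat_mean <- mean(lats)
  }
  structure(list(
    session_id = session_id,
    sa_high_nonobstacle = steering_activity(steer_high, !in_obst, fs),
    sa_high_obstacle = steering_activity(steer_high, in_obst, fs),
    sa_low_nonobstacle = steering_activity(steer_low, !in_obst, fs),
    sa_low_obstacle = steering_activity(steer_low, in_obst, fs),
    sdlp_nonobstacle = sdlp(trace$y_m, !in_obst, fs),
    long_dto_mean = long_mean,
    lat_dto_mean = lat_mean,
    n_long_dto_undefined = n_undef,
    collisions = collisions,
    per_obstacle = per_obstacle
  ), class = "driving_metrics")
}

#' @export
print.driving_metrics <- function(x, ...) {
  cat("Driving metrics,", x$session_id, "\n")
  cat(sprintf("  SA-high non-obst/obst: %.2f / %.2f deg/s\n",
              x$sa_high_nonobstacle, x$sa_high_obstacle))
  cat(sprintf("  SA-low  non-obst/obst: %.2f / %.2f deg/s\n",
              x$sa_low_nonobstacle, x$sa_low_obstacle))
  cat(sprintf("  SDLP (non-obst): %.3f m\n", x$sdlp_nonobstacle))
  if (!is.na(x$collisions)) {
    cat(sprintf("  LongDtO %.1f m, LatDtO %.2f m, collisions %d\n",
                x$long_dto_mean, x$lat_dto_mean, x$collisions))
  }
  invisible(x)
}

#' Read / write session-trace CSV
#'
#' Columns: `t`, `s_m`, `y_m`, `steer_deg`.
#'
#' @param trace session trace data frame.
#' @param path file path.
#' @return `read_session_trace` returns the trace data frame;
#'   `write_session_trace` returns `path` invisibly.
#' @export
write_session_trace <- function(trace, path) {
  utils::write.csv(trace[, c("t", "s_m", "y_m", "steer_deg")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_trace
#' @export
read_session_trace <- function(path) {
  utils::read.csv(path)
}
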