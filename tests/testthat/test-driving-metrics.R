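fs <- 60

## fitted amplitude of a sinusoid at frequency f, transient-trimmed
fit_amplitude <- function(x, t, f, trim = 0.1) {
  n <- length(x)
  keep <- seq(floor(n * trim), ceiling(n * (1 - trim)))
  co <- coef(lm(x[keep] ~ sin(2 * pi * f * t[keep]) +
                  cos(2 * pi * f * t[keep])))
  sqrt(co[2]^2 + co[3]^2)
}

test_that("zero-phase Butterworth gain is 0.5 at the cutoff and ~1 below", {
  t <- (0:(120 * fs - 1)) / fs
  for (cutoff in c(0.5, 2)) {
    x <- sin(2 * pi * cutoff * t)
    g <- fit_amplitude(lowpass(x, cutoff), t, cutoff)
    expect_equal(unname(g), 0.5, tolerance = 0.02 / 0.5)
  }
  ## passband: 0.1 Hz through the 2 Hz filter is preserved within 1%
  x <- sin(2 * pi * 0.1 * t)
  expect_equal(unname(fit_amplitude(lowpass(x, 2), t, 0.1)), 1,
               tolerance = 0.01)
  ## DC gain is 1 (away from the filtfilt edge transients)
  const <- lowpass(rep(3.7, 2000), 2)
  expect_equal(const[300:1700], rep(3.7, 1401), tolerance = 1e-6)
  ## too-short input is refused
  expect_error(lowpass(rnorm(30), 0.5), "too short")
})

test_that("steering activity matches the sinusoid closed form", {
  ## theta = 10 sin(2 pi 0.3 t): mean |dtheta/dt| = 4 * A * f = 12 deg/s
  t <- (0:(200 * fs - 1)) / fs
  theta <- 10 * sin(2 * pi * 0.3 * t)
  expect_equal(steering_activity(theta), 12, tolerance = 0.1 / 12)
  ## linear in amplitude
  expect_equal(steering_activity(2 * theta), 2 * steering_activity(theta))
  ## sign flip invariant
  expect_equal(steering_activity(-theta), steering_activity(theta))
  ## constant angle -> zero
  expect_equal(steering_activity(rep(5, 6000)), 0)
  expect_error(steering_activity(theta, mask = rep(FALSE, length(theta))),
               "less than 1 s")
})

test_that("SA with the low cutoff never exceeds SA with the high cutoff", {
  set.seed(2)
  for (k in 1:5) {
    x <- cumsum(rnorm(60 * fs))
    sa_low <- steering_activity(lowpass(x, 0.5))
    sa_high <- steering_activity(lowpass(x, 2))
    expect_lte(sa_low, sa_high)
  }
})

test_that("SDLP matches sinusoid and hand-computed values", {
  t <- (0:(100 * fs - 1)) / fs
  A <- 0.8
  y <- A * sin(2 * pi * 0.2 * t)   # whole periods over 100 s
  expect_equal(sdlp(y), A / sqrt(2), tolerance = 0.01)
  expect_equal(sdlp(rep(1.23, 1000)), 0)
  ## n-1 denominator: {0.1, 0.2, 0.3} -> 0.1 exactly
  expect_equal(sdlp(c(0.1, 0.2, 0.3), min_duration_s = 0.05), 0.1)
  ## invariant to adding a constant
  expect_equal(sdlp(y + 10), sdlp(y))
  expect_error(sdlp(y, mask = c(TRUE, rep(FALSE, length(y) - 1))),
               "less than 10 s")
})

test_that("LongDtO finds the last committed road-centre crossing", {
  ## linear ramp crossing y = 1.8 at s = 6045, obstacle at 6095
  s <- seq(5900, 6100, by = 1)
  y <- approx(c(5900, 6040, 6050, 6100), c(0, 1.3, 2.3, 3.2), xout = s)$y
  tr <- make_trace(s, y)
  ## crossing at s where y = 1.8 on the 6040->6050 ramp: 6045
  expect_equal(long_dto(tr, 6095), 50, tolerance = 1e-6)
  ## stays in right lane -> undefined
  expect_true(is.na(long_dto(make_trace(s, rep(0.2, length(s))), 6095)))
  ## weave then commit: distance measured from the later crossing
  y2 <- approx(c(5900, 5950, 5980, 6000, 6020, 6100),
               c(0, 2.5, 1.0, 1.0, 3.0, 3.0), xout = s)$y
  ## second upward 1.8-crossing on the 6000->6020 ramp: at 6008
  expect_equal(long_dto(make_trace(s, y2), 6095), 87, tolerance = 1e-6)
  ## crossing that later drops back below centre is not committed
  y3 <- approx(c(5900, 5960, 6000, 6100), c(0, 2.5, 2.5, 1.0), xout = s)$y
  expect_true(is.na(long_dto(make_trace(s, y3), 6095)))
  expect_error(long_dto(tr, 9999), "outside the trace")
})

test_that("LatDtO is the absolute interpolated clearance at the obstacle", {
  s <- seq(6000, 6200, by = 1)
  expect_equal(lat_dto(make_trace(s, rep(3.07, length(s))), 6095), 3.07)
  expect_equal(lat_dto(make_trace(s, rep(0, length(s))), 6095), 0)
  expect_equal(lat_dto(make_trace(s, rep(-0.5, length(s))), 6095), 0.5)
  ## interpolation between samples
  tr <- make_trace(c(6094, 6096), c(3.0, 3.2))
  expect_equal(lat_dto(tr, 6095), 3.1)
})

test_that("collision rule is strict at 1.6 m with longitudinal overlap", {
  s <- seq(6080, 6110, by = 0.25)
  near <- detect_collisions(make_trace(s, rep(1.5, length(s))), 6095)
  expect_true(near$flags)
  clear <- detect_collisions(make_trace(s, rep(1.7, length(s))), 6095)
  expect_false(clear$flags)
  exact <- detect_collisions(make_trace(s, rep(1.6, length(s))), 6095)
  expect_false(exact$flags)
  ## laterally close but longitudinally far is no collision
  far <- detect_collisions(make_trace(seq(6200, 6230, 0.25),
                                      rep(0, 121)), 6095)
  expect_false(far$flags)
})

test_that("collision flags equal a brute-force per-sample scan", {
  set.seed(33)
  for (k in 1:100) {
    n <- sample(50:200, 1)
    s <- seq(0, 60, length.out = n)
    y <- rnorm(n, sample(c(0, 1.6, 3), 1), runif(1, 0.05, 1))
    tr <- make_trace(s, y)
    positions <- sort(runif(3, 5, 55))
    got <- detect_collisions(tr, positions)$flags
    expect_identical(got, collision_oracle(tr, positions))
  }
})

test_that("session metrics apply obstacle windows in every session", {
  co <- course_spec()
  p <- participant_profile("T1", "control")
  tr <- simulate_drive(p, co, "S1", 77)
  m1 <- session_driving_metrics(tr, co, "S1")
  ## obstacle-period SA is reported even though S1 has no obstacles
  expect_true(is.finite(m1$sa_high_obstacle))
  expect_true(is.finite(m1$sa_low_obstacle))
  ## but obstacle distance metrics are not
  expect_true(is.na(m1$long_dto_mean))
  expect_null(m1$per_obstacle)

  tr3 <- simulate_drive(p, co, "S3", 78)
  m3 <- session_driving_metrics(tr3, co, "S3")
  ## nine avoidances -> nine defined LongDtO values, no collisions
  expect_equal(nrow(m3$per_obstacle), 9)
  expect_equal(m3$n_long_dto_undefined, 0)
  expect_equal(m3$collisions, 0)
  expect_true(all(m3$per_obstacle$lat_dto_m >= 1.6))
  expect_gt(m3$sa_high_obstacle, m3$sa_high_nonobstacle)
})

test_that("a noise-free centred trace yields zero SDLP and SA", {
  co <- course_spec()
  t <- (0:(278 * fs - 1)) / fs
  tr <- data.frame(t = t, s_m = position_at_time(co, t),
                   y_m = 0, steer_deg = 0)
  m <- session_driving_metrics(tr, co, "S1")
  expect_equal(m$sdlp_nonobstacle, 0)
  expect_equal(m$sa_high_nonobstacle, 0, tolerance = 1e-8)
  expect_equal(m$sa_low_nonobstacle, 0, tolerance = 1e-8)
})

test_that("session traces round-trip through CSV", {
  p <- participant_profile("T2", "control")
  co <- course_spec(session_duration_s = 30)
  tr <- simulate_drive(p, co, "S1", 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_session_trace(tr, path)
  tr2 <- read_session_trace(path)
  expect_equal(tr2$y_m, tr$y_m, tolerance = 1e-9)
})
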