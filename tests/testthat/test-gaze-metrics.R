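fs <- 60

test_that("blink margins, short segments and the removed fraction behave", {
  ## 20 s of valid gaze with one blink spanning 10.0-10.2 s
  n <- 20 * fs + 1
  t <- (0:(n - 1)) / fs
  valid <- !(t >= 10.0 & t <= 10.2)
  raw <- data.frame(t = t, x_mm = 500, y_mm = 400, valid = valid)
  cg <- preprocess_gaze(raw, cutoff_hz = NA)
  kept_t <- unlist(lapply(cg$segments, function(s) s$t))
  ## everything in [9.5, 10.7] is gone, boundaries survive
  expect_true(all(kept_t < 9.5 - 1e-9 | kept_t > 10.7 + 1e-9))
  expect_equal(length(cg$segments), 2)
  removed <- sum(!valid) + 2 * round(0.5 * fs)
  expect_equal(cg$removed_fraction, removed / n, tolerance = 1e-6)

  ## a surviving segment shorter than 1 s is dropped entirely:
  ## blinks at 5.0-5.2 and 6.5-6.7 leave a 0.3 s island between margins
  valid3 <- !((t >= 5.0 & t <= 5.2) | (t >= 6.5 & t <= 6.7))
  cg3 <- preprocess_gaze(data.frame(t = t, x_mm = 0, y_mm = 0,
                                    valid = valid3), cutoff_hz = NA)
  kept3 <- unlist(lapply(cg3$segments, function(s) s$t))
  ## island between 5.7 and 6.0 is under 1 s and must vanish
  expect_false(any(kept3 > 4.6 & kept3 < 7.15))
  expect_error(preprocess_gaze(data.frame(t = c(0, 0.1, 0.3), x_mm = 0,
                                          y_mm = 0, valid = TRUE)),
               "uniformly")
})

test_that("participants with over 60% removed data in any session are excluded", {
  fake <- function(f) structure(list(removed_fraction = f), class = "clean_gaze")
  expect_true(gaze_excluded(list(fake(0.2), fake(0.61))))
  expect_false(gaze_excluded(list(fake(0.2), fake(0.60))))
})

test_that("removed fraction grows with blink rate", {
  p <- function(rate) participant_profile("G", "control", blink_rate_hz = rate)
  frac <- vapply(c(0.05, 0.2, 0.5), function(r) {
    mean(vapply(1:3, function(s) {
      g <- simulate_gaze(p(r), NULL, rng_seed = 100 + s, duration_s = 60)
      preprocess_gaze(g)$removed_fraction
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("I-DT finds the constructed fixation structure", {
  ## two 0.5 s stationary clusters 100 mm apart -> two fixations
  x <- c(rep(300, 30), seq(300, 400, length.out = 6), rep(400, 30))
  raw <- make_gaze(x, rep(400, length(x)))
  cg <- preprocess_gaze(raw, min_segment_s = 0.5, cutoff_hz = NA)
  fx <- detect_fixations(cg, viewing_distance_mm = 780)
  expect_equal(nrow(fx), 2)
  expect_equal(fx$cx_mm, c(300, 400), tolerance = 12)
  ## stable gaze lasting only 0.10 s -> nothing
  short <- make_gaze(rep(100, 6), rep(100, 6))
  cg2 <- preprocess_gaze(short, min_segment_s = 0.05, cutoff_hz = NA)
  expect_equal(nrow(detect_fixations(cg2)), 0)
  ## fast continuous drift (> 3 deg per 150 ms) -> nothing
  drift <- make_gaze(seq(0, 1090, length.out = 120), rep(400, 120))
  cg3 <- preprocess_gaze(drift, cutoff_hz = NA)
  expect_equal(nrow(detect_fixations(cg3)), 0)
  expect_error(detect_fixations(cg, viewing_distance_mm = -1),
               "positive")
})

test_that("I-DT equals the brute-force dispersion-window oracle", {
  set.seed(99)
  for (k in 1:200) {
    seg <- random_gaze_segment()
    got <- glaucodrive:::idt_segment(seg$x, seg$y, seg$fs, 3, 0.15, 780)
    want <- idt_oracle(seg$x, seg$y, seg$fs, 3, 0.15, 780)
    expect_identical(got$start, want$start)
    expect_identical(got$end, want$end)
  }
})

test_that("fixations never overlap removed data and fit in retained time", {
  p <- participant_profile("G2", "control")
  g <- simulate_gaze(p, NULL, rng_seed = 12, duration_s = 120)
  cg <- preprocess_gaze(g)
  fx <- detect_fixations(cg)
  expect_lte(sum(fx$duration_s), cg$retained_s)
  seg_range <- lapply(cg$segments, function(s) range(s$t))
  for (i in seq_len(nrow(fx))) {
    r <- seg_range[[fx$segment[i]]]
    expect_gte(fx$start_s[i], r[1])
    expect_lte(fx$end_s[i], r[2])
  }
})

test_that("fixation rate uses retained time and saccade amplitude skips gaps", {
  fake_clean <- structure(list(retained_s = 100, fs = 60,
                               segments = list()), class = "clean_gaze")
  fx <- data.frame(segment = c(1, 1, 1), start_s = 1:3, end_s = 1:3 + 0.2,
                   duration_s = 0.2, cx_mm = c(0, 100, 300), cy_mm = 0)
  expect_equal(fixation_rate(fx, fake_clean), 3 / 100)
  expect_equal(fixation_rate(fx[0, ], fake_clean), 0)
  ## sixty fixations in 100 retained seconds -> 0.6 per second
  fx60 <- fx[rep(1, 60), ]
  expect_equal(fixation_rate(fx60, fake_clean), 0.6)
  ## consecutive distances 100 and 200 -> mean 150
  expect_equal(saccade_amplitude(fx), 150)
  ## a pair spanning two segments is excluded
  fx2 <- fx
  fx2$segment <- c(1, 1, 2)
  expect_equal(saccade_amplitude(fx2), 100)
  expect_true(is.na(saccade_amplitude(fx[1, ])))
  ## identical centroids -> zero amplitude
  fx3 <- fx
  fx3$cx_mm <- 50
  expect_equal(saccade_amplitude(fx3), 0)
})

test_that("region dwell percentages count retained samples in rectangles", {
  ## 1000 samples, 10% in the top band (y > 616 of a 770 mm screen)
  y <- c(rep(700, 100), rep(300, 900))
  raw <- make_gaze(rep(500, 1000), y)
  cg <- preprocess_gaze(raw, cutoff_hz = NA)
  dw <- region_dwell(cg)
  expect_equal(unname(dw["top"]), 10)
  expect_equal(unname(dw["bottom"]), 0)
  ## gaze at the screen centre touches neither band
  centre <- preprocess_gaze(make_gaze(rep(545, 200), rep(385, 200)),
                            cutoff_hz = NA)
  expect_true(all(region_dwell(centre) == 0))
  expect_error(region_dwell(cg, list(bad = c(xmin = 10, xmax = 5,
                                             ymin = 0, ymax = 1))),
               "degenerate")
})

test_that("gaze streams round-trip through CSV", {
  p <- participant_profile("G3", "control")
  g <- simulate_gaze(p, NULL, rng_seed = 3, duration_s = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gaze_stream(g, path)
  g2 <- read_gaze_stream(path)
  expect_equal(g2$valid, g$valid)
  expect_equal(g2$x_mm, g$x_mm, tolerance = 1e-9)
})
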