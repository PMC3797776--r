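## Independent brute-force oracles used to validate the implementations.

## Welch t-test from the textbook formulas
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

## Spearman rho as Pearson on midranks, computed from first principles
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

## paired t from the formulas
paired_oracle <- function(before, after) {
  d <- after - before
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

## I-DT, written as the naive re-scanning version: dispersion recomputed
## from scratch at every step
idt_oracle <- function(x, y, fs, dispersion_deg, min_dur_s, viewing_mm) {
  thr <- dispersion_deg * viewing_mm * pi / 180
  disp <- function(i, j) {
    (max(x[i:j]) - min(x[i:j])) + (max(y[i:j]) - min(y[i:j]))
  }
  w0 <- round(min_dur_s * fs) + 1L
  n <- length(x)
  s <- integer(0); e <- integer(0)
  i <- 1L
  while (i + w0 - 1L <= n) {
    j <- i + w0 - 1L
    if (disp(i, j) <= thr) {
      while (j < n && disp(i, j + 1L) <= thr) j <- j + 1L
      s <- c(s, i); e <- c(e, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  list(start = s, end = e)
}

## collision flags by an explicit per-sample scan
collision_oracle <- function(trace, positions, car_len = 4.5, obs_len = 4.5,
                             thr = 1.6) {
  flags <- logical(length(positions))
  for (k in seq_along(positions)) {
    half <- (car_len + obs_len) / 2
    hit <- FALSE
    for (i in seq_len(nrow(trace))) {
      if (abs(trace$s_m[i] - positions[k]) <= half &&
          abs(trace$y_m[i]) < thr) {
        hit <- TRUE
        break
      }
    }
    flags[k] <- hit
  }
  flags
}

## build a valid 60 Hz gaze stream from x/y vectors
make_gaze <- function(x, y, fs = 60, valid = TRUE) {
  n <- length(x)
  data.frame(t = (seq_len(n) - 1) / fs, x_mm = x, y_mm = y,
             valid = rep_len(valid, n))
}

## random piecewise-stationary gaze segment (clusters + drifts) for the
## fixation-detector equivalence checks
random_gaze_segment <- function(n_events = 6, fs = 60) {
  x <- numeric(0); y <- numeric(0)
  cx <- runif(1, 200, 800); cy <- runif(1, 200, 600)
  for (k in seq_len(n_events)) {
    len <- sample(5:60, 1)
    if (runif(1) < 0.6) {              # stationary cluster, small scatter
      x <- c(x, cx + rnorm(len, 0, runif(1, 0.5, 8)))
      y <- c(y, cy + rnorm(len, 0, runif(1, 0.5, 8)))
    } else {                           # fast drift to a new place
      nx <- runif(1, 100, 900); ny <- runif(1, 100, 650)
      x <- c(x, seq(cx, nx, length.out = len))
      y <- c(y, seq(cy, ny, length.out = len))
      cx <- nx; cy <- ny
    }
  }
  list(x = x, y = y, fs = fs)
}

## synthetic straight-driving trace with prescribed lateral path
make_trace <- function(s_m, y_m, steer_deg = 0, fs = 60) {
  n <- length(s_m)
  data.frame(t = (seq_len(n) - 1) / fs, s_m = s_m,
             y_m = rep_len(y_m, n), steer_deg = rep_len(steer_deg, n))
}
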