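#' Preprocess a raw gaze stream
#'
#' Cleans one session's 60 Hz gaze recording: maximal runs of invalid
#' samples (blinks / missing data) are removed together with a margin of
#' 0.5 s before and after each run; valid segments shorter than 1 s are
#' then dropped; each surviving segment is low-pass filtered (2nd-order
#' Butterworth, 20 Hz cutoff, zero phase). The removed fraction is
#' computed over the whole session.
#'
#' @param raw data frame with `t`, `x_mm`, `y_mm`, `valid` at a uniform
#'   sampling rate.
#' @param fs sampling frequency, Hz.
#' @param blink_margin_s margin removed around each invalid run, seconds.
#' @param min_segment_s minimum surviving segment length, seconds.
#' @param cutoff_hz low-pass cutoff, Hz (`NA` to skip filtering).
#' @return Object of class `clean_gaze`: list with `segments` (list of
#'   data frames `t`, `x_mm`, `y_mm`, each carrying a `segment` id),
#'   `removed_fraction`, `retained_s`, and `fs`.
#' @export
preprocess_gaze <- function(raw, fs = DEFAULT_FS, blink_margin_s = 0.5,
                            min_segment_s = 1, cutoff_hz = 20) {
  stopifnot(all(c("t", "x_mm", "y_mm", "valid") %in% names(raw)))
  dt <- diff(raw$t)
  if (length(dt) > 0 && (max(dt) - min(dt)) > 0.25 / fs) {
    stop("gaze stream is not uniformly sampled", call. = FALSE)
  }
  n <- nrow(raw)
  keep <- as.logical(raw$valid)
  ## expand every invalid run by the blink margin
  margin <- round(blink_margin_s * fs)
  bad <- which(!keep)
  if (length(bad) > 0 && margin > 0) {
    drop <- unique(unlist(lapply(bad, function(i) {
      max(1, i - margin):min(n, i + margin)
    })))
    keep[drop] <- FALSE
  }
  ## split retained samples into contiguous segments, drop short ones
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  min_len <- ceiling(min_segment_s * fs)
  segments <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    if (r$lengths[k] < min_len) {
      keep[starts[k]:ends[k]] <- FALSE
      next
    }
    seg <- raw[starts[k]:ends[k], c("t", "x_mm", "y_mm")]
    if (!is.na(cutoff_hz)) {
      bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
      seg$x_mm <- as.numeric(signal::filtfilt(bf, seg$x_mm))
      seg$y_mm <- as.numeric(signal::filtfilt(bf, seg$y_mm))
    }
    seg$segment <- length(segments) + 1L
    rownames(seg) <- NULL
    segments[[length(segments) + 1]] <- seg
  }
  structure(list(
    segments = segments,
    removed_fraction = 1 - sum(keep) / n,
    retained_s = sum(keep) / fs,
    fs = fs
  ), class = "clean_gaze")
}

#' @export
print.clean_gaze <- function(x, ...) {
  cat(sprintf("Clean gaze: %d segment(s), %.1f s retained, %.1f%% removed\n",
              length(x$segments), x$retained_s, 100 * x$removed_fraction))
  invisible(x)
}

#' Participant-level gaze exclusion
#'
#' A participant is excluded from all eye-scanning analyses when any of
#' their sessions has more than `threshold` of its data removed.
#'
#' @param clean_sessions list of [preprocess_gaze()] results.
#' @param threshold removed-fraction threshold.
#' @return Logical: `TRUE` if the participant is excluded.
#' @export
gaze_excluded <- function(clean_sessions, threshold = 0.6) {
  any(vapply(clean_sessions, function(cg) cg$removed_fraction,
             numeric(1)) > threshold)
}

## I-DT on one segment: returns start/end indices of fixations.
## Dispersion = (max x - min x) + (max y - min y), converted to degrees.
idt_segment <- function(x, y, fs, dispersion_deg, min_dur_s,
                        viewing_distance_mm) {
  n <- length(x)
  w0 <- round(min_dur_s * fs) + 1L  # w0 samples span min_dur_s
  thr_mm <- dispersion_deg * mm_per_degree(viewing_distance_mm)
  out_s <- integer(0)
  out_e <- integer(0)
  i <- 1L
  while (i + w0 - 1L <= n) {
    j <- i + w0 - 1L
    xmin <- min(x[i:j]); xmax <- max(x[i:j])
    ymin <- min(y[i:j]); ymax <- max(y[i:j])
    if ((xmax - xmin) + (ymax - ymin) <= thr_mm) {
      while (j < n) {
        nx <- x[j + 1L]; ny <- y[j + 1L]
        xmin2 <- min(xmin, nx); xmax2 <- max(xmax, nx)
        ymin2 <- min(ymin, ny); ymax2 <- max(ymax, ny)
        if ((xmax2 - xmin2) + (ymax2 - ymin2) > thr_mm) break
        j <- j + 1L
        xmin <- xmin2; xmax <- xmax2; ymin <- ymin2; ymax <- ymax2
      }
      out_s <- c(out_s, i)
      out_e <- c(out_e, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  list(start = out_s, end = out_e)
}

#' Dispersion-based (I-DT) fixation detection
#'
#' Classic dispersion-threshold identification: a candidate window of the
#' minimum fixation duration is grown sample by sample while its dispersion
#' - horizontal extent plus vertical extent, converted to visual degrees at
#' the viewing distance - stays within the threshold; the window is then
#' emitted as a fixation and the search restarts after it. Windows never
#' span the gaps between retained segments.
#'
#' @param clean a [preprocess_gaze()] result.
#' @param dispersion_deg dispersion threshold, degrees.
#' @param min_dur_s minimum fixation duration, seconds.
#' @param viewing_distance_mm eye-to-screen distance used for the
#'   millimetre-to-degree conversion.
#' @return Data frame with `segment`, `start_s`, `end_s`, `duration_s`,
#'   `cx_mm`, `cy_mm` (centroids).
#' @export
detect_fixations <- function(clean, dispersion_deg = 3, min_dur_s = 0.15,
                             viewing_distance_mm = 780) {
  if (viewing_distance_mm <= 0) {
    stop("viewing distance must be positive", call. = FALSE)
  }
  rows <- lapply(clean$segments, function(seg) {
    f <- idt_segment(seg$x_mm, seg$y_mm, clean$fs, dispersion_deg,
                     min_dur_s, viewing_distance_mm)
    if (length(f$start) == 0) return(NULL)
    data.frame(
      segment = seg$segment[1],
      start_s = seg$t[f$start],
      end_s = seg$t[f$end],
      duration_s = seg$t[f$end] - seg$t[f$start],
      cx_mm = vapply(seq_along(f$start),
                     function(k) mean(seg$x_mm[f$start[k]:f$end[k]]),
                     numeric(1)),
      cy_mm = vapply(seq_along(f$start),
                     function(k) mean(seg$y_mm[f$start[k]:f$end[k]]),
                     numeric(1))
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(segment = integer(0), start_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0),
                      cx_mm = numeric(0), cy_mm = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fixations per second
#'
#' Number of detected fixations divided by the retained (clean) recording
#' time. Removed data cannot contain detectable fixations, so retained
#' time, not session time, is the denominator (pass `denominator_s` to
#' override).
#'
#' @param fixations a [detect_fixations()] result.
#' @param clean the matching [preprocess_gaze()] result.
#' @param denominator_s optional custom denominator, seconds.
#' @return Fixation rate in 1/s; `NA` when no time was retained.
#' @export
fixation_rate <- function(fixations, clean, denominator_s = NULL) {
  denom <- if (is.null(denominator_s)) clean$retained_s else denominator_s
  if (denom <= 0) return(NA_real_)
  nrow(fixations) / denom
}

#' Mean saccade amplitude
#'
#' Mean Euclidean distance between the centroids of consecutive fixations.
#' Pairs spanning a removed gap (i.e., in different retained segments) are
#' excluded.
#'
#' @param fixations a [detect_fixations()] result.
#' @return Mean amplitude in millimetres; `NA` with fewer than one
#'   eligible pair.
#' @export
saccade_amplitude <- function(fixations) {
  n <- nrow(fixations)
  if (n < 2) return(NA_real_)
  same <- fixations$segment[-1] == fixations$segment[-n]
  if (!any(same)) return(NA_real_)
  d <- sqrt(diff(fixations$cx_mm)^2 + diff(fixations$cy_mm)^2)
  mean(d[same])
}

#' Default top/bottom screen regions
#'
#' Full-width bands covering the top and bottom `band_frac` of the screen,
#' the areas used to quantify off-road visual attention.
#'
#' @param screen_mm `c(width, height)` of the screen, millimetres.
#' @param band_frac fraction of the screen height per band.
#' @return Named list of regions, each `c(xmin, xmax, ymin, ymax)`.
#' @export
default_screen_regions <- function(screen_mm = c(1090, 770),
                                   band_frac = 0.2) {
  h <- screen_mm[2]
  list(
    top = c(xmin = 0, xmax = screen_mm[1],
            ymin = (1 - band_frac) * h, ymax = h),
    bottom = c(xmin = 0, xmax = screen_mm[1], ymin = 0,
               ymax = band_frac * h)
  )
}

#' Percentage of gaze time per screen region
#'
#' Share of retained samples whose gaze point lies inside each named
#' rectangular region.
#'
#' @param clean a [preprocess_gaze()] result.
#' @param regions named list of `c(xmin, xmax, ymin, ymax)` rectangles;
#'   defaults to [default_screen_regions()].
#' @return Named numeric vector of percentages.
#' @export
region_dwell <- function(clean, regions = default_screen_regions()) {
  for (r in regions) {
    if (r[["xmax"]] <= r[["xmin"]] || r[["ymax"]] <= r[["ymin"]]) {
      stop("degenerate region", call. = FALSE)
    }
  }
  x <- unlist(lapply(clean$segments, function(s) s$x_mm))
  y <- unlist(lapply(clean$segments, function(s) s$y_mm))
  if (length(x) == 0) {
    return(stats::setNames(rep(NA_real_, length(regions)), names(regions)))
  }
  vapply(regions, function(r) {
    100 * mean(x >= r[["xmin"]] & x <= r[["xmax"]] &
                 y >= r[["ymin"]] & y <= r[["ymax"]])
  }, numeric(1))
}

#' Read / write gaze CSV
#'
#' Columns: `t`, `x_mm`, `y_mm`, `valid` (0/1).
#'
#' @param stream gaze data frame.
#' @param path file path.
#' @return `read_gaze_stream` returns the gaze data frame;
#'   `write_gaze_stream` returns `path` invisibly.
#' @export
write_gaze_stream <- function(stream, path) {
  d <- stream[, c("t", "x_mm", "y_mm", "valid")]
  d$valid <- as.integer(d$valid)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze_stream
#' @export
read_gaze_stream <- function(path) {
  d <- utils::read.csv(path)
  d$valid <- as.logical(d$valid)
  d
}
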