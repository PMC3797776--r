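#' @keywords internal
"_PACKAGE"

## Sampling frequency of the simulator and eye tracker (Hz)
DEFAULT_FS <- 60

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stream of sub-seeds from one master seed
#'
#' All randomness in the cohort simulator flows from a single seed: the
#' master seed is used once to draw `n` independent 31-bit sub-seeds, which
#' are then handed to the individual generators.
#'
#' @param seed master seed.
#' @param n number of sub-seeds.
#' @return Integer vector of length `n`.
#' @keywords internal
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

#' Merge possibly overlapping numeric intervals
#'
#' @param start,end numeric vectors of interval bounds.
#' @return Data frame with merged, sorted `start`/`end` columns.
#' @keywords internal
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end), all(end >= start))
  o <- order(start)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

## TRUE for points inside any [start, end] interval
in_intervals <- function(x, intervals) {
  inside <- rep(FALSE, length(x))
  for (i in seq_len(nrow(intervals))) {
    inside <- inside | (x >= intervals$start[i] & x <= intervals$end[i])
  }
  inside
}

## millimetres on screen per degree of visual angle at a viewing distance
## (small-angle linearisation, the convention used throughout)
mm_per_degree <- function(viewing_distance_mm) {
  viewing_distance_mm * pi / 180
}
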