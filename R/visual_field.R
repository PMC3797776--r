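#' 24-2 perimetry grid
#'
#' Test locations of the Humphrey 24-2 pattern in visual-space coordinates
#' (degrees; positive x = right, positive y = up). The grid has 54 points on
#' a 6 degree-spaced offset lattice: rows at y = +/-3..+/-21, with the two
#' extra 27 degree points on the nasal side of the row pair y = +/-3, and
#' the two blind-spot locations at 15 degrees temporally.
#'
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @return Data frame with `x_deg`, `y_deg`, `blind_spot` (logical).
#' @export
build_grid_24_2 <- function(eye = c("OD", "OS")) {
  eye <- match.arg(eye)
  half_width <- c(`21` = 9, `15` = 15, `9` = 21, `3` = 21)
  rows <- lapply(c(21, 15, 9, 3, -3, -9, -15, -21), function(y) {
    w <- half_width[[as.character(abs(y))]]
    data.frame(x_deg = seq(-w, w, by = 6), y_deg = y)
  })
  g <- do.call(rbind, rows)
  ## nasal 27-degree column: nasal visual field is left (-x) for OD,
  ## right (+x) for OS; blind spot is temporal at +/-15 degrees
  nasal_x <- if (eye == "OD") -27 else 27
  blind_x <- if (eye == "OD") 15 else -15
  g <- rbind(g, data.frame(x_deg = nasal_x, y_deg = c(3, -3)))
  g <- g[order(-g$y_deg, g$x_deg), ]
  g$blind_spot <- g$x_deg == blind_x & abs(g$y_deg) == 3
  rownames(g) <- NULL
  stopifnot(nrow(g) == 54, sum(g$blind_spot) == 2)
  g
}

#' Monocular visual field
#'
#' One eye's 24-2 sensitivities plus its mean deviation. Sensitivities are
#' clamped to be non-negative; the mean deviation is an input taken from the
#' perimeter's report (no normative database is shipped).
#'
#' @param eye `"OD"` or `"OS"`.
#' @param sensitivity_db numeric vector of 54 sensitivities (dB), ordered as
#'   [build_grid_24_2()] for that eye (top row first, left to right).
#' @param md_db mean deviation, dB.
#' @return An object of class `visual_field`: a data frame with `x_deg`,
#'   `y_deg`, `blind_spot`, `sensitivity_db` and attributes `eye`, `md_db`.
#' @export
visual_field <- function(eye, sensitivity_db, md_db) {
  grid <- build_grid_24_2(eye)
  if (length(sensitivity_db) != nrow(grid)) {
    stop("expected ", nrow(grid), " sensitivities, got ",
         length(sensitivity_db), call. = FALSE)
  }
  if (any(sensitivity_db < 0, na.rm = TRUE)) {
    stop("sensitivities must be non-negative", call. = FALSE)
  }
  if (!is.numeric(md_db) || length(md_db) != 1L || is.na(md_db)) {
    stop("md_db must be a single number", call. = FALSE)
  }
  vf <- grid
  vf$sensitivity_db <- as.numeric(sensitivity_db)
  structure(vf, eye = eye, md_db = md_db,
            class = c("visual_field", "data.frame"))
}

#' @export
print.visual_field <- function(x, ...) {
  cat("24-2 visual field,", attr(x, "eye"),
      "| MD", sprintf("%.2f dB", attr(x, "md_db")),
      "| mean sensitivity",
      sprintf("%.1f dB", mean(x$sensitivity_db[!x$blind_spot])), "\n")
  invisible(x)
}

## the 52 visual-space locations shared by the integrated field:
## the symmetric 24-2 lattice without the nasal 27-degree columns
ivf_grid <- function() {
  half_width <- c(`21` = 9, `15` = 15, `9` = 21, `3` = 21)
  rows <- lapply(c(21, 15, 9, 3, -3, -9, -15, -21), function(y) {
    w <- half_width[[as.character(abs(y))]]
    data.frame(x_deg = seq(-w, w, by = 6), y_deg = y)
  })
  g <- do.call(rbind, rows)
  g <- g[order(g$y_deg, g$x_deg), ]
  rownames(g) <- NULL
  stopifnot(nrow(g) == 52)
  g
}

#' Integrated visual field
#'
#' Merges two monocular 24-2 fields into an integrated visual field (IVF)
#' by taking, at each of 52 visual-space locations around fixation, the
#' best (maximum) monocular sensitivity. Each eye's blind-spot locations
#' are covered by the fellow eye alone; the two nasal 27-degree columns
#' have no fellow-eye counterpart and are not part of the 52-point grid,
#' which keeps exactly 13 points in each quadrant.
#'
#' @param od,os [visual_field()] objects for the right and left eye.
#' @return An object of class `integrated_field`: a data frame with
#'   `x_deg`, `y_deg`, `sensitivity_db`, sorted by (y, x).
#' @export
integrate_fields <- function(od, os) {
  if (!inherits(od, "visual_field") || !inherits(os, "visual_field")) {
    stop("od and os must be visual_field objects", call. = FALSE)
  }
  if (!identical(attr(od, "eye"), "OD") || !identical(attr(os, "eye"), "OS")) {
    stop("integrate_fields(od, os) expects an OD then an OS field",
         call. = FALSE)
  }
  g <- ivf_grid()
  key <- function(d) paste(d$x_deg, d$y_deg)
  pick <- function(vf) {
    usable <- vf[!vf$blind_spot, ]
    usable$sensitivity_db[match(key(g), key(usable))]
  }
  sod <- pick(od)
  sos <- pick(os)
  if (any(is.na(sod) & is.na(sos))) {
    stop("malformed grid: location seen by neither eye", call. = FALSE)
  }
  g$sensitivity_db <- pmax(sod, sos, na.rm = TRUE)
  structure(g, class = c("integrated_field", "data.frame"))
}

#' @export
print.integrated_field <- function(x, ...) {
  ql <- quadrant_loss(x)
  cat("Integrated visual field: 52 locations; % points < 25 dB:",
      sprintf("%.1f", 100 * mean(x$sensitivity_db < 25)), "\n")
  cat("Quadrant loss (%):",
      paste(names(ql), sprintf("%.1f", ql), collapse = ", "), "\n")
  invisible(x)
}

#' Quadrant sensitivity-loss percentages
#'
#' Percentage of test points per visual-field quadrant (upper-left,
#' upper-right, lower-left, lower-right) whose sensitivity falls strictly
#' below a threshold. For the integrated field the denominator is 13 points
#' per quadrant (52/4); for a monocular field it is that eye's
#' non-blind-spot count in the quadrant.
#'
#' @param field an [integrate_fields()] result or a [visual_field()].
#' @param threshold_db sensitivity threshold, dB.
#' @return Named numeric vector `c(UL, UR, LL, LR)` of percentages.
#' @export
quadrant_loss <- function(field, threshold_db = 25) {
  if (inherits(field, "visual_field")) {
    d <- field[!field$blind_spot, ]
  } else if (inherits(field, "integrated_field")) {
    d <- field
  } else {
    stop("field must be a visual_field or integrated_field", call. = FALSE)
  }
  quad <- ifelse(d$y_deg > 0,
                 ifelse(d$x_deg < 0, "UL", "UR"),
                 ifelse(d$x_deg < 0, "LL", "LR"))
  vapply(c(UL = "UL", UR = "UR", LL = "LL", LR = "LR"), function(q) {
    sel <- quad == q
    100 * sum(d$sensitivity_db[sel] < threshold_db) / sum(sel)
  }, numeric(1))
}

#' Better / worse eye by mean deviation
#'
#' The better eye is the one with the higher (less negative) mean
#' deviation; ties go to the right eye (OD).
#'
#' @param od,os [visual_field()] objects.
#' @return List with elements `better` and `worse`.
#' @export
better_worse_eye <- function(od, os) {
  md_od <- attr(od, "md_db")
  md_os <- attr(os, "md_db")
  if (is.null(md_od) || is.null(md_os)) {
    stop("both fields must carry an MD value", call. = FALSE)
  }
  if (md_od >= md_os) list(better = od, worse = os)
  else list(better = os, worse = od)
}

#' Read / write visual-field CSV
#'
#' Columns: `eye`, `x_deg`, `y_deg`, `sensitivity_db`, `md_db` (MD repeated
#' on every row).
#'
#' @param vf a [visual_field()].
#' @param path file path.
#' @return `read_visual_field` returns a `visual_field`;
#'   `write_visual_field` returns `path` invisibly.
#' @export
write_visual_field <- function(vf, path) {
  d <- data.frame(
    eye = attr(vf, "eye"),
    x_deg = vf$x_deg, y_deg = vf$y_deg,
    sensitivity_db = vf$sensitivity_db,
    md_db = attr(vf, "md_db")
  )
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_visual_field
#' @export
read_visual_field <- function(path) {
  d <- utils::read.csv(path)
  eye <- unique(d$eye)
  stopifnot(length(eye) == 1)
  grid <- build_grid_24_2(eye)
  i <- match(paste(grid$x_deg, grid$y_deg), paste(d$x_deg, d$y_deg))
  if (any(is.na(i))) stop("CSV does not cover the 24-2 grid", call. = FALSE)
  visual_field(eye, d$sensitivity_db[i], unique(d$md_db))
}
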