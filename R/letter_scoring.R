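#' Score letter detections from voice events
#'
#' A letter counts as detected if any voice event falls inside its response
#' window: from letter onset until `grace_s` (default 1 s) after its
#' disappearance. Matching is one-to-one and greedy, earliest onset first;
#' within a window the earliest unassigned voice event is taken and the
#' reaction time is that event's time minus the onset. Letters without a
#' matched event are misses; voice events matching no letter are logged as
#' spurious.
#'
#' @param letters letter schedule data frame (`letter_id`, `onset_s`,
#'   `offset_s`).
#' @param voice_events numeric vector of voice timestamps, seconds.
#' @param grace_s seconds after offset during which a response still
#'   counts.
#' @return List of class `letter_score`: `per_letter` data frame
#'   (`letter_id`, `onset_s`, `offset_s`, `detected`, `voice_t`, `rt_s`),
#'   `n_misses`, `mean_lrt_s` (`NA` when nothing was detected), and
#'   `spurious_events`.
#' @export
score_letters <- function(letters, voice_events, grace_s = 1) {
  letters <- letters[order(letters$onset_s), , drop = FALSE]
  voice_events <- sort(voice_events)
  assigned <- rep(FALSE, length(voice_events))
  voice_t <- rep(NA_real_, nrow(letters))
  for (i in seq_len(nrow(letters))) {
    lo <- letters$onset_s[i]
    hi <- letters$offset_s[i] + grace_s
    cand <- which(!assigned & voice_events >= lo & voice_events <= hi)
    if (length(cand) > 0) {
      assigned[cand[1]] <- TRUE
      voice_t[i] <- voice_events[cand[1]]
    }
  }
  per_letter <- data.frame(
    letter_id = letters$letter_id,
    onset_s = letters$onset_s,
    offset_s = letters$offset_s,
    detected = !is.na(voice_t),
    voice_t = voice_t,
    rt_s = voice_t - letters$onset_s
  )
  structure(list(
    per_letter = per_letter,
    n_misses = sum(!per_letter$detected),
    mean_lrt_s = if (any(per_letter$detected)) {
      mean(per_letter$rt_s[per_letter$detected])
    } else {
      NA_real_
    },
    spurious_events = voice_events[!assigned]
  ), class = "letter_score")
}

#' @export
print.letter_score <- function(x, ...) {
  cat("Letter score:", nrow(x$per_letter) - x$n_misses, "detected,",
      x$n_misses, "missed")
  if (!is.na(x$mean_lrt_s)) cat(sprintf("; mean LRT %.2f s", x$mean_lrt_s))
  cat("\n")
  invisible(x)
}

#' Combined letter summary over the two letter-task sessions
#'
#' Misses are summed over sessions; the mean letter reaction time (LRT) is
#' pooled over every detected letter across both sessions (set
#' `per_session = TRUE` to average the two per-session means instead).
#'
#' @param score_s2,score_s4 [score_letters()] results for sessions 2 and 4.
#' @param per_session average the per-session mean LRTs rather than pooling
#'   letters.
#' @return List with `n_misses` and `mean_lrt_s`.
#' @export
session_letter_summary <- function(score_s2, score_s4, per_session = FALSE) {
  rt <- c(score_s2$per_letter$rt_s[score_s2$per_letter$detected],
          score_s4$per_letter$rt_s[score_s4$per_letter$detected])
  lrt <- if (per_session) {
    mean(c(score_s2$mean_lrt_s, score_s4$mean_lrt_s), na.rm = TRUE)
  } else if (length(rt) > 0) {
    mean(rt)
  } else {
    NA_real_
  }
  list(n_misses = score_s2$n_misses + score_s4$n_misses,
       mean_lrt_s = lrt)
}

#' Correlations between visual-field loss and letter performance
#'
#' Spearman correlations, within the patient group, between the quadrant
#' sensitivity-loss percentages of three field types (integrated, worse
#' eye, better eye) and the letter measures (number of misses, mean LRT).
#'
#' @param patients data frame with one row per patient containing columns
#'   `misses`, `lrt_s` and loss columns named `<type>_<quadrant>` for
#'   `type` in `ivf`, `worse`, `better` and `quadrant` in `UL`, `UR`,
#'   `LL`, `LR` (as produced by [cohort_metrics()]).
#' @return Data frame with 12 rows (`quadrant`, `field_type`,
#'   `rho_misses`, `p_misses`, `rho_lrt`, `p_lrt`); correlations are `NA`
#'   when a column has zero rank variance.
#' @export
letter_vf_correlations <- function(patients) {
  if (nrow(patients) < 5) {
    stop("need at least 5 patients for the correlation table",
         call. = FALSE)
  }
  types <- c(IVF = "ivf", `Worse eye` = "worse", `Better eye` = "better")
  quads <- c("UL", "UR", "LL", "LR")
  rows <- list()
  for (ti in seq_along(types)) {
    for (q in quads) {
      loss <- patients[[paste0(types[[ti]], "_", q)]]
      cm <- spearman_cor(loss, patients$misses)
      cl <- spearman_cor(loss, patients$lrt_s)
      rows[[length(rows) + 1]] <- data.frame(
        quadrant = q,
        field_type = names(types)[ti],
        rho_misses = cm$rho, p_misses = cm$p,
        rho_lrt = cl$rho, p_lrt = cl$p
      )
    }
  }
  do.call(rbind, rows)
}

#' Read / write letter event CSV
#'
#' Long format: `kind` in `letter_on`, `letter_off`, `voice`; `t_s`;
#' `letter_id` (`NA` for voice rows).
#'
#' @param letters letter schedule data frame.
#' @param voice_events numeric voice timestamps.
#' @param path file path.
#' @return `read_event_log` returns a list with `letters` (onsets/offsets
#'   joined back together) and `voice_events`; `write_event_log` returns
#'   `path` invisibly.
#' @export
write_event_log <- function(letters, voice_events, path) {
  d <- rbind(
    data.frame(kind = "letter_on", t_s = letters$onset_s,
               letter_id = letters$letter_id),
    data.frame(kind = "letter_off", t_s = letters$offset_s,
               letter_id = letters$letter_id),
    if (length(voice_events) > 0) {
      data.frame(kind = "voice", t_s = voice_events, letter_id = NA)
    }
  )
  utils::write.csv(d[order(d$t_s), ], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  d <- utils::read.csv(path)
  on <- d[d$kind == "letter_on", ]
  off <- d[d$kind == "letter_off", ]
  letters <- data.frame(
    letter_id = on$letter_id,
    onset_s = on$t_s,
    offset_s = off$t_s[match(on$letter_id, off$letter_id)]
  )
  list(letters = letters[order(letters$onset_s), ],
       voice_events = sort(d$t_s[d$kind == "voice"]))
}
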