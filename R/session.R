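# Session container and CSV I/O.
#
# A recording session is a light list of tibbles: one row per trial, one row
# per unit, one row per spike (unit_id, trial_id, t), and optionally one row
# per eye event. All times are trial-relative seconds with 0 at trial start;
# intervals are half-open [start, end).

TRIAL_COLS <- c(
  "trial_id", "block", "condition", "video_on", "video_off", "probe_on",
  "response_time", "feedback_on", "trial_end", "outcome", "response_side",
  "rt", "chosen_frame"
)
SPIKE_COLS <- c("unit_id", "trial_id", "t")
UNIT_COLS <- c("unit_id", "label")
EYE_COLS <- c(
  "trial_id", "kind", "t_start", "t_end", "x", "y", "end_x", "end_y",
  "amplitude"
)

# Task constant: positive feedback (or error blank) lasts 4 s.
FEEDBACK_DURATION <- 4

#' Construct a recording session
#'
#' Bundles the trials, units, spikes, and optional eye-event tables of one
#' recording day into a validated `session_recording` object. Spike times are
#' trial-relative seconds and are sorted on construction.
#'
#' @param trials Tibble with one row per trial. Required columns:
#'   `trial_id`, `block`, `condition` (`"immediate"`/`"delayed"`), the epoch
#'   boundary times `video_on`, `video_off`, `probe_on`, `response_time`,
#'   `feedback_on`, `trial_end` (seconds from trial start), `outcome`
#'   (`"correct"`/`"incorrect"`), `response_side`, `rt`, `chosen_frame`.
#' @param units Tibble with columns `unit_id`, `label`.
#' @param spikes Tibble with columns `unit_id`, `trial_id`, `t` (seconds).
#' @param eye_events Optional tibble of fixation/saccade/blink events with
#'   columns `trial_id`, `kind`, `t_start`, `t_end`, `x`, `y`, `end_x`,
#'   `end_y`, `amplitude`.
#' @param session_id Character scalar naming the session.
#' @param validate Run invariant checks (default `TRUE`).
#'
#' @return A `session_recording`: a list with elements `session_id`,
#'   `trials`, `units`, `spikes`, `eye_events`.
#' @export
session_recording <- function(trials, units, spikes,
                              eye_events = NULL,
                              session_id = "session",
                              validate = TRUE) {
  spikes <- as_tibble(spikes) %>% arrange(.data$unit_id, .data$trial_id, .data$t)
  x <- structure(
    list(
      session_id = session_id,
      trials = as_tibble(trials),
      units = as_tibble(units),
      spikes = spikes,
      eye_events = if (!is.null(eye_events)) as_tibble(eye_events) else NULL
    ),
    class = "session_recording"
  )
  if (validate) validate_session(x)
  x
}

#' @export
print.session_recording <- function(x, ...) {
  cat(
    sprintf(
      "<session_recording '%s': %d units, %d trials, %d spikes%s>\n",
      x$session_id, nrow(x$units), nrow(x$trials), nrow(x$spikes),
      if (is.null(x$eye_events)) "" else sprintf(", %d eye events", nrow(x$eye_events))
    )
  )
  invisible(x)
}

#' Validate session invariants
#'
#' Checks the structural invariants of a session: every spike lies within
#' `[0, trial_end)` of an existing trial and belongs to a known unit, spike
#' times are strictly increasing (no duplicates) within each (unit, trial)
#' pair, the encoding epoch is 8 s, the probe delay matches the condition
#' (0 s immediate, 3.6 s delayed), and `rt = response_time - probe_on > 0`.
#'
#' @param x A `session_recording`.
#' @param encoding_duration Expected encoding length in seconds (default 8).
#' @param delay_duration Expected retention delay for delayed trials (3.6).
#' @param tol Numeric tolerance on epoch geometry (default 1e-6).
#' @return `x`, invisibly; aborts with an informative message on violation.
#' @export
validate_session <- function(x, encoding_duration = 8, delay_duration = 3.6,
                             tol = 1e-6) {
  stopifnot(inherits(x, "session_recording"))
  tr <- x$trials
  missing_cols <- setdiff(TRIAL_COLS, names(tr))
  if (length(missing_cols) > 0) {
    abort(paste0("trials table missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(tr$trial_id)) abort("duplicated trial_id in trials table")
  bad <- which(abs(tr$video_off - tr$video_on - encoding_duration) > tol)
  if (length(bad) > 0) {
    abort(sprintf("trial %s: encoding epoch is not %g s", tr$trial_id[bad[1]], encoding_duration))
  }
  delay <- tr$probe_on - tr$video_off
  expected <- ifelse(tr$condition == "delayed", delay_duration, 0)
  bad <- which(abs(delay - expected) > 0.1)
  if (length(bad) > 0) {
    abort(sprintf(
      "trial %s: probe delay %.3f s inconsistent with condition '%s'",
      tr$trial_id[bad[1]], delay[bad[1]], tr$condition[bad[1]]
    ))
  }
  bad <- which(tr$rt <= 0 | abs(tr$rt - (tr$response_time - tr$probe_on)) > 1e-6)
  if (length(bad) > 0) {
    abort(sprintf("trial %s: rt must equal response_time - probe_on and be > 0", tr$trial_id[bad[1]]))
  }

  sp <- x$spikes
  if (nrow(sp) > 0) {
    unknown <- setdiff(unique(sp$trial_id), tr$trial_id)
    if (length(unknown) > 0) {
      abort(sprintf("spikes reference unknown trial_id %s", unknown[1]))
    }
    unknown <- setdiff(unique(sp$unit_id), x$units$unit_id)
    if (length(unknown) > 0) {
      abort(sprintf("spikes reference unknown unit_id %s", unknown[1]))
    }
    ends <- tr$trial_end[match(sp$trial_id, tr$trial_id)]
    bad <- which(sp$t < 0 | sp$t >= ends)
    if (length(bad) > 0) {
      abort(sprintf(
        "spike at t = %.4f s outside [0, trial_end) on trial %s",
        sp$t[bad[1]], sp$trial_id[bad[1]]
      ))
    }
    dup <- sp %>%
      group_by(.data$unit_id, .data$trial_id) %>%
      summarise(ok = all(diff(.data$t) > 0) || n() < 2, .groups = "drop")
    if (!all(dup$ok)) {
      offender <- dup[!dup$ok, ][1, ]
      abort(sprintf(
        "spike times not strictly increasing for unit %s, trial %s",
        offender$unit_id, offender$trial_id
      ))
    }
  }
  invisible(x)
}

#' Load a session directory
#'
#' Reads `trials.csv`, `units.csv`, `spikes.csv` (and `eye_events.csv` when
#' present) from a directory and returns a validated [session_recording()].
#' Unknown columns are dropped with a warning; missing files abort naming
#' the file.
#'
#' @param path Session directory.
#' @param session_id Session name; defaults to the directory basename.
#' @return A `session_recording`.
#' @export
load_session <- function(path, session_id = basename(normalizePath(path))) {
  read_one <- function(file, cols, required = TRUE) {
    fp <- file.path(path, file)
    if (!file.exists(fp)) {
      if (required) abort(sprintf("missing required file '%s' in %s", file, path))
      return(NULL)
    }
    x <- readr::read_csv(fp, show_col_types = FALSE, progress = FALSE)
    extra <- setdiff(names(x), cols)
    if (length(extra) > 0) {
      warn(sprintf("%s: ignoring unknown columns %s", file, paste(extra, collapse = ", ")))
      x <- x[intersect(names(x), cols)]
    }
    missing_cols <- setdiff(cols, names(x))
    if (length(missing_cols) > 0 && file != "eye_events.csv") {
      abort(sprintf("%s: missing columns %s", file, paste(missing_cols, collapse = ", ")))
    }
    x
  }
  trials <- read_one("trials.csv", TRIAL_COLS)
  units <- read_one("units.csv", UNIT_COLS)
  spikes <- read_one("spikes.csv", SPIKE_COLS)
  if (nrow(spikes) == 0) {
    spikes <- tibble(unit_id = character(), trial_id = integer(), t = double())
  }
  eye <- read_one("eye_events.csv", EYE_COLS, required = FALSE)
  session_recording(trials, units, spikes, eye, session_id = session_id)
}

#' Write a session directory
#'
#' Serializes a session to `trials.csv`, `units.csv`, `spikes.csv` and, when
#' present, `eye_events.csv`, in the column layout read by [load_session()].
#'
#' @param x A `session_recording`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(x, path) {
  stopifnot(inherits(x, "session_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(x$trials[TRIAL_COLS], file.path(path, "trials.csv"), progress = FALSE)
  readr::write_csv(x$units[UNIT_COLS], file.path(path, "units.csv"), progress = FALSE)
  readr::write_csv(x$spikes[SPIKE_COLS], file.path(path, "spikes.csv"), progress = FALSE)
  if (!is.null(x$eye_events)) {
    readr::write_csv(x$eye_events, file.path(path, "eye_events.csv"), progress = FALSE)
  }
  invisible(path)
}

#' Exclude slow-response trials
#'
#' Drops trials whose reaction time exceeds a cutoff (10 s by convention for
#' this task) and reports the excluded proportion.
#'
#' @param trials Trials tibble with an `rt` column (seconds).
#' @param cutoff Maximum reaction time retained, seconds (default 10).
#' @return A list with `trials` (the retained rows) and `excluded_fraction`.
#' @export
exclude_long_rt <- function(trials, cutoff = 10) {
  stopifnot(is.numeric(trials$rt), all(is.finite(trials$rt)))
  keep <- trials$rt <= cutoff
  list(
    trials = trials[keep, , drop = FALSE],
    excluded_fraction = mean(!keep)
  )
}

#' Per-trial task epochs
#'
#' Expands the trial table into one row per (trial, epoch) half-open
#' interval: pretrial `fixation`, `encoding` (video), retention `delay`
#' (absent on immediate trials), `toj` (probe onset to response), `feedback`
#' (4 s), and `iti` until trial end.
#'
#' @param trials Trials tibble.
#' @return Tibble with `trial_id`, `epoch`, `t_start`, `t_end`, `duration`.
#' @export
trial_epochs <- function(trials) {
  purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    fb_end <- min(tr$feedback_on + FEEDBACK_DURATION, tr$trial_end)
    ep <- tibble(
      trial_id = tr$trial_id,
      epoch = c("fixation", "encoding", "delay", "toj", "feedback", "iti"),
      t_start = c(0, tr$video_on, tr$video_off, tr$probe_on, tr$feedback_on, fb_end),
      t_end = c(tr$video_on, tr$video_off, tr$probe_on, tr$response_time, fb_end, tr$trial_end)
    )
    ep[ep$t_end > ep$t_start + 1e-12, ]
  }) %>%
    mutate(duration = .data$t_end - .data$t_start)
}

# Spikes of selected units cut to a per-trial window, returned as a list of
# numeric vectors indexed [[unit]][[trial]], with times re-referenced to the
# window start. `window` is a two-column matrix/data frame (start, end) with
# one row per trial of `trials`.
spike_trains_in_window <- function(session, unit_ids, trials, window) {
  sp <- session$spikes
  lapply(unit_ids, function(u) {
    su <- sp[sp$unit_id == u, ]
    lapply(seq_len(nrow(trials)), function(i) {
      ti <- trials$trial_id[i]
      w0 <- window[i, 1]
      w1 <- window[i, 2]
      t <- su$t[su$trial_id == ti]
      t[t >= w0 & t < w1] - w0
    })
  })
}
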