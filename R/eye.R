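# Eye-movement preprocessing: velocity-threshold saccade detection, blink
# interpolation, and scalar oculomotor metrics used by the control GLM.

#' Detect saccades by velocity threshold
#'
#' Finds maximal runs where gaze speed exceeds a velocity threshold
#' (15 deg/s by convention) and returns them as saccade events. Speed is
#' computed from central differences and smoothed with a short boxcar before
#' thresholding, so single-sample noise does not fragment a saccade.
#'
#' @param gaze Tibble with columns `t` (s, uniformly sampled), `x`, `y`
#'   (degrees).
#' @param threshold Speed threshold, deg/s (default 15).
#' @param smooth Boxcar width in samples applied to the speed trace
#'   (default 5).
#' @param trial_id Trial id stamped on the returned events (default `NA`).
#' @return Tibble of saccade events with `t_start`, `t_end`, start and end
#'   coordinates, and `amplitude` (endpoint distance, degrees); intervals
#'   are disjoint and sorted.
#' @export
detect_saccades <- function(gaze, threshold = 15, smooth = 5, trial_id = NA_integer_) {
  n <- nrow(gaze)
  if (n < 3) abort("detect_saccades needs at least 3 gaze samples")
  t <- gaze$t
  vx <- c(NA, (gaze$x[3:n] - gaze$x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]), NA)
  vy <- c(NA, (gaze$y[3:n] - gaze$y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]), NA)
  speed <- sqrt(vx^2 + vy^2)
  speed[c(1, n)] <- speed[c(2, n - 1)]
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    speed <- as.numeric(stats::filter(speed, k, sides = 2))
    # boxcar is undefined at the edges; hold the nearest defined value
    first_ok <- which(!is.na(speed))[1]
    last_ok <- max(which(!is.na(speed)))
    speed[seq_len(first_ok - 1)] <- speed[first_ok]
    if (last_ok < n) speed[(last_ok + 1):n] <- speed[last_ok]
  }
  above <- speed > threshold
  above[is.na(above)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  purrr::map_dfr(idx, function(j) {
    i0 <- starts[j]
    i1 <- ends[j]
    tibble(
      trial_id = trial_id,
      kind = "saccade",
      t_start = t[i0],
      t_end = t[i1],
      x = gaze$x[i0],
      y = gaze$y[i0],
      end_x = gaze$x[i1],
      end_y = gaze$y[i1],
      amplitude = sqrt((gaze$x[i1] - gaze$x[i0])^2 + (gaze$y[i1] - gaze$y[i0])^2)
    )
  })
}

#' Interpolate gaze through blinks
#'
#' Replaces gaze coordinates inside each blink, padded by `pad` seconds on
#' both sides, with the straight line joining the samples at
#' `blink_start - pad` and `blink_end + pad`. Blinks are flagged as runs of
#' missing (`NA`) coordinates. A blink touching the trace boundary is filled
#' with the nearest valid sample, with a warning.
#'
#' @param gaze Tibble with columns `t`, `x`, `y`; blink samples are `NA`.
#' @param pad Padding around each blink, seconds (default 0.1).
#' @return The gaze tibble with blink (and padded) samples replaced.
#' @export
interpolate_blinks <- function(gaze, pad = 0.1) {
  n <- nrow(gaze)
  miss <- is.na(gaze$x) | is.na(gaze$y)
  if (!any(miss)) return(gaze)
  t <- gaze$t
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  x <- gaze$x
  y <- gaze$y
  for (j in which(r$values)) {
    i0 <- starts[j]
    i1 <- ends[j]
    # anchor samples pad seconds outside the blink
    a <- which(t <= t[i0] - pad & !miss)
    b <- which(t >= t[i1] + pad & !miss)
    a <- if (length(a) > 0) max(a) else NA_integer_
    b <- if (length(b) > 0) min(b) else NA_integer_
    if (is.na(a) && is.na(b)) abort("gaze trace contains no valid samples around a blink")
    if (is.na(a) || is.na(b)) {
      warn("blink touches the trace boundary; filling with nearest valid sample")
      anchor <- if (is.na(a)) b else a
      fill_idx <- a_fill_range(i0, i1, a, b, t, pad)
      x[fill_idx] <- x[anchor]
      y[fill_idx] <- y[anchor]
      next
    }
    fill_idx <- which(t > t[a] & t < t[b])
    frac <- (t[fill_idx] - t[a]) / (t[b] - t[a])
    x[fill_idx] <- x[a] + frac * (x[b] - x[a])
    y[fill_idx] <- y[a] + frac * (y[b] - y[a])
  }
  gaze$x <- x
  gaze$y <- y
  gaze
}

a_fill_range <- function(i0, i1, a, b, t, pad) {
  lo <- if (is.na(a)) 1L else a + 1L
  hi <- if (is.na(b)) length(t) else b - 1L
  lo:hi
}

#' Oculomotor metrics in a window
#'
#' Summarises eye events over a time window into the four scalar regressors
#' of the eye-movement control model: saccade frequency, fixation frequency
#' (events overlapping the window, divided by window length, Hz), total
#' saccade path length (amplitudes weighted by the fraction of the saccade
#' inside the window, degrees), and total fixation duration (clipped to the
#' window, seconds).
#'
#' @param events Eye-event tibble (`kind`, `t_start`, `t_end`, `amplitude`).
#' @param window Numeric `c(t0, t1)`, `t1 > t0`.
#' @return One-row tibble: `saccade_freq`, `fixation_freq`, `scanpath_len`,
#'   `fixation_dur`.
#' @export
eye_metrics <- function(events, window) {
  t0 <- window[1]
  t1 <- window[2]
  if (t1 <= t0) abort("eye_metrics window must have t1 > t0")
  len <- t1 - t0
  if (is.null(events) || nrow(events) == 0) {
    return(tibble(saccade_freq = 0, fixation_freq = 0, scanpath_len = 0, fixation_dur = 0))
  }
  ov <- pmin(events$t_end, t1) - pmax(events$t_start, t0)
  keep <- ov > 0
  ev <- events[keep, , drop = FALSE]
  ov <- ov[keep]
  sacc <- ev$kind == "saccade"
  fix <- ev$kind == "fixation"
  dur <- ev$t_end - ev$t_start
  frac <- ifelse(dur > 0, ov / dur, 1)
  tibble(
    saccade_freq = sum(sacc) / len,
    fixation_freq = sum(fix) / len,
    scanpath_len = sum(ev$amplitude[sacc] * frac[sacc], na.rm = TRUE),
    fixation_dur = sum(ov[fix])
  )
}
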