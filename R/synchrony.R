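# Time-resolved spike-train synchrony: SPIKE-distance profiles, population
# time courses aligned to probe onset or response, and permutation + FDR
# inference on outcome/condition contrasts. Lower values mean tighter spike
# timing coordination; the measure is locally normalized by the
# instantaneous interspike intervals, so it is insensitive to overall rate.

#' Time-resolved SPIKE-distance profile of a spike-train pair
#'
#' At each grid time, each train contributes its preceding and following
#' spikes (corner spikes) `t_P`, `t_F`, the latencies `x_P = t - t_P`,
#' `x_F = t_F - t`, the local interval `x_ISI = t_F - t_P`, and the offsets
#' `dt_P`, `dt_F` from its corner spikes to the nearest spike of the other
#' train. The per-train term is
#' `S_n = (dt_P * x_F + dt_F * x_P) / x_ISI`, and the profile is
#' `S = (S_1 * x_ISI_2 + S_2 * x_ISI_1) / (2 * mean(x_ISI)^2)`.
#' Auxiliary spikes are placed at both window edges (the standard edge
#' convention), so the profile is defined even for sparse trains.
#'
#' @param train_a,train_b Sorted spike-time vectors, seconds.
#' @param window `c(t0, t1)` analysis window; spikes outside are dropped.
#' @param dt Sampling grid step, s (default 0.001).
#' @return Tibble with `time` and `value` (dissimilarity in `[0, 1]`;
#'   0 everywhere for identical trains).
#' @export
spike_distance_profile <- function(train_a, train_b, window, dt = 0.001) {
  if (window[2] <= window[1]) abort("spike_distance_profile window is empty")
  grid <- seq(window[1], window[2] - dt / 2, by = dt)
  a <- sort(unique(c(window[1], train_a[train_a >= window[1] & train_a <= window[2]], window[2])))
  b <- sort(unique(c(window[1], train_b[train_b >= window[1] & train_b <= window[2]], window[2])))

  corner <- function(spk) {
    iP <- findInterval(grid, spk)
    tP <- spk[iP]
    tF <- spk[pmin(iP + 1L, length(spk))]
    list(tP = tP, tF = tF, xP = grid - tP, xF = tF - grid, xISI = pmax(tF - tP, 1e-12))
  }
  nearest <- function(v, spk) {
    i <- findInterval(v, spk)
    lo <- spk[pmax(i, 1L)]
    hi <- spk[pmin(i + 1L, length(spk))]
    pmin(abs(v - lo), abs(hi - v))
  }

  ca <- corner(a)
  cb <- corner(b)
  S1 <- (nearest(ca$tP, b) * ca$xF + nearest(ca$tF, b) * ca$xP) / ca$xISI
  S2 <- (nearest(cb$tP, a) * cb$xF + nearest(cb$tF, a) * cb$xP) / cb$xISI
  mISI <- (ca$xISI + cb$xISI) / 2
  tibble(time = grid, value = (S1 * cb$xISI + S2 * ca$xISI) / (2 * mISI^2))
}

# Trapezoid time average of a profile sampled on a uniform grid.
profile_time_average <- function(values) {
  n <- length(values)
  if (n == 1) return(values)
  (values[1] / 2 + sum(values[2:(n - 1)]) + values[n] / 2) / (n - 1)
}

# Per-trial alignment anchor times.
alignment_anchor <- function(trials, alignment) {
  switch(alignment,
    probe_onset = trials$probe_on,
    response = trials$response_time,
    abort(sprintf("unknown alignment '%s'", alignment))
  )
}

#' Population synchrony time course for one session
#'
#' Cuts every unit's spike train to a window aligned to probe onset or
#' response, computes SPIKE-distance profiles for all unordered unit pairs,
#' and averages them over pairs within trial and then over trials within
#' each group.
#'
#' @param session A [session_recording()].
#' @param alignment `"probe_onset"` or `"response"`.
#' @param window `c(t0, t1)` relative to the alignment anchor, s.
#' @param group_by Trial column to contrast: `"outcome"` (default) or
#'   `"condition"`; `NULL` for a single group.
#' @param dt Grid step, s (default 0.001).
#' @param units Unit ids (default all; needs at least 2).
#' @return List with `means` (tibble: `group`, `time`, `value`, `n_trials`)
#'   and `trial_curves` (matrix trials x bins) + `groups` (per-trial label).
#' @export
session_synchrony <- function(session, alignment = "response",
                              window = c(-1, 0.5), group_by = "outcome",
                              dt = 0.001, units = session$units$unit_id) {
  if (length(units) < 2) abort("session_synchrony needs at least 2 units")
  trials <- session$trials
  anchor <- alignment_anchor(trials, alignment)
  win <- cbind(anchor + window[1], anchor + window[2])
  trains <- spike_trains_in_window(session, units, trials, win)
  wlen <- window[2] - window[1]
  n_bins <- length(seq(0, wlen - dt / 2, by = dt))
  pairs <- utils::combn(seq_along(units), 2)
  curves <- matrix(0, nrow(trials), n_bins)
  for (i in seq_len(nrow(trials))) {
    acc <- numeric(n_bins)
    for (k in seq_len(ncol(pairs))) {
      pr <- spike_distance_profile(
        trains[[pairs[1, k]]][[i]], trains[[pairs[2, k]]][[i]],
        window = c(0, wlen), dt = dt
      )
      acc <- acc + pr$value
    }
    curves[i, ] <- acc / ncol(pairs)
  }
  groups <- if (is.null(group_by)) rep("all", nrow(trials)) else trials[[group_by]]
  times <- window[1] + seq(0, wlen - dt / 2, by = dt)
  means <- purrr::map_dfr(unique(groups), function(g) {
    tibble(
      group = g, time = times,
      value = colMeans(curves[groups == g, , drop = FALSE]),
      n_trials = sum(groups == g)
    )
  })
  list(means = means, trial_curves = curves, groups = groups, times = times)
}

#' Time-averaged pairwise dissimilarity matrix
#'
#' Symmetric units x units matrix of trial-averaged, time-averaged
#' SPIKE-distance with a zero diagonal.
#'
#' @param session A [session_recording()].
#' @param alignment,window,dt As in [session_synchrony()].
#' @param units Unit ids (default all).
#' @return Symmetric numeric matrix named by unit.
#' @export
pairwise_matrix <- function(session, alignment = "probe_onset",
                            window = c(0, 1), dt = 0.001,
                            units = session$units$unit_id) {
  if (length(units) < 2) abort("pairwise_matrix needs at least 2 units")
  trials <- session$trials
  anchor <- alignment_anchor(trials, alignment)
  win <- cbind(anchor + window[1], anchor + window[2])
  trains <- spike_trains_in_window(session, units, trials, win)
  wlen <- window[2] - window[1]
  n <- length(units)
  m <- matrix(0, n, n, dimnames = list(units, units))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- mean(vapply(seq_len(nrow(trials)), function(k) {
        profile_time_average(
          spike_distance_profile(trains[[i]][[k]], trains[[j]][[k]],
            window = c(0, wlen), dt = dt
          )$value
        )
      }, numeric(1)))
      m[i, j] <- m[j, i] <- v
    }
  }
  m
}

#' Per-bin permutation test between two groups of curves
#'
#' Computes a t statistic per time bin between two groups of curves and
#' compares it two-tailed against a permutation null: group labels are
#' reshuffled (unpaired mode) or pair differences sign-flipped (paired
#' mode) `n_perm` times. P-values use the add-one convention
#' `(1 + #{|t_perm| >= |t_obs|}) / (n_perm + 1)`; degenerate-variance bins
#' get p = 1.
#'
#' @param curves_a,curves_b Matrices (curves x bins); in paired mode rows
#'   correspond.
#' @param n_perm Number of permutations (1000).
#' @param paired Sign-flip pair differences instead of relabeling (default
#'   `TRUE`, the across-session convention).
#' @param seed Integer seed.
#' @return Tibble with `bin`, `t_obs`, `p`.
#' @export
permutation_group_test <- function(curves_a, curves_b, n_perm = 1000,
                                   paired = TRUE, seed = 1L) {
  stopifnot(ncol(curves_a) == ncol(curves_b))
  if (nrow(curves_a) < 3 || nrow(curves_b) < 3) {
    abort("permutation_group_test needs at least 3 curves per group")
  }
  tstat_paired <- function(d) {
    s <- apply(d, 2, sd)
    m <- colMeans(d)
    ifelse(s > 0, m / (s / sqrt(nrow(d))), NA_real_)
  }
  tstat_unpaired <- function(a, b) {
    va <- apply(a, 2, var) / nrow(a)
    vb <- apply(b, 2, var) / nrow(b)
    ifelse(va + vb > 0, (colMeans(a) - colMeans(b)) / sqrt(va + vb), NA_real_)
  }
  with_seed(substream_seed(seed, "perm-group"), {
    if (paired) {
      stopifnot(nrow(curves_a) == nrow(curves_b))
      d <- curves_a - curves_b
      t_obs <- tstat_paired(d)
      n <- nrow(d)
      exceed <- rep(0L, ncol(d))
      for (p in seq_len(n_perm)) {
        flip <- sample(c(-1, 1), n, replace = TRUE)
        t_p <- tstat_paired(d * flip)
        exceed <- exceed + as.integer(!is.na(t_p) & !is.na(t_obs) & abs(t_p) >= abs(t_obs))
      }
    } else {
      all <- rbind(curves_a, curves_b)
      na <- nrow(curves_a)
      t_obs <- tstat_unpaired(curves_a, curves_b)
      exceed <- rep(0L, ncol(all))
      for (p in seq_len(n_perm)) {
        idx <- sample.int(nrow(all))
        t_p <- tstat_unpaired(all[idx[seq_len(na)], , drop = FALSE],
          all[idx[-seq_len(na)], , drop = FALSE])
        exceed <- exceed + as.integer(!is.na(t_p) & !is.na(t_obs) & abs(t_p) >= abs(t_obs))
      }
    }
    p <- ifelse(is.na(t_obs), 1, (1 + exceed) / (n_perm + 1))
    tibble(bin = seq_along(p), t_obs = t_obs, p = p)
  })
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q-values with a significance mask at `q_thresh`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q_thresh Significance threshold on q (default 0.01).
#' @return Tibble with `p`, `q`, `significant`.
#' @export
fdr_correct <- function(p, q_thresh = 0.01) {
  stopifnot(all(p >= 0 & p <= 1))
  q <- p.adjust(p, method = "BH")
  tibble(p = p, q = q, significant = q < q_thresh)
}

#' Across-session synchrony contrast
#'
#' Builds session-level mean synchrony curves per group, contrasts the two
#' groups with a per-bin permutation test across sessions, and applies BH
#' correction.
#'
#' @param sessions List of [session_recording()]s.
#' @param alignment,window,group_by,dt As in [session_synchrony()].
#' @param groups Two group labels to contrast (default
#'   `c("correct", "incorrect")`).
#' @param n_perm,paired,seed Passed to [permutation_group_test()].
#' @param q_thresh FDR threshold (0.01).
#' @return List with `means` (grand-average curves), `bins` (tibble: `bin`,
#'   `time`, `t_obs`, `p`, `q`, `significant`), and the per-session curve
#'   matrices.
#' @export
synchrony_timecourse <- function(sessions, alignment = "response",
                                 window = c(-1, 0.5), group_by = "outcome",
                                 groups = c("correct", "incorrect"),
                                 dt = 0.001, n_perm = 1000, paired = TRUE,
                                 q_thresh = 0.01, seed = 1L) {
  per_session <- purrr::map(sessions, session_synchrony,
    alignment = alignment, window = window, group_by = group_by, dt = dt
  )
  curve_of <- function(ss, g) {
    v <- ss$means$value[ss$means$group == g]
    if (length(v) == 0) rep(NA_real_, length(ss$times)) else v
  }
  a <- do.call(rbind, purrr::map(per_session, curve_of, g = groups[1]))
  b <- do.call(rbind, purrr::map(per_session, curve_of, g = groups[2]))
  ok <- complete.cases(a) & complete.cases(b)
  test <- permutation_group_test(a[ok, , drop = FALSE], b[ok, , drop = FALSE],
    n_perm = n_perm, paired = paired, seed = seed
  )
  fdr <- fdr_correct(test$p, q_thresh = q_thresh)
  times <- per_session[[1]]$times
  list(
    means = tibble(
      time = rep(times, 2),
      group = rep(groups, each = length(times)),
      value = c(colMeans(a[ok, , drop = FALSE]), colMeans(b[ok, , drop = FALSE]))
    ),
    bins = tibble(
      bin = test$bin, time = times, t_obs = test$t_obs,
      p = test$p, q = fdr$q, significant = fdr$significant
    ),
    curves = list(a = a[ok, , drop = FALSE], b = b[ok, , drop = FALSE]),
    n_sessions = sum(ok)
  )
}
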