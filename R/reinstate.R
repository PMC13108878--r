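# Encoding-retrieval reinstatement: trial-wise Mahalanobis distance between
# encoding and TOJ-period population vectors, normalized by twice the
# neuron count so sessions with different ensemble sizes are comparable
# (lower index = stronger reinstatement), with permutation and video-half
# controls.

#' Encoding and retrieval population vectors
#'
#' Per-trial mean firing rate of each neuron over the encoding span (the
#' full 8 s, or its first or second half) and over the TOJ period (probe
#' onset to response).
#'
#' @param session A [session_recording()].
#' @param video_half `"full"`, `"first"` (0-4 s) or `"second"` (4-8 s).
#' @param units Unit ids (default all).
#' @return List with matrices `encoding` and `retrieval` (trials x
#'   neurons, Hz).
#' @export
population_vectors <- function(session, video_half = c("full", "first", "second"),
                               units = session$units$unit_id) {
  video_half <- match.arg(video_half)
  trials <- session$trials
  enc_dur <- trials$video_off[1] - trials$video_on[1]
  span <- switch(video_half,
    full = c(0, enc_dur),
    first = c(0, enc_dur / 2),
    second = c(enc_dur / 2, enc_dur)
  )
  e_win <- cbind(trials$video_on + span[1], trials$video_on + span[2])
  r_win <- cbind(trials$probe_on, trials$response_time)
  if (any(r_win[, 2] <= r_win[, 1])) abort("TOJ period empty on some trial")
  e_tr <- spike_trains_in_window(session, units, trials, e_win)
  r_tr <- spike_trains_in_window(session, units, trials, r_win)
  rate_mat <- function(tr, durations) {
    m <- vapply(tr, function(per_trial) {
      lengths(per_trial) / durations
    }, numeric(nrow(trials)))
    matrix(m, nrow = nrow(trials), dimnames = list(NULL, units))
  }
  list(
    encoding = rate_mat(e_tr, span[2] - span[1]),
    retrieval = rate_mat(r_tr, trials$response_time - trials$probe_on)
  )
}

# Covariance with diagonal shrinkage. With shrinkage = NULL the intensity
# toward the scaled identity is estimated by the Ledoit-Wolf formula, the
# appropriate regime for ~10 neurons and >= 90 trials; shrinkage = 0 gives
# the bare sample covariance.
regularized_cov <- function(X, shrinkage = NULL) {
  S <- stats::cov(X)
  lam <- if (is.null(shrinkage)) ledoit_wolf_intensity(X, S) else shrinkage
  if (lam > 0) S <- (1 - lam) * S + lam * mean(diag(S)) * diag(ncol(S))
  if (!rcond_ok(S)) abort("population covariance singular even after shrinkage")
  S
}

# Ledoit-Wolf (2004) optimal intensity for shrinkage toward m * I.
ledoit_wolf_intensity <- function(X, S = stats::cov(X)) {
  n <- nrow(X)
  p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  m <- mean(diag(S))
  d2 <- sum((S - m * diag(p))^2) / p
  if (d2 <= 0) return(0)
  bbar2 <- 0
  for (k in seq_len(n)) {
    bbar2 <- bbar2 + sum((tcrossprod(Xc[k, ]) - S)^2)
  }
  bbar2 <- bbar2 / (n^2 * p)
  min(bbar2, d2) / d2
}

rcond_ok <- function(S) {
  is.finite(rcond(S)) && rcond(S) > 1e-10
}

# Squared Mahalanobis distances of paired rows: d2[i] under covariance S of
# (retrieval[i,] - encoding[i,]).
paired_mahalanobis <- function(encoding, retrieval, S) {
  d <- retrieval - encoding
  Sinv <- solve(S)
  rowSums((d %*% Sinv) * d)
}

#' Trial-wise Mahalanobis reinstatement index
#'
#' Squared Mahalanobis distance of each trial's retrieval vector from its
#' own encoding vector, under the covariance of encoding vectors across the
#' session's trials, divided by twice the number of neurons:
#' `index = d2 / (2 N)`. The trial-matched difference form is what makes
#' the permutation control (which breaks trial correspondence) meaningful.
#'
#' @param session A [session_recording()].
#' @param video_half Encoding span, see [population_vectors()].
#' @param units Unit ids (default all).
#' @param shrinkage Diagonal shrinkage intensity of the encoding
#'   covariance; `NULL` (default) uses the sample covariance when
#'   well-conditioned.
#' @return Tibble with one row per trial: `session_id`, `trial_id`,
#'   `index`, `outcome`, `condition`, `video_half`.
#' @export
mahalanobis_index <- function(session, video_half = "full",
                              units = session$units$unit_id,
                              shrinkage = NULL) {
  trials <- session$trials
  if (nrow(trials) < length(units) + 2) {
    abort("need at least n_neurons + 2 trials to estimate the covariance")
  }
  pv <- population_vectors(session, video_half, units)
  S <- regularized_cov(pv$encoding, shrinkage)
  d2 <- paired_mahalanobis(pv$encoding, pv$retrieval, S)
  tibble(
    session_id = session$session_id,
    trial_id = trials$trial_id,
    index = d2 / (2 * length(units)),
    outcome = trials$outcome,
    condition = trials$condition,
    video_half = video_half
  )
}

#' Outcome contrast of reinstatement indices
#'
#' Per-session mean index for correct and incorrect trials, with a paired
#' comparison across sessions: a sign-flip permutation test on the
#' session-level differences and an exact sign test.
#'
#' @param records Tibble from [mahalanobis_index()], possibly several
#'   sessions.
#' @param n_perm Sign-flip permutations (1000; used when >= 3 sessions).
#' @param seed Integer seed.
#' @return List with `by_session` (session means and difference),
#'   `mean_diff` (correct - incorrect), `p_perm`, `p_sign`.
#' @export
outcome_contrast <- function(records, n_perm = 1000, seed = 1L) {
  by_session <- records %>%
    group_by(.data$session_id, .data$outcome) %>%
    summarise(mean_index = mean(.data$index), n = n(), .groups = "drop") %>%
    tidyr::pivot_wider(
      id_cols = "session_id", names_from = "outcome",
      values_from = c("mean_index", "n")
    )
  need <- c("mean_index_correct", "mean_index_incorrect")
  if (!all(need %in% names(by_session)) || anyNA(by_session[need])) {
    abort("both outcomes must be present in every session")
  }
  d <- by_session$mean_index_correct - by_session$mean_index_incorrect
  p_perm <- if (length(d) >= 3) {
    with_seed(substream_seed(seed, "outcome-contrast"), {
      obs <- mean(d)
      null <- vapply(seq_len(n_perm), function(i) {
        mean(d * sample(c(-1, 1), length(d), replace = TRUE))
      }, numeric(1))
      (sum(abs(null) >= abs(obs)) + 1) / (n_perm + 1)
    })
  } else {
    NA_real_
  }
  p_sign <- binom.test(sum(d < 0), length(d))$p.value
  list(
    by_session = by_session %>% mutate(diff = d),
    mean_diff = mean(d),
    p_perm = p_perm,
    p_sign = p_sign
  )
}

#' Permutation control for encoding-retrieval similarity
#'
#' Independently permutes the trial rows of the encoding and retrieval
#' matrices, recomputes the distance indices, and compares the observed
#' group means against the null: `p = (#{null mean <= observed} + 1) /
#' (n_perm + 1)` per outcome group. Shuffling preserves marginal firing
#' statistics but destroys trial-specific correspondence.
#'
#' @param session A [session_recording()].
#' @param n_perm Permutations (1000).
#' @param video_half Encoding span.
#' @param units Unit ids.
#' @param shrinkage Covariance shrinkage, see [mahalanobis_index()].
#' @param seed Integer seed.
#' @return Tibble with one row per outcome group: `outcome`, `observed`
#'   (mean index), `null_mean`, `p`.
#' @export
permutation_control <- function(session, n_perm = 1000, video_half = "full",
                                units = session$units$unit_id,
                                shrinkage = NULL, seed = 1L) {
  trials <- session$trials
  if (nrow(trials) < 10) abort("permutation_control needs at least 10 trials")
  pv <- population_vectors(session, video_half, units)
  S <- regularized_cov(pv$encoding, shrinkage)
  N2 <- 2 * length(units)
  idx_fun <- function(perm_e, perm_r) {
    paired_mahalanobis(pv$encoding[perm_e, , drop = FALSE],
      pv$retrieval[perm_r, , drop = FALSE], S) / N2
  }
  obs <- idx_fun(seq_len(nrow(trials)), seq_len(nrow(trials)))
  groups <- unique(trials$outcome)
  with_seed(substream_seed(seed, "reinstate-null"), {
    null_means <- matrix(NA_real_, n_perm, length(groups),
      dimnames = list(NULL, groups)
    )
    for (p in seq_len(n_perm)) {
      v <- idx_fun(sample.int(nrow(trials)), sample.int(nrow(trials)))
      for (g in groups) null_means[p, g] <- mean(v[trials$outcome == g])
    }
    purrr::map_dfr(groups, function(g) {
      o <- mean(obs[trials$outcome == g])
      tibble(
        outcome = g,
        observed = o,
        null_mean = mean(null_means[, g]),
        p = (sum(null_means[, g] <= o) + 1) / (n_perm + 1)
      )
    })
  })
}

#' Pooled permutation control across sessions
#'
#' The per-session permutation control of [permutation_control()], pooled
#' over a cohort: each iteration independently permutes the encoding and
#' retrieval matrices within every session, and the per-outcome null means
#' are averaged across sessions before comparison with the pooled observed
#' means — the procedure used when several sessions of one subject are
#' tested together.
#'
#' @param sessions List of [session_recording()]s.
#' @param n_perm Permutations (1000).
#' @param video_half Encoding span.
#' @param shrinkage Covariance shrinkage, see [mahalanobis_index()].
#' @param seed Integer seed.
#' @return Tibble with one row per outcome: `outcome`, `observed`,
#'   `null_mean`, `p`, `n_sessions`.
#' @export
cohort_permutation_control <- function(sessions, n_perm = 1000,
                                       video_half = "full", shrinkage = NULL,
                                       seed = 1L) {
  prep <- purrr::map(sessions, function(s) {
    pv <- population_vectors(s, video_half)
    list(
      pv = pv,
      S = regularized_cov(pv$encoding, shrinkage),
      outcome = s$trials$outcome,
      n2 = 2 * ncol(pv$encoding)
    )
  })
  groups <- sort(unique(unlist(purrr::map(prep, "outcome"))))
  sess_means <- function(pr, perm_e, perm_r) {
    v <- paired_mahalanobis(pr$pv$encoding[perm_e, , drop = FALSE],
      pr$pv$retrieval[perm_r, , drop = FALSE], pr$S) / pr$n2
    vapply(groups, function(g) mean(v[pr$outcome == g]), numeric(1))
  }
  obs <- rowMeans(vapply(prep, function(pr) {
    sess_means(pr, seq_along(pr$outcome), seq_along(pr$outcome))
  }, numeric(length(groups))))
  with_seed(substream_seed(seed, "cohort-reinstate-null"), {
    null_means <- t(vapply(seq_len(n_perm), function(it) {
      rowMeans(vapply(prep, function(pr) {
        n <- length(pr$outcome)
        sess_means(pr, sample.int(n), sample.int(n))
      }, numeric(length(groups))))
    }, numeric(length(groups))))
    purrr::map_dfr(seq_along(groups), function(gi) {
      tibble(
        outcome = groups[gi],
        observed = obs[gi],
        null_mean = mean(null_means[, gi]),
        p = (sum(null_means[, gi] <= obs[gi]) + 1) / (n_perm + 1),
        n_sessions = length(sessions)
      )
    })
  })
}

#' Video-half control model
#'
#' Assembles first- and second-half distance records and fits the
#' fixed-effects structure `index ~ outcome * video_half + condition` with
#' a per-subject random intercept by REML. With a single subject the random
#' intercept collapses to an ordinary linear model.
#'
#' @param records Tibble of distance records computed for `video_half`
#'   `"first"` and `"second"` (stacked), with a `subject` column.
#' @return Tibble of fixed-effect estimates with `term`, `estimate`,
#'   `std_error`, `p`.
#' @export
video_half_control <- function(records) {
  stopifnot(all(c("first", "second") %in% records$video_half))
  d <- records %>%
    mutate(
      correctness = as.numeric(.data$outcome == "correct"),
      half = as.numeric(.data$video_half == "second"),
      delay = as.numeric(.data$condition == "delayed")
    )
  if (!"subject" %in% names(d)) d$subject <- "s1"
  if (length(unique(d$subject)) < 2) {
    fit <- lm(index ~ correctness * half + delay, data = d)
    sm <- summary(fit)$coefficients
    tibble(
      term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2], p = sm[, 4]
    )
  } else {
    fit <- lmerTest::lmer(index ~ correctness * half + delay + (1 | subject), data = d)
    sm <- summary(fit)$coefficients
    tibble(
      term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
      p = sm[, "Pr(>|t|)"]
    )
  }
}
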