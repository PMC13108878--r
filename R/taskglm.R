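# Per-neuron Poisson GLMs: epoch-resolved design construction, stepwise
# selection on adjusted pseudo-R-squared, TOJ-cell classification, the
# TOJ-epoch decomposition, reaction-time slopes, and the eye-movement
# control model.

EPOCH_TERMS <- c("encoding", "delay", "toj", "feedback", "iti") # fixation = reference
TOJ_SPLIT_TERMS <- c("toj_vis", "toj_mem", "toj_mot")
TRIAL_TERMS <- c("block", "rt", "outcome", "condition", "side")
EYE_TERMS <- c("saccade_freq", "fixation_freq", "scanpath_len", "fixation_dur")

#' Build the Poisson GLM design for one unit
#'
#' Expands a session into one observation per (trial, epoch) with the
#' unit's spike count `y`, the epoch duration as `exposure`, mutually
#' exclusive epoch indicators (pretrial fixation is the reference level),
#' and trial-level covariates repeated across that trial's rows. With
#' `decompose_toj` the TOJ epoch is split into an early visual window
#' (0-200 ms after probe onset), a retrieval/comparison window (200 ms
#' after onset until 200 ms before response), and a response-locked motor
#' window (last 200 ms); trials with `rt <= 0.4` s lose the retrieval row,
#' with a warning. With `eye = TRUE` the four oculomotor metrics over the
#' TOJ period are appended per trial.
#'
#' @param session A [session_recording()].
#' @param unit Unit id.
#' @param decompose_toj Split the TOJ epoch into vis/mem/mot windows.
#' @param eye Append eye-movement metrics (requires `session$eye_events`).
#' @return Tibble, one row per (trial, epoch): `trial_id`, `epoch`, `y`,
#'   `exposure`, indicator and covariate columns.
#' @export
build_design <- function(session, unit, decompose_toj = FALSE, eye = FALSE) {
  trials <- session$trials
  ep <- trial_epochs(trials)
  if (decompose_toj) {
    toj <- ep[ep$epoch == "toj", ]
    short <- trials$rt[match(toj$trial_id, trials$trial_id)] <= 0.4
    if (any(short)) {
      warn(sprintf(
        "%d trial(s) with rt <= 0.4 s: retrieval window empty, row dropped",
        sum(short)
      ))
    }
    split_rows <- purrr::map_dfr(seq_len(nrow(toj)), function(i) {
      r <- toj[i, ]
      rt <- r$t_end - r$t_start
      out <- tibble(
        trial_id = r$trial_id,
        epoch = TOJ_SPLIT_TERMS,
        t_start = r$t_start + c(0, 0.2, rt - 0.2),
        t_end = r$t_start + c(min(0.2, rt), rt - 0.2, rt)
      )
      out[out$t_end > out$t_start + 1e-12, ]
    })
    ep <- bind_rows(ep[ep$epoch != "toj", ], split_rows) %>%
      mutate(duration = .data$t_end - .data$t_start) %>%
      arrange(.data$trial_id, .data$t_start)
  }

  sp <- session$spikes[session$spikes$unit_id == unit, ]
  y <- vapply(seq_len(nrow(ep)), function(i) {
    sum(sp$trial_id == ep$trial_id[i] & sp$t >= ep$t_start[i] & sp$t < ep$t_end[i])
  }, integer(1))

  epoch_terms <- if (decompose_toj) c(setdiff(EPOCH_TERMS, "toj"), TOJ_SPLIT_TERMS) else EPOCH_TERMS
  design <- tibble(
    trial_id = ep$trial_id,
    epoch = ep$epoch,
    y = y,
    exposure = ep$duration
  )
  for (term in epoch_terms) design[[term]] <- as.numeric(ep$epoch == term)
  ti <- match(design$trial_id, trials$trial_id)
  design$block <- as.numeric(trials$block[ti])
  design$rt <- trials$rt[ti]
  design$outcome <- as.numeric(trials$outcome[ti] == "correct")
  design$condition <- as.numeric(trials$condition[ti] == "delayed")
  design$side <- as.numeric(trials$response_side[ti] == "right")

  if (eye) {
    em <- purrr::map_dfr(seq_len(nrow(trials)), function(i) {
      tr <- trials[i, ]
      ev <- session$eye_events
      ev <- if (is.null(ev)) NULL else ev[ev$trial_id == tr$trial_id, ]
      eye_metrics(ev, c(tr$probe_on, max(tr$response_time, tr$probe_on + 1e-6)))
    })
    for (term in EYE_TERMS) design[[term]] <- em[[term]][ti]
  }
  design
}

#' Fit a Poisson GLM with log-exposure offset
#'
#' Fits `y ~ Poisson(exp(X beta + log(exposure)))` by iteratively
#' reweighted least squares and returns per-term Wald statistics.
#'
#' @param design Tibble from [build_design()].
#' @param terms Character vector of design columns to include (besides the
#'   intercept); empty for the null model.
#' @return List with `terms`, `coefficients`, `wald_p`, `loglik`,
#'   `n_params` (terms beyond the intercept), and the `glm` object.
#' @export
fit_poisson_glm <- function(design, terms = character(0)) {
  stopifnot(all(design$exposure > 0), all(design$y >= 0))
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  f <- stats::as.formula(paste0("y ~ ", rhs, " + offset(log(exposure))"))
  fit <- glm(f, family = poisson(), data = design)
  if (!fit$converged) abort("Poisson GLM did not converge (possible separation)")
  aliased <- is.na(coef(fit))
  if (any(aliased)) {
    abort(sprintf(
      "rank-deficient design: column '%s' aliased", names(coef(fit))[aliased][1]
    ))
  }
  sm <- summary(fit)$coefficients
  keep <- setdiff(rownames(sm), "(Intercept)")
  list(
    terms = terms,
    coefficients = coef(fit),
    wald_p = setNames(sm[keep, "Pr(>|z|)"], keep),
    loglik = as.numeric(stats::logLik(fit)),
    n_params = length(terms),
    fit = fit
  )
}

#' McFadden pseudo-R-squared
#'
#' Likelihood-based goodness of fit, `1 - loglik_full / loglik_null`, with
#' an adjusted variant that charges `k` parameters to the numerator
#' log-likelihood: `1 - (loglik_full - k) / loglik_null`.
#'
#' @param loglik_full,loglik_null Model and intercept-only log-likelihoods.
#' @param n_params Parameters beyond the intercept in the full model.
#' @return List with `pseudo_r2` and `adj_pseudo_r2`.
#' @export
pseudo_r2 <- function(loglik_full, loglik_null, n_params = 0) {
  if (loglik_null == 0) abort("null model log-likelihood is zero; pseudo-R2 undefined")
  list(
    pseudo_r2 = 1 - loglik_full / loglik_null,
    adj_pseudo_r2 = 1 - (loglik_full - n_params) / loglik_null
  )
}

#' Stepwise regressor selection for one unit
#'
#' Forward-backward search over candidate regressors driven by adjusted
#' McFadden pseudo-R-squared: at each pass the candidate whose inclusion
#' raises the criterion most is added if the gain exceeds `add_gain`
#' (retain if > 0.01), then any retained term whose removal costs less than
#' `drop_gain` is dropped (exclude if < 0.005); the loop runs to a fixed
#' point. A unit is a TOJ cell when at least one TOJ-related regressor is
#' retained with Wald p below `alpha` in the final model.
#'
#' @param design Tibble from [build_design()].
#' @param candidates Candidate term names (default: all epoch, trial and —
#'   if present — eye columns).
#' @param add_gain,drop_gain Inclusion/exclusion thresholds on adjusted
#'   pseudo-R-squared (0.01 / 0.005).
#' @param alpha Wald significance level for TOJ classification (0.05).
#' @param max_iter Search iteration cap; exceeding it aborts (50).
#' @return One-row tibble: `retained_terms` and `eye_terms_retained`
#'   (list-columns), `coefficients` and `wald_p` (list-columns),
#'   `pseudo_r2`, `adj_pseudo_r2`, `is_toj_cell`, `strict_toj_cell`.
#' @export
stepwise_select <- function(design, candidates = NULL,
                            add_gain = 0.01, drop_gain = 0.005,
                            alpha = 0.05, max_iter = 50) {
  if (is.null(candidates)) {
    pool <- c(EPOCH_TERMS, TOJ_SPLIT_TERMS, TRIAL_TERMS, EYE_TERMS)
    candidates <- intersect(pool, names(design))
  }
  # constant columns cannot be estimated
  candidates <- candidates[vapply(candidates, function(cn) var(design[[cn]]) > 0, logical(1))]
  if (length(candidates) < 2) abort("stepwise_select needs at least 2 candidate terms")

  ll_null <- fit_poisson_glm(design)$loglik
  crit <- function(terms) {
    if (length(terms) == 0) return(list(adj = 0, fit = NULL))
    f <- tryCatch(fit_poisson_glm(design, terms), error = function(e) NULL)
    if (is.null(f)) return(list(adj = -Inf, fit = NULL))
    list(adj = pseudo_r2(f$loglik, ll_null, f$n_params)$adj_pseudo_r2, fit = f)
  }

  retained <- character(0)
  cur <- 0
  for (iter in seq_len(max_iter + 1)) {
    if (iter > max_iter) abort("stepwise selection failed to reach a fixed point")
    changed <- FALSE
    # forward
    pool <- setdiff(candidates, retained)
    if (length(pool) > 0) {
      gains <- vapply(pool, function(term) crit(c(retained, term))$adj - cur, numeric(1))
      if (max(gains) > add_gain) {
        retained <- c(retained, pool[which.max(gains)])
        cur <- cur + max(gains)
        changed <- TRUE
      }
    }
    # backward
    repeat {
      if (length(retained) == 0) break
      costs <- vapply(retained, function(term) cur - crit(setdiff(retained, term))$adj, numeric(1))
      if (min(costs) < drop_gain) {
        drop <- retained[which.min(costs)]
        retained <- setdiff(retained, drop)
        cur <- crit(retained)$adj
        changed <- TRUE
      } else {
        break
      }
    }
    if (!changed) break
  }

  final <- if (length(retained) > 0) fit_poisson_glm(design, retained) else NULL
  r2 <- if (is.null(final)) {
    list(pseudo_r2 = 0, adj_pseudo_r2 = 0)
  } else {
    pseudo_r2(final$loglik, ll_null, final$n_params)
  }
  toj_terms <- intersect(retained, c("toj", TOJ_SPLIT_TERMS))
  wald <- if (is.null(final)) numeric(0) else final$wald_p
  is_toj <- length(toj_terms) > 0 && any(wald[toj_terms] < alpha, na.rm = TRUE)
  eye_retained <- intersect(retained, EYE_TERMS)
  tibble(
    retained_terms = list(retained),
    coefficients = list(if (is.null(final)) numeric(0) else final$coefficients),
    wald_p = list(wald),
    pseudo_r2 = r2$pseudo_r2,
    adj_pseudo_r2 = r2$adj_pseudo_r2,
    is_toj_cell = is_toj,
    eye_terms_retained = list(eye_retained),
    strict_toj_cell = is_toj && length(eye_retained) == 0
  )
}

#' Classify TOJ cells across a session
#'
#' Runs [build_design()] and [stepwise_select()] for every unit.
#'
#' @param session A [session_recording()].
#' @param units Unit ids (default all).
#' @param decompose_toj,eye Passed to [build_design()].
#' @param ... Passed to [stepwise_select()].
#' @return Tibble with one row per unit (see [stepwise_select()]).
#' @export
classify_toj_cells <- function(session, units = session$units$unit_id,
                               decompose_toj = FALSE, eye = FALSE, ...) {
  purrr::map_dfr(units, function(u) {
    d <- build_design(session, u, decompose_toj = decompose_toj, eye = eye)
    res <- stepwise_select(d, ...)
    res$unit_id <- u
    dplyr::relocate(res, "unit_id")
  })
}

#' Strict TOJ classification under the eye-movement control model
#'
#' A unit passes the strict criterion when it is a TOJ cell and no
#' eye-movement regressor was retained in its final model.
#'
#' @param glm_results Tibble from [classify_toj_cells()] fitted with
#'   `eye = TRUE`.
#' @return The tibble with `strict_toj_cell` recomputed.
#' @export
eye_control_classify <- function(glm_results) {
  glm_results %>%
    mutate(strict_toj_cell = .data$is_toj_cell &
      purrr::map_int(.data$eye_terms_retained, length) == 0)
}

#' Reaction-time/firing-rate slopes
#'
#' Standardized OLS slope (equal to the Pearson correlation) between
#' z-scored TOJ-period firing rate and z-scored reaction time, separately
#' for correct and incorrect trials.
#'
#' @param session A [session_recording()].
#' @param unit Unit id.
#' @param min_trials Minimum trials per outcome (5).
#' @return Tibble with one row per outcome: `slope`, `n`, `degenerate`
#'   (zero variance in either variable).
#' @export
rt_rate_slopes <- function(session, unit, min_trials = 5) {
  trials <- session$trials
  sp <- session$spikes[session$spikes$unit_id == unit, ]
  cnt <- vapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    sum(sp$trial_id == tr$trial_id & sp$t >= tr$probe_on & sp$t < tr$response_time)
  }, numeric(1))
  rate <- cnt / trials$rt
  purrr::map_dfr(c("correct", "incorrect"), function(out) {
    i <- trials$outcome == out
    if (sum(i) < min_trials) {
      abort(sprintf("fewer than %d '%s' trials", min_trials, out))
    }
    degenerate <- sd(rate[i]) == 0 || sd(trials$rt[i]) == 0
    slope <- if (degenerate) NA_real_ else {
      coef(lm(scale(rate[i]) ~ scale(trials$rt[i])))[2]
    }
    tibble(outcome = out, slope = unname(slope), n = sum(i), degenerate = degenerate)
  })
}

#' Mixed-model contract for behavioural reaction times
#'
#' Fits `rt ~ condition + outcome + (1 | subject)` by REML across
#' sessions; with a single subject the random intercept collapses and an
#' ordinary linear model is returned.
#'
#' @param trials Trials tibble with a `subject` column.
#' @return A `lmerModLmerTest` or `lm` fit.
#' @export
rt_mixed_model <- function(trials) {
  trials <- trials[trials$rt <= 10, ]
  if (length(unique(trials$subject)) < 2) {
    lm(rt ~ condition + outcome, data = trials)
  } else {
    lmerTest::lmer(rt ~ condition + outcome + (1 | subject), data = trials)
  }
}
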