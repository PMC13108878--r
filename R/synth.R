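# Synthetic session generator. Emulates the statistical structure every
# downstream stage assumes: onset-anchored ex-Gaussian encoding profiles
# with heterogeneous relaxation times, task-epoch firing modulation with a
# TOJ-period gain, outcome-dependent pre-response spike-timing coordination,
# trial-wise encoding-retrieval pattern correspondence, and two-alternative
# behaviour around 65% correct under 0-s and 3.6-s probe delays.

#' Synthetic session configuration
#'
#' Parameters of the synthetic session generator. Defaults are the study
#' conditions the pipeline is validated under: 8-s encoding videos, 180
#' trials, ~10 simultaneously recorded neurons, 16% temporal context cells
#' (111/676 in the recorded population) with relaxation times log-uniform on
#' 0.1-20 s and latencies below 1 s, 68% TOJ-modulated cells (461/676),
#' behavioural accuracy 0.65, and log-normal reaction times with ~1.7%
#' exceeding the 10-s exclusion cutoff.
#'
#' @param n_neurons Simultaneously recorded units (default 10).
#' @param n_trials Trials per session (default 180).
#' @param frac_tcc Proportion of temporal context cells (default 0.16).
#' @param frac_toj Proportion of TOJ-modulated cells (default 0.68).
#' @param frac_decreasing Proportion of temporal context cells with
#'   decreasing onset responses (default 48/111).
#' @param tau_range Relaxation-time range, s; drawn log-uniformly (0.1-20).
#' @param latency_range Latency (`mu`) range, s; uniform (0.05-1).
#' @param sigma_range Gaussian width range, s; uniform (0.05-0.3).
#' @param baseline_rate Mean baseline rate, Hz (default 8).
#' @param peak_amplitude Peak rate change of context cells, Hz (default 8).
#' @param accuracy Probability of a correct trial (default 0.65).
#' @param toj_gain Multiplicative rate gain of TOJ cells during the TOJ
#'   epoch (default 1.5; 1 = no effect).
#' @param reinstatement_rho Correlation between the encoding and retrieval
#'   latent pattern on correct trials (default 0.4; incorrect trials always
#'   use independent patterns).
#' @param sync_gain Amplitude of the shared sinusoidal gain applied to all
#'   units in the 1 s before response on correct trials (default 0.3;
#'   0 = no effect).
#' @param pattern_sd SD of the log-normal per-(trial, unit) latent gain
#'   (default 0.3).
#' @param sync_freq Frequency of the shared pre-response gain, Hz (6).
#' @param rt_lognormal `c(meanlog, sdlog)` of reaction times; the default
#'   `c(0.6, 0.8)` puts ~1.7% of RTs above 10 s.
#' @param delay_duration Retention delay of delayed trials, s (3.6).
#' @param encoding_duration Video duration, s (8).
#' @param seed Integer seed; all stage randomness derives from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_neurons = 10,
                         n_trials = 180,
                         frac_tcc = 0.16,
                         frac_toj = 0.68,
                         frac_decreasing = 48 / 111,
                         tau_range = c(0.1, 20),
                         latency_range = c(0.05, 1.0),
                         sigma_range = c(0.05, 0.3),
                         baseline_rate = 8,
                         peak_amplitude = 8,
                         accuracy = 0.65,
                         toj_gain = 1.5,
                         reinstatement_rho = 0.4,
                         sync_gain = 0.3,
                         pattern_sd = 0.3,
                         sync_freq = 6,
                         rt_lognormal = c(0.6, 0.8),
                         delay_duration = 3.6,
                         encoding_duration = 8,
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    frac_tcc >= 0, frac_tcc <= 1, frac_toj >= 0, frac_toj <= 1,
    frac_decreasing >= 0, frac_decreasing <= 1,
    accuracy >= 0, accuracy <= 1,
    tau_range[1] > 0, tau_range[2] <= 20, tau_range[1] <= tau_range[2],
    baseline_rate >= 0, peak_amplitude >= 0, toj_gain >= 0,
    abs(reinstatement_rho) <= 1, sync_gain >= 0, sync_gain < 1
  )
  structure(cfg, class = "synth_config")
}

#' Sample an inhomogeneous Poisson spike train
#'
#' Draws one realization of an inhomogeneous Poisson process on
#' `[0, duration)` by thinning against the supremum rate: homogeneous
#' candidates at `rate_max` are kept with probability `rate_fn(t)/rate_max`.
#'
#' @param rate_fn Vectorized function time (s) -> rate (Hz), nonnegative and
#'   bounded.
#' @param duration Train length, s.
#' @param seed Optional integer seed.
#' @param rate_max Supremum of `rate_fn` on the window; estimated on a 1-ms
#'   grid when omitted.
#' @return Sorted spike times in `[0, duration)`.
#' @export
generate_spike_train <- function(rate_fn, duration, seed = NULL, rate_max = NULL) {
  draw <- function() {
    if (is.null(rate_max)) {
      grid <- seq(0, duration, by = 1e-3)
      rate_max <<- max(rate_fn(grid)) * 1.05 + 1e-9
    }
    if (rate_max <= 0) return(numeric(0))
    n_cand <- rpois(1, rate_max * duration)
    if (n_cand == 0) return(numeric(0))
    t_cand <- sort(runif(n_cand, 0, duration))
    r <- rate_fn(t_cand)
    if (any(r < -1e-9)) abort("rate_fn returned a negative rate")
    r <- pmax(r, 0)
    if (any(r > rate_max + 1e-6)) abort("rate_fn exceeds rate_max; thinning invalid")
    # runif has finite granularity, so exact candidate collisions occur at
    # ~1e-3 per train; a Poisson process has no coincident points
    unique(t_cand[runif(n_cand) < r / rate_max])
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate a synthetic session
#'
#' Simulates one recording session under a [synth_config()]: the trial table
#' with correct epoch geometry, and inhomogeneous-Poisson spike trains whose
#' rate profiles carry the programmed effects. Returns the session together
#' with the ground truth (per-unit labels and parameters, per-trial latent
#' patterns) that recovery tests score against.
#'
#' @param config A [synth_config()].
#' @return List with `session` (a [session_recording()]) and `truth` (list
#'   with `units` and `trials` tibbles plus the `config`).
#' @export
generate_session <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(substream_seed(config$seed, "session"), generate_session_impl(config))
}

generate_session_impl <- function(cfg) {
  n_tr <- cfg$n_trials
  n_u <- cfg$n_neurons

  # ---- trials ----------------------------------------------------------
  condition <- rep(c("immediate", "delayed"), length.out = n_tr)[sample.int(n_tr)]
  rt <- pmin(rlnorm(n_tr, cfg$rt_lognormal[1], cfg$rt_lognormal[2]), 60)
  outcome <- ifelse(rbinom(n_tr, 1, cfg$accuracy) == 1, "correct", "incorrect")
  video_on <- 1
  video_off <- video_on + cfg$encoding_duration
  probe_on <- video_off + ifelse(condition == "delayed", cfg$delay_duration, 0)
  response_time <- probe_on + rt
  feedback_on <- response_time
  trial_end <- feedback_on + FEEDBACK_DURATION + 1
  trials <- tibble(
    trial_id = seq_len(n_tr),
    block = (seq_len(n_tr) - 1L) %/% 30L + 1L,
    condition = condition,
    video_on = video_on,
    video_off = video_off,
    probe_on = probe_on,
    response_time = response_time,
    feedback_on = feedback_on,
    trial_end = trial_end,
    outcome = outcome,
    response_side = sample(c("left", "right"), n_tr, replace = TRUE),
    rt = rt,
    chosen_frame = ifelse(outcome == "correct", "early", "late")
  )

  # ---- unit labels and parameters --------------------------------------
  n_tcc <- round(cfg$frac_tcc * n_u)
  n_toj <- round(cfg$frac_toj * n_u)
  is_tcc <- seq_len(n_u) %in% sample.int(n_u, n_tcc)
  is_toj <- seq_len(n_u) %in% sample.int(n_u, n_toj)
  a0 <- cfg$baseline_rate * exp(rnorm(n_u, 0, 0.2))
  decreasing <- is_tcc & (runif(n_u) < cfg$frac_decreasing)
  a1 <- ifelse(decreasing,
    -pmin(cfg$peak_amplitude, a0 - 0.5), # decreasing units floored at 0.5 Hz
    cfg$peak_amplitude
  )
  a1[!is_tcc] <- 0
  units <- tibble(
    unit_id = sprintf("u%02d", seq_len(n_u)),
    label = ifelse(is_tcc, ifelse(decreasing, "tcc_dec", "tcc_inc"),
      ifelse(is_toj, "toj", "untuned")
    ),
    is_tcc = is_tcc,
    is_toj = is_toj,
    a0 = a0,
    a1 = a1,
    mu = runif(n_u, cfg$latency_range[1], cfg$latency_range[2]),
    sigma = runif(n_u, cfg$sigma_range[1], cfg$sigma_range[2]),
    tau = exp(runif(n_u, log(cfg$tau_range[1]), log(cfg$tau_range[2])))
  )

  # ---- latent encoding/retrieval patterns ------------------------------
  z_enc <- matrix(rnorm(n_tr * n_u), n_tr, n_u)
  z_ind <- matrix(rnorm(n_tr * n_u), n_tr, n_u)
  rho <- cfg$reinstatement_rho
  z_ret <- ifelse(
    matrix(outcome == "correct", n_tr, n_u),
    rho * z_enc + sqrt(1 - rho^2) * z_ind,
    z_ind
  )

  # ---- spike trains ----------------------------------------------------
  sync_phase <- runif(n_tr, 0, 2 * pi)
  spike_rows <- vector("list", n_u * n_tr)
  k <- 0L
  for (u in seq_len(n_u)) {
    pars <- units[u, ]
    for (i in seq_len(n_tr)) {
      tr <- trials[i, ]
      g_enc <- exp(cfg$pattern_sd * z_enc[i, u])
      g_ret <- exp(cfg$pattern_sd * z_ret[i, u])
      toj_mult <- if (pars$is_toj) cfg$toj_gain else 1
      sync_on <- cfg$sync_gain > 0 && tr$outcome == "correct"
      rate_fn <- local({
        p <- pars; trr <- tr
        force(g_enc); force(g_ret); force(toj_mult); force(sync_on)
        ph <- sync_phase[i]
        function(t) {
          r <- rep(p$a0, length(t))
          enc <- t >= trr$video_on & t < trr$video_off
          if (p$is_tcc && any(enc)) {
            r[enc] <- pmax(
              p$a0 + p$a1 * exgauss_shape(t[enc] - trr$video_on, p$mu, p$sigma, p$tau),
              0.5
            )
          }
          if (any(enc)) r[enc] <- r[enc] * g_enc
          toj <- t >= trr$probe_on & t < trr$response_time
          if (any(toj)) r[toj] <- r[toj] * toj_mult * g_ret
          if (sync_on) {
            pre <- t >= trr$response_time - 1 & t < trr$response_time
            if (any(pre)) {
              r[pre] <- r[pre] *
                (1 + cfg$sync_gain * sin(2 * pi * cfg$sync_freq * (t[pre] - trr$response_time) + ph))
            }
          }
          pmax(r, 0)
        }
      })
      rmax <- (pars$a0 + max(pars$a1, 0)) * exp(cfg$pattern_sd * 3.5) *
        max(toj_mult, 1) * (1 + cfg$sync_gain) * 1.05
      g_hi <- exp(cfg$pattern_sd * max(abs(z_enc[i, u]), abs(z_ret[i, u])))
      rmax <- max(rmax, (pars$a0 + max(pars$a1, 0)) * g_hi * max(toj_mult, 1) * (1 + cfg$sync_gain)) + 1e-6
      st <- generate_spike_train(rate_fn, tr$trial_end, rate_max = rmax)
      if (length(st) > 0) {
        k <- k + 1L
        spike_rows[[k]] <- tibble(unit_id = pars$unit_id, trial_id = tr$trial_id, t = st)
      }
    }
  }
  spikes <- if (k > 0) bind_rows(spike_rows[seq_len(k)]) else {
    tibble(unit_id = character(), trial_id = integer(), t = double())
  }

  session <- session_recording(
    trials, units[, c("unit_id", "label")], spikes,
    session_id = sprintf("synth-%d", cfg$seed)
  )
  truth <- list(
    units = units,
    trials = tibble(trial_id = trials$trial_id, z_enc = I(split(z_enc, row(z_enc))),
                    outcome = outcome),
    config = cfg
  )
  list(session = session, truth = truth)
}

#' Generate eye events for a session
#'
#' Adds synthetic eye events to a session: during each trial's TOJ period
#' the gaze alternates between the two probe locations, producing fixation
#' and saccade events. With `coupling > 0` a designated unit's TOJ-period
#' firing is regenerated with a rate gain tied to that trial's saccade
#' frequency, creating a known oculomotor confound for the control GLM.
#'
#' @param session A [session_recording()].
#' @param coupling Log-rate gain per SD of saccade frequency (default 0).
#' @param coupled_unit Unit id to confound (default the first unit).
#' @param seed Integer seed.
#' @return The session with `eye_events` attached (and the coupled unit's
#'   TOJ spikes regenerated when `coupling != 0`).
#' @export
generate_eye_session <- function(session, coupling = 0,
                                 coupled_unit = session$units$unit_id[1],
                                 seed = 1L) {
  with_seed(substream_seed(seed, "eye"), {
    trials <- session$trials
    probe_x <- c(-8, 8)
    ev_list <- vector("list", nrow(trials))
    sacc_freq <- numeric(nrow(trials))
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      t <- tr$probe_on
      side <- sample(1:2, 1)
      rows <- list()
      mean_fix <- runif(1, 0.18, 0.45) # trial-level gaze tempo varies
      # TOJ periods shorter than 1 ms yield no resolvable eye events
      while (t < tr$response_time - 1e-3) {
        fix_dur <- min(runif(1, 0.6, 1.4) * mean_fix, tr$response_time - t)
        rows[[length(rows) + 1]] <- tibble(
          trial_id = tr$trial_id, kind = "fixation",
          t_start = t, t_end = t + fix_dur,
          x = probe_x[side], y = 0, end_x = NA_real_, end_y = NA_real_,
          amplitude = NA_real_
        )
        t <- t + fix_dur
        if (t >= tr$response_time - 1e-9) break
        sac_dur <- min(0.04, tr$response_time - t)
        rows[[length(rows) + 1]] <- tibble(
          trial_id = tr$trial_id, kind = "saccade",
          t_start = t, t_end = t + sac_dur,
          x = probe_x[side], y = 0,
          end_x = probe_x[3 - side], end_y = 0,
          amplitude = abs(probe_x[3 - side] - probe_x[side])
        )
        t <- t + sac_dur
        side <- 3 - side
      }
      ev <- if (length(rows) > 0) bind_rows(rows) else NULL
      ev_list[[i]] <- ev
      m <- eye_metrics(ev, c(tr$probe_on, max(tr$response_time, tr$probe_on + 1e-6)))
      sacc_freq[i] <- m$saccade_freq
    }
    eye_events <- bind_rows(ev_list)
    session$eye_events <- eye_events

    if (coupling != 0) {
      z <- as.numeric(scale(sacc_freq))
      z[!is.finite(z)] <- 0
      sp <- session$spikes
      base_rate <- local({
        cnt <- sum(sp$unit_id == coupled_unit &
          sp$t >= trials$probe_on[match(sp$trial_id, trials$trial_id)] &
          sp$t < trials$response_time[match(sp$trial_id, trials$trial_id)])
        cnt / max(sum(trials$rt), 1e-9)
      })
      keep <- !(sp$unit_id == coupled_unit &
        sp$t >= trials$probe_on[match(sp$trial_id, trials$trial_id)] &
        sp$t < trials$response_time[match(sp$trial_id, trials$trial_id)])
      sp <- sp[keep, ]
      new_rows <- purrr::map_dfr(seq_len(nrow(trials)), function(i) {
        tr <- trials[i, ]
        rate <- base_rate * exp(coupling * z[i])
        st <- generate_spike_train(function(t) rep(rate, length(t)),
          duration = tr$response_time - tr$probe_on, rate_max = rate + 1e-9
        )
        if (length(st) == 0) return(NULL)
        tibble(unit_id = coupled_unit, trial_id = tr$trial_id, t = st + tr$probe_on)
      })
      session$spikes <- bind_rows(sp, new_rows) %>%
        arrange(.data$unit_id, .data$trial_id, .data$t)
    }
    validate_session(session)
    session
  })
}

#' Generate a cohort of sessions
#'
#' Draws several independent synthetic sessions from one configuration,
#' optionally with session-level variation: each session's encoding effect
#' amplitude is scaled by a factor drawn uniformly on 0.4-1.6, and with
#' `snr_accuracy_coupling > 0` the session's behavioural accuracy increases
#' with that factor, creating a session-level association between encoding
#' fidelity and task performance.
#'
#' @param n_sessions Number of sessions.
#' @param config Base [synth_config()].
#' @param snr_accuracy_coupling Logit-accuracy shift per unit amplitude
#'   scale (default 0 = sessions differ only by seed).
#' @param seed Integer seed.
#' @return List of `list(session, truth)` as from [generate_session()].
#' @export
generate_cohort <- function(n_sessions, config = synth_config(),
                            snr_accuracy_coupling = 0, seed = 1L) {
  scales <- with_seed(
    substream_seed(seed, "cohort"),
    runif(n_sessions, 0.4, 1.6)
  )
  purrr::map(seq_len(n_sessions), function(s) {
    cfg <- config
    cfg$peak_amplitude <- config$peak_amplitude * scales[s]
    if (snr_accuracy_coupling != 0) {
      cfg$accuracy <- stats::plogis(
        stats::qlogis(config$accuracy) + snr_accuracy_coupling * (scales[s] - 1)
      )
    }
    cfg$seed <- substream_seed(seed, paste0("cohort-session-", s))
    generate_session(cfg)
  })
}
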