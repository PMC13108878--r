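# Shared fixtures. Expensive synthetic sessions are generated once per test
# run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A mid-sized session with all generator effects on.
std_session <- function() {
  cached("std", generate_session(
    synth_config(n_neurons = 6, n_trials = 90, seed = 101)
  ))
}

# Minimal hand-built trial table with valid epoch geometry.
make_trials <- function(n = 3, condition = rep(c("immediate", "delayed"), length.out = n),
                        rt = rep(1.5, n), outcome = rep("correct", n)) {
  delay <- ifelse(condition == "delayed", 3.6, 0)
  probe_on <- 9 + delay
  tibble::tibble(
    trial_id = seq_len(n),
    block = 1L,
    condition = condition,
    video_on = 1, video_off = 9,
    probe_on = probe_on,
    response_time = probe_on + rt,
    feedback_on = probe_on + rt,
    trial_end = probe_on + rt + 5,
    outcome = outcome,
    response_side = "left",
    rt = rt,
    chosen_frame = "early"
  )
}

make_units <- function(ids = c("u1", "u2")) {
  tibble::tibble(unit_id = ids, label = "unlabeled")
}

# Deterministic spikes: one unit firing at fixed offsets in every trial.
make_spikes <- function(trials, unit_ids, offsets = c(0.5, 2, 5)) {
  purrr::map_dfr(unit_ids, function(u) {
    purrr::map_dfr(trials$trial_id, function(ti) {
      tibble::tibble(unit_id = u, trial_id = ti, t = offsets)
    })
  })
}

tiny_session <- function() {
  tr <- make_trials(3)
  session_recording(tr, make_units(), make_spikes(tr, c("u1", "u2")),
    session_id = "tiny"
  )
}

# Independent literal-formula SPIKE-distance evaluator (loop-based), kept
# deliberately separate from the package implementation.
brute_spike_distance <- function(train_a, train_b, window, times) {
  a <- sort(unique(c(window[1], train_a[train_a >= window[1] & train_a <= window[2]], window[2])))
  b <- sort(unique(c(window[1], train_b[train_b >= window[1] & train_b <= window[2]], window[2])))
  vapply(times, function(t) {
    corner <- function(spk) {
      tP <- max(spk[spk <= t])
      tF <- min(spk[spk > t])
      c(tP, tF)
    }
    ca <- corner(a)
    cb <- corner(b)
    term <- function(cn, other, t) {
      dP <- min(abs(cn[1] - other))
      dF <- min(abs(cn[2] - other))
      xP <- t - cn[1]
      xF <- cn[2] - t
      xI <- max(cn[2] - cn[1], 1e-12)
      c(S = (dP * xF + dF * xP) / xI, xI = xI)
    }
    t1 <- term(ca, b, t)
    t2 <- term(cb, a, t)
    mI <- (t1["xI"] + t2["xI"]) / 2
    unname((t1["S"] * t2["xI"] + t2["S"] * t1["xI"]) / (2 * mI^2))
  }, numeric(1))
}
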