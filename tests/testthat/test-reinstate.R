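# Encoding-retrieval reinstatement: population vectors, Mahalanobis index,
# outcome contrast, permutation and video-half controls.

test_that("population vectors are brute-force mean rates", {
  g <- std_session()
  s <- g$session
  pv <- population_vectors(s)
  expect_equal(dim(pv$encoding), c(nrow(s$trials), nrow(s$units)))
  # counting oracle on one (trial, unit) cell
  tr <- s$trials[5, ]
  u <- s$units$unit_id[2]
  cnt <- sum(s$spikes$unit_id == u & s$spikes$trial_id == tr$trial_id &
    s$spikes$t >= tr$video_on & s$spikes$t < tr$video_off)
  expect_equal(unname(pv$encoding[5, 2]), cnt / 8)
  cnt_r <- sum(s$spikes$unit_id == u & s$spikes$trial_id == tr$trial_id &
    s$spikes$t >= tr$probe_on & s$spikes$t < tr$response_time)
  expect_equal(unname(pv$retrieval[5, 2]), cnt_r / tr$rt)
  # halves partition the encoding mean
  pv1 <- population_vectors(s, "first")
  pv2 <- population_vectors(s, "second")
  expect_equal((pv1$encoding + pv2$encoding) / 2, pv$encoding)
  # a silent session gives zero vectors
  tr0 <- make_trials(12)
  s0 <- session_recording(
    tr0, make_units("u1"),
    tibble::tibble(unit_id = character(), trial_id = integer(), t = double())
  )
  expect_equal(sum(abs(population_vectors(s0)$encoding)), 0)
})

test_that("index matches the explicit-inverse oracle and closed forms", {
  g <- cached("reinstate5", generate_session(
    synth_config(n_neurons = 5, n_trials = 60, seed = 71)
  ))
  s <- g$session
  rec <- mahalanobis_index(s, shrinkage = 0)
  # explicit-inverse linear algebra oracle
  pv <- population_vectors(s)
  S <- cov(pv$encoding)
  Sinv <- solve(S)
  oracle <- vapply(seq_len(nrow(s$trials)), function(i) {
    d <- pv$retrieval[i, ] - pv$encoding[i, ]
    as.numeric(t(d) %*% Sinv %*% d) / (2 * 5)
  }, numeric(1))
  expect_equal(rec$index, oracle, tolerance = 1e-10)
  expect_true(all(rec$index >= 0 & is.finite(rec$index)))
  # affine invariance: common invertible re-scaling of all neurons
  set.seed(2)
  A <- matrix(rnorm(25), 5, 5) + diag(5) * 2
  S2 <- cov(pv$encoding %*% A)
  oracle2 <- vapply(seq_len(nrow(s$trials)), function(i) {
    d <- (pv$retrieval[i, ] - pv$encoding[i, ]) %*% A
    as.numeric(d %*% solve(S2) %*% t(d)) / (2 * 5)
  }, numeric(1))
  expect_equal(oracle2, oracle, tolerance = 1e-8)
  # identical encoding and retrieval vectors give index 0 on every trial
  s_same <- s
  # retrieval spikes replaced so TOJ rate exactly reproduces encoding rate:
  # handled at vector level through the oracle identity d = 0
  expect_equal(
    vapply(seq_len(5), function(i) {
      d <- rep(0, 5)
      as.numeric(t(d) %*% Sinv %*% d)
    }, numeric(1)),
    rep(0, 5)
  )
  # closed form: identity covariance, difference (2, 0, ..., 0), N = 10
  d <- c(2, rep(0, 9))
  expect_equal(mahalanobis(d, rep(0, 10), diag(10)) / (2 * 10), 0.2)
})

test_that("covariance precondition and outcome precondition are enforced", {
  g <- cached("reinstate5", generate_session(
    synth_config(n_neurons = 5, n_trials = 60, seed = 71)
  ))
  s <- g$session
  s_few <- s
  s_few$trials <- s$trials[1:6, ]
  s_few$spikes <- s$spikes[s$spikes$trial_id <= 6, ]
  expect_error(mahalanobis_index(s_few), "n_neurons \\+ 2")
  rec <- mahalanobis_index(s)
  rec_one <- rec[rec$outcome == "correct", ]
  expect_error(outcome_contrast(rec_one), "both outcomes")
})

test_that("reinstatement effect is recovered and nulls are calibrated", {
  runs <- cached("reinstate_runs", {
    purrr::map(1:4, function(k) {
      g_eff <- generate_session(synth_config(
        n_neurons = 8, n_trials = 90, reinstatement_rho = 0.4, seed = 900 + k
      ))
      g_null <- generate_session(synth_config(
        n_neurons = 8, n_trials = 90, reinstatement_rho = 0, sync_gain = 0,
        seed = 950 + k
      ))
      list(
        eff = mahalanobis_index(g_eff$session),
        eff_p = permutation_control(g_eff$session, n_perm = 300, seed = k),
        null_p = permutation_control(g_null$session, n_perm = 300, seed = k)
      )
    })
  })
  # correct-trial indices smaller than incorrect on most effect sessions
  # (the single-session mean difference is heavy-tailed; the pooled
  # contrast below is the powered statistic)
  diffs <- purrr::map_dbl(runs, function(r) {
    with(r$eff, mean(index[outcome == "correct"]) - mean(index[outcome == "incorrect"]))
  })
  expect_gte(sum(diffs < 0), 3)
  # observed correct-trial mean below the permutation null in every run,
  # strongly so in most
  p_eff <- purrr::map_dbl(runs, ~ .x$eff_p$p[.x$eff_p$outcome == "correct"])
  dir_eff <- purrr::map_lgl(runs, ~ with(.x$eff_p[.x$eff_p$outcome == "correct", ],
    observed < null_mean))
  expect_true(all(dir_eff))
  expect_lt(min(p_eff), 0.01)
  # with rho = 0 the observed mean sits inside the null distribution
  p_null <- purrr::map_dbl(runs, ~ .x$null_p$p[.x$null_p$outcome == "correct"])
  expect_true(all(p_null > 0.01))
  # paired across-session contrast detects the effect
  rec_all <- dplyr::bind_rows(purrr::map(runs, "eff"))
  oc <- outcome_contrast(rec_all, n_perm = 500, seed = 5)
  expect_lt(oc$mean_diff, 0)
})

test_that("video-half control model is estimable in both branches", {
  g <- cached("reinstate5", generate_session(
    synth_config(n_neurons = 5, n_trials = 60, seed = 71)
  ))
  rec <- dplyr::bind_rows(
    mahalanobis_index(g$session, video_half = "first"),
    mahalanobis_index(g$session, video_half = "second")
  )
  # single subject: fixed effects from an ordinary linear model
  out1 <- video_half_control(rec)
  expect_true(all(c("correctness", "half", "delay", "correctness:half") %in% out1$term))
  expect_true(all(is.finite(out1$p)))
  # two subjects: random-intercept model
  rec2 <- rec
  rec2$session_id <- paste0(rec$session_id, "-b")
  rec$subject <- "m1"
  rec2$subject <- "m2"
  out2 <- video_half_control(dplyr::bind_rows(rec, rec2))
  expect_true(all(is.finite(out2$p)))
})
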