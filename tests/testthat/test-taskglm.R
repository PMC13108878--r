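# Poisson GLM design construction, fitting, pseudo-R2, stepwise selection,
# RT slopes, eye-control classification.

test_that("TOJ decomposition windows have the right arithmetic", {
  tr <- make_trials(2, rt = c(1.0, 0.3))
  s <- session_recording(tr, make_units("u1"), make_spikes(tr, "u1"))
  expect_warning(d <- build_design(s, "u1", decompose_toj = TRUE), "0.4")
  w1 <- d[d$trial_id == 1 & d$epoch %in% c("toj_vis", "toj_mem", "toj_mot"), ]
  expect_equal(w1$exposure, c(0.2, 0.6, 0.2))
  # short trial loses its retrieval window
  w2 <- d[d$trial_id == 2 & d$epoch %in% c("toj_vis", "toj_mem", "toj_mot"), ]
  expect_false("toj_mem" %in% w2$epoch)
})

test_that("epoch indicators are exclusive and exposures positive", {
  s <- std_session()$session
  d <- build_design(s, s$units$unit_id[1])
  ind <- as.matrix(d[, c("encoding", "delay", "toj", "feedback", "iti")])
  expect_true(all(rowSums(ind) <= 1))
  expect_true(all(d$exposure > 0))
  expect_true(all(d$y >= 0 & d$y == round(d$y)))
})

test_that("Poisson GLM honours the closed form and the offset contract", {
  d <- tibble::tibble(
    trial_id = 1:3, epoch = "encoding", y = c(3L, 5L, 4L), exposure = 1,
    encoding = 0, toj = 0
  )
  f <- fit_poisson_glm(d)
  expect_equal(unname(f$coefficients["(Intercept)"]), log(4), tolerance = 1e-8)
  # doubling exposure and counts together leaves coefficients unchanged
  d2 <- d
  d2$exposure <- 2
  d2$y <- d$y * 2L
  f2 <- fit_poisson_glm(d2)
  expect_equal(f2$coefficients, f$coefficients, tolerance = 1e-8)
})

test_that("GLM recovers known epoch effects", {
  reps <- cached("glm_recovery", {
    g <- generate_session(synth_config(
      n_neurons = 1, n_trials = 300, frac_tcc = 0, frac_toj = 0, seed = 55
    ))
    d0 <- build_design(g$session, "u01")
    purrr::map(1:5, function(k) {
      d <- d0
      eta <- log(5) + 0.5 * d$encoding + 0.7 * d$toj + log(d$exposure)
      d$y <- with_seed(100 + k, rpois(nrow(d), exp(eta)))
      fit_poisson_glm(d, c("encoding", "toj"))$coefficients
    })
  })
  enc <- purrr::map_dbl(reps, "encoding")
  toj <- purrr::map_dbl(reps, "toj")
  expect_true(all(abs(enc - 0.5) < 0.15))
  expect_true(all(abs(toj - 0.7) < 0.15))
})

test_that("pseudo-R2 follows the McFadden definitions", {
  expect_equal(pseudo_r2(-100, -100, 0)$pseudo_r2, 0)
  r <- pseudo_r2(-80, -100, 3)
  expect_equal(r$pseudo_r2, 1 - 80 / 100)
  expect_equal(r$adj_pseudo_r2, 1 - (-80 - 3) / -100)
  expect_error(pseudo_r2(-80, 0), "zero")
  # hand computation on a 5-row example
  d <- tibble::tibble(
    trial_id = 1:5, epoch = "x", y = c(0L, 1L, 3L, 6L, 8L), exposure = 1,
    dose = c(0, 0.25, 0.5, 0.75, 1)
  )
  full <- fit_poisson_glm(d, "dose")
  null <- fit_poisson_glm(d)
  ll <- function(lambda) sum(dpois(d$y, lambda, log = TRUE))
  ll_null_hand <- ll(mean(d$y))
  expect_equal(null$loglik, ll_null_hand, tolerance = 1e-8)
  r2 <- pseudo_r2(full$loglik, null$loglik, 1)
  expect_equal(r2$pseudo_r2, 1 - full$loglik / ll_null_hand, tolerance = 1e-10)
})

test_that("stepwise selection finds real effects and ignores noise", {
  runs <- cached("stepwise_runs", {
    base <- generate_session(synth_config(
      n_neurons = 1, n_trials = 250, frac_tcc = 0, frac_toj = 0, seed = 77
    ))
    d0 <- build_design(base$session, "u01")
    list(
      # pure-noise units: counts independent of every regressor
      noise = purrr::map(1:5, function(k) {
        d <- d0
        d$y <- with_seed(200 + k, rpois(nrow(d), 6 * d$exposure))
        stepwise_select(d)
      }),
      # TOJ-modulated unit
      toj = purrr::map(1:5, function(k) {
        d <- d0
        eta <- log(6) + log(1.5) * d$toj + log(d$exposure)
        d$y <- with_seed(300 + k, rpois(nrow(d), exp(eta)))
        stepwise_select(d)
      }),
      # encoding-only unit
      enc = purrr::map(1:5, function(k) {
        d <- d0
        eta <- log(6) + 0.5 * d$encoding + log(d$exposure)
        d$y <- with_seed(400 + k, rpois(nrow(d), exp(eta)))
        stepwise_select(d)
      })
    )
  })
  n_noise_hits <- sum(purrr::map_int(runs$noise, ~ length(.x$retained_terms[[1]])) > 0)
  expect_lte(n_noise_hits, 1)
  expect_true(all(purrr::map_lgl(runs$toj, "is_toj_cell")))
  enc_ok <- purrr::map_lgl(runs$enc, function(r) {
    "encoding" %in% r$retained_terms[[1]] &&
      !any(c("toj", "toj_vis", "toj_mem", "toj_mot") %in% r$retained_terms[[1]])
  })
  expect_true(all(enc_ok))
})

test_that("stepwise selection is invariant to candidate ordering", {
  g <- std_session()
  d <- build_design(g$session, g$session$units$unit_id[1])
  cand <- intersect(
    c("encoding", "delay", "toj", "feedback", "iti", "block", "rt",
      "outcome", "condition", "side"),
    names(d)
  )
  ref <- stepwise_select(d, candidates = cand)
  for (k in 1:5) {
    shuf <- with_seed(k, sample(cand))
    out <- stepwise_select(d, candidates = shuf)
    expect_setequal(out$retained_terms[[1]], ref$retained_terms[[1]])
  }
  # adjusted criterion never falls below the null model's
  expect_gte(ref$adj_pseudo_r2, 0)
})

test_that("RT slopes are standardized correlations with outcome split", {
  # exact anticorrelation: rate = 10 - rt by construction
  rts <- c(1, 2, 4, 5, 1, 2, 4, 5, 3, 6)
  outc <- rep(c("correct", "incorrect"), each = 5)
  tr <- make_trials(10, rt = rts, outcome = outc)
  counts <- round(rts * (10 - rts) * 4) # rate = count / rt ~ 10 - rt, up to rounding
  sp <- purrr::map_dfr(1:10, function(i) {
    n <- counts[i]
    tibble::tibble(
      unit_id = "u1", trial_id = i,
      t = tr$probe_on[i] + (seq_len(n) - 0.5) / n * rts[i]
    )
  })
  s <- session_recording(tr, make_units("u1"), sp)
  sl <- rt_rate_slopes(s, "u1")
  expect_equal(nrow(sl), 2)
  expect_lt(sl$slope[sl$outcome == "correct"], -0.97)
  expect_lt(sl$slope[sl$outcome == "incorrect"], -0.97)

  # independent rate and RT: slope near zero
  g <- cached("rt_null", generate_session(synth_config(
    n_neurons = 1, n_trials = 1000, frac_tcc = 0, frac_toj = 0, seed = 88
  )))
  sl0 <- rt_rate_slopes(g$session, "u01")
  expect_true(all(abs(sl0$slope) < 0.1))
})

test_that("eye-control classification strips oculomotor-confounded units", {
  expect_true(eye_control_classify(tibble::tibble(
    unit_id = "a", is_toj_cell = TRUE, eye_terms_retained = list(character(0))
  ))$strict_toj_cell)
  expect_false(eye_control_classify(tibble::tibble(
    unit_id = "a", is_toj_cell = TRUE, eye_terms_retained = list("fixation_dur")
  ))$strict_toj_cell)

  # injected confound: unit driven by saccade frequency loses strict status
  hits <- cached("eye_confound", {
    purrr::map_lgl(1:3, function(k) {
      g <- generate_session(synth_config(
        n_neurons = 2, n_trials = 200, frac_tcc = 0, frac_toj = 1,
        toj_gain = 1.5, seed = 500 + k
      ))
      s <- generate_eye_session(g$session, coupling = 0.8,
        coupled_unit = "u01", seed = k
      )
      res <- classify_toj_cells(s, units = "u01", eye = TRUE)
      isTRUE(res$strict_toj_cell[1])
    })
  })
  expect_lte(sum(hits), 1)
})

test_that("the behavioural mixed-model contract is estimable", {
  tr1 <- std_session()$session$trials
  tr1$subject <- "m1"
  f1 <- rt_mixed_model(tr1)
  expect_s3_class(f1, "lm")
  tr2 <- tr1
  tr2$subject <- "m2"
  f2 <- rt_mixed_model(dplyr::bind_rows(tr1, tr2))
  expect_s4_class(f2, "lmerModLmerTest")
  expect_true(all(c("conditionimmediate", "outcomeincorrect") %in%
    rownames(summary(f2)$coefficients) |
    c("conditiondelayed", "outcomeincorrect") %in%
      rownames(summary(f2)$coefficients)))
})
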