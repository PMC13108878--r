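# Nested rate-model fitting, likelihood-ratio tests, relaxation time,
# temporal-context-cell classification.

const_trains <- function(rate = 10, n_trials = 120, seed = 3) {
  with_seed(seed, {
    lapply(seq_len(n_trials), function(i) {
      generate_spike_train(function(t) rep(rate, length(t)), 8, rate_max = rate + 0.5)
    })
  })
}

exg_trains <- function(a0 = 5, a1 = 8, mu = 0.3, sigma = 0.15, tau = 2,
                       n_trials = 180, seed = 4) {
  rate_fn <- function(t) a0 + a1 * exgauss_shape(t, mu, sigma, tau)
  with_seed(seed, {
    lapply(seq_len(n_trials), function(i) {
      generate_spike_train(rate_fn, 8, rate_max = a0 + max(a1, 0) + 0.5)
    })
  })
}

test_that("constant-model MLE recovers the mean rate", {
  fit <- fit_rate_model(const_trains(10), "constant")
  expect_equal(fit$model_kind, "constant")
  expect_gt(fit$pars[["a0"]], 9)
  expect_lt(fit$pars[["a0"]], 11)
  expect_false(fit$degenerate)
  # all-empty trains degrade to a flagged zero-rate constant fit
  f0 <- fit_rate_model(list(numeric(0), numeric(0)), "constant")
  expect_equal(f0$pars[["a0"]], 0)
  expect_true(f0$degenerate)
})

test_that("ex-Gaussian fit recovers tau and latency", {
  fits <- cached("exg_recovery", {
    trains <- exg_trains(a0 = 5, a1 = 8, mu = 0.3, sigma = 0.15, tau = 2)
    fe <- fit_rate_model(trains, "exgauss", seed = 10)
    fg <- fit_rate_model(trains, "gaussian", seed = 10)
    fc <- fit_rate_model(trains, "constant")
    list(fc = fc, fg = fg, fe = fe)
  })
  expect_lt(abs(fits$fe$pars[["tau"]] - 2) / 2, 0.25)
  expect_lt(fits$fe$pars[["mu"]], 1)
  expect_lt(abs(fits$fe$pars[["a0"]] - 5), 1)
  # nesting of maximized log-likelihoods
  expect_lte(fits$fc$loglik, fits$fg$loglik + 1e-6)
  expect_lte(fits$fg$loglik, fits$fe$loglik + 1e-6)
})

test_that("likelihood ratio test follows the chi-squared contract", {
  f1 <- fit_rate_model(const_trains(8, 30, seed = 5), "constant")
  f2 <- fit_rate_model(const_trains(8, 30, seed = 5), "exgauss", seed = 2)
  # identical logliks -> p = 1
  fa <- f1
  fb <- f2
  fb$loglik <- f1$loglik
  expect_equal(lrt(fa, fb), 1)
  # 2 * delta-loglik = 3.841 at df 1 -> p ~ 0.05
  fg <- fit_rate_model(const_trains(8, 30, seed = 5), "gaussian", seed = 2)
  fb2 <- f2
  fb2$loglik <- fg$loglik + 3.841 / 2
  expect_equal(lrt(fg, fb2), 0.05, tolerance = 1e-3)
  # optimizer failure guard
  fb3 <- f2
  fb3$loglik <- f1$loglik - 1
  expect_error(lrt(f1, fb3), "optimizer failure")
})

test_that("relaxation time matches analytic and dense-grid references", {
  mk <- function(mu, sigma, tau) {
    structure(
      list(model_kind = "exgauss", pars = c(a0 = 5, a1 = 8, mu = mu, sigma = sigma, tau = tau)),
      class = "rate_model_fit"
    )
  }
  # sigma -> 0: pure exponential decay, relaxation time = tau
  expect_equal(relaxation_time(mk(0.3, 0.01, 2))$relaxation_time, 2, tolerance = 0.01)
  # dense-grid oracle at 1-ms resolution
  fit <- mk(0.3, 0.2, 5)
  grid <- seq(0, 25, by = 0.001)
  shape <- exgauss_shape(grid, 0.3, 0.2, 5)
  t_peak <- grid[which.max(shape)]
  t_cross <- grid[grid > t_peak][which(shape[grid > t_peak] <= exp(-1))[1]]
  expect_equal(
    relaxation_time(fit)$relaxation_time, t_cross - t_peak,
    tolerance = 2e-3
  )
  # decreasing units mirror their increasing twin
  dec <- mk(0.3, 0.2, 5)
  dec$pars[["a1"]] <- -8
  expect_equal(
    relaxation_time(dec)$relaxation_time,
    relaxation_time(fit)$relaxation_time
  )
  # curves that never decay within 20 s are censored
  slow <- mk(0.3, 0.2, 20)
  rx <- relaxation_time(slow)
  expect_true(rx$censored || rx$relaxation_time <= 20)
})

test_that("classification applies all three selection criteria", {
  # constant unit: not a temporal context cell
  res_const <- cached("classify_const", {
    tr <- make_trials(1)
    tr$trial_id <- 1L
    trains <- const_trains(10, 120, seed = 6)
    sp <- purrr::map_dfr(seq_along(trains), function(i) {
      tibble::tibble(unit_id = "c1", trial_id = i, t = trains[[i]] + 1)
    })
    trs <- make_trials(length(trains))
    s <- session_recording(trs, make_units("c1"), sp)
    fit_temporal_context(s, seed = 2)
  })
  expect_false(res_const$is_tcc[1])

  # strong ex-Gaussian unit: detected, with direction and latency
  res_exg <- cached("classify_exg", {
    trains <- exg_trains(a0 = 5, a1 = 8, mu = 0.3, sigma = 0.15, tau = 2)
    sp <- purrr::map_dfr(seq_along(trains), function(i) {
      tibble::tibble(unit_id = "e1", trial_id = i, t = trains[[i]] + 1)
    })
    trs <- make_trials(length(trains))
    s <- session_recording(trs, make_units("e1"), sp)
    fit_temporal_context(s, seed = 2)
  })
  expect_true(res_exg$is_tcc[1])
  expect_equal(res_exg$direction[1], "increase")
  expect_lt(res_exg$latency[1], 1)
  expect_lt(abs(res_exg$relaxation_time[1] - 2), 1)

  # a unit peaking at 3.5 Hz fails the 4-Hz criterion even if well fit
  res_dim <- cached("classify_dim", {
    trains <- exg_trains(a0 = 1, a1 = 2.5, mu = 0.3, sigma = 0.15, tau = 2, seed = 8)
    sp <- purrr::map_dfr(seq_along(trains), function(i) {
      tibble::tibble(unit_id = "d1", trial_id = i, t = trains[[i]] + 1)
    })
    trs <- make_trials(length(trains))
    s <- session_recording(trs, make_units("d1"), sp)
    fit_temporal_context(s, seed = 2)
  })
  expect_false(res_dim$is_tcc[1])
  expect_lt(res_dim$peak_rate[1], 4)
})

test_that("population heatmap is normalized and sorted by relaxation time", {
  g <- cached("psth_session", generate_session(
    synth_config(n_neurons = 3, n_trials = 300, frac_tcc = 1, frac_decreasing = 0,
                 pattern_sd = 0, seed = 15)
  ))
  res <- cached("psth_tcc", fit_temporal_context(g$session, seed = 3))
  psth <- encoding_psth(g$session)
  hm <- population_heatmap(res, psth, tcc_only = FALSE)
  expect_equal(unname(apply(hm, 1, min)), rep(0, nrow(hm)))
  expect_equal(unname(apply(hm, 1, max)), rep(1, nrow(hm)))
  # row order tracks the true relaxation-time order for well-separated taus
  truth_order <- order(g$truth$units$tau)
  fit_order <- match(rownames(hm), g$truth$units$unit_id)
  if (min(diff(sort(g$truth$units$tau))) > 1) {
    expect_equal(fit_order, truth_order)
  }
  expect_error(population_heatmap(res[0, ], psth), "at least one unit")
})
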