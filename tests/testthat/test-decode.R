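# Population binning, LDA time decoding, permutation null, truncation scan,
# representational similarity.

noise_tensor <- function(n_trials = 100, n_bins = 32, n_neurons = 8, seed = 7) {
  with_seed(seed, {
    structure(
      list(
        rates = array(rnorm(n_trials * n_bins * n_neurons, 10, 2),
          dim = c(n_trials, n_bins, n_neurons)
        ),
        bin_width = 0.25,
        bin_centers = seq(0.125, 8, by = 0.25),
        trials = tibble::tibble(
          trial_id = seq_len(n_trials),
          condition = rep(c("immediate", "delayed"), length.out = n_trials),
          outcome = "correct"
        ),
        units = paste0("u", seq_len(n_neurons))
      ),
      class = "population_tensor"
    )
  })
}

# separable tensor: per-bin means far apart, tiny noise
separable_tensor <- function(n_trials = 40, n_bins = 8, n_neurons = 5, seed = 3) {
  with_seed(seed, {
    base <- matrix(rnorm(n_bins * n_neurons, 0, 1) * 10, n_bins, n_neurons)
    rates <- array(0, dim = c(n_trials, n_bins, n_neurons))
    for (i in seq_len(n_trials)) rates[i, , ] <- base + rnorm(n_bins * n_neurons, 0, 0.01)
    structure(
      list(
        rates = rates, bin_width = 0.25,
        bin_centers = (seq_len(n_bins) - 0.5) * 0.25,
        trials = tibble::tibble(
          trial_id = seq_len(n_trials),
          condition = rep(c("immediate", "delayed"), length.out = n_trials),
          outcome = "correct"
        ),
        units = paste0("u", seq_len(n_neurons))
      ),
      class = "population_tensor"
    )
  })
}

test_that("binning respects half-open bin edges and conserves spikes", {
  tr <- make_trials(1)
  sp <- tibble::tibble(unit_id = "u1", trial_id = 1L, t = 1 + c(0.1, 0.35))
  s <- session_recording(tr, make_units("u1"), sp)
  tn <- bin_activity(s)
  expect_equal(dim(tn$rates), c(1, 32, 1))
  expect_equal(tn$rates[1, 1, 1], 4) # 1 spike / 0.25 s
  expect_equal(tn$rates[1, 2, 1], 4)
  expect_equal(sum(tn$rates[1, , 1]) * 0.25, 2)
  # empty trains give a zero tensor
  s0 <- session_recording(
    tr, make_units("u1"),
    tibble::tibble(unit_id = character(), trial_id = integer(), t = double())
  )
  expect_equal(sum(bin_activity(s0)$rates), 0)
})

test_that("a noiseless separable population decodes perfectly", {
  tn <- separable_tensor()
  res <- decode_time(tn, seed = 1)
  expect_equal(res$mae, 0)
  # posterior concentrated on the diagonal
  expect_equal(max.col(res$posterior), seq_len(nrow(res$posterior)))
  expect_equal(unname(rowSums(res$posterior)), rep(1, nrow(res$posterior)),
    tolerance = 1e-9
  )
  # minimum attainable permutation p
  pn <- permutation_null(tn, res, n_perm = 1000, seed = 1)
  expect_equal(pn$p, 1 / 1001)
})

test_that("decoding is invariant to neuron order and seed-reproducible", {
  tn <- noise_tensor(60, 16, 6, seed = 5)
  res1 <- decode_time(tn, seed = 9)
  perm <- sample(seq_len(dim(tn$rates)[3]))
  tn2 <- tn
  tn2$rates <- tn$rates[, , perm, drop = FALSE]
  res2 <- decode_time(tn2, seed = 9)
  expect_equal(res2$mae, res1$mae)
  res3 <- decode_time(tn, seed = 9)
  expect_identical(res3$samples, res1$samples)
  expect_identical(res3$mae, res1$mae)
})

test_that("pure-noise decoding sits inside the permutation null band", {
  tn <- noise_tensor(100, 32, 8, seed = 7)
  res <- decode_time(tn, seed = 2)
  pn <- permutation_null(tn, res, n_perm = 500, seed = 2)
  expect_gt(pn$p, 0.01)
  band <- quantile(pn$null_maes, c(0.005, 0.995))
  expect_gt(res$mae, band[1] - 0.1)
  expect_lt(res$mae, band[2] + 0.1)
})

test_that("chance error follows the closed form", {
  expect_equal(chance_mae(32, 0.25), (32^2 - 1) / (3 * 32) * 0.25)
  expect_equal(chance_mae(32, 0.25), 2.6640625)
  expect_equal(chance_mae(8, 0.25), 0.65625)
})

test_that("refit-mode permutation null destroys decodability", {
  tn <- separable_tensor(n_trials = 30, n_bins = 8)
  res <- decode_time(tn, seed = 4)
  pn <- permutation_null(tn, res, n_perm = 30, mode = "refit", seed = 4)
  expect_gt(mean(pn$null_maes), 0.4) # far above the observed mae of 0
  expect_equal(pn$p, 1 / 31)
})

test_that("early-bin exclusion reduces to the full decode at drop 0", {
  tn <- separable_tensor(n_trials = 30, n_bins = 32)
  scan <- early_bin_exclusion(tn, drop_seconds = c(0, 6), n_perm = 0, seed = 8)
  full <- decode_time(tn, seed = substream_seed(8, "trunc0"))
  expect_equal(scan$mae[1], full$mae)
  expect_equal(scan$n_bins, c(32, 8))
  expect_equal(scan$chance[2], 0.65625)
  expect_error(early_bin_exclusion(tn, drop_seconds = 7.5), "4 bins")
})

test_that("representational similarity is a correlation matrix with drift", {
  g <- cached("psth_session", generate_session(
    synth_config(n_neurons = 3, n_trials = 300, frac_tcc = 1, frac_decreasing = 0,
                 pattern_sd = 0, seed = 15)
  ))
  m <- rsa_matrix(bin_activity(g$session))
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_equal(unname(diag(m)), rep(1, 32))
  # drift: mean correlation decreases over the first few separation lags
  lag_mean <- vapply(0:5, function(k) {
    mean(m[cbind(seq_len(32 - k), seq_len(32 - k) + k)])
  }, numeric(1))
  expect_true(all(diff(lag_mean[1:4]) < 0))
  # duplicated bins correlate exactly
  tn <- separable_tensor(n_bins = 8)
  tn$rates[, 2, ] <- tn$rates[, 1, ]
  m2 <- rsa_matrix(tn)
  expect_equal(m2[1, 2], 1, tolerance = 1e-6)
})

test_that("decoding-behaviour correlation has the expected endpoints", {
  df <- tibble::tibble(decoding = 1:6 / 10, accuracy = 1:6 / 10)
  out <- decoding_behavior_correlation(df)
  expect_equal(out$r, 1)
  expect_error(decoding_behavior_correlation(df[1:3, ]), "5 sessions")
  set.seed(3)
  null <- decoding_behavior_correlation(tibble::tibble(
    decoding = rnorm(63), accuracy = rnorm(63)
  ))
  expect_lt(abs(null$r), 0.3)
})
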