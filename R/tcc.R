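# Temporal context cell identification: maximum-likelihood fits of three
# nested firing-rate models (constant, Gaussian, ex-Gaussian) to encoding-
# period spiking, likelihood-ratio model comparison, and relaxation-time
# estimation from the fitted curve.

MODEL_NPARAMS <- c(constant = 1L, gaussian = 4L, exgauss = 5L)

#' Fit a firing-rate model to encoding spiking
#'
#' Maximizes the Poisson likelihood of 50-ms binned, trial-summed spike
#' counts under a parametric rate curve. The constant model has the
#' closed-form solution (mean rate); the Gaussian and ex-Gaussian models
#' are fit by bounded quasi-Newton optimization from multiple starts,
#' always including a start at the best nested solution so the nesting
#' inequality of the log-likelihoods holds.
#'
#' @param spike_trains List of per-trial spike-time vectors, seconds
#'   relative to encoding onset.
#' @param model_kind `"constant"`, `"gaussian"`, or `"exgauss"`.
#' @param window Encoding window `c(t0, t1)`, default `c(0, 8)`.
#' @param bin_width Count bin width, s (default 0.05).
#' @param n_starts Random multi-starts for the nonlinear models (10).
#' @param seed Seed for the random starts.
#' @param init Optional named parameter vector used as an extra start
#'   (e.g. the nested model's solution).
#' @return A `rate_model_fit` list: `model_kind`, `pars` (a0, a1, mu,
#'   sigma, tau as applicable), `loglik` (nats), `n_params`, `n_trials`,
#'   `degenerate` flag, plus the binned data.
#' @export
fit_rate_model <- function(spike_trains, model_kind,
                           window = c(0, 8), bin_width = 0.05,
                           n_starts = 10, seed = 1L, init = NULL) {
  n_trials <- length(spike_trains)
  if (n_trials < 1) abort("fit_rate_model needs at least one trial")
  breaks <- seq(window[1], window[2], by = bin_width)
  centers <- breaks[-length(breaks)] + bin_width / 2
  all_spikes <- unlist(spike_trains, use.names = FALSE)
  all_spikes <- all_spikes[all_spikes >= window[1] & all_spikes < window[2]]
  y <- if (length(all_spikes) > 0) {
    tabulate(findInterval(all_spikes, breaks, rightmost.closed = FALSE),
      nbins = length(centers)
    )
  } else {
    integer(length(centers))
  }
  exposure <- bin_width * n_trials # rate (Hz) -> expected count per bin

  nll <- function(pars) {
    rate <- pmax(rate_curve(model_kind, as.list(pars))(centers), 1e-8)
    -sum(stats::dpois(y, rate * exposure, log = TRUE))
  }

  if (model_kind == "constant") {
    a0 <- sum(y) / (n_trials * (window[2] - window[1]))
    pars <- c(a0 = a0)
    return(new_rate_model_fit(
      model_kind, pars,
      loglik = -nll(pars), n_trials = n_trials,
      degenerate = sum(y) == 0, y = y, centers = centers, exposure = exposure
    ))
  }

  a0_hat <- max(sum(y) / (n_trials * (window[2] - window[1])), 1e-3)
  # crude data-driven start: location/sign of the largest smoothed deviation
  sm <- as.numeric(stats::filter(y, rep(1 / 9, 9), sides = 2, circular = TRUE))
  dev <- sm / exposure - a0_hat
  i_pk <- which.max(abs(dev[centers <= 2.5]))
  mu0 <- min(max(centers[i_pk], 0.05), 1.95)
  amp0 <- dev[i_pk]

  if (model_kind == "gaussian") {
    lower <- c(a0 = 1e-6, a1 = -100, mu = 0, sigma = 0.01)
    upper <- c(a0 = 200, a1 = 100, mu = 2, sigma = 2)
    starts <- list(
      c(a0 = a0_hat, a1 = amp0, mu = mu0, sigma = 0.3),
      c(a0 = a0_hat, a1 = 0, mu = 0.5, sigma = 0.3)
    )
  } else {
    lower <- c(a0 = 1e-6, a1 = -100, mu = 0, sigma = 0.01, tau = 0)
    upper <- c(a0 = 200, a1 = 100, mu = 2, sigma = 2, tau = 20)
    starts <- list(
      c(a0 = a0_hat, a1 = amp0, mu = mu0, sigma = 0.2, tau = 1),
      c(a0 = a0_hat, a1 = amp0, mu = mu0, sigma = 0.2, tau = 8)
    )
  }
  if (!is.null(init)) {
    starts <- c(starts, list(pmin(pmax(init[names(lower)], lower), upper)))
  }
  rand_starts <- with_seed(substream_seed(seed, paste0("fit-", model_kind)), {
    lapply(seq_len(n_starts), function(i) {
      s <- lower + runif(length(lower)) * (pmin(upper, c(4 * a0_hat + 5, rep(Inf, length(lower) - 1))) - lower)
      s[["a0"]] <- a0_hat * exp(rnorm(1, 0, 0.2))
      s[["a1"]] <- rnorm(1, amp0, max(abs(amp0), 2))
      if (model_kind == "exgauss") s[["tau"]] <- exp(runif(1, log(0.02), log(20)))
      pmin(pmax(s, lower), upper)
    })
  })
  starts <- c(starts, rand_starts)

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, nll,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(maxit = 300)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort(sprintf("%s fit failed to converge from any start", model_kind))
  new_rate_model_fit(
    model_kind, best$par,
    loglik = -best$value, n_trials = n_trials,
    degenerate = sum(y) == 0, y = y, centers = centers, exposure = exposure
  )
}

new_rate_model_fit <- function(model_kind, pars, loglik, n_trials, degenerate,
                               y, centers, exposure) {
  structure(
    list(
      model_kind = model_kind,
      pars = pars,
      loglik = loglik,
      n_params = MODEL_NPARAMS[[model_kind]],
      n_trials = n_trials,
      degenerate = degenerate,
      data = list(y = y, centers = centers, exposure = exposure)
    ),
    class = "rate_model_fit"
  )
}

#' @export
print.rate_model_fit <- function(x, ...) {
  cat(sprintf(
    "<rate_model_fit %s: loglik %.2f, %s>\n", x$model_kind, x$loglik,
    paste(sprintf("%s=%.3g", names(x$pars), x$pars), collapse = ", ")
  ))
  invisible(x)
}

#' Likelihood ratio test between nested rate models
#'
#' Chi-squared test on `2 * (loglik_full - loglik_nested)` with degrees of
#' freedom equal to the parameter-count difference. The statistic is
#' clipped below at zero; a full-model log-likelihood more than 1e-6 below
#' the nested one indicates an optimizer failure and aborts.
#'
#' @param nested,full `rate_model_fit` objects on the same data.
#' @return The p-value.
#' @export
lrt <- function(nested, full) {
  stopifnot(nested$n_params < full$n_params)
  if (full$loglik < nested$loglik - 1e-6) {
    abort("full model log-likelihood below nested model: optimizer failure")
  }
  stat <- max(2 * (full$loglik - nested$loglik), 0)
  pchisq(stat, df = full$n_params - nested$n_params, lower.tail = FALSE)
}

#' Relaxation time of a fitted ex-Gaussian rate curve
#'
#' Interval from peak firing to 63% (`1 - 1/e`) return toward baseline: the
#' first time after the curve's extremum at which the absolute deviation
#' from baseline `a0` has fallen to `1/e` of its peak value. Found by root
#' bisection on the closed-form curve. For a pure exponential decay
#' (`sigma -> 0`) this equals `tau` exactly. Curves that have not decayed
#' within 20 s are censored at 20 s.
#'
#' @param fit An ex-Gaussian `rate_model_fit`.
#' @return List with `relaxation_time` (s), `peak_time` (s), `censored`.
#' @export
relaxation_time <- function(fit) {
  stopifnot(fit$model_kind == "exgauss")
  p <- as.list(fit$pars)
  t_peak <- exgauss_peak_time(p$mu, p$sigma, p$tau)
  # deviation from baseline is |a1| * shape; shape is unimodal with peak 1
  f <- function(t) exgauss_shape(t, p$mu, p$sigma, p$tau) - exp(-1)
  horizon <- t_peak + 20
  if (f(horizon) > 0) {
    return(list(relaxation_time = 20, peak_time = t_peak, censored = TRUE))
  }
  root <- uniroot(f, lower = t_peak, upper = horizon, tol = 1e-6)$root
  list(relaxation_time = root - t_peak, peak_time = t_peak, censored = FALSE)
}

#' Identify temporal context cells in a session
#'
#' Fits the three nested rate models to each unit's encoding-period
#' activity and applies the selection criteria: the ex-Gaussian model must
#' beat both the Gaussian (df 1) and the constant (df 4) model at the 0.05
#' level by likelihood ratio test, the fitted curve must change rate by at
#' least 2 Hz from baseline, and it must reach at least 4 Hz. Latency,
#' relaxation time and fitted parameters are reported for every unit.
#'
#' @param session A [session_recording()].
#' @param units Unit ids to fit (default all).
#' @param alpha LRT significance level (0.05).
#' @param min_rate_change Minimum fitted rate change, Hz (2).
#' @param min_peak_rate Minimum fitted peak rate, Hz (4).
#' @param bin_width Count bin width, s (0.05).
#' @param n_starts Multi-starts per nonlinear model (10).
#' @param seed Seed for the random starts.
#' @return Tibble with one row per unit: fitted parameters, per-model
#'   log-likelihoods, `p_vs_gaussian`, `p_vs_constant`, `is_tcc`,
#'   `direction`, `latency`, `relaxation_time`, `censored`, `peak_rate`,
#'   `rate_change`.
#' @export
fit_temporal_context <- function(session, units = session$units$unit_id,
                                 alpha = 0.05, min_rate_change = 2,
                                 min_peak_rate = 4, bin_width = 0.05,
                                 n_starts = 10, seed = 1L) {
  trials <- session$trials
  win <- cbind(trials$video_on, trials$video_off)
  enc_dur <- trials$video_off[1] - trials$video_on[1]
  trains <- spike_trains_in_window(session, units, trials, win)
  purrr::map_dfr(seq_along(units), function(ui) {
    st <- trains[[ui]]
    f_const <- fit_rate_model(st, "constant", window = c(0, enc_dur), bin_width = bin_width)
    f_gauss <- fit_rate_model(st, "gaussian",
      window = c(0, enc_dur), bin_width = bin_width,
      n_starts = n_starts, seed = substream_seed(seed, paste0("g-", units[ui])),
      init = c(f_const$pars, a1 = 0, mu = 0.5, sigma = 0.3)
    )
    # seed the ex-Gaussian search at the Gaussian solution (its tau -> 0
    # limit) so the nesting inequality holds up to optimizer tolerance
    g <- as.list(f_gauss$pars)
    init_exg <- c(a0 = g$a0, a1 = g$a1, mu = g$mu, sigma = g$sigma, tau = 0)
    f_exg <- fit_rate_model(st, "exgauss",
      window = c(0, enc_dur), bin_width = bin_width,
      n_starts = n_starts, seed = substream_seed(seed, paste0("e-", units[ui])),
      init = init_exg
    )
    classify_tcc(units[ui], f_const, f_gauss, f_exg,
      alpha = alpha, min_rate_change = min_rate_change,
      min_peak_rate = min_peak_rate, enc_dur = enc_dur
    )
  })
}

#' Classify one unit from its three nested fits
#'
#' Applies the temporal-context-cell criteria to fitted models; see
#' [fit_temporal_context()] for the rule. The 2-Hz and 4-Hz criteria are
#' evaluated on the fitted ex-Gaussian curve rather than raw histogram
#' bins.
#'
#' @param unit_id Unit identifier.
#' @param f_const,f_gauss,f_exg The three `rate_model_fit`s.
#' @param alpha,min_rate_change,min_peak_rate Selection thresholds.
#' @param enc_dur Encoding duration, s.
#' @return One-row tibble (see [fit_temporal_context()]).
#' @export
classify_tcc <- function(unit_id, f_const, f_gauss, f_exg, alpha = 0.05,
                         min_rate_change = 2, min_peak_rate = 4, enc_dur = 8) {
  p_vs_g <- lrt(f_gauss, f_exg)
  p_vs_c <- lrt(f_const, f_exg)
  p <- as.list(f_exg$pars)
  grid <- seq(0, enc_dur, by = 0.01)
  curve <- rate_curve("exgauss", p)(grid)
  peak_rate <- max(curve)
  rate_change <- max(abs(curve - p$a0))
  rx <- relaxation_time(f_exg)
  is_tcc <- !f_exg$degenerate && p_vs_g < alpha && p_vs_c < alpha &&
    rate_change >= min_rate_change && peak_rate >= min_peak_rate
  tibble(
    unit_id = unit_id,
    a0 = p$a0, a1 = p$a1, mu = p$mu, sigma = p$sigma, tau = p$tau,
    loglik_constant = f_const$loglik,
    loglik_gaussian = f_gauss$loglik,
    loglik_exgauss = f_exg$loglik,
    p_vs_gaussian = p_vs_g,
    p_vs_constant = p_vs_c,
    is_tcc = is_tcc,
    direction = ifelse(p$a1 >= 0, "increase", "decrease"),
    latency = p$mu,
    relaxation_time = rx$relaxation_time,
    censored = rx$censored,
    peak_rate = peak_rate,
    rate_change = rate_change,
    degenerate = f_exg$degenerate
  )
}

#' Encoding-period population PSTH
#'
#' Trial-averaged firing rate of each unit over the encoding period.
#'
#' @param session A [session_recording()].
#' @param bin_width Bin width, s (default 0.1).
#' @param units Unit ids (default all).
#' @return Matrix units x bins (Hz), with unit ids as row names and bin
#'   centers as an attribute `bin_centers`.
#' @export
encoding_psth <- function(session, bin_width = 0.1, units = session$units$unit_id) {
  trials <- session$trials
  enc_dur <- trials$video_off[1] - trials$video_on[1]
  breaks <- seq(0, enc_dur, by = bin_width)
  centers <- breaks[-length(breaks)] + bin_width / 2
  win <- cbind(trials$video_on, trials$video_off)
  trains <- spike_trains_in_window(session, units, trials, win)
  m <- t(vapply(trains, function(st) {
    spikes <- unlist(st, use.names = FALSE)
    cnt <- if (length(spikes) > 0) {
      tabulate(findInterval(spikes, breaks, rightmost.closed = FALSE),
        nbins = length(centers)
      )
    } else {
      integer(length(centers))
    }
    cnt / (bin_width * nrow(trials))
  }, numeric(length(centers))))
  rownames(m) <- units
  attr(m, "bin_centers") <- centers
  m
}

#' Normalized population heatmap sorted by relaxation time
#'
#' Min-max normalizes each temporal-context unit's PSTH row to `[0, 1]` and
#' orders rows by ascending relaxation time, the standard display of a
#' relaxation-time spectrum.
#'
#' @param tcc_results Tibble from [fit_temporal_context()].
#' @param psth Matrix from [encoding_psth()] (rows named by unit).
#' @param tcc_only Keep only units flagged `is_tcc` (default `TRUE`).
#' @return Normalized matrix, rows sorted by relaxation time.
#' @export
population_heatmap <- function(tcc_results, psth, tcc_only = TRUE) {
  res <- if (tcc_only) tcc_results[tcc_results$is_tcc, ] else tcc_results
  if (nrow(res) < 1) abort("population_heatmap needs at least one unit")
  res <- res[order(res$relaxation_time), ]
  m <- psth[match(res$unit_id, rownames(psth)), , drop = FALSE]
  t(apply(m, 1, function(r) {
    rng <- range(r)
    if (diff(rng) == 0) rep(0, length(r)) else (r - rng[1]) / diff(rng)
  }))
}
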