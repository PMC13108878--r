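# Firing-rate model curves shared by the generator and the nested-model
# fitter: constant, Gaussian, and ex-Gaussian (Gaussian convolved with an
# exponential decay).

#' Ex-Gaussian rate shape
#'
#' Density of the exponentially modified Gaussian — a Gaussian response of
#' latency `mu` and width `sigma` convolved with an exponential decay of
#' time constant `tau` — normalized so its peak equals 1. With the peak
#' normalization, `a0 + a1 * exgauss_shape(t, ...)` is a rate curve whose
#' extremum differs from baseline by exactly `a1` Hz.
#'
#' Evaluated in log space so that small `tau` (where the shape approaches
#' the Gaussian) and small `sigma` (where it approaches a pure exponential
#' starting at `mu`) are both numerically stable.
#'
#' @param t Times, seconds.
#' @param mu Latency (Gaussian mean), s.
#' @param sigma Gaussian width, s (> 0).
#' @param tau Exponential decay constant, s (> 0).
#' @return Shape values in `[0, 1]` at `t`.
#' @export
exgauss_shape <- function(t, mu, sigma, tau) {
  # the family includes its tau -> 0 (Gaussian) limit so the nested
  # parameter spaces coincide exactly
  if (tau <= 1e-6) return(exp(-(t - mu)^2 / (2 * sigma^2)))
  peak <- exgauss_peak_time(mu, sigma, tau)
  exp(log_emg_density(t, mu, sigma, tau) - log_emg_density(peak, mu, sigma, tau))
}

log_emg_density <- function(t, mu, sigma, tau) {
  -log(tau) + sigma^2 / (2 * tau^2) - (t - mu) / tau +
    pnorm((t - mu) / sigma - sigma / tau, log.p = TRUE)
}

# Mode of the exponentially modified Gaussian, found numerically; it lies
# between mu and roughly mu + sigma^2 / tau + tau.
exgauss_peak_time <- function(mu, sigma, tau) {
  if (tau <= 1e-6) return(mu)
  lo <- mu - 4 * sigma
  hi <- mu + 4 * sigma + 2 * tau
  optimize(function(x) log_emg_density(x, mu, sigma, tau),
    interval = c(lo, hi), maximum = TRUE, tol = 1e-8
  )$maximum
}

# Model rate curves in Hz over encoding time. Both nonlinear models use the
# peak parametrization (a1 = rate change at the extremum, Hz), so the
# Gaussian is exactly the tau -> 0 limit of the ex-Gaussian and the nested
# parameter spaces coincide.
rate_curve <- function(model_kind, pars) {
  switch(model_kind,
    constant = function(t) rep(pars[["a0"]], length(t)),
    gaussian = function(t) {
      pars[["a0"]] + pars[["a1"]] *
        exp(-(t - pars[["mu"]])^2 / (2 * pars[["sigma"]]^2))
    },
    exgauss = function(t) {
      pars[["a0"]] + pars[["a1"]] *
        exgauss_shape(t, pars[["mu"]], pars[["sigma"]], pars[["tau"]])
    },
    abort(sprintf("unknown model kind '%s'", model_kind))
  )
}
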