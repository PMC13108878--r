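# broom-style tidiers for the fitted objects.

#' Tidy a rate-model fit
#'
#' @param x A `rate_model_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`.
#' @method tidy rate_model_fit
#' @export
tidy.rate_model_fit <- function(x, ...) {
  tibble(term = names(x$pars), estimate = unname(x$pars))
}

#' One-row summary of a rate-model fit
#'
#' @param x A `rate_model_fit`.
#' @param ... Unused.
#' @return Tibble with `model_kind`, `loglik`, `n_params`, `n_trials`,
#'   `degenerate`.
#' @method glance rate_model_fit
#' @export
glance.rate_model_fit <- function(x, ...) {
  tibble(
    model_kind = x$model_kind, loglik = x$loglik, n_params = x$n_params,
    n_trials = x$n_trials, degenerate = x$degenerate
  )
}

#' Tidy a decoding result
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return Tibble of held-out samples: `trial_id`, `true_bin`,
#'   `decoded_bin`, `error_s`.
#' @method tidy decoding_result
#' @export
tidy.decoding_result <- function(x, ...) {
  x$samples %>%
    mutate(error_s = abs(.data$true_bin - .data$decoded_bin) * x$bin_width)
}

#' One-row summary of a decoding result
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return Tibble with `mae`, `chance`, `n_bins`, `n_folds`,
#'   `subsample_n`.
#' @method glance decoding_result
#' @export
glance.decoding_result <- function(x, ...) {
  tibble(
    mae = x$mae,
    chance = chance_mae(length(x$bins), x$bin_width),
    n_bins = length(x$bins),
    n_folds = x$n_folds,
    subsample_n = x$subsample_n
  )
}
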