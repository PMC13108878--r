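# Elapsed-time decoding from binned population activity: a cross-validated
# Gaussian linear discriminant over time-bin classes, a permutation null on
# shuffled bin labels, early-bin-exclusion robustness, and representational
# similarity matrices.

#' Bin encoding-period population activity
#'
#' Divides each trial's encoding period into nonoverlapping bins (32 x
#' 250 ms by default) and returns firing rates as a trial x bin x neuron
#' array.
#'
#' @param session A [session_recording()].
#' @param bin_width Bin width, s (default 0.25).
#' @param units Unit ids (default all).
#' @return A `population_tensor`: list with `rates` (array, Hz),
#'   `bin_width`, `bin_centers`, `trials` (id, condition, outcome),
#'   `units`.
#' @export
bin_activity <- function(session, bin_width = 0.25, units = session$units$unit_id) {
  trials <- session$trials
  enc_dur <- trials$video_off[1] - trials$video_on[1]
  n_bins <- round(enc_dur / bin_width)
  stopifnot(abs(n_bins * bin_width - enc_dur) < 1e-9)
  breaks <- seq(0, enc_dur, by = bin_width)
  win <- cbind(trials$video_on, trials$video_off)
  trains <- spike_trains_in_window(session, units, trials, win)
  rates <- array(0, dim = c(nrow(trials), n_bins, length(units)))
  for (u in seq_along(units)) {
    for (i in seq_len(nrow(trials))) {
      st <- trains[[u]][[i]]
      if (length(st) > 0) {
        rates[i, , u] <- tabulate(
          findInterval(st, breaks, rightmost.closed = FALSE),
          nbins = n_bins
        ) / bin_width
      }
    }
  }
  structure(
    list(
      rates = rates,
      bin_width = bin_width,
      bin_centers = breaks[-length(breaks)] + bin_width / 2,
      trials = trials[, c("trial_id", "condition", "outcome")],
      units = units
    ),
    class = "population_tensor"
  )
}

# Gaussian linear discriminant with pooled, diagonally shrunk covariance
# and uniform class priors. X: samples x features; class: integer labels.
lda_fit <- function(X, class, n_class, shrinkage = 0.1) {
  p <- ncol(X)
  means <- matrix(0, n_class, p)
  S <- matrix(0, p, p)
  for (k in seq_len(n_class)) {
    Xk <- X[class == k, , drop = FALSE]
    means[k, ] <- colMeans(Xk)
    C <- sweep(Xk, 2, means[k, ])
    S <- S + crossprod(C)
  }
  S <- S / (nrow(X) - n_class)
  S <- (1 - shrinkage) * S + shrinkage * mean(diag(S)) * diag(p)
  Sinv <- tryCatch(solve(S), error = function(e) {
    abort("pooled covariance singular even after shrinkage")
  })
  list(means = means, Sinv = Sinv)
}

lda_posterior <- function(model, X) {
  # discriminant: x' Sinv mu_k - 0.5 mu_k' Sinv mu_k (uniform priors)
  G <- X %*% model$Sinv %*% t(model$means)
  const <- 0.5 * rowSums((model$means %*% model$Sinv) * model$means)
  D <- sweep(G, 2, const)
  D <- D - apply(D, 1, max)
  P <- exp(D)
  P / rowSums(P)
}

#' Decode elapsed time by cross-validated linear discriminant
#'
#' Subsamples trials without replacement to `subsample_n`, partitions them
#' into stratified folds (by delay condition), and for each fold trains a
#' Gaussian linear discriminant — time-bin classes, per-class means,
#' pooled covariance with diagonal shrinkage, uniform priors — on the
#' training trials' (trial, bin) samples and assigns posteriors to the
#' held-out trials, so each trial is tested exactly once. All bins of a
#' held-out trial are held out together.
#'
#' @param tensor A [bin_activity()] tensor.
#' @param n_folds Cross-validation folds (5).
#' @param subsample_n Trials used (default all).
#' @param shrinkage Diagonal shrinkage intensity of the pooled covariance
#'   (default 0.1).
#' @param seed Integer seed (subsampling and fold assignment).
#' @param bins Bin indices to decode over (default all; used by the
#'   early-bin-exclusion analysis).
#' @return A `decoding_result`: `posterior` (true-bin x decoded-bin,
#'   rows sum to 1), `samples` tibble (trial, true bin, decoded bin,
#'   error s), `mae` (s), `n_folds`, `subsample_n`, `bin_width`.
#' @export
decode_time <- function(tensor, n_folds = 5, subsample_n = NULL,
                        shrinkage = 0.1, seed = 1L, bins = NULL) {
  rates <- tensor$rates
  n_trials <- dim(rates)[1]
  if (is.null(bins)) bins <- seq_len(dim(rates)[2])
  if (length(bins) < 4) abort("decode_time needs at least 4 time bins")
  if (is.null(subsample_n)) subsample_n <- n_trials
  stopifnot(subsample_n <= n_trials, n_trials >= n_folds)
  with_seed(substream_seed(seed, "decode"), {
    keep <- sort(sample.int(n_trials, subsample_n))
    cond <- tensor$trials$condition[keep]
    fold <- integer(subsample_n)
    for (g in unique(cond)) {
      idx <- which(cond == g)
      fold[idx] <- rep_len(sample.int(n_folds), length(idx))[sample.int(length(idx))]
    }
    n_bins <- length(bins)
    post_sum <- matrix(0, n_bins, n_bins)
    post_n <- integer(n_bins)
    out <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      tr_idx <- keep[fold != f]
      te_idx <- keep[fold == f]
      if (length(te_idx) == 0) next
      Xtr <- do.call(rbind, lapply(seq_along(bins), function(bi) rates[tr_idx, bins[bi], , drop = TRUE]))
      ytr <- rep(seq_len(n_bins), each = length(tr_idx))
      Xte <- do.call(rbind, lapply(seq_along(bins), function(bi) rates[te_idx, bins[bi], , drop = TRUE]))
      yte <- rep(seq_len(n_bins), each = length(te_idx))
      model <- lda_fit(as.matrix(Xtr), ytr, n_bins, shrinkage)
      P <- lda_posterior(model, as.matrix(Xte))
      dec <- max.col(P, ties.method = "first")
      for (k in seq_len(n_bins)) {
        rows <- which(yte == k)
        post_sum[k, ] <- post_sum[k, ] + colSums(P[rows, , drop = FALSE])
        post_n[k] <- post_n[k] + length(rows)
      }
      out[[f]] <- tibble(
        trial_id = rep(tensor$trials$trial_id[te_idx], times = n_bins),
        true_bin = yte, decoded_bin = dec
      )
    }
    samples <- bind_rows(out)
    mae <- mean(abs(samples$true_bin - samples$decoded_bin)) * tensor$bin_width
    structure(
      list(
        posterior = post_sum / post_n,
        samples = samples,
        mae = mae,
        n_folds = n_folds,
        subsample_n = subsample_n,
        bin_width = tensor$bin_width,
        bins = bins,
        shrinkage = shrinkage,
        seed = seed
      ),
      class = "decoding_result"
    )
  })
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "<decoding_result: %d bins x %.0f ms, mae %.3f s (chance %.3f s)>\n",
    length(x$bins), x$bin_width * 1000, x$mae,
    chance_mae(length(x$bins), x$bin_width)
  ))
  invisible(x)
}

#' Chance-level mean absolute decoding error
#'
#' Closed-form expectation of `|true - decoded|` when both are independent
#' uniform over `n_bins` bins: `(n_bins^2 - 1) / (3 * n_bins)` bins, times
#' the bin width. For 32 x 250-ms bins this is 2.664 s.
#'
#' @param n_bins Number of time-bin classes.
#' @param bin_width Bin width, s.
#' @return Chance mean absolute error, s.
#' @export
chance_mae <- function(n_bins, bin_width = 0.25) {
  (n_bins^2 - 1) / (3 * n_bins) * bin_width
}

#' Permutation null for the decoding error
#'
#' Generates a null distribution of the mean absolute error by shuffling
#' time-bin labels within trial. In `"shuffle_labels"` mode the fitted
#' decoder's held-out predictions are kept and only the true labels are
#' permuted each iteration; in `"refit"` mode the decoder is retrained on
#' label-shuffled data each iteration (at possibly reduced folds, for
#' speed). The p-value is `(#{null <= observed} + 1) / (n_perm + 1)`.
#'
#' @param tensor A [bin_activity()] tensor.
#' @param result A [decode_time()] result on that tensor.
#' @param n_perm Permutations (1000).
#' @param mode `"shuffle_labels"` (default) or `"refit"`.
#' @param refit_folds Folds used in refit mode (2).
#' @param seed Integer seed.
#' @return List with `null_maes`, `p`, `observed`, `mode`.
#' @export
permutation_null <- function(tensor, result, n_perm = 1000,
                             mode = c("shuffle_labels", "refit"),
                             refit_folds = 2, seed = 1L) {
  mode <- match.arg(mode)
  with_seed(substream_seed(seed, "decode-null"), {
    if (mode == "shuffle_labels") {
      n_bins <- length(result$bins)
      sp <- split(result$samples$decoded_bin, result$samples$trial_id)
      tr_true <- split(result$samples$true_bin, result$samples$trial_id)
      null_maes <- vapply(seq_len(n_perm), function(i) {
        err <- purrr::map2_dbl(sp, tr_true, function(d, tb) {
          perm <- sample.int(n_bins)
          mean(abs(perm[tb] - d))
        })
        mean(err) * result$bin_width
      }, numeric(1))
    } else {
      null_maes <- vapply(seq_len(n_perm), function(i) {
        shuf <- tensor
        for (tr in seq_len(dim(shuf$rates)[1])) {
          shuf$rates[tr, result$bins, ] <-
            shuf$rates[tr, result$bins[sample.int(length(result$bins))], ]
        }
        decode_time(shuf,
          n_folds = refit_folds, subsample_n = result$subsample_n,
          shrinkage = result$shrinkage, seed = sample.int(1e6, 1),
          bins = result$bins
        )$mae
      }, numeric(1))
    }
    list(
      null_maes = null_maes,
      p = (sum(null_maes <= result$mae) + 1) / (n_perm + 1),
      observed = result$mae,
      mode = mode
    )
  })
}

#' Decoding robustness to early-bin exclusion
#'
#' Repeats the decoding after dropping the first `k` seconds of the
#' encoding period, for each truncation level, recomputing chance for the
#' reduced bin count and (optionally) the permutation p-value.
#'
#' @param tensor A [bin_activity()] tensor.
#' @param drop_seconds Seconds of early encoding to drop (default
#'   `0:6`, 1-s increments).
#' @param n_perm Permutations per level (default 1000; 0 skips).
#' @param ... Passed to [decode_time()].
#' @param seed Integer seed.
#' @return Tibble: `drop_s`, `n_bins`, `mae`, `chance`, `p`.
#' @export
early_bin_exclusion <- function(tensor, drop_seconds = 0:6, n_perm = 1000,
                                seed = 1L, ...) {
  n_bins_all <- dim(tensor$rates)[2]
  purrr::map_dfr(drop_seconds, function(k) {
    first_bin <- round(k / tensor$bin_width) + 1
    bins <- first_bin:n_bins_all
    if (length(bins) < 4) abort("fewer than 4 bins remain after truncation")
    res <- decode_time(tensor, bins = bins, seed = substream_seed(seed, paste0("trunc", k)), ...)
    p <- if (n_perm > 0) {
      permutation_null(tensor, res,
        n_perm = n_perm,
        seed = substream_seed(seed, paste0("truncnull", k))
      )$p
    } else {
      NA_real_
    }
    tibble(
      drop_s = k, n_bins = length(bins), mae = res$mae,
      chance = chance_mae(length(bins), tensor$bin_width), p = p
    )
  })
}

#' Representational similarity across time bins
#'
#' Trial-averages the tensor to a bin x neuron matrix, z-scores each
#' neuron's time course (controlling baseline rate differences across
#' neurons), and returns the bin x bin Pearson correlation matrix of
#' population vectors. Adjacent bins correlate highly; the fall-off with
#' temporal separation indexes representational drift.
#'
#' @param tensor A [bin_activity()] tensor with at least 2 neurons.
#' @return Symmetric bin x bin correlation matrix with unit diagonal.
#' @export
rsa_matrix <- function(tensor) {
  if (dim(tensor$rates)[3] < 2) abort("rsa_matrix needs at least 2 neurons")
  M <- apply(tensor$rates, c(2, 3), mean) # bins x neurons
  Z <- scale(M) # z-score each neuron across bins
  # neurons with zero variance carry no pattern information
  Z <- Z[, apply(M, 2, sd) > 0, drop = FALSE]
  cor(t(Z))
}

#' Session-level decoding-behaviour correlation
#'
#' Pearson correlation (two-tailed) between a per-session decoding summary
#' and per-session behavioural accuracy.
#'
#' @param sessions_tbl Tibble with one row per session, columns `decoding`
#'   (e.g. negative mae or accuracy) and `accuracy`.
#' @return Tibble with `r`, `p`, `n`.
#' @export
decoding_behavior_correlation <- function(sessions_tbl) {
  if (nrow(sessions_tbl) < 5) abort("needs at least 5 sessions")
  ct <- stats::cor.test(sessions_tbl$decoding, sessions_tbl$accuracy)
  tibble(r = unname(ct$estimate), p = ct$p.value, n = nrow(sessions_tbl))
}
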