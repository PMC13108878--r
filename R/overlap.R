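# Behavioural summaries and the cell-category overlap analyses that are
# fully reconstructible from category counts.

#' Behavioural accuracy summary
#'
#' Proportion correct overall and per delay condition, each with an exact
#' two-tailed binomial test against the two-alternative chance level 0.5.
#'
#' @param trials Trials tibble (or several sessions' trials stacked).
#' @param chance Chance proportion (default 0.5).
#' @return Tibble with `condition` (`"all"`, then each condition),
#'   `n_trials`, `accuracy`, `p_binomial`.
#' @export
behavior_summary <- function(trials, chance = 0.5) {
  one <- function(label, sub) {
    k <- sum(sub$outcome == "correct")
    n <- nrow(sub)
    tibble(
      condition = label, n_trials = n, accuracy = k / n,
      p_binomial = binom.test(k, n, p = chance)$p.value
    )
  }
  bind_rows(
    one("all", trials),
    purrr::map_dfr(sort(unique(trials$condition)), function(cc) {
      one(cc, trials[trials$condition == cc, ])
    })
  )
}

#' Expected category overlap under independence
#'
#' `n_A * n_B / n_total`: the expected number of neurons in both
#' categories if membership were independent.
#'
#' @param n_total Total neurons.
#' @param n_a,n_b Category sizes.
#' @return Expected overlap count.
#' @export
expected_overlap <- function(n_total, n_a, n_b) {
  stopifnot(n_a <= n_total, n_b <= n_total, n_total > 0)
  n_a * n_b / n_total
}

#' Independence test for two cell categories
#'
#' Builds the 2x2 contingency table {AB, A not-B, not-A B, neither} from
#' the counts and returns the continuity-corrected (Yates) chi-squared
#' statistic with its df-1 p-value.
#'
#' @param n_total Total neurons.
#' @param n_a,n_b Category sizes.
#' @param n_ab Observed overlap.
#' @return Tibble with `chisq`, `df`, `p`, `expected_overlap`.
#' @export
overlap_independence_test <- function(n_total, n_a, n_b, n_ab) {
  stopifnot(n_ab <= min(n_a, n_b), n_a <= n_total, n_b <= n_total)
  tab <- matrix(
    c(
      n_ab, n_a - n_ab,
      n_b - n_ab, n_total - n_a - n_b + n_ab
    ),
    nrow = 2
  )
  if (any(tab < 1)) abort("all four table cells must be at least 1")
  ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
  tibble(
    chisq = unname(ct$statistic),
    df = unname(ct$parameter),
    p = ct$p.value,
    expected_overlap = expected_overlap(n_total, n_a, n_b)
  )
}

#' Overlap report from pipeline results
#'
#' Joins temporal-context and TOJ classifications over the same unit
#' universe, assembles the category counts, and runs the independence
#' test.
#'
#' @param tcc_results Tibble from [fit_temporal_context()].
#' @param glm_results Tibble from [classify_toj_cells()].
#' @return List with `counts` (tibble: `n_total`, `n_tcc`, `n_toj`,
#'   `n_both`) and `test` (see [overlap_independence_test()]).
#' @export
pipeline_overlap_report <- function(tcc_results, glm_results) {
  joined <- dplyr::inner_join(
    tcc_results[, c("unit_id", "is_tcc")],
    glm_results[, c("unit_id", "is_toj_cell")],
    by = "unit_id"
  )
  if (nrow(joined) != nrow(tcc_results) || nrow(joined) != nrow(glm_results)) {
    abort("tcc and glm results must cover the same unit universe")
  }
  counts <- tibble(
    n_total = nrow(joined),
    n_tcc = sum(joined$is_tcc),
    n_toj = sum(joined$is_toj_cell),
    n_both = sum(joined$is_tcc & joined$is_toj_cell)
  )
  test <- tryCatch(
    overlap_independence_test(counts$n_total, counts$n_tcc, counts$n_toj, counts$n_both),
    error = function(e) NULL
  )
  list(counts = counts, test = test)
}
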