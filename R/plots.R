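# ggplot2 displays for the main result types.

#' Plot a population heatmap sorted by relaxation time
#'
#' @param heatmap Matrix from [population_heatmap()].
#' @param bin_width PSTH bin width used, s (for the time axis).
#' @return A ggplot.
#' @export
plot_population_heatmap <- function(heatmap, bin_width = 0.1) {
  colnames(heatmap) <- paste0("b", seq_len(ncol(heatmap)))
  df <- as_tibble(heatmap, rownames = "unit_id") %>%
    mutate(row = dplyr::row_number()) %>%
    tidyr::pivot_longer(-c("unit_id", "row"), names_to = "bin", values_to = "rate") %>%
    mutate(time = (as.integer(gsub("\\D", "", .data$bin)) - 0.5) * bin_width)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$row, fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "norm. rate") +
    ggplot2::labs(
      x = "time from video onset (s)",
      y = "unit (sorted by relaxation time)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a decoding posterior matrix
#'
#' True versus decoded time bin, posterior probability on a log scale,
#' with the maximum-probability decoded bin marked.
#'
#' @param x A [decode_time()] result.
#' @return A ggplot.
#' @export
plot_posterior <- function(x) {
  P <- x$posterior
  df <- tidyr::expand_grid(
    true_bin = seq_len(nrow(P)), decoded_bin = seq_len(ncol(P))
  ) %>%
    mutate(posterior = as.vector(t(P)))
  peak <- tibble(
    true_bin = seq_len(nrow(P)), decoded_bin = max.col(P, ties.method = "first")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$true_bin, .data$decoded_bin)) +
    ggplot2::geom_raster(ggplot2::aes(fill = log10(.data$posterior + 1e-6))) +
    ggplot2::geom_point(data = peak, colour = "red", size = 0.8) +
    ggplot2::scale_fill_gradient(
      low = "black", high = "white",
      name = "log10 posterior"
    ) +
    ggplot2::labs(x = "true time bin", y = "decoded time bin") +
    ggplot2::theme_minimal()
}

#' Plot synchrony time courses with significance marks
#'
#' @param tc Result of [synchrony_timecourse()].
#' @return A ggplot.
#' @export
plot_synchrony <- function(tc) {
  sig <- tc$bins[tc$bins$significant, ]
  g <- ggplot2::ggplot(
    tc$means,
    ggplot2::aes(.data$time, .data$value, colour = .data$group)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "SPIKE-distance") +
    ggplot2::theme_minimal()
  if (nrow(sig) > 0) {
    y0 <- min(tc$means$value)
    g <- g + ggplot2::geom_point(
      data = sig, ggplot2::aes(x = .data$time, y = y0),
      inherit.aes = FALSE, colour = "darkgreen", size = 0.6
    )
  }
  g
}

#' Plot a representational similarity matrix
#'
#' @param m Matrix from [rsa_matrix()].
#' @param bin_width Bin width, s.
#' @return A ggplot.
#' @export
plot_rsa <- function(m, bin_width = 0.25) {
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m))) %>%
    mutate(
      r = as.vector(t(m)),
      t_i = (.data$i - 0.5) * bin_width,
      t_j = (.data$j - 0.5) * bin_width
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$t_i, .data$t_j, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Pearson r") +
    ggplot2::labs(x = "time bin (s)", y = "time bin (s)") +
    ggplot2::theme_minimal()
}
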