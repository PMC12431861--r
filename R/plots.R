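# ggplot2 displays for the result types.

#' Plot an APA result
#'
#' Heat map of the mean contact sub-matrix around loop centroids; the
#' focal enrichment of genuine loops appears as a bright center pixel.
#'
#' @param object An `apa_result` from [apa()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.apa_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$dy, y = .data$dx,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "mean signal") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "offset from 3' anchor (bins)", y = "offset from 5' anchor (bins)",
      title = sprintf("APA (%d loops), score %.2f",
                      object$n_loops_used, object$apa_score)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a compartment saddle or eigenvector
#'
#' With a saddle present, draws the observed/expected means over
#' eigenvector quantile pairs (upper-left = B-B, lower-right = A-A);
#' otherwise draws the per-bin eigenvector track.
#'
#' @param object A `compartment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.compartment_result <- function(object, ...) {
  if (!is.null(object$saddle)) {
    nq <- nrow(object$saddle)
    df <- tibble::tibble(
      q_row = rep(seq_len(nq), times = nq),
      q_col = rep(seq_len(nq), each = nq),
      value = as.vector(object$saddle)
    )
    ggplot2::ggplot(df, ggplot2::aes(x = .data$q_col, y = .data$q_row,
                                     fill = log2(.data$value))) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() +
      ggplot2::scale_fill_gradient2(name = "log2 obs/exp") +
      ggplot2::coord_fixed() +
      ggplot2::labs(x = "eigenvector quantile (B → A)",
                    y = "eigenvector quantile (B → A)",
                    title = "Compartment saddle") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(tidy(object),
                    ggplot2::aes(x = .data$start / 1e6,
                                 y = .data$eigenvector)) +
      ggplot2::geom_col(ggplot2::aes(fill = .data$compartment),
                        width = object$resolution / 1e6) +
      ggplot2::labs(x = "position (Mb)", y = "eigenvector") +
      ggplot2::theme_minimal()
  }
}

#' Plot distance-decay curves
#'
#' Median normalized contact signal against genomic distance on log-log
#' axes, one curve per chromosome (the cross-chromosome summary, when
#' present, is labelled `"all"`).
#'
#' @param decay Output of [distance_decay()].
#' @return A ggplot object.
#' @export
plot_distance_decay <- function(decay) {
  ggplot2::ggplot(dplyr::filter(decay, !is.na(.data$median_value),
                                .data$median_value > 0),
                  ggplot2::aes(x = .data$distance_bp,
                               y = .data$median_value,
                               colour = .data$chrom)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "genomic distance (bp)", y = "median signal") +
    ggplot2::theme_minimal()
}

#' Plot an insulation-score track with called peaks
#'
#' @param track An [insulation_track()].
#' @param peaks Optional [insulation_peaks()] result to overlay.
#' @param threshold Threshold line to draw.
#' @return A ggplot object.
#' @export
plot_insulation <- function(track, peaks = NULL, threshold = 0.75) {
  p <- ggplot2::ggplot(dplyr::filter(track, !is.na(.data$score)),
                       ggplot2::aes(x = .data$start / 1e6,
                                    y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "position (Mb)", y = "insulation score") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks)) {
    res <- attr(track, "resolution")
    p <- p + ggplot2::geom_rect(
      data = peaks,
      ggplot2::aes(xmin = .data$start_bin * res / 1e6,
                   xmax = (.data$end_bin + 1) * res / 1e6),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "firebrick",
      inherit.aes = FALSE
    )
  }
  p
}
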