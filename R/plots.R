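# ggplot2 views of the main result types

#' Plot a threshold sweep
#'
#' L1 error against bit-score threshold, with the within-1%-of-optimum
#' band shaded and the optimum marked.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sweep_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$l1_error)) +
    ggplot2::annotate("rect", xmin = object$within1pct_band[1],
                      xmax = object$within1pct_band[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$optimum_bits, linetype = 2) +
    ggplot2::labs(x = "bit-score threshold", y = "L1 relative-abundance error",
                  title = sprintf("Threshold sweep (%s, %s)", object$mode,
                                  object$metric)) +
    ggplot2::theme_minimal()
}

#' Plot a rarefaction error curve
#'
#' Mean L1 error (with per-replicate points) as a function of read depth.
#'
#' @param object A `rarefaction_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rarefaction_curve <- function(object, ...) {
  s <- glance(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$depth, y = .data$mean_l1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_jitter(data = tibble::as_tibble(object),
                         ggplot2::aes(y = .data$l1), width = 0.02, height = 0,
                         alpha = 0.4, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "reads sampled", y = "L1 relative-abundance error") +
    ggplot2::theme_minimal()
}

#' Plot an empirical false-positive-rate curve
#'
#' @param object An `fpr_curve` from [empirical_fpr()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fpr_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$threshold, y = .data$fpr)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "bit-score threshold",
                  y = "shuffled-read classification rate") +
    ggplot2::theme_minimal()
}

#' Plot PCA sample scores
#'
#' @param object A `metafam_pca`.
#' @param colour Optional vector of group labels, one per sample.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2 with explained-variance axis labels.
#' @export
autoplot.metafam_pca <- function(object, colour = NULL, ...) {
  d <- object$scores
  if (!is.null(colour)) d$group <- colour
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point() else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  }
}
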