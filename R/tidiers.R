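#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a threshold sweep
#'
#' @param x A `sweep_result` from [threshold_sweep()].
#' @param ... Unused.
#' @return `tidy()`: tibble `threshold`, `l1_error`, `in_band`;
#'   `glance()`: one-row tibble with the optimum and band.
#' @export
tidy.sweep_result <- function(x, ...) {
  tibble::tibble(threshold = x$thresholds, l1_error = x$errors,
                 in_band = x$errors <= 1.01 * min(x$errors))
}

#' @rdname tidy.sweep_result
#' @export
glance.sweep_result <- function(x, ...) {
  tibble::tibble(optimum_bits = x$optimum_bits,
                 min_l1 = min(x$errors),
                 band_low = x$within1pct_band[1],
                 band_high = x$within1pct_band[2],
                 mode = x$mode, metric = x$metric)
}

#' Tidy a PERMANOVA fit
#'
#' @param x A `metafam_permanova` from [permanova()].
#' @param ... Unused.
#' @return `tidy()`: the partition table; `glance()`: one row with
#'   `pseudo_F`, `p`, `n_perm`.
#' @export
tidy.metafam_permanova <- function(x, ...) x$table

#' @rdname tidy.metafam_permanova
#' @export
glance.metafam_permanova <- function(x, ...) {
  tibble::tibble(pseudo_F = x$pseudo_F, p = x$p, n_perm = x$n_perm)
}

#' Tidy a profile PCA
#'
#' @param x A `metafam_pca` from [pca_profiles()].
#' @param ... Unused.
#' @return `tidy()`: sample scores; `glance()`: one row with explained
#'   variance of the leading components.
#' @export
tidy.metafam_pca <- function(x, ...) x$scores

#' @rdname tidy.metafam_pca
#' @export
glance.metafam_pca <- function(x, ...) {
  e <- x$explained
  tibble::tibble(pc1_var = e[1],
                 pc2_var = if (length(e) > 1) e[2] else NA_real_,
                 pc3_var = if (length(e) > 2) e[3] else NA_real_,
                 n_families = x$n_families)
}

#' Summarize a rarefaction error curve
#'
#' @param x A `rarefaction_curve` from [rarefaction_error_curve()].
#' @param ... Unused.
#' @return One row per depth with the mean and sd of the L1 error.
#' @export
glance.rarefaction_curve <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$depth) |>
    dplyr::summarise(mean_l1 = mean(.data$l1), sd_l1 = stats::sd(.data$l1),
                     replicates = dplyr::n(), .groups = "drop")
}
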