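#' L1 relative-abundance error between expected and estimated profiles
#'
#' \eqn{D = \frac{1}{2}\sum_i |R_i - \hat R_i|} over the union of family
#' ids (missing families count as zero). Both profiles must be normalized.
#' D is 0 iff the profiles are identical and 1 iff their supports are
#' disjoint (the maximum prediction error).
#'
#' @param expected,estimated Normalized profile tibbles (`family_id`,
#'   `abundance`).
#' @return L1 error in \[0, 1\].
#' @export
l1_error <- function(expected, estimated) {
  for (p in list(expected, estimated)) {
    if (!is_normalized_profile(p)) {
      abort_("l1_error requires normalized profiles (values sum to 1)")
    }
  }
  m <- dplyr::full_join(tibble::as_tibble(expected),
                        tibble::as_tibble(estimated),
                        by = "family_id", suffix = c("_e", "_o")) |>
    tidyr::replace_na(list(abundance_e = 0, abundance_o = 0))
  sum(abs(m$abundance_e - m$abundance_o)) / 2
}

#' Bray-Curtis dissimilarity between two normalized profiles
#'
#' \eqn{\sum_i |p_i - q_i| / \sum_i (p_i + q_i)}. On normalized profiles
#' the denominator is 2, so this equals [l1_error()] exactly; it is kept
#' as a separate operation because beta-diversity analyses are phrased in
#' Bray-Curtis terms.
#'
#' @param p,q Normalized profile tibbles.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(p, q) {
  for (x in list(p, q)) {
    if (!is_normalized_profile(x)) {
      abort_("bray_curtis requires normalized profiles")
    }
  }
  m <- dplyr::full_join(tibble::as_tibble(p), tibble::as_tibble(q),
                        by = "family_id", suffix = c("_p", "_q")) |>
    tidyr::replace_na(list(abundance_p = 0, abundance_q = 0))
  sum(abs(m$abundance_p - m$abundance_q)) /
    sum(m$abundance_p + m$abundance_q)
}

#' Sweep classification thresholds and measure profile error
#'
#' For each bit-score threshold in `grid`: classify the hits, build the
#' abundance profile, and compute its L1 error against the expected
#' profile. A threshold at which nothing classifies scores the maximum
#' error of 1. Reports the error-minimizing threshold and the band of
#' thresholds whose error is within 1% of the optimum.
#'
#' @param hits Alignment-hit tibble.
#' @param expected Expected (normalized) profile.
#' @param ref A [ref_set()].
#' @param grid Ascending numeric vector of bit-score thresholds.
#' @param mode Classification mode, see [classify_hits()].
#' @param metric `"count"` or `"coverage"`.
#' @return A `sweep_result`: list with `thresholds`, `errors`,
#'   `optimum_bits`, `within1pct_band` (low, high). Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
threshold_sweep <- function(hits, expected, ref, grid,
                            mode = c("per_read", "per_orf"),
                            metric = c("count", "coverage")) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  if (length(grid) == 0 || is.unsorted(grid, strictly = TRUE)) {
    abort_("`grid` must be a non-empty strictly ascending vector")
  }
  abun <- if (metric == "count") count_abundance else coverage_abundance
  errors <- vapply(grid, function(t) {
    cls <- classify_hits(hits, mode = mode, min_bits = t)
    if (nrow(cls) == 0) return(1)
    l1_error(expected, abun(cls, ref))
  }, numeric(1))
  in_band <- errors <= 1.01 * min(errors)
  structure(list(thresholds = grid, errors = errors,
                 optimum_bits = grid[which.min(errors)],
                 within1pct_band = range(grid[in_band]),
                 mode = mode, metric = metric),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "<sweep_result> %d thresholds, optimum %.4g bits (min L1 %.4g), %s\n",
    length(x$thresholds), x$optimum_bits, min(x$errors),
    sprintf("within-1%% band [%.4g, %.4g]",
            x$within1pct_band[1], x$within1pct_band[2])))
  invisible(x)
}

#' Rarefy classifications to a fixed read depth
#'
#' Subsamples *source reads* (not ORFs) to the given depth and rebuilds
#' the abundance profile, one profile per replicate. Sampling is without
#' replacement for rarefaction; with replacement it is a read-level
#' bootstrap, and a read drawn twice contributes twice.
#'
#' @param classifications Classification tibble.
#' @param ref A [ref_set()].
#' @param depth Number of reads per replicate (> 0; at most the number of
#'   available reads when sampling without replacement).
#' @param replicates Number of replicate profiles.
#' @param seed Integer seed; the procedure is deterministic given it.
#' @param with_replacement Bootstrap instead of rarefy.
#' @param read_ids Universe of read ids to sample from; defaults to the
#'   distinct read ids present in `classifications`. Supply the full read
#'   list to account for unclassified reads.
#' @param metric Abundance metric for the rebuilt profiles.
#' @return List of normalized `fam_profile`s, length `replicates`.
#' @export
rarefy_classifications <- function(classifications, ref, depth,
                                   replicates = 1, seed = 1,
                                   with_replacement = FALSE,
                                   read_ids = NULL,
                                   metric = c("count", "coverage")) {
  metric <- match.arg(metric)
  check_number(depth, "depth", lower = 0, allow_zero = FALSE)
  check_number(replicates, "replicates", lower = 0, allow_zero = FALSE)
  universe <- read_ids %||% unique(classifications$read_id)
  if (!with_replacement && depth > length(universe)) {
    abort_(sprintf("depth %d exceeds the %d available reads",
                   as.integer(depth), length(universe)))
  }
  with_seed_(seed, {
    lapply(seq_len(replicates), function(i) {
      drawn <- sample(universe, depth, replace = with_replacement)
      w <- table(drawn)
      cls <- classifications[classifications$read_id %in% names(w), ]
      if (nrow(cls) == 0) {
        abort_("a rarefied replicate contained no classified reads")
      }
      abundance_impl(cls, ref, metric = metric, normalize = TRUE,
                     weights = as.numeric(w[cls$read_id]))
    })
  })
}

#' Mean profile error as a function of sequencing depth
#'
#' Convenience driver around [rarefy_classifications()]: rarefies to each
#' depth, scores every replicate profile against the expected profile with
#' [l1_error()], and returns the per-replicate and summarized errors.
#'
#' @inheritParams rarefy_classifications
#' @param expected Expected (normalized) profile.
#' @param depths Vector of read depths.
#' @return A tibble of class `rarefaction_curve`: `depth`, `replicate`,
#'   `l1`. Summarize with [glance()] or draw with [autoplot()].
#' @export
rarefaction_error_curve <- function(classifications, ref, expected, depths,
                                    replicates = 3, seed = 1,
                                    read_ids = NULL,
                                    metric = c("count", "coverage")) {
  metric <- match.arg(metric)
  rows <- purrr::map(seq_along(depths), function(di) {
    profs <- rarefy_classifications(
      classifications, ref, depth = depths[di], replicates = replicates,
      seed = seed + di, read_ids = read_ids, metric = metric)
    tibble::tibble(depth = depths[di],
                   replicate = seq_len(replicates),
                   l1 = vapply(profs, l1_error, numeric(1),
                               expected = expected))
  })
  structure(dplyr::bind_rows(rows),
            class = c("rarefaction_curve", class(tibble::tibble())))
}

#' Bootstrap coefficient of variation of per-family classified counts
#'
#' In the absence of biological variation, a family's classified-read
#' count at a given depth is Poisson distributed, so its coefficient of
#' variation falls as \eqn{1/\sqrt{\mathrm{mean}}}. This routine resamples
#' counts and reports the empirical sd/mean per family and depth. Family
#' proportions are taken from `classified_counts`; the expected count of a
#' family at depth `d` is its proportion times `d`.
#'
#' @param classified_counts Named numeric vector (or tibble `family_id`,
#'   `count`) of per-family classified-read counts.
#' @param depths Vector of total classified-read depths to evaluate.
#' @param replicates Bootstrap replicates per depth (>= 100 recommended;
#'   fewer triggers a warning).
#' @param seed Integer seed.
#' @param method `"poisson"` resamples each family independently from
#'   Poisson(mean); `"multinomial"` resamples reads jointly at fixed
#'   depth.
#' @return Tibble `family_id`, `depth`, `mean_count`, `cv`; `cv` is `NA`
#'   for zero-mean families, where it is undefined.
#' @export
bootstrap_family_cv <- function(classified_counts, depths, replicates = 100,
                                seed = 1, method = c("poisson",
                                                     "multinomial")) {
  method <- match.arg(method)
  check_number(replicates, "replicates", lower = 2)
  if (replicates < 100) {
    warning("fewer than 100 bootstrap replicates gives unstable CVs")
  }
  if (is.data.frame(classified_counts)) {
    classified_counts <- stats::setNames(classified_counts$count,
                                         classified_counts$family_id)
  }
  if (any(classified_counts < 0)) abort_("counts must be >= 0")
  prop <- classified_counts / sum(classified_counts)
  with_seed_(seed, {
    purrr::map(depths, function(d) {
      mu <- prop * d
      draws <- if (method == "poisson") {
        matrix(stats::rpois(length(mu) * replicates, mu),
               nrow = length(mu))
      } else {
        stats::rmultinom(replicates, size = d, prob = prop)
      }
      means <- unname(rowMeans(draws))
      sds <- unname(apply(draws, 1, stats::sd))
      tibble::tibble(family_id = names(classified_counts) %||%
                       as.character(seq_along(mu)),
                     depth = d, mean_count = means,
                     cv = ifelse(means > 0, sds / means, NA_real_))
    }) |>
      dplyr::bind_rows()
  })
}

#' Library size needed for a target per-family coefficient of variation
#'
#' A single-copy gene of length `gene_len_bp` in a community of average
#' genome size `ags_bp` occupies a fraction `gene_len_bp / ags_bp` of the
#' average genome, so a library of N reads yields about
#' `N * gene_len_bp / ags_bp` classified reads for it. Under Poisson
#' counting, CV <= `cv_target` requires `1 / cv_target^2` classified
#' reads, hence
#' \eqn{N = \lceil (1/\mathrm{cv}^2) \cdot \mathrm{ags} / \mathrm{len} \rceil}.
#' For example, a CV of 0.10 for a 1-kb gene at a 3-Mb average genome size
#' requires 100 classified reads and therefore 300,000 total reads.
#'
#' @param cv_target Target coefficient of variation (0 < cv <= 1).
#' @param gene_len_bp Gene length in bp.
#' @param ags_bp Average genome size in bp.
#' @return Required number of reads (integer-valued numeric).
#' @export
reads_for_target_cv <- function(cv_target, gene_len_bp, ags_bp) {
  check_number(cv_target, "cv_target", lower = 0, allow_zero = FALSE)
  if (cv_target > 1) abort_("`cv_target` must be <= 1")
  check_number(gene_len_bp, "gene_len_bp", lower = 0, allow_zero = FALSE)
  check_number(ags_bp, "ags_bp", lower = 0, allow_zero = FALSE)
  ceiling((1 / cv_target^2) * ags_bp / gene_len_bp)
}

#' Alpha diversity of a classified-read count profile
#'
#' Richness (families with positive count), Shannon entropy in nats
#' (\eqn{H = -\sum p_i \ln p_i}), and Good's coverage
#' \eqn{C = 1 - F_1/N}, where \eqn{F_1} is the number of families observed
#' exactly once and N the total count — the estimated probability that the
#' next classified read belongs to an already-observed family.
#'
#' @param counts Named numeric vector (or tibble `family_id`, `count`) of
#'   non-negative integer classified-read counts, at least one positive.
#' @return One-row tibble: `richness`, `shannon`, `goods_coverage`.
#' @export
alpha_diversity <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$count
  if (any(counts < 0)) abort_("counts must be >= 0")
  n <- sum(counts)
  if (n <= 0) abort_("all-zero count profile has no diversity")
  pos <- counts[counts > 0]
  p <- pos / n
  tibble::tibble(richness = length(pos),
                 shannon = -sum(p * log(p)),
                 goods_coverage = 1 - sum(pos == 1) / n)
}

#' Empirical false-positive rate of shuffled-read classification
#'
#' Shuffled reads carry no homology signal, so any classification of one
#' is a false positive. For each threshold `t`, the FPR is the fraction of
#' the `n_reads` shuffled reads with at least one hit of bit score >= t;
#' it is non-increasing in `t`.
#'
#' @param shuffled_hits Alignment hits produced from [shuffle_reads()]
#'   output.
#' @param grid Numeric vector of bit-score thresholds.
#' @param n_reads Number of shuffled reads searched.
#' @return A tibble of class `fpr_curve`: `threshold`, `fpr`.
#' @export
empirical_fpr <- function(shuffled_hits, grid, n_reads) {
  check_number(n_reads, "n_reads", lower = 0, allow_zero = FALSE)
  fpr <- vapply(grid, function(t) {
    dplyr::n_distinct(shuffled_hits$read_id[shuffled_hits$bit_score >= t]) /
      n_reads
  }, numeric(1))
  structure(tibble::tibble(threshold = grid, fpr = fpr),
            class = c("fpr_curve", class(tibble::tibble())))
}
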