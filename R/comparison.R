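#' Filter families by prevalence across samples
#'
#' Restricting tests to widely observed families reduces the multiple-
#' testing burden. `fully_observed` keeps families with a positive value
#' in every sample (equivalent to `min_fraction` with `f = 1`);
#' `min_fraction` keeps families observed in at least a fraction `f` of
#' samples.
#'
#' @param matrix Family-by-sample tibble: `family_id` plus one numeric
#'   column per sample.
#' @param mode `"fully_observed"` or `"min_fraction"`.
#' @param f Minimum fraction of samples for `min_fraction` mode.
#' @return The filtered matrix; empty results trigger a warning, not an
#'   error.
#' @export
prevalence_filter <- function(matrix, mode = c("fully_observed",
                                               "min_fraction"), f = NULL) {
  mode <- match.arg(mode)
  vals <- as.matrix(matrix[setdiff(names(matrix), "family_id")])
  frac <- rowMeans(vals > 0)
  thr <- if (mode == "fully_observed") 1 else {
    check_number(f, "f", lower = 0)
    f
  }
  keep <- frac >= thr
  if (!any(keep)) warning("prevalence filter removed every family")
  matrix[keep, ]
}

# Kruskal-Wallis H with average-rank tie correction (same statistic as
# stats::kruskal.test)
kw_stat <- function(x, g) {
  n <- length(x)
  r <- rank(x)
  means <- tapply(r, g, mean)
  sizes <- tapply(r, g, length)
  h <- 12 / (n * (n + 1)) * sum(sizes * (means - (n + 1) / 2)^2)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) return(NA_real_)
  h / corr
}

# exact Kruskal-Wallis p-value by enumeration of all distinct assignments
# of the observations to groups of the observed sizes
kw_exact_p <- function(x, g) {
  g <- as.factor(g)
  sizes <- as.vector(table(g))
  obs <- kw_stat(x, g)
  if (is.na(obs)) return(1)
  count <- 0L
  total <- 0L
  recurse <- function(avail, assigned) {
    k <- length(assigned) + 1L
    if (k > length(sizes)) {
      grp <- rep.int(seq_along(sizes), sizes)
      idx <- unlist(assigned)
      stat <- kw_stat(x[idx], grp)
      total <<- total + 1L
      if (!is.na(stat) && stat >= obs - 1e-12) count <<- count + 1L
      return(invisible())
    }
    if (k == length(sizes)) {
      recurse(integer(0), c(assigned, list(avail)))
      return(invisible())
    }
    combos <- utils::combn(avail, sizes[k], simplify = FALSE)
    for (cb in combos) recurse(setdiff(avail, cb), c(assigned, list(cb)))
    invisible()
  }
  recurse(seq_along(x), list())
  count / total
}

#' Per-family association tests across samples
#'
#' One rank-based test per family: Kruskal-Wallis for a categorical
#' covariate, Kendall's tau for a continuous one. Families with constant
#' abundance across samples get p = 1 (no signal). For small cohorts
#' (total n <= `exact_n`, default 10) the Kruskal-Wallis p-value is
#' computed exactly by enumerating every distinct assignment of the
#' observations to groups; otherwise the chi-square asymptotic is used.
#' Kendall tests use the exact null distribution where
#' [stats::cor.test()] provides it.
#'
#' @param matrix Family-by-sample tibble (`family_id` + sample columns).
#' @param meta Sample metadata tibble with a `sample` column matching the
#'   matrix's sample columns.
#' @param covariate Name of the metadata column to test against.
#' @param exact_n Largest total sample count at which exact enumeration is
#'   used for the categorical test.
#' @return Tibble `family_id`, `statistic`, `p` (uncorrected; see
#'   [storey_qvalues()]).
#' @export
family_association_tests <- function(matrix, meta, covariate, exact_n = 10) {
  if (!covariate %in% names(meta)) {
    abort_(sprintf("covariate '%s' not found in metadata", covariate))
  }
  samples <- setdiff(names(matrix), "family_id")
  if (!all(samples %in% meta$sample)) {
    abort_("metadata is missing sample(s) present in the matrix")
  }
  z <- meta[[covariate]][match(samples, meta$sample)]
  categorical <- is.character(z) || is.factor(z) || is.logical(z)
  if (categorical) {
    z <- droplevels(as.factor(z))
    if (nlevels(z) < 2) abort_("categorical covariate needs >= 2 groups")
  } else if (length(unique(z)) < 3) {
    abort_("continuous covariate needs >= 3 distinct values")
  }
  vals <- as.matrix(matrix[samples])
  res <- purrr::map(seq_len(nrow(vals)), function(i) {
    x <- as.numeric(vals[i, ])
    if (length(unique(x)) < 2) {
      return(tibble::tibble(statistic = NA_real_, p = 1))
    }
    if (categorical) {
      stat <- kw_stat(x, z)
      p <- if (length(x) <= exact_n) kw_exact_p(x, z) else {
        stats::kruskal.test(x, z)$p.value
      }
    } else {
      ct <- suppressWarnings(stats::cor.test(x, z, method = "kendall"))
      stat <- unname(ct$estimate)
      p <- ct$p.value
    }
    tibble::tibble(statistic = stat, p = p)
  })
  dplyr::bind_cols(tibble::tibble(family_id = matrix$family_id),
                   dplyr::bind_rows(res))
}

#' Storey q-values
#'
#' Converts p-values to q-values. The proportion of true nulls
#' \eqn{\pi_0} is estimated with the Storey-Tibshirani smoother: the
#' naive estimates \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))}
#' over `lambda` are smoothed with a cubic spline (df = 3) and the fit is
#' evaluated at the largest \eqn{\lambda}, clamped to (0, 1]. q-values are
#' the step-up minima \eqn{q_{(i)} = \min_{j \ge i} \pi_0 m p_{(j)}/j}.
#' With `pi0 = 1` the result equals Benjamini-Hochberg adjusted p-values
#' exactly.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param pi0 Override for \eqn{\pi_0}; `NULL` estimates it.
#' @param lambda Grid for the \eqn{\pi_0} smoother.
#' @return Numeric vector of q-values, in the order of `p`.
#' @export
storey_qvalues <- function(p, pi0 = NULL, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort_("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  if (is.null(pi0)) {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    pi0 <- tryCatch({
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      stats::predict(fit, x = max(lambda))$y
    }, error = function(e) min(1, utils::tail(pi0_l, 1)))
    if (!is.finite(pi0) || pi0 <= 0) pi0 <- 1
    pi0 <- min(pi0, 1)
  } else {
    check_number(pi0, "pi0", lower = 0, allow_zero = FALSE)
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- pmin(1, rev(cummin(rev(q_sorted))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Pathway enrichment of significant families
#'
#' One-sided (enrichment) Fisher's exact test per pathway on the 2x2
#' table of significant/non-significant by in-pathway/out-of-pathway
#' families, with q-values from [storey_qvalues()]. Pathways with no
#' member in the universe are skipped with a message.
#'
#' @param significant Character vector of significant family ids (must be
#'   a subset of `universe`).
#' @param universe Character vector of all tested family ids.
#' @param pathway_map Tibble `pathway_id`, `family_id`.
#' @param pi0 \eqn{\pi_0} passed to [storey_qvalues()]; the default 1
#'   gives Benjamini-Hochberg behaviour, appropriate for the small number
#'   of pathways usually tested.
#' @return Tibble `pathway_id`, `n_sig`, `n_pathway`, `odds`, `p`, `q`.
#' @export
pathway_enrichment <- function(significant, universe, pathway_map, pi0 = 1) {
  if (!all(significant %in% universe)) {
    abort_("`significant` must be a subset of `universe`")
  }
  significant <- unique(significant)
  universe <- unique(universe)
  rows <- pathway_map |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(members = list(intersect(.data$family_id, universe)),
                     .groups = "drop")
  empty <- lengths(rows$members) == 0
  if (any(empty)) {
    message(sprintf("skipping %d pathway(s) with no members in the universe",
                    sum(empty)))
    rows <- rows[!empty, ]
  }
  res <- purrr::pmap(rows, function(pathway_id, members) {
    a <- length(intersect(significant, members))
    b <- length(significant) - a
    cc <- length(members) - a
    d <- length(universe) - a - b - cc
    ft <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2),
                             alternative = "greater")
    tibble::tibble(pathway_id = pathway_id, n_sig = a,
                   n_pathway = length(members),
                   odds = unname(ft$estimate), p = ft$p.value)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(pathway_id = character(), n_sig = integer(),
                          n_pathway = integer(), odds = numeric(),
                          p = numeric(), q = numeric()))
  }
  out$q <- storey_qvalues(out$p, pi0 = pi0)
  out
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Tests whether between-group dissimilarities exceed within-group
#' dissimilarities, via the pseudo-F of Anderson's method as implemented
#' by [vegan::adonis2()]. The permutation p-value is
#' \eqn{(1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})} and the result is
#' deterministic given `seed`.
#'
#' @param dist Symmetric sample-by-sample dissimilarity matrix (or
#'   `dist`) with zero diagonal.
#' @param groups Group labels, one per sample; >= 2 groups, every group of
#'   size >= 2.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return Object of class `metafam_permanova`: list with `pseudo_F`,
#'   `p`, `n_perm`, `table` (the full partition table as a tibble). Has
#'   [tidy()] and [glance()] methods.
#' @export
permanova <- function(dist, groups, n_perm = 10000, seed = 1) {
  if (!inherits(dist, "dist")) {
    dist <- as.matrix(dist)
    if (nrow(dist) != ncol(dist) || any(abs(dist - t(dist)) > 1e-12) ||
        any(abs(diag(dist)) > 1e-12)) {
      abort_("`dist` must be symmetric with a zero diagonal")
    }
    dist <- stats::as.dist(dist)
  }
  groups <- as.factor(groups)
  if (length(groups) != attr(dist, "Size")) {
    abort_("`groups` length must match the distance matrix")
  }
  if (nlevels(droplevels(groups)) < 2) abort_("need >= 2 groups")
  if (any(table(groups) < 2)) abort_("every group must have >= 2 samples")
  df <- data.frame(group = groups)
  fit <- with_seed_(seed,
                    vegan::adonis2(dist ~ group, data = df,
                                   permutations = n_perm))
  structure(list(pseudo_F = fit$F[1], p = fit$`Pr(>F)`[1], n_perm = n_perm,
                 table = tibble::as_tibble(as.data.frame(fit),
                                           rownames = "term")),
            class = "metafam_permanova")
}

#' @export
print.metafam_permanova <- function(x, ...) {
  cat(sprintf("<permanova> pseudo-F = %.4g, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$p, x$n_perm))
  invisible(x)
}

#' Principal components analysis of family abundance profiles
#'
#' Samples are the observations and families the variables. Families are
#' centered and (by default) scaled to zero mean and unit variance;
#' zero-variance families are dropped first, since they carry no
#' between-sample information and break unit-variance scaling.
#'
#' @param matrix Family-by-sample tibble (`family_id` + sample columns).
#' @param scale Scale families to unit variance (default `TRUE`).
#' @return Object of class `metafam_pca`: list with `scores` (tibble:
#'   `sample` + PC columns), `explained` (per-component fraction of
#'   variance) and `n_families` used. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
pca_profiles <- function(matrix, scale = TRUE) {
  samples <- setdiff(names(matrix), "family_id")
  if (length(samples) < 2) abort_("need >= 2 samples")
  x <- t(as.matrix(matrix[samples]))
  colnames(x) <- matrix$family_id
  v <- apply(x, 2, stats::var)
  x <- x[, v > 0, drop = FALSE]
  if (ncol(x) < 2) abort_("need >= 2 non-constant families")
  fit <- stats::prcomp(x, center = TRUE, scale. = scale)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(sample = samples),
                              tibble::as_tibble(fit$x)),
    explained = expl,
    n_families = ncol(x)),
    class = "metafam_pca")
}

#' @export
print.metafam_pca <- function(x, ...) {
  cat(sprintf("<pca> %d samples x %d families; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), x$n_families, 100 * x$explained[1],
              100 * x$explained[min(2, length(x$explained))]))
  invisible(x)
}

#' Test every family and attach q-values
#'
#' Convenience wrapper: [family_association_tests()] followed by
#' [storey_qvalues()] and a significance call at the given FDR.
#'
#' @inheritParams family_association_tests
#' @param fdr FDR threshold for the `significant` flag (default 0.10).
#' @param pi0 Passed to [storey_qvalues()].
#' @return Tibble `family_id`, `statistic`, `p`, `q`, `significant`.
#' @export
compare_families <- function(matrix, meta, covariate, fdr = 0.10,
                             pi0 = NULL) {
  res <- family_association_tests(matrix, meta, covariate)
  res$q <- storey_qvalues(res$p, pi0 = pi0)
  res$significant <- res$q <= fdr
  res
}
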