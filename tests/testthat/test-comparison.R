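test_that("prevalence filtering keeps widely observed families", {
  m <- tibble::tibble(family_id = c("A", "B", "C"),
                      s1 = c(1, 0, 2), s2 = c(2, 1, 3), s3 = c(3, 1, 0))
  expect_equal(prevalence_filter(m)$family_id, "A")       # fully observed
  expect_equal(prevalence_filter(m, "min_fraction", f = 0), m)
  expect_equal(prevalence_filter(m, "min_fraction", f = 1),
               prevalence_filter(m, "fully_observed"))
  expect_equal(prevalence_filter(m, "min_fraction", f = 2 / 3)$family_id,
               c("A", "B", "C"))
  none <- tibble::tibble(family_id = "A", s1 = 0, s2 = 0)
  expect_warning(prevalence_filter(none), "every family")
})

test_that("exact Kruskal-Wallis p-values match hand and brute-force enumeration", {
  # two separated groups of 3: 2 of C(6,3)=20 assignments are as extreme
  x <- c(1, 2, 3, 10, 11, 12)
  g <- rep(c("a", "b"), each = 3)
  expect_equal(metafam:::kw_exact_p(x, g), 0.1)
  expect_equal(metafam:::kw_exact_p(x, g), brute_kw_p(x, g))

  set.seed(21)
  for (i in 1:5) {
    n <- sample(5:8, 1)
    x <- stats::rnorm(n)
    g <- sample(rep_len(letters[1:sample(2:3, 1)], n))
    if (length(unique(g)) < 2) next
    expect_equal(metafam:::kw_exact_p(x, g), brute_kw_p(x, g),
                 tolerance = 1e-12)
  }
})

test_that("association tests dispatch on covariate type", {
  mat <- tibble::tibble(
    family_id = c("sep", "flat", "mono"),
    s1 = c(1, 5, 1), s2 = c(2, 5, 2), s3 = c(3, 5, 3),
    s4 = c(10, 5, 4), s5 = c(11, 5, 5), s6 = c(12, 5, 6))
  meta <- tibble::tibble(sample = sprintf("s%d", 1:6),
                         group = rep(c("ctl", "case"), each = 3),
                         dose = 1:6)
  cat_res <- family_association_tests(mat, meta, "group")
  expect_equal(cat_res$p[cat_res$family_id == "sep"], 0.1)   # exact, n = 6
  expect_equal(cat_res$p[cat_res$family_id == "flat"], 1)

  cont_res <- family_association_tests(mat, meta, "dose")
  expect_equal(cont_res$statistic[cont_res$family_id == "mono"], 1) # tau
  expect_lt(cont_res$p[cont_res$family_id == "mono"], 0.01)
  expect_equal(cont_res$p[cont_res$family_id == "flat"], 1)

  expect_error(family_association_tests(mat, meta, "absent"), "absent")
  expect_error(family_association_tests(mat, meta[-1, ], "group"),
               "missing sample")
})

test_that("large-sample categorical tests fall back to kruskal.test", {
  set.seed(31)
  n <- 24
  mat <- tibble::tibble(family_id = "f")
  mat[sprintf("s%02d", 1:n)] <- as.list(stats::rnorm(n))
  meta <- tibble::tibble(sample = sprintf("s%02d", 1:n),
                         group = rep(c("a", "b", "c"), each = 8))
  res <- family_association_tests(mat, meta, "group")
  x <- as.numeric(mat[1, -1])
  expect_equal(res$p, stats::kruskal.test(x, factor(meta$group))$p.value)
})

test_that("rank tests keep their nominal type-I error under the null", {
  set.seed(41)
  sm <- synth_sample_matrix(n_families = 400, n_samples = 20, n_diff = 0,
                            seed = 51)
  res <- family_association_tests(sm$matrix, sm$meta, "group")
  rate <- mean(res$p <= 0.05)
  # binomial(400, 0.05): 3.5 sigma band around 0.05
  expect_lt(abs(rate - 0.05), 3.5 * sqrt(0.05 * 0.95 / 400))
})

test_that("Storey q-values reduce to Benjamini-Hochberg when pi0 is 1", {
  expect_equal(storey_qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1),
               rep(0.04, 4))
  expect_equal(storey_qvalues(rep(0.5, 6), pi0 = 1), rep(0.5, 6))
  set.seed(61)
  for (i in 1:20) {
    p <- stats::runif(sample(5:200, 1))^sample(c(1, 2, 3), 1)
    expect_equal(storey_qvalues(p, pi0 = 1), stats::p.adjust(p, "BH"),
                 tolerance = 1e-12)
  }
  # monotone in sorted p
  p <- stats::runif(50)
  q <- storey_qvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # estimated pi0 shrinks q-values relative to BH when signal abounds
  p_sig <- c(stats::runif(300, 0, 1e-3), stats::runif(50))
  expect_true(all(storey_qvalues(p_sig) <= stats::p.adjust(p_sig, "BH") + 1e-12))
  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pathway enrichment equals brute-force hypergeometric tails", {
  universe <- sprintf("F%03d", 1:100)
  pmap <- tibble::tibble(pathway_id = "P1", family_id = universe[1:10])
  res <- pathway_enrichment(universe[1:10], universe, pmap)
  expect_equal(res$p, 1 / choose(100, 10), tolerance = 1e-12)

  # (a, b, c, d) = (5, 5, 0, 90): oracle sums the hypergeometric tail
  pmap2 <- tibble::tibble(pathway_id = "P2", family_id = universe[1:5])
  res2 <- pathway_enrichment(universe[1:10], universe, pmap2)
  tail_p <- sum(stats::dhyper(5:5, m = 5, n = 95, k = 10))
  expect_equal(res2$p, tail_p, tolerance = 1e-12)

  # random tables against dhyper summation
  set.seed(71)
  for (i in 1:20) {
    sig <- sample(universe, 15)
    members <- sample(universe, 12)
    pm <- tibble::tibble(pathway_id = "P", family_id = members)
    got <- pathway_enrichment(sig, universe, pm)$p
    a <- length(intersect(sig, members))
    oracle <- sum(stats::dhyper(a:min(15, 12), m = 12, n = 88, k = 15))
    expect_equal(got, oracle, tolerance = 1e-9)
  }

  empty <- pathway_enrichment(character(0), universe, pmap)
  expect_equal(empty$p, 1)
  expect_message(
    pathway_enrichment(universe[1:2], universe,
                       tibble::tibble(pathway_id = "PX",
                                      family_id = "not_in_universe")),
    "skipping")
  expect_error(pathway_enrichment("zzz", universe, pmap), "subset")
})

test_that("PERMANOVA separates planted clusters and is deterministic", {
  # two tight clusters, far apart
  set.seed(81)
  pts <- rbind(matrix(stats::rnorm(10, 0, 0.1), ncol = 2),
               matrix(stats::rnorm(10, 10, 0.1), ncol = 2))
  d <- as.matrix(stats::dist(pts))
  g <- rep(c("a", "b"), each = 5)
  fit <- permanova(d, g, n_perm = 999, seed = 1)
  # only permutations reproducing the planted partition can tie the
  # observed F: 2 * 5! * 5! / 10! of them, so p stays near 1/(n_perm + 1)
  expect_lt(fit$p, 0.03)
  expect_gt(fit$pseudo_F, 100)
  fit2 <- permanova(d, g, n_perm = 999, seed = 1)
  expect_identical(glance(fit), glance(fit2))

  expect_error(permanova(d, c("a", rep("b", 9)), n_perm = 99), ">= 2")
  expect_error(permanova(d[1:9, 1:9], g, n_perm = 99), "length")
  asym <- d
  asym[1, 2] <- 99
  expect_error(permanova(asym, g, n_perm = 99), "symmetric")
})

test_that("PERMANOVA p-values are uniform under a true null", {
  set.seed(91)
  ps <- vapply(1:150, function(i) {
    x <- matrix(stats::rnorm(24), ncol = 2)
    permanova(as.matrix(stats::dist(x)), rep(c("a", "b"), each = 6),
              n_perm = 199, seed = i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("PCA scales families and orders explained variance", {
  sm <- synth_sample_matrix(n_families = 30, n_samples = 10, n_diff = 10,
                            effect = 8, seed = 101)
  fit <- pca_profiles(sm$matrix)
  expect_true(all(diff(fit$explained) <= 1e-12))
  expect_lte(sum(fit$explained), 1 + 1e-9)

  # planted two-group structure separates on PC1
  grp <- sm$meta$group
  pc1 <- fit$scores$PC1
  expect_true(max(tapply(pc1, grp, min)) > min(tapply(pc1, grp, max)) ||
                abs(mean(pc1[grp == "case"]) - mean(pc1[grp == "control"])) >
                  stats::sd(pc1))

  # a duplicated sample gets identical scores
  m2 <- sm$matrix
  m2$dup <- m2$S01
  fit2 <- pca_profiles(m2)
  sc <- fit2$scores
  expect_equal(unlist(sc[sc$sample == "dup", -1]),
               unlist(sc[sc$sample == "S01", -1]))

  expect_error(pca_profiles(sm$matrix[, 1:2]), ">= 2 samples")
  const <- tibble::tibble(family_id = c("a", "b"), s1 = c(1, 1), s2 = c(1, 1))
  expect_error(pca_profiles(const), "non-constant")
})

test_that("compare_families flags planted signal at the chosen FDR", {
  sm <- synth_sample_matrix(n_families = 60, n_samples = 16, n_diff = 12,
                            effect = 6, seed = 111)
  res <- compare_families(sm$matrix, sm$meta, "group", fdr = 0.10)
  found <- res$family_id[res$significant]
  expect_gt(length(intersect(found, sm$diff_families)),
            0.6 * length(sm$diff_families))
  # false positives controlled: most discoveries are planted
  expect_lt(length(setdiff(found, sm$diff_families)), 6)
})
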