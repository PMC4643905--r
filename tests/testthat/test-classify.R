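make_orf <- function(peptide, orf_id = "r1_f+1_1",
                     read_id = sub("_f.*$", "", orf_id)) {
  tibble::tibble(orf_id = orf_id, read_id = read_id, frame = "+1",
                 aa_start = 1L, peptide = peptide)
}

test_that("the built-in aligner reproduces hand-computed scores", {
  p <- "MKVLWAAHH"
  ref <- ref_set(c(g1 = paste0("AA", cds_for(p), "TT")),
                 tibble::tibble(gene_id = "gene1", genome_id = "g1",
                                start = 3, end = 2 + nchar(cds_for(p)),
                                strand = "+", family_id = "F1", protein = p),
                 manual_taxonomy("g1"))
  # self-alignment of MKVL against the first four residues:
  # BLOSUM62 diagonal 5+5+4+4 = 18 raw
  hit <- naive_translated_align(make_orf("MKVL"), ref,
                                aligner_params(db_residues = 1000))
  expect_equal(nrow(hit), 1)
  bits_expected <- (0.267 * 18 - log(0.041)) / log(2)
  expect_equal(hit$bit_score, bits_expected, tolerance = 1e-9)
  expect_equal(hit$bit_score, 11.53, tolerance = 2e-3)
  expect_equal(hit$e_value, 1000 * 4 * 2^(-bits_expected), tolerance = 1e-9)
  expect_equal(hit$sstart, 1L)
  expect_equal(hit$send, 4L)
  expect_equal(hit$family_id, "F1")

  # no positive-scoring pair -> no hit (P vs W scores -4 in BLOSUM62)
  none <- naive_translated_align(make_orf("PPPP"),
                                 ref_set(c(g1 = paste0("AA", cds_for("WWWW"),
                                                       "TT")),
                                         tibble::tibble(
                                           gene_id = "w", genome_id = "g1",
                                           start = 3, end = 17, strand = "+",
                                           family_id = "FW",
                                           protein = "WWWW"),
                                         manual_taxonomy("g1")),
                                 aligner_params())
  expect_equal(nrow(none), 0)

  expect_error(naive_translated_align(make_orf("MK*VL"), ref),
               "stop symbols")
})

test_that("the k-mer seed prefilter only prunes, never invents hits", {
  ref <- medium_pipeline()$ref
  orfs <- medium_pipeline()$orfs[1:40, ]
  full <- naive_translated_align(orfs, ref, aligner_params())
  seeded <- naive_translated_align(orfs, ref, aligner_params(seed_k = 6))
  key <- function(h) paste(h$query_id, h$target_gene)
  expect_true(all(key(seeded) %in% key(full)))
  shared <- dplyr::inner_join(seeded, full,
                              by = c("query_id", "target_gene"))
  expect_equal(shared$bit_score.x, shared$bit_score.y)
})

test_that("m8 parsing handles both dialects and validates", {
  ref <- manual_ref()
  f <- withr::local_tempfile(fileext = ".m8")
  line <- function(q, s, ev, bits) {
    paste(q, s, "98.5", "9", "0", "0", "1", "9", "1", "9", ev, bits,
          sep = "\t")
  }
  writeLines(c("# comment", line("r1_f+1_1", "g1_a", "1e-5", "42.1")), f)
  hits <- parse_tabular_alignments(f, "blast", ref)
  expect_equal(hits$e_value, 1e-5)
  expect_equal(hits$bit_score, 42.1)
  expect_equal(hits$read_id, "r1")
  expect_equal(hits$family_id, "F1")
  expect_equal(hits$send - hits$sstart + 1L, 9L)   # X_k span arithmetic

  # rapsearch2: column 11 is log10(E)
  writeLines(line("r1_f-2_3", "g1_b", "-5", "42.1"), f)
  rs <- parse_tabular_alignments(f, "rapsearch2", ref)
  expect_equal(rs$e_value, 1e-5)
  expect_equal(rs$read_id, "r1")

  writeLines(line("r1_f+1_1", "gene_unknown", "1e-5", "40"), f)
  expect_error(parse_tabular_alignments(f, "blast", ref), "gene_unknown")
  expect_warning(
    out <- parse_tabular_alignments(f, "blast", ref, allow_unmapped = TRUE),
    "skipping")
  expect_equal(nrow(out), 0)

  writeLines(paste(c("q", "g1_a", rep("x", 10)), collapse = "\t"), f)
  expect_error(parse_tabular_alignments(f, "blast", ref), "line")
})

test_that("clade exclusion removes taxon-sharing targets with nested sets", {
  ref <- synth_reference_set(n_genomes = 4, genes_per_genome = 6, seed = 13)
  gids <- names(ref$genomes)
  # one hit from a read of each genome against every genome
  hits <- tidyr::expand_grid(src = gids, tgt = gids) |>
    dplyr::mutate(query_id = paste0("read_", src, "_f+1_1"),
                  read_id = paste0("read_", src),
                  target_gene = ref$genes$gene_id[
                    match(tgt, ref$genes$genome_id)],
                  target_genome = tgt,
                  family_id = "F", bit_score = 50, e_value = 1e-9,
                  aln_len = 30L, sstart = 1L, send = 30L,
                  identity_pct = 100)
  src_map <- stats::setNames(gids, paste0("read_", gids))

  at_strain <- clade_exclude(hits, ref, "strain", src_map)
  expect_true(all(at_strain$target_genome != at_strain$src))
  expect_equal(nrow(hits) - nrow(at_strain), length(gids))

  # genus groups genomes pairwise: each read loses hits to its genus pair
  at_genus <- clade_exclude(hits, ref, "genus", src_map)
  expect_equal(nrow(hits) - nrow(at_genus), 2 * length(gids))

  # nesting: excluded(strain) subset of excluded(genus) subset of excluded(phylum)
  key <- function(h) paste(h$read_id, h$target_gene)
  expect_true(all(setdiff(key(hits), key(at_strain)) %in%
                    setdiff(key(hits), key(at_genus))))
  at_phylum <- clade_exclude(hits, ref, "phylum", src_map)
  expect_true(all(setdiff(key(hits), key(at_genus)) %in%
                    setdiff(key(hits), key(at_phylum))))
  expect_equal(nrow(at_phylum), 0)   # single synthetic phylum

  expect_error(clade_exclude(hits, ref, "genus",
                             src_map[-1]), "unknown source")
})

test_that("classification picks deterministic winners under thresholds", {
  hit <- function(q, read, fam, bits, ev = 1e-6, gene = paste0("g_", fam)) {
    tibble::tibble(query_id = q, read_id = read, target_gene = gene,
                   target_genome = "g1", family_id = fam, bit_score = bits,
                   e_value = ev, aln_len = 20L, sstart = 1L, send = 20L,
                   identity_pct = 100)
  }
  hits <- dplyr::bind_rows(hit("rA_f+1_1", "rA", "F1", 40),
                           hit("rA_f+2_1", "rA", "F2", 38))
  per_read <- classify_hits(hits, "per_read", min_bits = 35)
  expect_equal(nrow(per_read), 1)
  expect_equal(per_read$family_id, "F1")
  per_orf <- classify_hits(hits, "per_orf", min_bits = 35)
  expect_equal(sort(per_orf$family_id), c("F1", "F2"))

  expect_equal(nrow(classify_hits(hits, "per_read", min_bits = 41)), 0)
  # threshold is inclusive: a 40-bit hit survives min_bits = 40
  expect_equal(nrow(classify_hits(hits, "per_read", min_bits = 40)), 1)

  ties <- dplyr::bind_rows(hit("rB_f+1_1", "rB", "F1", 40, ev = 1e-5),
                           hit("rB_f+2_1", "rB", "F2", 40, ev = 1e-6))
  expect_equal(classify_hits(ties, "per_read", min_bits = 0)$family_id, "F2")
  ties2 <- dplyr::bind_rows(
    hit("rC_f+1_1", "rC", "F1", 40, gene = "g_b"),
    hit("rC_f+2_1", "rC", "F2", 40, gene = "g_a"))
  expect_equal(classify_hits(ties2, "per_read", min_bits = 0)$target_gene,
               "g_a")

  expect_error(classify_hits(hits, "per_read"), "at least one")
  # e-value thresholding alone also works
  expect_equal(nrow(classify_hits(hits, "per_orf", max_evalue = 1e-7)), 0)
})

test_that("classification count is monotone in the threshold and mode", {
  hits <- medium_pipeline()$hits
  grid <- c(10, 20, 30, 40, 60)
  n_read <- vapply(grid, function(t) {
    nrow(classify_hits(hits, "per_read", min_bits = t))
  }, numeric(1))
  n_orf <- vapply(grid, function(t) {
    nrow(classify_hits(hits, "per_orf", min_bits = t))
  }, numeric(1))
  expect_true(all(diff(n_read) <= 0))
  expect_true(all(diff(n_orf) <= 0))
  expect_true(all(n_read <= n_orf))
})

test_that("default bit-score thresholds interpolate the anchor table", {
  expect_equal(default_bitscore_threshold(100), 31)
  expect_equal(default_bitscore_threshold(250), 35)
  expect_equal(default_bitscore_threshold(175), 33)
  expect_warning(lo <- default_bitscore_threshold(50), "extrapolation")
  expect_equal(lo, 31)
  expect_warning(hi <- default_bitscore_threshold(3000), "extrapolation")
  expect_equal(hi, 35)
  expect_error(default_bitscore_threshold(10), "read_length")
})
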