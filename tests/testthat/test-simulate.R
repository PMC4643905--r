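test_that("read allocation is proportional to genome coverage", {
  ref <- synth_reference_set(n_genomes = 2, genes_per_genome = 8, seed = 5)
  comm <- stats::setNames(c(3, 1), names(ref$genomes))
  reads <- simulate_reads(ref, comm, n_reads = 1000, read_length = 101,
                          model = error_model("error_free"), seed = 9)
  n1 <- sum(reads$truth_genome == names(ref$genomes)[1])
  # binomial(1000, 0.75): mean 750, sd ~13.7; 4 sigma band
  expect_lt(abs(n1 - 750), 4 * sqrt(1000 * 0.75 * 0.25))
})

test_that("error-free reads are exact substrings of their source genome", {
  ref <- synth_reference_set(n_genomes = 2, genes_per_genome = 5, seed = 2)
  reads <- simulate_reads(ref, stats::setNames(c(1, 1), names(ref$genomes)),
                          n_reads = 50, read_length = 80,
                          model = error_model("error_free"), seed = 4)
  for (i in seq_len(nrow(reads))) {
    src <- substr(ref$genomes[[reads$truth_genome[i]]],
                  reads$truth_start[i], reads$truth_start[i] + 79L)
    if (reads$truth_strand[i] == "-") src <- revcomp_chr(src)
    expect_identical(reads$seq[i], src)
  }
})

test_that("simulation is deterministic given the seed", {
  ref <- synth_reference_set(n_genomes = 2, genes_per_genome = 5, seed = 2)
  comm <- stats::setNames(c(2, 1), names(ref$genomes))
  r1 <- simulate_reads(ref, comm, 100, 101, error_model("uniform"), seed = 77)
  r2 <- simulate_reads(ref, comm, 100, 101, error_model("uniform"), seed = 77)
  expect_identical(r1, r2)
  r3 <- simulate_reads(ref, comm, 100, 101, error_model("uniform"), seed = 78)
  expect_false(identical(r1$seq, r3$seq))
})

test_that("degenerate simulation inputs are rejected", {
  ref <- synth_reference_set(n_genomes = 1, genes_per_genome = 2, seed = 3)
  comm <- stats::setNames(1, names(ref$genomes))
  expect_error(simulate_reads(ref, comm, 0, 101), "n_reads")
  expect_error(simulate_reads(ref, comm, 10, 10), "read_length")
  expect_error(simulate_reads(ref, comm, 10, 1e6), "shorter")
})

test_that("mutate_sequence honours the error model", {
  s <- strrep("ACGT", 50)
  expect_identical(mutate_sequence(s, error_model("error_free")), s)
  expect_identical(mutate_sequence(s, error_model("uniform", rate = 0)), s)

  # forced substitutions: rate 1 with an overwhelming sub:indel ratio
  set.seed(1)
  m <- mutate_sequence(s, error_model("uniform", rate = 1,
                                      sub_indel_ratio = 1e12))
  expect_equal(nchar(m), nchar(s))
  expect_true(all(strsplit(m, "")[[1]] != strsplit(s, "")[[1]]))

  expect_error(error_model("uniform", rate = 1.5), "\\[0, 1\\]")
  expect_error(mutate_sequence("acgt", error_model("uniform")), "uppercase")
})

test_that("per-position probabilities follow the model definitions", {
  # linear: 1% at the first base to 2% at the last
  p_lin <- metafam:::error_probs(error_model("linear"), 101)
  expect_equal(p_lin[1], 0.01)
  expect_equal(p_lin[101], 0.02)
  expect_equal(p_lin[51], 0.015)
  # poly4 percent convention at position 100
  p4 <- metafam:::error_probs(error_model("poly4"), 100)
  expect_equal(p4[100], (3e-3 + 3.3e-8 * 100^4) / 100)
  expect_equal(p4[100], 0.03303, tolerance = 1e-9)
  # the polynomial eventually exceeds 1 and must be refused
  expect_error(metafam:::error_probs(error_model("poly4"), 1500),
               "probability > 1")
})

test_that("observed per-base error rate matches the uniform model", {
  ref <- synth_reference_set(n_genomes = 1, genes_per_genome = 10, seed = 6)
  comm <- stats::setNames(1, names(ref$genomes))
  clean <- simulate_reads(ref, comm, 2000, 101, error_model("error_free"),
                          seed = 21)
  set.seed(22)
  noisy <- mutate_sequence(clean$seq,
                           error_model("uniform", rate = 0.01,
                                       sub_indel_ratio = 1e12))
  mism <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, clean$seq, noisy)
  rate <- sum(mism) / sum(nchar(clean$seq))
  expect_equal(rate, 0.01, tolerance = 0.15)
})

test_that("read start positions are uniform over a single genome", {
  ref <- synth_reference_set(n_genomes = 1, genes_per_genome = 20, seed = 8)
  comm <- stats::setNames(1, names(ref$genomes))
  reads <- simulate_reads(ref, comm, 2e4, 101, error_model("error_free"),
                          seed = 31)
  n_pos <- nchar(ref$genomes[[1]]) - 101 + 1
  bins <- cut(reads$truth_start, breaks = seq(0, n_pos, length.out = 21))
  p <- stats::chisq.test(table(bins))$p.value
  expect_gt(p, 0.01)
  # strands are balanced
  expect_gt(stats::binom.test(sum(reads$truth_strand == "+"),
                              nrow(reads))$p.value, 0.001)
})

test_that("homopolymer model only perturbs run lengths", {
  set.seed(5)
  s <- "AAAACCCGGTTTTTTTT"
  m <- mutate_sequence(s, error_model("homopolymer"))
  r <- rle(strsplit(m, "")[[1]])
  # run order of surviving bases is a subsequence of the original
  expect_true(all(r$values %in% c("A", "C", "G", "T")))
  expect_lte(length(r$values), 4)
})

test_that("shuffling preserves composition and clears truth", {
  ref <- synth_reference_set(n_genomes = 1, genes_per_genome = 4, seed = 9)
  reads <- simulate_reads(ref, stats::setNames(1, names(ref$genomes)),
                          20, 101, error_model("error_free"), seed = 1)
  shuf <- shuffle_reads(reads, seed = 2)
  expect_identical(shuf$read_id, reads$read_id)
  expect_true(all(is.na(shuf$truth_genome)))
  for (i in seq_len(nrow(reads))) {
    expect_identical(sort(strsplit(shuf$seq[i], "")[[1]]),
                     sort(strsplit(reads$seq[i], "")[[1]]))
  }
  expect_identical(shuffle_reads(reads, seed = 2)$seq, shuf$seq)
  one <- reads[1, ]
  one$seq <- "AAAA"
  expect_identical(shuffle_reads(one, seed = 3)$seq, "AAAA")
})

test_that("reads round-trip through FASTA and FASTQ with truth", {
  ref <- synth_reference_set(n_genomes = 1, genes_per_genome = 3, seed = 10)
  reads <- simulate_reads(ref, stats::setNames(1, names(ref$genomes)),
                          10, 101, error_model("error_free"), seed = 1)
  fa <- withr::local_tempfile(fileext = ".fa")
  fq <- withr::local_tempfile(fileext = ".fq")
  tr <- withr::local_tempfile(fileext = ".tsv")
  write_reads(reads, fa, truth_path = tr)
  write_reads(reads, fq, format = "fastq")
  back <- read_reads(fa)
  expect_equal(back$seq, reads$seq)
  expect_equal(back$truth_genome, reads$truth_genome)
  expect_equal(back$truth_start, reads$truth_start)
  backq <- read_reads(fq, format = "fastq")
  expect_equal(backq$seq, reads$seq)
  truth <- readr::read_tsv(tr, show_col_types = FALSE)
  expect_equal(truth$read_id, reads$read_id)
})
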