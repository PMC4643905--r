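# Hand-buildable fixtures used across test files.

# deterministic reverse translation: always the alphabetically first codon
cds_for <- function(protein, stop_codon = "TAA") {
  gc_tab <- Biostrings::GENETIC_CODE
  first_codon <- vapply(split(names(gc_tab), unname(gc_tab)),
                        function(x) sort(x)[1], character(1))
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste0(paste(first_codon[aa], collapse = ""), stop_codon)
}

# two genomes, hand-placed genes: g1 carries F1 x2 + F2 x1, g2 carries F1 x1.
# Proteins are fixed so expected abundances can be evaluated by hand.
manual_ref <- function() {
  p1 <- "MKVLWAAHH"   # family F1, 9 aa
  p2 <- "MGGDEEYYCC" # family F2, 10 aa
  cds1 <- cds_for(p1)
  cds2 <- cds_for(p2)
  pad <- "ACGTACGTAC"
  g1 <- paste0(pad, cds1, pad, cds2, pad, cds1, pad)
  g2 <- paste0(pad, cds1, pad)
  st1 <- nchar(pad) + 1L
  genes <- tibble::tibble(
    gene_id = c("g1_a", "g1_b", "g1_c", "g2_a"),
    genome_id = c("g1", "g1", "g1", "g2"),
    start = c(st1,
              st1 + nchar(cds1) + nchar(pad),
              st1 + nchar(cds1) + nchar(cds2) + 2L * nchar(pad),
              st1),
    end = NA_integer_,
    strand = "+",
    family_id = c("F1", "F2", "F1", "F1"),
    protein = c(p1, p2, p1, p1))
  genes$end <- genes$start + nchar(c(cds1, cds2, cds1, cds1)) - 1L
  ref_set(c(g1 = g1, g2 = g2), genes, manual_taxonomy(c("g1", "g2")))
}

manual_taxonomy <- function(genome_ids) {
  n <- length(genome_ids)
  tibble::tibble(genome_id = genome_ids,
                 strain = genome_ids,
                 species = paste0("sp", seq_len(n)),
                 genus = paste0("gen", ceiling(seq_len(n) / 2)),
                 family = "famA", order = "ordA", class = "clsA",
                 phylum = "phyA")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# reference with genes of known length: F1 100 aa (gA), F2 200 aa (gB),
# F3 100 aa (gC); used wherever gene-length normalization must be checked
# by hand
two_gene_ref <- function() {
  p100 <- strrep("MKVLWAAHHG", 10)
  p200 <- strrep("MGGDEEYYCC", 20)
  p100b <- strrep("MFFNNQQRRS", 10)
  cds <- lapply(list(p100, p200, p100b), cds_for)
  pad <- "ACGTACGTAC"
  starts <- integer(3)
  genome <- pad
  for (i in 1:3) {
    starts[i] <- nchar(genome) + 1L
    genome <- paste0(genome, cds[[i]], pad)
  }
  genes <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"), genome_id = "g1",
    start = starts,
    end = starts + vapply(cds, nchar, integer(1)) - 1L,
    strand = "+",
    family_id = c("F1", "F2", "F3"),
    protein = c(p100, p200, p100b))
  ref_set(c(g1 = genome), genes, manual_taxonomy("g1"))
}

cls_row <- function(unit, read, fam, gene, sstart = 1L, send = 10L) {
  tibble::tibble(unit_id = unit, read_id = read, family_id = fam,
                 bit_score = 50, e_value = 1e-9, target_gene = gene,
                 sstart = sstart, send = send, mode = "per_read")
}

# minimal normalized profile tibble
prof <- function(...) {
  v <- c(...)
  metafam::relative_normalize(tibble::tibble(family_id = names(v),
                                             abundance = unname(v)))
}

# random normalized profile over a family universe
random_profile <- function(n_fam = 8, universe = sprintf("F%02d", 1:20)) {
  fams <- sample(universe, n_fam)
  prof(stats::setNames(stats::runif(n_fam), fams))
}

# full-permutation oracle for the exact Kruskal-Wallis p-value
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (i in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = i - 1L)
    }
  }
  out
}

brute_kw_p <- function(x, g) {
  obs <- metafam:::kw_stat(x, g)
  stats <- vapply(all_perms(length(x)),
                  function(p) metafam:::kw_stat(x[p], g), numeric(1))
  mean(stats >= obs - 1e-12)
}

# cached medium synthetic pipeline shared by slower tests
medium_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- synth_reference_set(n_genomes = 4, genes_per_genome = 10,
                                 gene_len_aa = c(120, 180), seed = 42)
      comm <- synth_community(ref, seed = 43)
      reads <- simulate_reads(ref, comm, n_reads = 2000, read_length = 101,
                              model = error_model("error_free"), seed = 44)
      orfs <- predict_orfs(reads)
      hits <- naive_translated_align(orfs, ref, aligner_params(seed_k = 6))
      cache <<- list(ref = ref, comm = comm, reads = reads, orfs = orfs,
                     hits = hits,
                     expected = expected_family_abundance(comm, ref))
    }
    cache
  }
})
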