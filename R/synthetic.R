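# Synthetic reference sets, communities and sample matrices.
#
# These generators emulate the structure the pipeline consumes in real use:
# annotated genomes whose protein-coding genes carry family labels (so family
# copy numbers are known exactly), community coverage profiles with a skewed
# species-abundance distribution, and family-by-sample matrices with planted
# group effects. They exist so that every downstream computation can be
# benchmarked against known truth without any external database.

aa_alphabet <- function() {
  c("A","R","N","D","C","Q","E","G","H","I",
    "L","K","M","F","P","S","T","W","Y","V")
}

# aa -> matrix of synonymous codons (NA-padded), for fast reverse translation
codon_choices <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc_tab <- Biostrings::GENETIC_CODE
      by_aa <- split(names(gc_tab), unname(gc_tab))
      width <- max(lengths(by_aa))
      m <- matrix(NA_character_, nrow = length(by_aa), ncol = width,
                  dimnames = list(names(by_aa), NULL))
      for (aa in names(by_aa)) m[aa, seq_along(by_aa[[aa]])] <- by_aa[[aa]]
      cache <<- list(mat = m, n = lengths(by_aa))
    }
    cache
  }
})

random_protein <- function(len) {
  paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
}

# reverse-translate a protein with uniformly random synonymous codons
reverse_translate <- function(protein) {
  cc <- codon_choices()
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  k <- cc$n[aa]
  pick <- floor(stats::runif(length(aa)) * k) + 1L
  paste(cc$mat[cbind(match(aa, rownames(cc$mat)), pick)], collapse = "")
}

#' Generate a synthetic annotated reference set
#'
#' Builds toy genomes with planted protein-coding genes. Each protein family
#' has one canonical amino-acid sequence; each genome draws its genes from
#' the family pool *with replacement*, so per-genome copy numbers vary
#' naturally. Gene nucleotide sequences are independent synonymous
#' reverse-translations of the family protein followed by a stop codon, laid
#' down on a random strand and separated by short random intergenic spacers.
#' Genomes are therefore almost entirely coding, which makes the expected
#' family profile an accurate description of where simulated reads land.
#'
#' Defaults give 10 genomes of ~50 genes each over a pool of 100 families
#' with gene lengths of 150-250 amino acids, the scale used throughout the
#' package's own benchmarks.
#'
#' @param n_genomes,genes_per_genome Number of genomes and genes per genome.
#' @param n_families Size of the family pool genes are drawn from.
#' @param gene_len_aa Length-2 integer range of protein lengths (aa).
#' @param intergenic_len Length of random spacer between genes (nt).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A [ref_set()]. Taxonomy nests genomes pairwise into genera and
#'   onward up the ranks, so clade exclusion at increasing rank removes
#'   nested supersets of reference genomes.
#' @export
synth_reference_set <- function(n_genomes = 10, genes_per_genome = 50,
                                n_families = 2 * genes_per_genome,
                                gene_len_aa = c(150, 250),
                                intergenic_len = 10, seed = 1) {
  with_seed_(seed, {
    fam_ids <- sprintf("F%04d", seq_len(n_families))
    fam_len <- sample(gene_len_aa[1]:gene_len_aa[2], n_families, replace = TRUE)
    fam_prot <- vapply(fam_len, random_protein, character(1))
    names(fam_prot) <- fam_ids

    stops <- c("TAA", "TAG", "TGA")
    genomes <- character(n_genomes)
    names(genomes) <- sprintf("G%02d", seq_len(n_genomes))
    gene_rows <- vector("list", n_genomes)

    for (j in seq_len(n_genomes)) {
      fams <- sample(fam_ids, genes_per_genome, replace = TRUE)
      cds <- vapply(fam_prot[fams], reverse_translate, character(1))
      cds <- paste0(cds, sample(stops, genes_per_genome, replace = TRUE))
      strand <- sample(c("+", "-"), genes_per_genome, replace = TRUE)
      placed <- ifelse(strand == "-", revcomp(cds), cds)
      spacer <- vapply(rep(intergenic_len, genes_per_genome + 1L),
                       function(n) paste(sample(c("A", "C", "G", "T"), n,
                                                replace = TRUE), collapse = ""),
                       character(1))
      widths <- nchar(placed)
      starts <- intergenic_len + 1L +
        cumsum(c(0L, (widths + intergenic_len)[-genes_per_genome]))
      genomes[j] <- paste0(paste0(spacer[-length(spacer)], placed,
                                  collapse = ""), spacer[length(spacer)])
      gene_rows[[j]] <- tibble::tibble(
        gene_id = sprintf("%s_g%03d", names(genomes)[j], seq_len(genes_per_genome)),
        genome_id = names(genomes)[j],
        start = starts, end = starts + widths - 1L,
        strand = strand, family_id = fams,
        protein = unname(fam_prot[fams]))
    }

    idx <- seq_len(n_genomes)
    taxonomy <- tibble::tibble(
      genome_id = names(genomes),
      strain = names(genomes),
      species = sprintf("sp%02d", idx),
      genus = sprintf("gen%02d", ceiling(idx / 2)),
      family = sprintf("fam%02d", ceiling(idx / 4)),
      order = sprintf("ord%02d", ceiling(idx / 8)),
      class = sprintf("cls%02d", ceiling(idx / 16)),
      phylum = sprintf("phy%02d", ceiling(idx / 32)))

    ref_set(genomes, dplyr::bind_rows(gene_rows), taxonomy)
  })
}

#' Generate a synthetic community coverage profile
#'
#' Draws genome coverages from a log-normal species-abundance distribution
#' (`sdlog = 1`), the canonical skewed shape of real community profiles.
#'
#' @param ref A [ref_set()].
#' @param seed Integer seed.
#' @param sdlog Log-scale standard deviation of the coverage distribution.
#' @return A community tibble (`genome_id`, `coverage`).
#' @export
synth_community <- function(ref, seed = 1, sdlog = 1) {
  stopifnot(inherits(ref, "ref_set"))
  with_seed_(seed, {
    tibble::tibble(genome_id = names(ref$genomes),
                   coverage = stats::rlnorm(length(ref$genomes),
                                            meanlog = 0, sdlog = sdlog))
  })
}

#' Generate a synthetic pathway membership map
#'
#' Assigns each family to exactly one pathway (a partition), the simplest
#' structure exercising enrichment tests.
#'
#' @param family_ids Character vector of family ids (the universe).
#' @param n_pathways Number of pathways.
#' @param seed Integer seed.
#' @return A tibble (`pathway_id`, `family_id`).
#' @export
synth_pathway_map <- function(family_ids, n_pathways = 10, seed = 1) {
  with_seed_(seed, {
    tibble::tibble(
      pathway_id = sprintf("P%02d", sample.int(n_pathways,
                                               length(family_ids),
                                               replace = TRUE)),
      family_id = family_ids) |>
      dplyr::arrange(.data$pathway_id, .data$family_id)
  })
}

#' Generate a synthetic family-by-sample abundance matrix
#'
#' Log-normal family abundances across samples with a planted fold-change in
#' a subset of families for the non-reference groups, plus a sample metadata
#' table carrying the group label and a continuous covariate correlated with
#' it. Used to exercise the per-family association tests, q-values,
#' enrichment, ordination and PERMANOVA.
#'
#' @param n_families,n_samples Matrix dimensions.
#' @param groups Character vector of group labels recycled across samples.
#' @param n_diff Number of differentially abundant families.
#' @param effect Multiplicative effect applied to differential families in
#'   non-reference groups.
#' @param seed Integer seed.
#' @return A list with `matrix` (tibble: `family_id` + one column per
#'   sample), `meta` (tibble: `sample`, `group`, `covariate`), and
#'   `diff_families` (character vector of the planted signal).
#' @export
synth_sample_matrix <- function(n_families = 50, n_samples = 12,
                                groups = c("control", "case"),
                                n_diff = 10, effect = 3, seed = 1) {
  with_seed_(seed, {
    fam <- sprintf("F%04d", seq_len(n_families))
    samp <- sprintf("S%02d", seq_len(n_samples))
    grp <- rep_len(groups, n_samples)
    base <- stats::rlnorm(n_families, meanlog = 2, sdlog = 0.5)
    vals <- matrix(stats::rlnorm(n_families * n_samples,
                                 meanlog = log(base), sdlog = 0.3),
                   nrow = n_families)
    diff_fam <- sample(fam, min(n_diff, n_families))
    bump <- which(grp != groups[1])
    vals[match(diff_fam, fam), bump] <- vals[match(diff_fam, fam), bump] * effect
    colnames(vals) <- samp
    list(matrix = dplyr::bind_cols(tibble::tibble(family_id = fam),
                                   tibble::as_tibble(vals)),
         meta = tibble::tibble(sample = samp, group = grp,
                               covariate = as.numeric(grp != groups[1]) +
                                 stats::rnorm(n_samples, sd = 0.5)),
         diff_families = diff_fam)
  })
}
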