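#' Construct an annotated reference set
#'
#' A reference set bundles the three pieces of information the rest of the
#' pipeline needs about the organisms that may occur in a community: the
#' genome sequences themselves, a table of annotated protein-coding genes
#' (each assigned to a protein family), and a seven-rank taxonomic lineage
#' per genome. Family copy numbers are never supplied directly; they are
#' always derived by counting gene records, so the gene table is the single
#' source of truth.
#'
#' @param genomes Named character vector of nucleotide sequences, one per
#'   genome; names are genome ids.
#' @param genes Data frame with columns `gene_id`, `genome_id`, `start`,
#'   `end` (1-based inclusive nucleotide coordinates), `strand` (`"+"` or
#'   `"-"`), `family_id`, and optionally `protein` (amino-acid sequence).
#'   Genes lacking a protein string get one by translating their coding
#'   span; their `length_aa` is `floor(span/3)`, otherwise
#'   `nchar(protein)`.
#' @param taxonomy Data frame with columns `genome_id`, `strain`,
#'   `species`, `genus`, `family`, `order`, `class`, `phylum`; every rank
#'   must be non-empty.
#'
#' @return An object of class `ref_set`: a list with elements `genomes`
#'   (named character), `genes` (tibble, with `length_aa` filled in) and
#'   `taxonomy` (tibble).
#' @seealso [load_reference_set()] to read the same structure from files,
#'   [synth_reference_set()] to generate one.
#' @export
ref_set <- function(genomes, genes, taxonomy) {
  if (is.null(names(genomes)) || any(!nzchar(names(genomes)))) {
    abort_("`genomes` must be a named character vector of sequences")
  }
  genes <- tibble::as_tibble(genes)
  taxonomy <- tibble::as_tibble(taxonomy)
  needed <- c("gene_id", "genome_id", "start", "end", "strand", "family_id")
  missing_cols <- setdiff(needed, names(genes))
  if (length(missing_cols)) {
    abort_(paste0("gene table is missing columns: ",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"protein" %in% names(genes)) genes$protein <- NA_character_
  genes$protein[!is.na(genes$protein) & !nzchar(genes$protein)] <- NA_character_

  bad <- setdiff(genes$genome_id, names(genomes))
  if (length(bad)) {
    offender <- genes$gene_id[match(bad[1], genes$genome_id)]
    abort_(sprintf(
      "gene '%s' references genome '%s' which is not in `genomes`",
      offender, bad[1]))
  }
  if (any(genes$end < genes$start)) {
    abort_("gene table contains records with end < start")
  }
  glen <- nchar(genomes)[match(genes$genome_id, names(genomes))]
  if (any(genes$start < 1L | genes$end > glen)) {
    abort_("gene coordinates fall outside their genome sequence")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort_("gene strand must be '+' or '-'")
  }
  if (any(is.na(genes$family_id) | !nzchar(genes$family_id))) {
    abort_("every gene must carry a non-empty family_id")
  }
  if (anyDuplicated(genes$gene_id)) abort_("gene ids must be unique")

  ranks <- c("strain", "species", "genus", "family", "order", "class", "phylum")
  missing_rank <- setdiff(c("genome_id", ranks), names(taxonomy))
  if (length(missing_rank)) {
    abort_(paste0("taxonomy lineage must have exactly 7 ranks; missing: ",
                  paste(missing_rank, collapse = ", ")))
  }
  tax_vals <- as.matrix(taxonomy[ranks])
  if (any(is.na(tax_vals) | !nzchar(tax_vals))) {
    abort_("taxonomy lineage must have exactly 7 non-empty ranks per genome")
  }

  # length in amino acids: supplied protein wins, else floor(span/3)
  span <- genes$end - genes$start + 1L
  genes$length_aa <- ifelse(is.na(genes$protein),
                            span %/% 3L, nchar(genes$protein))

  fill <- which(is.na(genes$protein))
  if (length(fill)) {
    genes$protein[fill] <- translate_span(
      genomes[genes$genome_id[fill]],
      genes$start[fill], genes$end[fill], genes$strand[fill])
  }
  if (any(grepl("*", genes$protein, fixed = TRUE))) {
    abort_("gene proteins must not contain internal stop symbols")
  }

  structure(
    list(genomes = genomes,
         genes = genes[c("gene_id", "genome_id", "start", "end", "strand",
                         "family_id", "protein", "length_aa")],
         taxonomy = taxonomy[c("genome_id", ranks)]),
    class = "ref_set")
}

# translate a coding span on the given strand; trailing stop stripped
translate_span <- function(genome_seq, start, end, strand) {
  sub <- substr(genome_seq, start, end)
  sub[strand == "-"] <- revcomp(sub[strand == "-"])
  sub <- substr(sub, 1L, (nchar(sub) %/% 3L) * 3L)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(sub), if.fuzzy.codon = "X"))
  unname(sub("\\*$", "", aa))
}

#' @export
print.ref_set <- function(x, ...) {
  cat(sprintf("<ref_set> %d genome(s), %d gene(s), %d famil(ies)\n",
              length(x$genomes), nrow(x$genes),
              dplyr::n_distinct(x$genes$family_id)))
  invisible(x)
}

#' Read a reference set from files
#'
#' Reads a genome FASTA, a tab-separated gene table and a tab-separated
#' taxonomy table and cross-links them into a [ref_set()]. The gene table
#' must have the header
#' `gene_id genome_id start end strand family_id protein` (the `protein`
#' column may be empty, in which case proteins are derived by translating
#' the coding span); the taxonomy table has the header
#' `genome_id strain species genus family order class phylum`.
#'
#' @param genomes_path Path to a nucleotide FASTA of genome sequences.
#' @param genes_path Path to the gene table (TSV).
#' @param taxonomy_path Path to the lineage table (TSV).
#' @return A [ref_set()].
#' @export
load_reference_set <- function(genomes_path, genes_path, taxonomy_path) {
  seqs <- Biostrings::readDNAStringSet(genomes_path)
  genomes <- as.character(seqs)
  names(genomes) <- sub("\\s.*$", "", names(seqs))
  genes <- readr::read_tsv(genes_path, show_col_types = FALSE,
                           col_types = readr::cols(
                             start = readr::col_integer(),
                             end = readr::col_integer(),
                             .default = readr::col_character()))
  taxonomy <- readr::read_tsv(taxonomy_path, show_col_types = FALSE,
                              col_types = readr::cols(.default = readr::col_character()))
  ref_set(genomes, genes, taxonomy)
}

#' Coerce a community abundance specification to a tibble
#'
#' A community profile records the coverage `A_j` of each genome: the
#' (relative) abundance of the genome in the community, on the scale of
#' mapped reads per genome-length unit. Accepts a named numeric vector or a
#' two-column data frame.
#'
#' @param x Named numeric vector of coverages, or data frame with columns
#'   `genome_id` and `coverage`.
#' @return A tibble with columns `genome_id`, `coverage`.
#' @export
as_community <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- tibble::tibble(genome_id = names(x), coverage = unname(x))
  }
  x <- tibble::as_tibble(x)
  if (!all(c("genome_id", "coverage") %in% names(x))) {
    abort_("community must have columns `genome_id` and `coverage`")
  }
  if (any(!is.finite(x$coverage) | x$coverage < 0)) {
    abort_("community coverages must be finite and >= 0")
  }
  if (!any(x$coverage > 0)) {
    abort_("community must contain at least one genome with coverage > 0")
  }
  x[c("genome_id", "coverage")]
}

new_fam_profile <- function(family_id, abundance, flavor, normalized,
                            provenance = character()) {
  out <- tibble::tibble(family_id = as.character(family_id),
                        abundance = as.numeric(abundance))
  out <- dplyr::arrange(out, .data$family_id)
  structure(out,
            class = c("fam_profile", class(tibble::tibble())),
            flavor = flavor, normalized = normalized,
            provenance = provenance)
}

#' @export
print.fam_profile <- function(x, ...) {
  cat(sprintf("<fam_profile> flavor=%s normalized=%s, %d families\n",
              attr(x, "flavor") %||% "?",
              isTRUE(attr(x, "normalized")), nrow(x)))
  NextMethod()
}

#' Expected protein-family relative abundance of a mock community
#'
#' Given genome coverages \eqn{A_j} and per-genome family copy numbers
#' \eqn{C_{i,j}} (counted from the gene table), the abundance of family
#' \eqn{i} is \eqn{A_i = \sum_j C_{i,j} A_j}, and its relative abundance is
#' \eqn{R_i = A_i / \sum_i A_i}. This is the ground-truth profile against
#' which estimated profiles are scored.
#'
#' @param community Community coverages; see [as_community()].
#' @param ref A [ref_set()] containing every community genome.
#' @return A normalized `fam_profile` tibble (`family_id`, `abundance`)
#'   with flavor `"expected"`, covering exactly the families carried by
#'   genomes with positive coverage.
#' @examples
#' ref <- synth_reference_set(n_genomes = 2, genes_per_genome = 4, seed = 1)
#' comm <- as_community(setNames(c(2, 1), names(ref$genomes)))
#' expected_family_abundance(comm, ref)
#' @export
expected_family_abundance <- function(community, ref) {
  stopifnot(inherits(ref, "ref_set"))
  community <- as_community(community)
  absent <- setdiff(community$genome_id, names(ref$genomes))
  if (length(absent)) {
    abort_(sprintf("community genome(s) absent from reference: %s",
                   paste(absent, collapse = ", ")))
  }
  prof <- ref$genes |>
    dplyr::count(.data$genome_id, .data$family_id, name = "copy_number") |>
    dplyr::inner_join(community, by = "genome_id") |>
    dplyr::filter(.data$coverage > 0) |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(abundance = sum(.data$copy_number * .data$coverage),
                     .groups = "drop")
  if (nrow(prof) == 0 || sum(prof$abundance) <= 0) {
    abort_("community has no positive-coverage genome carrying any gene")
  }
  relative_normalize(new_fam_profile(prof$family_id, prof$abundance,
                                     flavor = "expected", normalized = FALSE))
}

#' Normalize an abundance profile to sum to one
#'
#' Divides each family's value by the profile total. Idempotent; preserves
#' the profile's flavor.
#'
#' @param profile A `fam_profile` or data frame with columns `family_id`
#'   and `abundance`.
#' @return A normalized `fam_profile`.
#' @export
relative_normalize <- function(profile) {
  flavor <- attr(profile, "flavor") %||% "count"
  prov <- attr(profile, "provenance") %||% character()
  profile <- tibble::as_tibble(profile)
  if (!all(c("family_id", "abundance") %in% names(profile))) {
    abort_("profile must have columns `family_id` and `abundance`")
  }
  if (any(profile$abundance < 0)) abort_("profile values must be >= 0")
  total <- sum(profile$abundance)
  if (nrow(profile) == 0 || total <= 0) {
    abort_("cannot normalize an empty or all-zero profile")
  }
  new_fam_profile(profile$family_id, profile$abundance / total,
                  flavor = flavor, normalized = TRUE,
                  provenance = c(prov, "relative_normalize"))
}

is_normalized_profile <- function(profile, tol = 1e-9) {
  abs(sum(profile$abundance) - 1) <= tol && all(profile$abundance >= 0)
}

#' Write / read a family abundance profile as TSV
#'
#' @param profile A profile tibble (`family_id`, `abundance`).
#' @param path Output path.
#' @return `write_profile_tsv` returns `path` invisibly; `read_profile_tsv`
#'   returns a `fam_profile`.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(tibble::as_tibble(profile)[c("family_id", "abundance")], path)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @param flavor Flavor tag to attach on read.
#' @export
read_profile_tsv <- function(path, flavor = "count") {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = "cd")
  new_fam_profile(x$family_id, x$abundance, flavor = flavor,
                  normalized = abs(sum(x$abundance) - 1) <= 1e-9)
}
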