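#' Parameters for the built-in translated aligner
#'
#' The built-in aligner performs exact Smith-Waterman local alignment of
#' peptides against reference proteins (via Biostrings) and converts raw
#' scores to bit scores with the Karlin-Altschul transform
#' \eqn{S' = (\lambda S - \ln K)/\ln 2} and E-values
#' \eqn{E = \mathrm{db\_residues} \times \mathrm{query\_len} \times 2^{-S'}}.
#' The default \eqn{\lambda} and \eqn{K} are published gapped-BLOSUM62
#' constants; they only need to be internally consistent, since
#' classification thresholds are swept rather than transferred from an
#' external search tool.
#'
#' @param matrix Substitution matrix name (a Biostrings dataset).
#' @param gap_open,gap_extend Affine gap penalties (positive costs; the
#'   first gap position costs `gap_open + gap_extend`, BLAST convention).
#' @param lambda,K Karlin-Altschul parameters.
#' @param db_residues Database size in residues; `NULL` means "sum of
#'   reference protein lengths", filled in at alignment time.
#' @param seed_k Optional k-mer seed length for the candidate-pair
#'   prefilter: when set, only peptide/target pairs sharing at least one
#'   exact amino-acid k-mer are aligned. `NULL` (default) aligns every
#'   pair. The prefilter makes library-scale searches tractable; with
#'   k = 6 a true homolog peptide of 30+ residues at typical error rates
#'   almost surely retains a clean seed.
#' @return An object of class `aligner_params`.
#' @export
aligner_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041, db_residues = NULL,
                           seed_k = NULL) {
  if (gap_open <= 0 || gap_extend <= 0) abort_("gap penalties must be positive")
  if (lambda <= 0 || K <= 0) abort_("lambda and K must be positive")
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K, db_residues = db_residues,
                 seed_k = seed_k),
            class = "aligner_params")
}

get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

raw_to_bits <- function(raw, lambda, K) (lambda * raw - log(K)) / log(2)

#' Align predicted peptides against reference proteins
#'
#' The package's self-contained stand-alone search: Smith-Waterman local
#' alignment of each peptide against each reference protein under the
#' configured substitution matrix and affine gap penalties. Only the best
#' local alignment per (peptide, gene) pair is emitted, and alignments
#' with raw score <= 0 are suppressed. See [aligner_params()] for the
#' score-to-bits conversion and the optional k-mer seed prefilter.
#'
#' @param orfs ORF tibble (from [predict_orfs()] or
#'   [import_external_orfs()]).
#' @param ref A [ref_set()]; its gene proteins are the search database.
#' @param params An [aligner_params()].
#' @return Alignment-hit tibble: `query_id`, `read_id`, `target_gene`,
#'   `target_genome`, `family_id`, `bit_score`, `e_value`, `aln_len`,
#'   `sstart`, `send` (1-based inclusive aa positions on the target),
#'   `identity_pct`.
#' @export
naive_translated_align <- function(orfs, ref, params = aligner_params()) {
  stopifnot(inherits(ref, "ref_set"), inherits(params, "aligner_params"))
  if (nrow(ref$genes) == 0) abort_("reference contains no proteins")
  if (nrow(orfs) == 0) return(empty_hits())
  if (any(grepl("*", orfs$peptide, fixed = TRUE))) {
    abort_("peptides must not contain stop symbols")
  }
  submat <- get_submat(params$matrix)
  db_res <- params$db_residues %||% sum(ref$genes$length_aa)

  pairs <- candidate_pairs(orfs$peptide, ref$genes$protein, params$seed_k)
  if (nrow(pairs) == 0) return(empty_hits())

  res <- pairs |>
    dplyr::group_by(.data$tgt) |>
    dplyr::group_map(function(d, key) {
      t_idx <- key$tgt[[1]]
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(orfs$peptide[d$qry]),
        Biostrings::AAString(ref$genes$protein[t_idx]),
        type = "local", substitutionMatrix = submat,
        gapOpening = params$gap_open, gapExtension = params$gap_extend)
      raw <- BiocGenerics::score(pa)
      keep <- raw > 0
      if (!any(keep)) return(NULL)
      tibble::tibble(
        qry = d$qry[keep], tgt = t_idx, raw = raw[keep],
        aln_len = Biostrings::nchar(pa)[keep],
        sstart = BiocGenerics::start(Biostrings::subject(pa))[keep],
        send = BiocGenerics::end(Biostrings::subject(pa))[keep],
        identity_pct = Biostrings::pid(pa)[keep])
    }) |>
    dplyr::bind_rows()
  if (nrow(res) == 0) return(empty_hits())

  bits <- raw_to_bits(res$raw, params$lambda, params$K)
  qlen <- nchar(orfs$peptide)[res$qry]
  tibble::tibble(
    query_id = orfs$orf_id[res$qry],
    read_id = orfs$read_id[res$qry],
    target_gene = ref$genes$gene_id[res$tgt],
    target_genome = ref$genes$genome_id[res$tgt],
    family_id = ref$genes$family_id[res$tgt],
    bit_score = bits,
    e_value = db_res * qlen * 2^(-bits),
    aln_len = res$aln_len,
    sstart = res$sstart, send = res$send,
    identity_pct = res$identity_pct)
}

empty_hits <- function() {
  tibble::tibble(query_id = character(), read_id = character(),
                 target_gene = character(), target_genome = character(),
                 family_id = character(), bit_score = numeric(),
                 e_value = numeric(), aln_len = integer(),
                 sstart = integer(), send = integer(),
                 identity_pct = numeric())
}

# which (query, target) index pairs to align; seed_k = NULL -> all pairs
candidate_pairs <- function(peptides, targets, seed_k) {
  if (is.null(seed_k)) {
    return(tidyr::expand_grid(qry = seq_along(peptides),
                              tgt = seq_along(targets)))
  }
  k <- as.integer(seed_k)
  kmerize <- function(x, id) {
    n <- nchar(x)
    use <- which(n >= k)
    if (!length(use)) {
      return(tibble::tibble(kmer = character(), id = integer()))
    }
    nk <- n[use] - k + 1L
    starts <- sequence(nk)
    seqs <- rep.int(x[use], nk)
    tibble::tibble(kmer = substring(seqs, starts, starts + k - 1L),
                   id = rep.int(use, nk)) |>
      dplyr::distinct()
  }
  dplyr::inner_join(kmerize(peptides, "qry"), kmerize(targets, "tgt"),
                    by = "kmer", relationship = "many-to-many") |>
    dplyr::distinct(qry = .data$id.x, tgt = .data$id.y)
}

#' Parse BLAST-tabular (m8) alignments
#'
#' Reads 12-column tab-separated alignment records (qseqid, sseqid,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore) and resolves each subject id to its gene, genome and family
#' through the reference set. Query ids are assumed to be ORF ids of the
#' form `readid_f{frame}_{i}`; the read id is recovered by stripping the
#' frame suffix. The `rapsearch2` dialect interprets column 11 as
#' log10(E-value) and converts it to an E-value; lines starting with `#`
#' are skipped in either dialect.
#'
#' @param path m8 file.
#' @param dialect `"blast"` or `"rapsearch2"`.
#' @param ref A [ref_set()] used to resolve subject ids.
#' @param allow_unmapped Skip (with a warning) hits whose subject id is
#'   not a known gene, instead of erroring.
#' @return Alignment-hit tibble as in [naive_translated_align()].
#' @export
parse_tabular_alignments <- function(path, dialect = c("blast", "rapsearch2"),
                                     ref, allow_unmapped = FALSE) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ref, "ref_set"))
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- suppressWarnings(
    readr::read_tsv(path, col_names = cols, comment = "#",
                    col_types = "ccdiiiiiiidd", show_col_types = FALSE))
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort_(sprintf("malformed m8 record at line %d: expected %s",
                   probs$row[1], probs$expected[1]))
  }
  gi <- match(x$sseqid, ref$genes$gene_id)
  if (anyNA(gi)) {
    unknown <- unique(x$sseqid[is.na(gi)])
    if (!allow_unmapped) {
      abort_(sprintf("unknown subject id(s) in alignment file: %s",
                     paste(utils::head(unknown, 5), collapse = ", ")))
    }
    warning(sprintf("skipping %d hit(s) with unknown subject ids",
                    sum(is.na(gi))))
    x <- x[!is.na(gi), ]
    gi <- gi[!is.na(gi)]
  }
  if (any(x$sstart < 1 | x$send < x$sstart) ||
      any(x$send > ref$genes$length_aa[gi])) {
    abort_("subject alignment spans fall outside the target protein")
  }
  ev <- if (dialect == "rapsearch2") 10^x$evalue else x$evalue
  tibble::tibble(
    query_id = x$qseqid,
    read_id = sub("_f(\\+[123]|-[123]|ext)_[0-9]+$", "", x$qseqid),
    target_gene = x$sseqid,
    target_genome = ref$genes$genome_id[gi],
    family_id = ref$genes$family_id[gi],
    bit_score = x$bitscore,
    e_value = ev,
    aln_len = x$length,
    sstart = x$sstart, send = x$send,
    identity_pct = x$pident)
}

#' Remove alignments to taxa related to the read's source organism
#'
#' Clade exclusion simulates the annotation of communities containing
#' organisms absent from the reference database: a hit is removed if and
#' only if its target genome shares the read's source-genome taxon at the
#' given rank. At `"strain"` only hits back to the identical source strain
#' are removed; at `"genus"` all targets from the source organism's genus
#' are removed, and so on up the lineage, giving nested removal sets.
#'
#' @param hits Alignment-hit tibble.
#' @param ref A [ref_set()] with taxonomy for all genomes involved.
#' @param rank One of strain, species, genus, family, order, class,
#'   phylum.
#' @param source_of Mapping of `read_id` to source genome: a named
#'   character vector, or a tibble with columns `read_id` and
#'   `truth_genome` (a read table from [simulate_reads()] works as is).
#' @return The filtered hit tibble.
#' @export
clade_exclude <- function(hits, ref, rank = c("strain", "species", "genus",
                                              "family", "order", "class",
                                              "phylum"),
                          source_of) {
  rank <- match.arg(rank)
  stopifnot(inherits(ref, "ref_set"))
  if (is.data.frame(source_of)) {
    source_of <- stats::setNames(source_of$truth_genome, source_of$read_id)
  }
  src <- source_of[hits$read_id]
  if (anyNA(src)) {
    abort_(sprintf("read(s) with unknown source genome: %s",
                   paste(utils::head(unique(hits$read_id[is.na(src)]), 5),
                         collapse = ", ")))
  }
  taxon <- stats::setNames(ref$taxonomy[[rank]], ref$taxonomy$genome_id)
  keep <- taxon[hits$target_genome] != taxon[src]
  if (anyNA(keep)) abort_("taxonomy missing for genome(s) involved in hits")
  hits[keep, ]
}

#' Classify reads or ORFs into protein families from alignment hits
#'
#' Hits failing the threshold are removed first (a hit is kept iff
#' `bit_score >= min_bits`, and/or `e_value <= max_evalue`). Surviving
#' hits are grouped per read (`per_read`: one annotation per read, the
#' top-scoring hit across all of its ORFs) or per ORF (`per_orf`: every
#' ORF classified independently). Within each group the winner has the
#' highest bit score; ties break by lowest E-value, then lexicographically
#' smallest target gene id, so classification is fully deterministic.
#' Units with no surviving hit are simply unclassified and absent from the
#' output.
#'
#' @param hits Alignment-hit tibble.
#' @param mode `"per_read"` or `"per_orf"`.
#' @param min_bits Minimum bit score (inclusive), or `NULL`.
#' @param max_evalue Maximum E-value (inclusive), or `NULL`. At least one
#'   of `min_bits`/`max_evalue` must be supplied.
#' @return Classification tibble: `unit_id`, `read_id`, `family_id`,
#'   `bit_score`, `e_value`, `target_gene`, `sstart`, `send`, `mode`.
#' @export
classify_hits <- function(hits, mode = c("per_read", "per_orf"),
                          min_bits = NULL, max_evalue = NULL) {
  mode <- match.arg(mode)
  if (is.null(min_bits) && is.null(max_evalue)) {
    abort_("supply at least one of `min_bits` or `max_evalue`")
  }
  keep <- rep(TRUE, nrow(hits))
  if (!is.null(min_bits)) keep <- keep & hits$bit_score >= min_bits
  if (!is.null(max_evalue)) keep <- keep & hits$e_value <= max_evalue
  hits <- hits[keep, ]
  if (nrow(hits) == 0) {
    return(tibble::tibble(unit_id = character(), read_id = character(),
                          family_id = character(), bit_score = numeric(),
                          e_value = numeric(), target_gene = character(),
                          sstart = integer(), send = integer(),
                          mode = character()))
  }
  hits$unit_id <- if (mode == "per_read") hits$read_id else hits$query_id
  hits |>
    dplyr::arrange(.data$unit_id, dplyr::desc(.data$bit_score),
                   .data$e_value, .data$target_gene) |>
    dplyr::distinct(.data$unit_id, .keep_all = TRUE) |>
    dplyr::transmute(.data$unit_id, .data$read_id, .data$family_id,
                     .data$bit_score, .data$e_value, .data$target_gene,
                     .data$sstart, .data$send, mode = .env$mode)
}

#' Default read-length specific bit-score threshold
#'
#' Piecewise-linear interpolation over the anchor table
#' `{100 bp: 31 bits, 250 bp: 35 bits}`, clamped outside the anchors.
#' Short-read annotation accuracy is sharply sensitive to this threshold,
#' and the optimum grows with read length; outside the anchored range the
#' clamped value is an extrapolation and a warning says so.
#'
#' @param read_length Read length in bp (>= 25).
#' @return Default threshold in bits.
#' @examples
#' default_bitscore_threshold(100) # 31
#' default_bitscore_threshold(250) # 35
#' @export
default_bitscore_threshold <- function(read_length) {
  check_number(read_length, "read_length", lower = 25)
  anchors_x <- c(100, 250)
  anchors_y <- c(31, 35)
  if (read_length < anchors_x[1] || read_length > anchors_x[2]) {
    warning(sprintf(
      "read length %d bp is outside the anchored range [100, 250]; %s",
      as.integer(read_length),
      "the clamped threshold is an extrapolation"))
  }
  stats::approx(anchors_x, anchors_y, xout = read_length, rule = 2)$y
}
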