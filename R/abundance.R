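#' Count-based family abundance from classifications
#'
#' Each classified unit contributes `1 / L_k` to its family, where `L_k`
#' is the length in amino acids of the winning hit's own target gene (not
#' a family average). This gene-length normalization removes the bias by
#' which long genes would otherwise appear more abundant. In `per_orf`
#' mode a read with several classified ORFs contributes one hit per ORF.
#'
#' @param classifications Classification tibble from [classify_hits()].
#' @param ref A [ref_set()] supplying target gene lengths.
#' @param normalize Scale the profile to sum to one (default). With
#'   `FALSE` the raw gene-length-normalized values are returned, e.g. as
#'   input for [ags_normalize()].
#' @return A `fam_profile` tibble with flavor `"count"`.
#' @export
count_abundance <- function(classifications, ref, normalize = TRUE) {
  abundance_impl(classifications, ref, metric = "count", normalize = normalize)
}

#' Coverage-based family abundance from classifications
#'
#' Instead of counting hits, sums aligned target residues: each hit
#' contributes `X_k / L_k`, where `X_k = send - sstart + 1` is the number
#' of target residues covered by the alignment. This credits reads that
#' hang off the 5' or 3' end of a gene in proportion to their overlap, and
#' improves accuracy for long reads whose alignments often terminate at
#' gene boundaries.
#'
#' @inheritParams count_abundance
#' @return A `fam_profile` tibble with flavor `"coverage"`.
#' @export
coverage_abundance <- function(classifications, ref, normalize = TRUE) {
  abundance_impl(classifications, ref, metric = "coverage",
                 normalize = normalize)
}

abundance_impl <- function(classifications, ref, metric, normalize,
                           weights = NULL) {
  stopifnot(inherits(ref, "ref_set"))
  if (nrow(classifications) == 0) {
    abort_("no classifications: cannot build an abundance profile")
  }
  gi <- match(classifications$target_gene, ref$genes$gene_id)
  if (anyNA(gi)) {
    abort_(sprintf("winning hit target gene(s) absent from reference: %s",
                   paste(utils::head(unique(
                     classifications$target_gene[is.na(gi)]), 5),
                     collapse = ", ")))
  }
  L <- ref$genes$length_aa[gi]
  contrib <- if (metric == "count") 1 / L else {
    if (anyNA(classifications$sstart) || anyNA(classifications$send)) {
      abort_("coverage abundance requires target spans (sstart/send)")
    }
    (classifications$send - classifications$sstart + 1) / L
  }
  if (!is.null(weights)) contrib <- contrib * weights
  prof <- tibble::tibble(family_id = classifications$family_id,
                         value = contrib) |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(abundance = sum(.data$value), .groups = "drop")
  out <- new_fam_profile(prof$family_id, prof$abundance, flavor = metric,
                         normalized = FALSE,
                         provenance = "gene_length_normalized")
  if (normalize) relative_normalize(out) else out
}

#' Average-genome-size normalization
#'
#' Divides each (unnormalized) family value by the community's average
#' genome size in megabases, yielding abundances comparable across samples
#' whose communities differ in genome-size composition. Within-sample
#' *relative* profiles are unchanged by this scaling:
#' `relative_normalize(ags_normalize(x))` equals `relative_normalize(x)`.
#'
#' @param raw_values Unnormalized family values: named numeric vector or
#'   a profile tibble (`family_id`, `abundance`).
#' @param ags_bp Average genome size in base pairs (> 0); estimated
#'   externally (e.g. by MicrobeCensus) and supplied as an input.
#' @param library_reads Optional library size, recorded in the profile's
#'   provenance for cross-sample bookkeeping; it does not enter the
#'   arithmetic.
#' @return A `fam_profile` tibble (unnormalized) of AGS-scaled values.
#' @export
ags_normalize <- function(raw_values, ags_bp, library_reads = NULL) {
  check_number(ags_bp, "ags_bp", lower = 0, allow_zero = FALSE)
  if (is.numeric(raw_values) && !is.null(names(raw_values))) {
    raw_values <- tibble::tibble(family_id = names(raw_values),
                                 abundance = unname(raw_values))
  }
  flavor <- attr(raw_values, "flavor") %||% "count"
  prov <- attr(raw_values, "provenance") %||% character()
  raw_values <- tibble::as_tibble(raw_values)
  new_fam_profile(raw_values$family_id,
                  raw_values$abundance / (ags_bp / 1e6),
                  flavor = flavor, normalized = FALSE,
                  provenance = c(prov,
                                 sprintf("ags_normalize(%g bp%s)", ags_bp,
                                         if (is.null(library_reads)) ""
                                         else sprintf(", %d reads",
                                                      as.integer(library_reads)))))
}

#' Fraction of reads classified into any family
#'
#' Unclassified reads contribute nothing to abundance profiles; their
#' share is reported separately as a per-sample classification rate.
#'
#' @param classifications Classification tibble.
#' @param n_reads Total number of reads searched.
#' @return Fraction in \[0, 1\] of reads with at least one classification.
#' @export
classification_rate <- function(classifications, n_reads) {
  check_number(n_reads, "n_reads", lower = 0, allow_zero = FALSE)
  dplyr::n_distinct(classifications$read_id) / n_reads
}
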