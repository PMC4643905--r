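#' Six-frame translation of a nucleotide read
#'
#' Translates a read in all six reading frames: `+1`..`+3` at offsets 0-2
#' of the read, `-1`..`-3` at offsets 0-2 of its reverse complement, under
#' the standard genetic code. Stop codons are rendered as `*`, codons
#' containing `N` as `X`, and 1-2 trailing nucleotides that do not complete
#' a codon are dropped.
#'
#' @param seq A single nucleotide sequence (character scalar).
#' @return Named character vector of 6 translations (`+1`, `+2`, `+3`,
#'   `-1`, `-2`, `-3`). A read shorter than 3 nt yields all-empty frames
#'   with a warning.
#' @examples
#' six_frame_translate("ATGGCCTAA")
#' @export
six_frame_translate <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < 3L) {
    warning("read shorter than 3 nt yields no translated frames")
    return(stats::setNames(rep("", 6L), frame_labels()))
  }
  translate_frames(seq)[1L, ]
}

frame_labels <- function() c("+1", "+2", "+3", "-1", "-2", "-3")

# batch translation: character vector of reads -> n x 6 character matrix
translate_frames <- function(seqs) {
  n <- length(seqs)
  fwd <- Biostrings::DNAStringSet(seqs)
  rev <- Biostrings::reverseComplement(fwd)
  out <- matrix("", nrow = n, ncol = 6L,
                dimnames = list(NULL, frame_labels()))
  widths <- Biostrings::width(fwd)
  for (off in 0:2) {
    keep <- widths - off >= 3L
    ends <- off + ((widths - off) %/% 3L) * 3L
    for (strand in c("+", "-")) {
      x <- if (strand == "+") fwd else rev
      tr <- rep("", n)
      if (any(keep)) {
        sub <- Biostrings::subseq(x[keep], start = off + 1L, end = ends[keep])
        tr[keep] <- as.character(Biostrings::translate(
          sub, if.fuzzy.codon = "X"))
      }
      out[, paste0(strand, off + 1L)] <- tr
    }
  }
  out
}

#' Split translated frames into ORFs and filter short ones
#'
#' Each frame is split on stop symbols (`*`) into maximal stop-free
#' substrings; substrings shorter than `min_len` amino acids are discarded
#' (strictly less than, so a peptide of exactly `min_len` residues is
#' kept). Survivors are not required to start with methionine: reads are
#' genome fragments, so an ORF here is simply a maximal stop-free run.
#'
#' @param frames Named character vector of 6 translations from
#'   [six_frame_translate()].
#' @param min_len Minimum peptide length in amino acids (default 15, the
#'   value used for short-read annotation throughout the package).
#' @param read_id Read identifier used to build ORF ids
#'   (`readid_f{frame}_{index}`).
#' @return Tibble of ORF records: `orf_id`, `read_id`, `frame`,
#'   `aa_start` (1-based position within the frame's translation),
#'   `peptide`.
#' @export
split_and_filter_orfs <- function(frames, min_len = 15, read_id = "read") {
  check_number(min_len, "min_len", lower = 1)
  split_frames_batch(
    frames_mat = matrix(frames[frame_labels()], nrow = 1,
                        dimnames = list(NULL, frame_labels())),
    read_ids = read_id, min_len = min_len)
}

# vectorized stop-splitting over a reads x 6 frame matrix
split_frames_batch <- function(frames_mat, read_ids, min_len) {
  n <- nrow(frames_mat)
  fr_vec <- as.vector(frames_mat)                       # column-major
  fr_read <- rep(read_ids, times = 6L)
  fr_name <- rep(colnames(frames_mat), each = n)

  pieces <- strsplit(fr_vec, "*", fixed = TRUE)
  np <- lengths(pieces)
  if (sum(np) == 0) return(empty_orfs())
  pep <- unlist(pieces, use.names = FALSE)
  wid <- nchar(pep)
  grp <- rep.int(seq_along(pieces), np)
  # start of each piece within its frame: pieces are separated by one '*'
  s <- wid + 1L
  cs <- cumsum(s)
  first <- !duplicated(grp)
  offset <- rep.int(cs[first] - s[first], times = np[np > 0])
  aa_start <- cs - offset - s + 1L

  keep <- wid >= min_len
  if (!any(keep)) return(empty_orfs())
  out <- tibble::tibble(
    read_id = fr_read[grp][keep],
    frame = fr_name[grp][keep],
    aa_start = aa_start[keep],
    peptide = pep[keep])
  out <- out |>
    dplyr::group_by(.data$read_id, .data$frame) |>
    dplyr::mutate(orf_id = sprintf("%s_f%s_%d", .data$read_id, .data$frame,
                                   dplyr::row_number())) |>
    dplyr::ungroup()
  out[c("orf_id", "read_id", "frame", "aa_start", "peptide")]
}

empty_orfs <- function() {
  tibble::tibble(orf_id = character(), read_id = character(),
                 frame = character(), aa_start = integer(),
                 peptide = character())
}

#' Predict ORFs for a table of reads by six-frame translation
#'
#' Batch driver for the 6FT + stop-split + length-filter procedure: every
#' read is translated in six frames, frames are split on stops, and
#' peptides shorter than `min_len` are dropped.
#'
#' @param reads Read tibble (columns `read_id`, `seq`).
#' @param min_len Minimum ORF length in amino acids.
#' @return ORF tibble as in [split_and_filter_orfs()].
#' @export
predict_orfs <- function(reads, min_len = 15) {
  check_number(min_len, "min_len", lower = 1)
  ok <- nchar(reads$seq) >= 3L
  if (!all(ok)) {
    warning(sprintf("%d read(s) shorter than 3 nt yield no frames",
                    sum(!ok)))
    reads <- reads[ok, ]
  }
  if (nrow(reads) == 0) return(empty_orfs())
  split_frames_batch(translate_frames(reads$seq), reads$read_id, min_len)
}

#' Import externally predicted ORFs from an amino-acid FASTA
#'
#' Brings peptides produced by an external gene finder (Prodigal,
#' FragGeneScan, MetaGeneMark, ...) into the same ORF table used by the
#' built-in translator; the `frame` field is set to `"ext"`. Terminal stop
#' symbols are stripped; internal stops are rejected, since gene finders
#' should never emit them.
#'
#' @param fasta_path Amino-acid FASTA of predicted ORFs.
#' @param read_id_rule How to recover the source read id from a header:
#'   either a function mapping the header (first whitespace-delimited
#'   token) to a read id, or a regular expression with one capture group.
#'   The default `"^(.+)_\\d+$"` handles Prodigal-style headers such as
#'   `read7_1`.
#' @return ORF tibble (`orf_id`, `read_id`, `frame`, `aa_start`,
#'   `peptide`); `aa_start` is `NA` for imported ORFs.
#' @export
import_external_orfs <- function(fasta_path, read_id_rule = "^(.+)_\\d+$") {
  x <- Biostrings::readAAStringSet(fasta_path)
  if (length(x) == 0) return(empty_orfs())
  hdr <- sub("\\s.*$", "", names(x))
  if (is.function(read_id_rule)) {
    rid <- vapply(hdr, read_id_rule, character(1), USE.NAMES = FALSE)
  } else {
    hit <- grepl(read_id_rule, hdr)
    rid <- ifelse(hit, sub(read_id_rule, "\\1", hdr), NA_character_)
  }
  bad <- is.na(rid) | !nzchar(rid)
  if (any(bad)) {
    abort_(paste0("headers not matching the read-id rule: ",
                  paste(utils::head(hdr[bad], 5), collapse = ", ")))
  }
  pep <- unname(sub("\\*+$", "", as.character(x)))
  if (any(grepl("*", pep, fixed = TRUE))) {
    abort_("imported peptides contain internal stop symbols")
  }
  if (any(!nzchar(pep))) abort_("imported peptides must be non-empty")
  tibble::tibble(read_id = rid, frame = "ext", aa_start = NA_integer_,
                 peptide = pep) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::mutate(orf_id = sprintf("%s_f%s_%d", .data$read_id, .data$frame,
                                   dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::select("orf_id", "read_id", "frame", "aa_start", "peptide")
}
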