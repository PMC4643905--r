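#' Sequencing error models
#'
#' Constructs the per-position error model applied to simulated reads.
#' Supported kinds:
#' \describe{
#'   \item{`error_free`}{no errors.}
#'   \item{`uniform`}{constant per-base error probability `rate`
#'     (default 0.01).}
#'   \item{`linear`}{probability interpolating linearly from `start_rate`
#'     at the first base to `end_rate` at the last (Sanger-style; defaults
#'     0.01 to 0.02).}
#'   \item{`poly4`}{Illumina-style position-dependent rate
#'     \eqn{p(i) = (a + b i^4)/100} with defaults `a = 3e-3`,
#'     `b = 3.3e-8`. Note the percent convention: parameters are in
#'     percentage points, so the default rate at position 100 is
#'     \eqn{(3\times10^{-3} + 3.3\times10^{-8}\cdot10^8)/100 = 0.03303}.
#'     Without the /100 the rate would exceed 1 past position ~100.}
#'   \item{`homopolymer`}{454-style model: each homopolymer run of length
#'     n is resampled from round(Normal(n, 0.03 + 0.15 n)), clamped at 0.
#'     A deliberately simple approximation of pyrosequencing length noise;
#'     no substitutions are introduced.}
#' }
#' Given that an error occurs at a position, it is a substitution (to a
#' uniformly chosen different base) with probability `r/(r+1)` where `r` is
#' `sub_indel_ratio`, and otherwise an insertion or deletion with equal
#' probability. The default 4:1 ratio gives substitution 4/5, insertion
#' 1/10, deletion 1/10, approximating raw Illumina error composition.
#'
#' @param kind One of `"error_free"`, `"uniform"`, `"linear"`, `"poly4"`,
#'   `"homopolymer"`.
#' @param rate Uniform per-base error probability.
#' @param start_rate,end_rate Linear-model endpoints.
#' @param a,b poly4 coefficients (percent convention).
#' @param sub_indel_ratio Substitutions per indel.
#' @return An object of class `error_model`.
#' @export
error_model <- function(kind = c("uniform", "error_free", "linear", "poly4",
                                 "homopolymer"),
                        rate = 0.01, start_rate = 0.01, end_rate = 0.02,
                        a = 3e-3, b = 3.3e-8, sub_indel_ratio = 4) {
  kind <- match.arg(kind)
  if (kind == "uniform" && (rate < 0 || rate > 1)) {
    abort_("uniform error rate must lie in [0, 1]")
  }
  if (kind == "linear" &&
      (min(start_rate, end_rate) < 0 || max(start_rate, end_rate) > 1)) {
    abort_("linear error rates must lie in [0, 1]")
  }
  if (kind == "poly4" && (a < 0 || b < 0)) {
    abort_("poly4 coefficients must be >= 0")
  }
  check_number(sub_indel_ratio, "sub_indel_ratio", lower = 0, allow_zero = FALSE)
  structure(list(kind = kind, rate = rate, start_rate = start_rate,
                 end_rate = end_rate, a = a, b = b,
                 sub_indel_ratio = sub_indel_ratio),
            class = "error_model")
}

# per-position error probabilities for one read length
error_probs <- function(model, len) {
  i <- seq_len(len)
  p <- switch(model$kind,
    error_free = rep(0, len),
    uniform = rep(model$rate, len),
    linear = if (len == 1) model$start_rate else {
      model$start_rate + (model$end_rate - model$start_rate) * (i - 1) / (len - 1)
    },
    poly4 = (model$a + model$b * i^4) / 100,
    homopolymer = rep(0, len))
  if (any(p > 1)) {
    abort_(sprintf(
      "error model '%s' yields probability > 1 at read position %d",
      model$kind, which(p > 1)[1]))
  }
  p
}

#' Apply a sequencing error model to nucleotide sequences
#'
#' Vectorized over `seqs`; uses the current RNG state (seed it with
#' `set.seed()` or rely on [simulate_reads()], which seeds for you).
#'
#' @param seqs Character vector of uppercase A/C/G/T/N sequences.
#' @param model An [error_model()].
#' @return Character vector of mutated sequences. Indels change sequence
#'   length; substitutions never reproduce the original base.
#' @export
mutate_sequence <- function(seqs, model) {
  stopifnot(inherits(model, "error_model"))
  if (any(!nzchar(seqs))) abort_("sequences must be non-empty")
  if (any(grepl("[^ACGTN]", seqs))) {
    abort_("sequences must be uppercase A/C/G/T/N")
  }
  if (model$kind == "error_free") return(seqs)
  if (model$kind == "homopolymer") return(mutate_homopolymer(seqs))

  bases <- c("A", "C", "G", "T")
  lens <- nchar(seqs)
  pos <- sequence(lens)
  idx <- rep.int(seq_along(seqs), lens)
  # probability per concatenated position; group by read length so the
  # position->probability map is computed once per distinct length
  p <- numeric(length(pos))
  for (L in unique(lens)) {
    sel <- which(lens[idx] == L)
    p[sel] <- error_probs(model, L)[pos[sel]]
  }
  hit <- stats::runif(length(p)) < p
  if (!any(hit)) return(seqs)

  r <- model$sub_indel_ratio
  u <- stats::runif(sum(hit))
  type <- ifelse(u < r / (r + 1), "sub",
                 ifelse(u < (r + 0.5) / (r + 1), "ins", "del"))
  err <- tibble::tibble(read = idx[hit], pos = pos[hit], type = type)

  out <- seqs
  for (rd in unique(err$read)) {
    chars <- strsplit(seqs[rd], "", fixed = TRUE)[[1]]
    ed <- err[err$read == rd, ]
    # apply right-to-left so earlier positions stay valid
    for (k in order(ed$pos, decreasing = TRUE)) {
      i <- ed$pos[k]
      if (ed$type[k] == "sub") {
        alt <- setdiff(bases, chars[i])
        chars[i] <- alt[sample.int(length(alt), 1L)]
      } else if (ed$type[k] == "ins") {
        chars <- append(chars, bases[sample.int(4L, 1L)], after = i)
      } else {
        chars <- chars[-i]
      }
    }
    out[rd] <- paste(chars, collapse = "")
  }
  out
}

mutate_homopolymer <- function(seqs) {
  vapply(seqs, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    n <- pmax(0L, as.integer(round(stats::rnorm(
      length(r$lengths), mean = r$lengths, sd = 0.03 + 0.15 * r$lengths))))
    paste(rep.int(r$values, n), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate truth-labelled shotgun reads from a mock community
#'
#' Allocates `n_reads` across genomes by a multinomial draw with weights
#' proportional to community coverage `A_j` (or, with
#' `weight_by_length = TRUE`, to `A_j` times genome length, which realizes
#' per-base coverage proportional to `A_j`). Start positions are uniform
#' over valid positions, strands uniform, and the error model is applied
#' per read. Deterministic given `seed`.
#'
#' @param ref A [ref_set()].
#' @param community Community coverages; see [as_community()].
#' @param n_reads Number of reads to simulate (> 0).
#' @param read_length Nominal read length in bp (>= 25).
#' @param model An [error_model()].
#' @param seed Integer seed.
#' @param weight_by_length Weight genome sampling by genome length as well
#'   as coverage.
#' @return A tibble of reads: `read_id`, `seq`, `truth_genome`,
#'   `truth_start`, `truth_strand`, `length`.
#' @export
simulate_reads <- function(ref, community, n_reads, read_length,
                           model = error_model("uniform"), seed = 1,
                           weight_by_length = FALSE) {
  stopifnot(inherits(ref, "ref_set"))
  community <- as_community(community)
  check_number(n_reads, "n_reads", lower = 0, allow_zero = FALSE)
  check_number(read_length, "read_length", lower = 25)
  absent <- setdiff(community$genome_id, names(ref$genomes))
  if (length(absent)) {
    abort_(sprintf("community genome(s) absent from reference: %s",
                   paste(absent, collapse = ", ")))
  }
  glen <- nchar(ref$genomes)[community$genome_id]
  if (any(glen < read_length)) {
    abort_(sprintf("genome(s) shorter than read_length: %s",
                   paste(community$genome_id[glen < read_length],
                         collapse = ", ")))
  }
  w <- community$coverage
  if (weight_by_length) w <- w * glen

  with_seed_(seed, {
    alloc <- as.vector(stats::rmultinom(1, size = n_reads, prob = w))
    parts <- purrr::pmap(
      list(community$genome_id, alloc, glen),
      function(g, n, L) {
        if (n == 0) return(NULL)
        starts <- sample.int(L - read_length + 1L, n, replace = TRUE)
        strand <- sample(c("+", "-"), n, replace = TRUE)
        s <- substring(ref$genomes[[g]], starts, starts + read_length - 1L)
        s[strand == "-"] <- revcomp(s[strand == "-"])
        tibble::tibble(seq = s, truth_genome = g, truth_start = starts,
                       truth_strand = strand)
      })
    reads <- dplyr::bind_rows(parts)
    reads$seq <- mutate_sequence(reads$seq, model)
    tibble::tibble(read_id = sprintf("r%07d", seq_len(nrow(reads))),
                   seq = reads$seq,
                   truth_genome = reads$truth_genome,
                   truth_start = reads$truth_start,
                   truth_strand = reads$truth_strand,
                   length = nchar(reads$seq))
  })
}

#' Shuffle read sequences to create synthetic negatives
#'
#' Each output sequence is a uniform random permutation of the input's
#' characters: length and base composition are preserved but all homology
#' signal is destroyed, so shuffled reads should not classify into any
#' protein family. Truth fields are cleared.
#'
#' @param reads Read tibble from [simulate_reads()].
#' @param seed Integer seed.
#' @return A read tibble with permuted sequences and `NA` truth fields.
#' @export
shuffle_reads <- function(reads, seed = 1) {
  if (nrow(reads) == 0) abort_("no reads to shuffle")
  with_seed_(seed, {
    shuf <- vapply(strsplit(reads$seq, "", fixed = TRUE),
                   function(ch) paste(sample(ch), collapse = ""),
                   character(1))
    tibble::tibble(read_id = reads$read_id, seq = shuf,
                   truth_genome = NA_character_,
                   truth_start = NA_integer_,
                   truth_strand = NA_character_,
                   length = nchar(shuf))
  })
}

#' Write simulated reads to FASTA/FASTQ with sidecar truth table
#'
#' FASTA headers encode the truth as `readid|genome|start|strand`; FASTQ
#' output assigns a constant quality of 30 to every base. If `truth_path`
#' is given, a TSV `read_id truth_genome truth_start truth_strand` is
#' written alongside.
#'
#' @param reads Read tibble.
#' @param path Output FASTA/FASTQ path.
#' @param truth_path Optional truth TSV path.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, truth_path = NULL,
                        format = c("fasta", "fastq")) {
  format <- match.arg(format)
  hdr <- paste(reads$read_id,
               reads$truth_genome %||% NA, reads$truth_start,
               reads$truth_strand, sep = "|")
  if (format == "fasta") {
    writeLines(rbind(paste0(">", hdr), reads$seq), path)
  } else {
    qual <- vapply(nchar(reads$seq),
                   function(n) strrep(rawToChar(as.raw(30 + 33)), n),
                   character(1))
    writeLines(rbind(paste0("@", hdr), reads$seq, "+", qual), path)
  }
  if (!is.null(truth_path)) {
    readr::write_tsv(reads[c("read_id", "truth_genome", "truth_start",
                             "truth_strand")], truth_path)
  }
  invisible(path)
}

#' Read shotgun reads from FASTA/FASTQ
#'
#' Headers of the form `readid|genome|start|strand` (as written by
#' [write_reads()]) have their truth fields recovered; other headers yield
#' `NA` truth.
#'
#' @param path FASTA or FASTQ file.
#' @param format `"fasta"` or `"fastq"`.
#' @return A read tibble.
#' @export
read_reads <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- if (format == "fasta") Biostrings::readDNAStringSet(path)
       else Biostrings::readDNAStringSet(path, format = "fastq")
  hdr <- sub("\\s.*$", "", names(x))
  parts <- stringr::str_split_fixed(hdr, stringr::fixed("|"), 4)
  has_truth <- nzchar(parts[, 2])
  tibble::tibble(
    read_id = parts[, 1],
    seq = unname(as.character(x)),
    truth_genome = ifelse(has_truth, parts[, 2], NA_character_),
    truth_start = suppressWarnings(as.integer(parts[, 3])),
    truth_strand = ifelse(nzchar(parts[, 4]), parts[, 4], NA_character_),
    length = Biostrings::width(x))
}
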