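# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_ <- function(msg, class = NULL) {
  rlang::abort(msg, class = c(class, "metafam_error"))
}

# run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never clobbers user streams
with_seed_ <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

check_number <- function(x, name, lower = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || (!allow_zero && x == lower)) {
    abort_(sprintf("`%s` must be %s %s", name,
                   if (allow_zero) ">=" else ">", format(lower)))
  }
  invisible(x)
}

# reverse-complement for plain character vectors of A/C/G/T/N
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
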