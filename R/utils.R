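# Internal helpers shared across modules.

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the `{A,C,G,T,N}` alphabet.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
# seed = NULL means "use the ambient stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Draw an i.i.d. nucleotide string of length n at the given GC fraction.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

# Replace s[at..at+nchar(with)-1] by `with` (in-place string surgery).
str_assign <- function(s, at, with) {
  n <- nchar(with)
  paste0(substr(s, 1L, at - 1L), with, substr(s, at + n, nchar(s)))
}

stop_ctx <- function(...) stop(paste0(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Count per-element character mismatches between equal-length string pairs.
# Cheap for the small subsets on which it is called; exact matches should be
# screened out with `==` first.
mismatch_counts <- function(a, b) {
  if (!length(a)) return(integer(0))
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b, USE.NAMES = FALSE)
}
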