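# CircularSequence: a finite circular nucleotide molecule with a canonical
# rotation and derived statistics. Internally the sequence is stored as a
# plain upper-case character string; position arithmetic is 1-based on the
# linearised string and wraps modulo the length.

#' Circular (or linear) nucleotide sequence
#'
#' Container for a single nucleotide molecule. Circularity is a flag: most
#' operations in the package are wrap-aware when it is set.
#'
#' @param seq Nucleotide string over `{A,C,G,T,N}` (lower case accepted).
#' @param circular Logical; is the molecule closed into a circle?
#' @param id Optional identifier.
#' @return An object of class `circ_seq`.
#' @export
circ_seq <- function(seq, circular = TRUE, id = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(chartr("u", "t", seq))
  if (nchar(seq) == 0L) stop_ctx("empty sequence")
  if (grepl("[^ACGTN]", seq)) stop_ctx("sequence contains letters outside {A,C,G,T,N}")
  structure(list(id = id, seq = seq, circular = isTRUE(circular)),
            class = "circ_seq")
}

#' @export
print.circ_seq <- function(x, ...) {
  cat(sprintf("<circ_seq '%s'> %s, %d bp, GC %.1f%%\n", x$id,
              if (x$circular) "circular" else "linear",
              nchar(x$seq), gc_content(x$seq)))
  invisible(x)
}

#' @export
length.circ_seq <- function(x) nchar(x$seq)

as_seq <- function(x) if (inherits(x, "circ_seq")) x$seq else as.character(x)

#' Rotate a circular sequence
#'
#' Moves the origin so that old position `offset + 1` becomes position 1.
#'
#' @param x A `circ_seq`.
#' @param offset Number of bases to rotate by (0-based shift).
#' @return A rotated `circ_seq`.
#' @export
rotate <- function(x, offset) {
  stopifnot(inherits(x, "circ_seq"), x$circular)
  n <- nchar(x$seq)
  offset <- ((offset %% n) + n) %% n
  if (offset == 0) return(x)
  x$seq <- paste0(substr(x$seq, offset + 1L, n), substr(x$seq, 1L, offset))
  x
}

# 1-based start index of the lexicographically least rotation of s.
# Candidate-refinement scan: linear expected time on non-periodic sequences;
# long shared prefixes (exact repeats) only prolong the scan proportionally.
least_rotation_start <- function(s) {
  n <- nchar(s)
  if (n == 1L) return(1L)
  x <- utf8ToInt(s)
  d <- c(x, x)
  cand <- which(x == min(x))
  depth <- 1L
  while (length(cand) > 1L && depth < n) {
    v <- d[cand + depth]
    cand <- cand[v == min(v)]
    depth <- depth + 1L
  }
  cand[1L]
}

#' Canonical rotation of a circular sequence
#'
#' Returns the lexicographically least rotation over both strands, giving a
#' unique representative of a circular molecule up to rotation and strand.
#' Idempotent by construction.
#'
#' @param x A `circ_seq` (or plain string, treated as circular).
#' @return A `circ_seq` in canonical form.
#' @export
canonical_rotation <- function(x) {
  if (!inherits(x, "circ_seq")) x <- circ_seq(x)
  stopifnot(x$circular)
  f <- rotate(x, least_rotation_start(x$seq) - 1L)$seq
  rx <- x
  rx$seq <- revcomp(x$seq)
  r <- rotate(rx, least_rotation_start(rx$seq) - 1L)$seq
  x$seq <- if (f <= r) f else r
  x
}

#' Test whether two molecules are the same circle
#'
#' Equality up to rotation and strand, via canonical rotation.
#'
#' @param a,b `circ_seq` objects or strings.
#' @return Logical scalar.
#' @export
same_circle <- function(a, b) {
  identical(canonical_rotation(a)$seq, canonical_rotation(b)$seq)
}

# Linearised view with wrap: positions 1..2L index the doubled string.
doubled <- function(x) {
  s <- as_seq(x)
  paste0(s, s)
}

#' GC content
#'
#' Percentage of G+C over unambiguous bases. `N` is excluded from the
#' denominator; an all-`N` input is an error.
#'
#' @param x A `circ_seq` or character vector of sequences (pooled).
#' @param digits Decimal places in the returned percentage (default 1).
#' @return GC percentage.
#' @export
gc_content <- function(x, digits = 1) {
  s <- if (inherits(x, "circ_seq")) x$seq else as.character(x)
  s <- toupper(s)
  if (!length(s) || all(nchar(s) == 0L)) stop_ctx("gc_content: empty input")
  fr <- Biostrings::letterFrequency(Biostrings::DNAStringSet(s),
                                    letters = c("A", "C", "G", "T"))
  tot <- sum(fr)
  if (tot == 0) stop_ctx("gc_content: no unambiguous bases in input")
  round(100 * sum(fr[, c("C", "G")]) / tot, digits)
}
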