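# Trim-and-cut preprocessing: remove a fixed number of bases from each read,
# then slice the remainder into overlapping short fragments on a fixed start
# offset. Converting a long-read library into a dense short-fragment library
# this way raises effective coverage for a fixed-readlength overlap
# assembler. "Trim length" is the number of bases REMOVED (from the 3' end
# by default, where base quality decays); only this reading reproduces the
# canonical 2- and 3-fragments-per-75-bp-read worked examples.

#' Per-read fragment count of the trim-and-cut procedure (closed form)
#'
#' With working length `W = read_length - trim_length`, fragments start at
#' offsets `0, s, 2s, ...` while `start + out_readlength <= W`, giving
#' `floor((W - out_readlength)/s) + 1` fragments when `W >= out_readlength`
#' and 0 otherwise.
#'
#' @param read_length Input read length(s) in bp.
#' @param trim_length Bases removed per read.
#' @param out_readlength Length of each emitted fragment.
#' @param start_offset Step between successive fragment starts.
#' @return Number of fragments per read (vectorised over `read_length`).
#' @export
fragment_count <- function(read_length, trim_length, out_readlength,
                           start_offset) {
  stopifnot(trim_length >= 0, out_readlength >= 1, start_offset >= 1)
  W <- read_length - trim_length
  ifelse(W >= out_readlength, (W - out_readlength) %/% start_offset + 1, 0)
}

#' Total fragments emitted for a homogeneous library (closed form)
#'
#' @param n_reads Number of input reads.
#' @param read_length Uniform input read length in bp.
#' @inheritParams fragment_count
#' @return Total fragment count (double precision, exact for desk-scale
#'   and archive-scale library sizes).
#' @export
total_fragments <- function(n_reads, read_length, trim_length,
                            out_readlength, start_offset) {
  as.numeric(n_reads) *
    fragment_count(read_length, trim_length, out_readlength, start_offset)
}

#' Trim reads and cut them into overlapping short fragments
#'
#' Fragment ids encode the parent read and slice index
#' (`<parent>.cut<k>`); pairing metadata is propagated to every fragment.
#' Reads too short to yield any fragment are dropped (count reported via
#' `attr(, "dropped")` and a message).
#'
#' @param reads A [read_library()].
#' @param trim_length Bases removed per read.
#' @param out_readlength Emitted fragment length (bp).
#' @param start_offset Step between successive fragment starts (bp).
#' @param trim_end Which end to trim: `"3p"` (default) or `"5p"`. The end
#'   choice does not affect fragment counts.
#' @return A [read_library()] of fragments.
#' @export
trim_and_cut <- function(reads, trim_length, out_readlength, start_offset,
                         trim_end = c("3p", "5p")) {
  trim_end <- match.arg(trim_end)
  stopifnot(trim_length >= 0, out_readlength >= 1, start_offset >= 1)
  L <- nchar(reads$seq)
  W <- pmax(L - trim_length, 0L)
  if (trim_end == "3p") {
    seq_t <- substr(reads$seq, 1L, W)
    qual_t <- substr(reads$qual, 1L, W)
  } else {
    seq_t <- substr(reads$seq, L - W + 1L, L)
    qual_t <- substr(reads$qual, L - W + 1L, L)
  }
  counts <- fragment_count(L, trim_length, out_readlength, start_offset)
  dropped <- sum(counts == 0L)
  if (dropped > 0L)
    message("trim_and_cut: ", dropped, " read(s) too short, emitted 0 fragments")
  idx <- rep.int(seq_along(L), counts)
  slice <- sequence(counts)                      # 1..count within each read
  starts <- (slice - 1L) * start_offset + 1L
  lib <- read_library(
    id = sprintf("%s.cut%d", reads$id[idx], slice),
    seq = substr(seq_t[idx], starts, starts + out_readlength - 1L),
    qual = substr(qual_t[idx], starts, starts + out_readlength - 1L),
    pair_id = reads$pair_id[idx],
    mate = reads$mate[idx])
  attr(lib, "dropped") <- dropped
  lib
}
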