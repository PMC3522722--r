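# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately avoid the package's own algorithmic
# paths: the overlap-graph oracle is an all-pairs string comparison, the
# trim/cut oracle slices with a plain loop, and the alignment oracle
# enumerates every global alignment.

rc1 <- function(s) mastercircle::revcomp(s)

# All-pairs suffix/prefix oracle over oriented canonical nodes: for every
# ordered oriented pair, the minimal offset (1..max_offset) whose implied
# overlap matches exactly.
oracle_overlap_edges <- function(reads, readlength, max_offset) {
  rc <- rc1(reads)
  canon <- ifelse(reads <= rc, reads, rc)
  nodes <- sort(unique(canon))
  n <- length(nodes)
  oseq <- c(nodes, rc1(nodes))
  out <- list()
  for (i in seq_along(oseq)) for (j in seq_along(oseq)) {
    if (i == j) next
    for (d in seq_len(max_offset)) {
      if (substr(oseq[i], d + 1L, readlength) ==
          substr(oseq[j], 1L, readlength - d)) {
        out[[length(out) + 1L]] <- c(from = i, to = j, offset = d)
        break
      }
    }
  }
  if (!length(out))
    return(data.frame(from = integer(0), to = integer(0), offset = integer(0)))
  as.data.frame(do.call(rbind, out))
}

# Plain-loop slicer for trim_and_cut.
oracle_slices <- function(seq, trim, out_len, step) {
  w <- substr(seq, 1L, max(nchar(seq) - trim, 0L))
  out <- character(0)
  s <- 1L
  while (s + out_len - 1L <= nchar(w)) {
    out <- c(out, substr(w, s, s + out_len - 1L))
    s <- s + step
  }
  out
}

# Exhaustive global-alignment score: enumerate all alignments under
# match/mismatch and affine gap scoring (gap of length g costs
# open + g * extend). Feasible for sequence lengths <= 6.
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = -5, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      rec(i + 1L, j + 1L,
          score + if (av[i] == bv[j]) match else mismatch, "m")
    if (i <= length(av))
      rec(i + 1L, j, score + gap_extend +
            if (state != "a") gap_open else 0, "a")
    if (j <= length(bv))
      rec(i, j + 1L, score + gap_extend +
            if (state != "b") gap_open else 0, "b")
  }
  rec(1L, 1L, 0, "start")
  best
}

# Maximal exact repeat oracle on a small circle: for each rotation shift d
# (direct) or each anti-diagonal against the reverse complement (inverted),
# run-lengths of matching characters give the maximal repeats.
oracle_direct_repeats <- function(seq, min_len) {
  L <- nchar(seq)
  x <- strsplit(seq, "")[[1]]
  out <- list()
  for (d in seq_len(L - 1L)) {
    y <- x[((seq_len(L) - 1L + d) %% L) + 1L]
    r <- rle(x == y)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len)) {
      if (r$lengths[k] >= L) next
      i <- starts[k]
      out[[length(out) + 1L]] <-
        c(startA = i, len = r$lengths[k], startB = ((i - 1L + d) %% L) + 1L)
    }
  }
  if (!length(out))
    return(data.frame(startA = integer(0), len = integer(0),
                      startB = integer(0)))
  df <- as.data.frame(do.call(rbind, out))
  swap <- df$startB < df$startA
  tmp <- df$startA[swap]; df$startA[swap] <- df$startB[swap]; df$startB[swap] <- tmp
  df[!duplicated(df), , drop = FALSE]
}

# Deterministic toy circle with a planted repeat, for assembler tests.
toy_circle <- function(L, seed, repeat_len = 0, kind = "direct") {
  spec <- mastercircle::genome_spec(
    L, gc = 0.45,
    repeats = if (repeat_len > 0)
      list(list(kind = kind, length = repeat_len)) else list(),
    origin = NULL, seed = seed)
  mastercircle::generate_genome(spec)
}

# Error-free 36 bp paired-end library at ~50x for a circ_seq genome.
toy_library <- function(genome, seed, coverage = 50) {
  L <- nchar(genome$seq)
  mastercircle::simulate_read_library(
    genome, mastercircle::library_spec("pe36",
                                       n_pairs = round(coverage * L / 72),
                                       seed = seed))
}
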