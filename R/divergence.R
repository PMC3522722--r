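# Per-gene divergence between species pairs, as 100 minus pairwise percent
# identity (PID) over a global alignment. PID scores a column as a hit
# when its two symbols are identical and neither is a gap, divided by the
# total number of columns. Nucleotide-level divergence of coding sequences
# tracks (mostly synonymous) substitution rate; amino-acid-level divergence
# of their translations tracks non-synonymous change. No codon-model dN/dS
# is computed.

#' Global pairwise alignment
#'
#' Needleman-Wunsch global alignment through `Biostrings`, with identity
#' scoring (match/mismatch) and affine gaps (a gap of length g costs
#' `gap_open + g * gap_extend`). Deterministic.
#'
#' @param a,b Sequences (strings). `type = "dna"` or `"protein"`.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters
#'   (penalties negative).
#' @param type Alphabet.
#' @return A `pairwise_alignment`: `a`, `b` (gap-padded rows of equal
#'   length) and `score`.
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap_open = -5,
                         gap_extend = -1, type = c("dna", "protein")) {
  type <- match.arg(type)
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  if (type == "dna") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch,
                                                    baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      type = "global", substitutionMatrix = mat,
      gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  } else {
    letters <- unique(c(strsplit(paste0(a, b), "")[[1]],
                        Biostrings::AA_STANDARD, "*", "X"))
    mat <- matrix(mismatch, length(letters), length(letters),
                  dimnames = list(letters, letters))
    diag(mat) <- match
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      type = "global", substitutionMatrix = mat,
      gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  }
  structure(list(a = as.character(Biostrings::alignedPattern(pa)),
                 b = as.character(Biostrings::alignedSubject(pa)),
                 score = Biostrings::score(pa)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %d columns, score %.1f, PID %.2f%%\n",
              nchar(x$a), x$score, percent_identity(x)))
  invisible(x)
}

#' Pairwise percent identity of an alignment
#'
#' 100 times the number of columns whose two symbols are identical (gap
#' columns never count as identical) over the total number of columns,
#' two decimals. Terminal gap columns are included by default.
#'
#' @param aln A `pairwise_alignment`, or a length-2 character vector of
#'   equal-length gap-padded rows (e.g. read from an external aligned
#'   FASTA).
#' @param terminal_gaps Include terminal gap columns in the denominator?
#' @return Percent identity (2 decimals).
#' @export
percent_identity <- function(aln, terminal_gaps = TRUE) {
  rows <- if (inherits(aln, "pairwise_alignment")) c(aln$a, aln$b) else aln
  stopifnot(length(rows) == 2L, nchar(rows[1L]) == nchar(rows[2L]))
  if (nchar(rows[1L]) == 0L) stop_ctx("percent_identity: zero-length alignment")
  x <- strsplit(rows[1L], "", fixed = TRUE)[[1L]]
  y <- strsplit(rows[2L], "", fixed = TRUE)[[1L]]
  if (!terminal_gaps) {
    inner <- which(x != "-" & y != "-")
    keep <- seq(min(inner), max(inner))
    x <- x[keep]; y <- y[keep]
  }
  round(100 * sum(x == y & x != "-") / length(x), 2)
}

# Translate a CDS: trim an incomplete terminal codon, tolerate an
# alternative (e.g. ACG, often completed to AUG by RNA editing) initiation
# codon, drop a terminal stop, warn and truncate at an internal stop.
translate_cds <- function(seq, id = "cds") {
  n <- 3L * (nchar(seq) %/% 3L)
  seq <- substr(seq, 1L, n)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                           if.fuzzy.codon = "solve"))
  if (substr(seq, 1L, 3L) %in% c("ACG", "GTG", "TTG"))
    aa <- paste0("M", substr(aa, 2L, nchar(aa)))
  if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
  star <- regexpr("*", aa, fixed = TRUE)
  if (star > 0L) {
    warning("translate_cds: internal stop codon in '", id,
            "'; translation truncated", call. = FALSE)
    aa <- substr(aa, 1L, star - 1L)
  }
  aa
}

#' Divergence of two homologous coding sequences
#'
#' Aligns the sequences (nucleotide level) or their translations
#' (amino-acid level) and returns `100 - percent identity`.
#'
#' @param cds_a,cds_b Coding sequences (coding strand).
#' @param level `"nt"` or `"aa"`.
#' @param ... Scoring parameters passed to [global_align()].
#' @return Divergence percentage (2 decimals).
#' @export
gene_divergence <- function(cds_a, cds_b, level = c("nt", "aa"), ...) {
  level <- match.arg(level)
  stopifnot(nchar(cds_a) >= 3L, nchar(cds_b) >= 3L)
  if (level == "nt") {
    aln <- global_align(cds_a, cds_b, type = "dna", ...)
  } else {
    aln <- global_align(translate_cds(cds_a, "cds_a"),
                        translate_cds(cds_b, "cds_b"), type = "protein", ...)
  }
  round(100 - percent_identity(aln), 2)
}

#' Summarise per-gene divergence records
#'
#' Per genome (chloroplast/mitochondrion) and level (nt/aa): the mean over
#' species pairs of the per-pair mean over genes, rounded to two decimals;
#' plus the chloroplast/mitochondrion fold ratio of the rounded means.
#'
#' @param records Data frame with columns `gene`, `pair` (species pair),
#'   `genome` (`"cp"`/`"mt"`), `level` (`"nt"`/`"aa"`), `divergence`.
#' @return List with `pair_means` (per genome/level/pair), `genome_means`
#'   (per genome/level) and `fold_cp_over_mt` (per level).
#' @export
summarize_divergence <- function(records) {
  need <- c("gene", "pair", "genome", "level", "divergence")
  stopifnot(all(need %in% names(records)))
  pm <- stats::aggregate(divergence ~ genome + level + pair, records, mean)
  cells <- unique(pm[, c("genome", "level")])
  gm <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    v <- pm$divergence[pm$genome == cells$genome[i] &
                         pm$level == cells$level[i]]
    data.frame(genome = cells$genome[i], level = cells$level[i],
               mean = divergence_mean(v), n_pairs = length(v))
  }))
  folds <- vapply(unique(gm$level), function(lv) {
    cp <- gm$mean[gm$genome == "cp" & gm$level == lv]
    mt <- gm$mean[gm$genome == "mt" & gm$level == lv]
    if (length(cp) && length(mt)) fold_ratio(cp, mt) else NA_real_
  }, 0)
  list(pair_means = pm, genome_means = gm, fold_cp_over_mt = folds)
}

#' Mean of per-pair divergence values, two decimals
#' @param pair_means Numeric vector of per-species-pair mean divergences.
#' @return Rounded mean.
#' @export
divergence_mean <- function(pair_means) round(mean(pair_means), 2)

#' Fold ratio of two rounded means, two decimals
#' @param a,b Numerator and denominator.
#' @return `round(a/b, 2)`.
#' @export
fold_ratio <- function(a, b) round(a / b, 2)
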