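# C-to-U RNA editing and expression accounting. Edit sites are 1-based
# offsets into a CDS where position 1 is the first base of the start
# codon; applying an edit rewrites C to T in the DNA reading. Editing can
# complete an ACG start codon to ATG, create a stop, or change a residue;
# organellar editing is not expected to create in-frame internal stops, so
# any such outcome is reported as a violation rather than silently kept.
# Confirmation from transcript pileups uses the allele balance ratio
# (ABR): edited reads over total covering reads at the site.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Apply C-to-U edits to a CDS
#'
#' @param cds CDS sequence string (coding strand), or a one-row data frame
#'   with `id`, `seq`.
#' @param sites Integer vector of 1-based edit positions; each must index
#'   a `C`.
#' @return List: `seq` (edited CDS) and `effects`, one row per site with
#'   `pos`, `codon_index`, `before`, `after`, `effect` in
#'   {`silent`, `nonsynonymous`, `start-creation`, `stop-creation`,
#'   `stop-removal`} and `internal_stop` (logical violation flag).
#' @export
apply_edits <- function(cds, sites) {
  id <- "cds"
  if (is.data.frame(cds)) { id <- cds$id[1L]; cds <- cds$seq[1L] }
  sites <- as.integer(sites)
  if (!length(sites))
    return(list(seq = cds,
                effects = data.frame(pos = integer(0), codon_index = integer(0),
                                     before = character(0), after = character(0),
                                     effect = character(0),
                                     internal_stop = logical(0))))
  if (any(sites < 1L | sites > nchar(cds)))
    stop_ctx("apply_edits: site outside CDS '", id, "'")
  ref <- substring(cds, sites, sites)
  if (any(ref != "C"))
    stop_ctx("apply_edits: site ", sites[ref != "C"][1L], " in '", id,
             "' is not a C (found ", ref[ref != "C"][1L], ")")
  edited <- cds
  for (p in sites) substr(edited, p, p) <- "T"
  n_codon <- nchar(cds) %/% 3L
  effects <- do.call(rbind, lapply(sites, function(p) {
    ci <- (p - 1L) %/% 3L + 1L
    before <- substr(cds, 3L * ci - 2L, 3L * ci)
    after <- substr(edited, 3L * ci - 2L, 3L * ci)
    eff <-
      if (ci == 1L && before == "ACG" && after == "ATG") "start-creation"
      else if (!(before %in% STOP_CODONS) && after %in% STOP_CODONS)
        "stop-creation"
      else if (before %in% STOP_CODONS && !(after %in% STOP_CODONS))
        "stop-removal"
      else if (codon_aa(before) == codon_aa(after)) "silent"
      else "nonsynonymous"
    data.frame(pos = p, codon_index = ci, before = before, after = after,
               effect = eff,
               internal_stop = eff == "stop-creation" && ci < n_codon,
               stringsAsFactors = FALSE)
  }))
  list(seq = edited, effects = effects %||% data.frame())
}

codon_aa <- function(codon) {
  if (nchar(codon) < 3L) return("?")
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     if.fuzzy.codon = "solve"))
}

#' Check an edit set for internal stop creation
#'
#' Organellar C-to-U editing is not expected to introduce in-frame stop
#' codons before the terminal codon; this checker reports every violation
#' in a set of CDS/edit-list pairs rather than silently accepting them.
#'
#' @param cds Data frame with `id`, `seq`.
#' @param edit_sites Named list of per-CDS edit position vectors.
#' @return Data frame of violations (empty when the claim holds).
#' @export
check_internal_stops <- function(cds, edit_sites) {
  out <- list()
  for (cid in names(edit_sites)) {
    row <- cds[cds$id == cid, , drop = FALSE]
    if (!nrow(row)) stop_ctx("check_internal_stops: unknown CDS '", cid, "'")
    eff <- apply_edits(row, edit_sites[[cid]])$effects
    bad <- eff[eff$internal_stop, , drop = FALSE]
    if (nrow(bad)) out[[cid]] <- cbind(cds = cid, bad)
  }
  if (!length(out))
    return(data.frame(cds = character(0), pos = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Codon usage per thousand bp of coding sequence
#'
#' `score(codon) = 1000 * count(codon) / total coding bp`, over all
#' supplied CDS (duplicated genes included; incomplete terminal codons
#' trimmed). The scores satisfy `sum(score) * 3 = 1000` up to rounding.
#'
#' @param cds Character vector of CDS (or data frame with `seq`).
#' @param digits Decimals in the reported score.
#' @return Data frame `codon`, `aa`, `count`, `score`, all 64 codons.
#' @export
codon_usage <- function(cds, digits = 2) {
  seqs <- if (is.data.frame(cds)) cds$seq else as.character(cds)
  seqs <- substr(seqs, 1L, 3L * (nchar(seqs) %/% 3L))
  total_bp <- sum(nchar(seqs))
  if (total_bp == 0L) stop_ctx("codon_usage: no complete codons")
  codons <- unlist(lapply(seqs, function(s)
    substring(s, seq(1L, nchar(s) - 2L, by = 3L),
              seq(3L, nchar(s), by = 3L))))
  all64 <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                 paste0), c("T", "C", "A", "G"), paste0))
  all64 <- sort(all64)
  count <- tabulate(factor(codons, levels = all64), length(all64))
  data.frame(codon = all64,
             aa = vapply(all64, codon_aa, ""),
             count = count,
             score = round(1000 * count / total_bp, digits),
             stringsAsFactors = FALSE)
}

#' Confirm edit sites from transcript read pileups
#'
#' Maps transcript reads onto each CDS, builds a base pileup, and emits an
#' observation for every reference `C` with at least one `T`-supporting
#' read. An observation passes when `ABR >= min_abr` and
#' `coverage >= min_cov` (the published filter is ABR >= 0.40,
#' coverage >= 3).
#'
#' @param cds Data frame with `id`, `seq`.
#' @param reads Transcript [read_library()].
#' @param min_abr Minimum allele balance ratio (edited / covering reads).
#' @param min_cov Minimum covering reads.
#' @param seed_len,max_mismatch Mapping parameters (see [map_reads()]);
#'   the mismatch allowance must accommodate the edits themselves.
#' @return Data frame `cds`, `pos`, `coverage`, `edited`, `abr`, `pass`.
#' @export
confirm_edits <- function(cds, reads, min_abr = 0.40, min_cov = 3L,
                          seed_len = 18L, max_mismatch = 6L) {
  out <- list()
  for (i in seq_len(nrow(cds))) {
    ref <- cds$seq[i]
    len <- nchar(ref)
    aln <- map_reads(ref, reads, seed_len = seed_len,
                     max_mismatch = max_mismatch)
    aln <- aln[aln$mapped, , drop = FALSE]
    if (!nrow(aln)) next
    seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
    oriented <- ifelse(aln$strand == "+",
                       seqs[match(aln$read_id, reads$id)],
                       revcomp(seqs[match(aln$read_id, reads$id)]))
    rl <- nchar(oriented)
    pos_vec <- unlist(Map(seq, aln$pos, aln$pos + rl - 1L))
    base_vec <- unlist(strsplit(oriented, "", fixed = TRUE))
    keep <- pos_vec >= 1L & pos_vec <= len
    tab <- table(factor(base_vec[keep], levels = c("A", "C", "G", "T")),
                 factor(pos_vec[keep], levels = seq_len(len)))
    coverage <- colSums(tab)
    tcount <- tab["T", ]
    cpos <- which(strsplit(ref, "", fixed = TRUE)[[1L]] == "C")
    cand <- cpos[tcount[cpos] >= 1L]
    if (!length(cand)) next
    abr <- as.numeric(tcount[cand] / coverage[cand])
    out[[i]] <- data.frame(cds = cds$id[i], pos = cand,
                           coverage = as.integer(coverage[cand]),
                           edited = as.integer(tcount[cand]),
                           abr = abr,
                           pass = abr >= min_abr & coverage[cand] >= min_cov,
                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(cds = character(0), pos = integer(0),
                      coverage = integer(0), edited = integer(0),
                      abr = numeric(0), pass = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reads Per Kilobase of gene model per Million mapped reads
#'
#' `RPKM = count / (gene_length/1000) / (total_mapped/1e6)`.
#'
#' @param counts Per-gene read counts.
#' @param lengths Per-gene lengths in bp (> 0).
#' @param total_mapped Total mapped reads in the sample (> 0).
#' @return Numeric vector of RPKM values.
#' @export
rpkm <- function(counts, lengths, total_mapped) {
  if (any(lengths <= 0)) stop_ctx("rpkm: zero or negative gene length")
  if (total_mapped <= 0) stop_ctx("rpkm: total mapped reads must be positive")
  counts / (lengths / 1000) / (total_mapped / 1e6)
}

#' Flag fold changes between two conditions
#'
#' A gene is flagged when the larger of its two values is at least
#' `threshold` times the smaller; a zero denominator is replaced by the
#' `eps` pseudocount so that genes expressed in only one condition can
#' still be flagged.
#'
#' @param a,b RPKM values under the two conditions (e.g. fresh/salt).
#' @param threshold Minimum fold change (default 2.5).
#' @param eps Pseudocount for zero denominators (RPKM units).
#' @return Logical vector of flags.
#' @export
flag_fold_change <- function(a, b, threshold = 2.5, eps = 0.01) {
  stopifnot(length(a) == length(b))
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  hi / ifelse(lo > 0, lo, eps) >= threshold
}

#' Expression table with per-tissue fold-change flags
#'
#' @param genes Gene ids.
#' @param lengths Gene lengths (bp).
#' @param counts Named list of per-condition count vectors, e.g.
#'   `list(leaf_fresh =, leaf_salt =, root_fresh =, root_salt =)`.
#' @param total_mapped Named vector of per-condition totals.
#' @param threshold,eps See [flag_fold_change()].
#' @return Data frame with per-condition RPKM, per-tissue `flag_*`
#'   columns, and `dual_tissue` when flagged in both tissues.
#' @export
expression_table <- function(genes, lengths, counts, total_mapped,
                             threshold = 2.5, eps = 0.01) {
  stopifnot(all(names(counts) %in% names(total_mapped)))
  out <- data.frame(gene = genes, length = lengths, stringsAsFactors = FALSE)
  for (cond in names(counts))
    out[[paste0("rpkm_", cond)]] <- rpkm(counts[[cond]], lengths,
                                         total_mapped[[cond]])
  tissues <- unique(sub("_(fresh|salt)$", "", names(counts)))
  flag_cols <- character(0)
  for (t in tissues) {
    f <- paste0("rpkm_", t, "_fresh"); s <- paste0("rpkm_", t, "_salt")
    if (all(c(f, s) %in% names(out))) {
      out[[paste0("flag_", t)]] <- flag_fold_change(out[[f]], out[[s]],
                                                    threshold, eps)
      flag_cols <- c(flag_cols, paste0("flag_", t))
    }
  }
  if (length(flag_cols) >= 2L)
    out$dual_tissue <- Reduce(`&`, out[flag_cols])
  out
}
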