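# Repeat architecture of circular genomes. Plant mitochondrial master
# circles carry sets of large (often > 1 kb) direct and inverted repeat
# pairs; intramolecular recombination between a direct pair splits the
# circle into two subcircles whose sizes sum to the parent length, while an
# inverted pair yields an isomeric circle differing by segmental
# inversion. This module finds repeat pairs, accounts for repeat fraction,
# gene density and GC, scans for upstream ribosome-binding motifs, and
# predicts the recombination products.

#' Find direct and inverted repeat pairs on a circle
#'
#' Seed k-mers are matched over the doubled genome on both strands,
#' clustered along (anti)diagonals, extended to maximal runs, and reported
#' as repeat pairs with percent identity. Pairs contained in a larger pair
#' are suppressed. Deterministic order: length descending, then start.
#'
#' @param genome A [circ_seq()].
#' @param min_len Minimum repeat copy length (>= 20). 1000 suits "large
#'   repeat" inventories; 100 suits exhaustive scans.
#' @param min_identity Minimum percent identity (100 = exact; values below
#'   100 merge nearby seed runs on the same diagonal).
#' @param seed_k Seed k-mer length.
#' @return Data frame: `kind`, `startA`, `lenA`, `startB`, `lenB`,
#'   `identity`; starts are 1-based circle positions, copies may wrap.
#' @export
find_repeats <- function(genome, min_len = 1000L, min_identity = 100,
                         seed_k = 20L) {
  stopifnot(min_len >= 20L, seed_k <= min_len)
  s <- as_seq(genome)
  L <- nchar(s)
  dbl <- paste0(s, s)
  # seed positions over the doubled genome, so repeats spanning the circle
  # origin appear as ordinary contiguous runs; pairs are de-duplicated
  # modulo L afterwards
  pos <- seq_len(2L * L - seed_k + 1L)
  km <- substring(dbl, pos, pos + seed_k - 1L)

  pair_runs <- function(i, j, anti = FALSE) {
    # cluster seed matches on a (anti)diagonal into maximal runs; js is the
    # j value of the seed giving copy B's start (at min i for direct runs,
    # at max i for inverted runs, where j decreases as i increases)
    diag <- if (anti) i + j else j - i
    ord <- order(diag, i)
    i <- i[ord]; j <- j[ord]; diag <- diag[ord]
    new_run <- c(TRUE, diff(i) != 1L | diff(diag) != 0L)
    run_id <- cumsum(new_run)
    ix <- tapply(seq_along(i), run_id, function(v)
      v[if (anti) which.max(i[v]) else which.min(i[v])])
    data.frame(is = as.integer(tapply(i, run_id, min)),
               ie = as.integer(tapply(i, run_id, max)) + seed_k - 1L,
               js = as.integer(j[unlist(ix)]))
  }

  out <- list()
  # direct: identical k-mers at two forward positions
  dupd <- duplicated(km) | duplicated(km, fromLast = TRUE)
  if (any(dupd)) {
    grp <- split(which(dupd), km[dupd])
    grp <- grp[lengths(grp) >= 2L]
    if (length(grp)) {
      prs <- do.call(rbind, lapply(grp, function(g) {
        cmb <- utils::combn(sort(g), 2L)
        cbind(i = cmb[1L, ], j = cmb[2L, ])
      }))
      runs <- pair_runs(prs[, "i"], prs[, "j"])
      keep <- (runs$ie - runs$is + 1L) >= min_len
      runs <- runs[keep, , drop = FALSE]
      if (nrow(runs))
        out$direct <- data.frame(kind = "direct", startA = runs$is,
                                 lenA = runs$ie - runs$is + 1L,
                                 startB = runs$js,
                                 lenB = runs$ie - runs$is + 1L,
                                 identity = 100)
    }
  }
  # inverted: forward k-mer equals reverse complement of another window
  rckm <- revcomp(km)
  m <- match(rckm, km)
  hit <- which(!is.na(m))
  if (length(hit)) {
    # all occurrences, not just the first
    dupall <- duplicated(km) | duplicated(km, fromLast = TRUE)
    ii <- integer(0); jj <- integer(0)
    grp <- split(pos, km)
    occ <- grp[rckm[hit]]
    ii <- rep(hit, lengths(occ))
    jj <- unlist(occ, use.names = FALSE)
    sel <- ii < jj                      # one orientation of each pair
    if (any(sel)) {
      runs <- pair_runs(ii[sel], jj[sel], anti = TRUE)
      lenr <- runs$ie - runs$is + 1L
      keep <- lenr >= min_len
      runs <- runs[keep, , drop = FALSE]
      lenr <- lenr[keep]
      if (nrow(runs)) {
        out$inverted <- data.frame(kind = "inverted", startA = runs$is,
                                   lenA = lenr,
                                   startB = ((runs$js - 1L) %% L) + 1L,
                                   lenB = lenr, identity = 100)
      }
    }
  }
  if (!length(out))
    return(data.frame(kind = character(0), startA = integer(0),
                      lenA = integer(0), startB = integer(0),
                      lenB = integer(0), identity = numeric(0)))
  rp <- do.call(rbind, unname(out))
  rp <- rp[rp$lenA < L, , drop = FALSE]           # drop the trivial self-match
  rp$startA <- ((rp$startA - 1L) %% L) + 1L
  rp$startB <- ((rp$startB - 1L) %% L) + 1L
  rp <- rp[!(rp$kind == "direct" & rp$startA == rp$startB), , drop = FALSE]
  # canonical copy order and containment suppression
  swap <- rp$startB < rp$startA
  tmp <- rp$startA[swap]; rp$startA[swap] <- rp$startB[swap]
  rp$startB[swap] <- tmp
  rp <- rp[!duplicated(rp[, c("kind", "startA", "startB", "lenA")]), ,
           drop = FALSE]
  # suppress pairs whose copies both lie (circularly) inside a larger pair
  circ_in <- function(s, l, S, Lb) ((s - S) %% L) + l <= Lb
  contained <- vapply(seq_len(nrow(rp)), function(a) {
    any(vapply(seq_len(nrow(rp)), function(b) {
      if (b == a || rp$kind[b] != rp$kind[a] || rp$lenA[b] < rp$lenA[a])
        return(FALSE)
      if (rp$lenA[b] == rp$lenA[a] && rp$startA[b] == rp$startA[a] &&
          rp$startB[b] == rp$startB[a])
        return(FALSE)
      (circ_in(rp$startA[a], rp$lenA[a], rp$startA[b], rp$lenA[b]) &&
         circ_in(rp$startB[a], rp$lenB[a], rp$startB[b], rp$lenB[b])) ||
        (circ_in(rp$startA[a], rp$lenA[a], rp$startB[b], rp$lenB[b]) &&
           circ_in(rp$startB[a], rp$lenB[a], rp$startA[b], rp$lenA[b]))
    }, TRUE))
  }, TRUE)
  rp <- rp[!contained, , drop = FALSE]
  rp <- rp[order(-rp$lenA, rp$startA), , drop = FALSE]
  rownames(rp) <- NULL
  rp
}

#' Repeat fraction of a genome
#'
#' `100 * sum(2 * copy length) / genome_length`, rounded to two decimals.
#' Bases shared by overlapping repeat copies are deliberately
#' double-counted: the inventory convention counts each copy's full span
#' as repeat content even where two elements overlap.
#'
#' @param repeats Data frame with a `lenA` column (one row per pair), or a
#'   numeric vector of per-pair copy lengths.
#' @param genome_length Genome length in bp.
#' @return Repeat percentage (2 decimals).
#' @export
repeat_fraction <- function(repeats, genome_length) {
  stopifnot(genome_length > 0)
  lens <- if (is.data.frame(repeats)) repeats$lenA else as.numeric(repeats)
  round(100 * sum(2 * lens) / genome_length, 2)
}

#' Predict recombination products of a repeat-bearing circle
#'
#' For each direct pair with copy starts `s1 < s2` on a circle of length
#' `L`, intramolecular recombination yields two subcircles of sizes
#' `(s2 - s1) %% L` and `(s1 - s2) %% L` (start-of-copy to start-of-copy,
#' so each subcircle retains exactly one repeat copy and the sizes sum to
#' `L`). Each inverted pair yields, per parent molecule, one isomeric
#' circle of the parent's size differing by inversion of the segment
#' between the copies. Subcircles are recursively annotated with the
#' repeat pairs falling wholly inside them: contained inverted pairs add
#' isoforms, contained direct pairs add further subcircles.
#'
#' @param genome A [circ_seq()] or integer genome length.
#' @param repeats Repeat pair data frame (see [find_repeats()]).
#' @return Data frame of products: `kind` (`subcircle`/`isomer`), `size`,
#'   `parent` (repeat pair row), `retained` (copy kept / segment
#'   inverted), `n_isoforms`, `child_subcircles`.
#' @export
recombination_products <- function(genome, repeats) {
  L <- if (inherits(genome, "circ_seq")) nchar(genome$seq)
       else as.integer(genome)
  rp <- repeats
  if (!nrow(rp))
    return(data.frame(kind = character(0), size = integer(0),
                      parent = integer(0), retained = character(0),
                      n_isoforms = integer(0), child_subcircles = character(0)))
  ovl <- rp$startB <= rp$startA + rp$lenA - 1L &
         rp$startA <= rp$startB + rp$lenB - 1L
  if (any(ovl))
    stop_ctx("recombination_products: copies of pair ", which(ovl)[1L],
             " overlap; recombination between them is undefined")
  # wholly-inside test on the arc [from, from+size) of the circle
  inside <- function(pos, len, from, size) {
    rel <- ((pos - from) %% L)
    rel + len <= size
  }
  out <- list()
  for (i in seq_len(nrow(rp))) {
    s1 <- rp$startA[i]; s2 <- rp$startB[i]
    if (rp$kind[i] == "direct") {
      for (cc in list(c(s1, s2, "A"), c(s2, s1, "B"))) {
        from <- as.integer(cc[1L]); to <- as.integer(cc[2L])
        size <- ((to - from) %% L)
        others <- setdiff(seq_len(nrow(rp)), i)
        inv_in <- others[rp$kind[others] == "inverted" &
                           inside(rp$startA[others], rp$lenA[others], from, size) &
                           inside(rp$startB[others], rp$lenB[others], from, size)]
        dir_in <- others[rp$kind[others] == "direct" &
                           inside(rp$startA[others], rp$lenA[others], from, size) &
                           inside(rp$startB[others], rp$lenB[others], from, size)]
        child <- if (length(dir_in))
          paste(vapply(dir_in, function(k) {
            sz <- (rp$startB[k] - rp$startA[k]) %% L
            paste0(sz, "/", size - sz)
          }, ""), collapse = ";") else ""
        out[[length(out) + 1L]] <- data.frame(
          kind = "subcircle", size = size, parent = i,
          retained = paste0("copy", cc[3L]),
          n_isoforms = 1L + length(inv_in),
          child_subcircles = child, stringsAsFactors = FALSE)
      }
    } else {
      seg_from <- s1 + rp$lenA[i]
      seg_to <- s2 - 1L
      out[[length(out) + 1L]] <- data.frame(
        kind = "isomer", size = L, parent = i,
        retained = sprintf("inverted segment %d..%d",
                           ((seg_from - 1L) %% L) + 1L,
                           ((seg_to - 1L) %% L) + 1L),
        n_isoforms = 1L, child_subcircles = "", stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene density by feature class
#'
#' Per class, 100 * (union of base spans) / genome length, one decimal.
#' Overlapping features of one class are counted once; duplicated genes on
#' repeat copies occupy distinct spans and therefore both contribute.
#'
#' @param features Feature data frame (`type`, `start`, `end`).
#' @param genome_length Genome length in bp.
#' @param classes Named list mapping report classes to feature types.
#' @return Named numeric vector of percentages.
#' @export
gene_density <- function(features, genome_length,
                         classes = list(`protein-coding` = "CDS",
                                        rRNA = "rRNA", tRNA = "tRNA")) {
  if (nrow(features) && any(features$end > genome_length | features$start < 1L))
    stop_ctx("gene_density: feature outside the genome")
  vapply(classes, function(types) {
    f <- features[features$type %in% types, , drop = FALSE]
    if (!nrow(f)) return(0)
    spans <- IRanges::reduce(IRanges::IRanges(f$start, f$end))
    round(100 * sum(IRanges::width(spans)) / genome_length, 1)
  }, 0)
}

#' Scan for a motif upstream of genes
#'
#' Reports the genes whose strand-aware upstream window contains the
#' motif (e.g. the Shine-Dalgarno ribosome-binding sequence `GGAGG`);
#' wrap-aware on circles.
#'
#' @param genome A [circ_seq()].
#' @param features Feature data frame (`type`, `start`, `end`, `strand`,
#'   and an `ID` column if present).
#' @param motif Motif over `{A,C,G,T}`.
#' @param window Upstream window width (>= motif length).
#' @param types Feature types scanned (default CDS).
#' @return Subset of `features` with the motif, plus `motif_offset` (bp
#'   upstream of the start at which the motif begins, 1-based).
#' @export
upstream_motif_scan <- function(genome, features, motif = "GGAGG",
                                window = 20L, types = "CDS") {
  stopifnot(!grepl("[^ACGT]", motif), window >= nchar(motif))
  s <- as_seq(genome)
  L <- nchar(s)
  dbl <- paste0(s, s)
  f <- features[features$type %in% types, , drop = FALSE]
  hit <- logical(nrow(f))
  off <- integer(nrow(f))
  for (i in seq_len(nrow(f))) {
    if (f$strand[i] == "-") {
      from <- f$end[i] + 1L
      win <- revcomp(substring(dbl, from, from + window - 1L))
    } else {
      from <- f$start[i] - window
      from <- ((from - 1L) %% L) + 1L
      win <- substring(dbl, from, from + window - 1L)
    }
    p <- regexpr(motif, win, fixed = TRUE)
    hit[i] <- p > 0L
    off[i] <- if (p > 0L) window - (as.integer(p) + nchar(motif) - 1L) + 1L
              else NA_integer_
  }
  res <- f[hit, , drop = FALSE]
  res$motif_offset <- off[hit]
  rownames(res) <- NULL
  res
}
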