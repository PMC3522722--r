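# Synthetic-data generators: circular genomes with planted repeat
# architecture, paired-read libraries of the three historical Illumina
# designs, and edited-transcript reads. Every generator is a pure function
# of (spec, seed) and returns a truth table alongside its output, so that
# downstream modules can be tested against known ground truth.

## ---- genome -----------------------------------------------------------

#' Specification of a synthetic circular genome
#'
#' @param length Genome length in bp.
#' @param gc Background GC fraction (plant mtDNA sits near 0.45, cpDNA
#'   near 0.35).
#' @param repeats List of repeat plans: each `list(kind = "direct"|"inverted",
#'   length = bp, startA = NULL, startB = NULL)`; NULL positions are placed
#'   randomly without overlap.
#' @param origin `list(start =, width =, at =)` AT-rich replication-origin
#'   window, or NULL for none.
#' @param genes `list(n_cds =, cds_len = c(lo, hi), n_trna =, trna_len =,
#'   n_rrna =, rrna_len =, motif_n =)`; `motif_n` genes get a GGAGG
#'   ribosome-binding motif planted upstream.
#' @param seed Integer RNG seed; all outputs are pure functions of
#'   (spec, seed).
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(length, gc = 0.45, repeats = list(), origin = NULL,
                        genes = NULL, seed = 1L) {
  stopifnot(length >= 1000)
  planned <- sum(vapply(repeats, function(r) 2 * as.numeric(r$length), 0)) +
    (if (is.null(origin)) 0 else origin$width) +
    (if (is.null(genes)) 0 else
      (genes$n_cds %||% 0) * mean(genes$cds_len %||% 0) +
      (genes$n_trna %||% 0) * (genes$trna_len %||% 75) +
      (genes$n_rrna %||% 0) * (genes$rrna_len %||% 1500))
  if (planned > length)
    stop_ctx("genome_spec: planned feature length (", round(planned),
             " bp) exceeds genome length (", length, " bp)")
  structure(list(length = as.integer(length), gc = gc, repeats = repeats,
                 origin = origin, genes = genes, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Randomised genome spec for assembly benchmarking
#'
#' Draws a genome length uniformly in `length_range` and plants
#' `n_repeats` repeat pairs (mixed direct/inverted) with lengths in
#' `repeat_len_range`, at mtDNA-like GC. Defaults are sized so repeats are
#' longer than the 36 bp working read but shorter than the span a 390 bp
#' paired-end insert can bridge, which is the regime in which paired reads
#' are required (and sufficient) for exact repeat resolution.
#'
#' @param seed Integer seed (also used inside the generated spec).
#' @param length_range Genome length range in bp.
#' @param n_repeats Number of planted repeat pairs.
#' @param repeat_len_range Repeat copy length range in bp.
#' @param gc Background GC fraction.
#' @return A [genome_spec()].
#' @export
random_genome_spec <- function(seed, length_range = c(20000L, 100000L),
                               n_repeats = 2L,
                               repeat_len_range = c(100L, 250L), gc = 0.45) {
  with_seed(seed, {
    L <- sample(length_range[1]:length_range[2], 1L)
    reps <- lapply(seq_len(n_repeats), function(i) {
      list(kind = sample(c("direct", "inverted"), 1L),
           length = sample(repeat_len_range[1]:repeat_len_range[2], 1L))
    })
    genome_spec(L, gc = gc, repeats = reps,
                origin = list(start = NULL, width = 200L, at = 0.85),
                seed = seed)
  })
}

# Place `len`-bp intervals avoiding `occupied` (data frame start/end) with a
# clearance margin; linear placement in [1, L - len + 1].
place_interval <- function(L, len, occupied, margin = 0L, tries = 500L) {
  for (t in seq_len(tries)) {
    s <- sample.int(L - len + 1L, 1L)
    e <- s + len - 1L
    if (!nrow(occupied) ||
        all(e + margin < occupied$start | s - margin > occupied$end))
      return(c(s, e))
  }
  NULL
}

#' Generate a synthetic circular genome
#'
#' Background sequence is i.i.d. at the requested GC; the AT-rich origin
#' window and gene bodies are written in, then each repeat pair's second
#' copy is copied (direct: verbatim; inverted: reverse complement) from the
#' first, guaranteeing repeat exactness. Deterministic given the spec seed.
#'
#' @param spec A [genome_spec()].
#' @return List with `genome` (a [circ_seq()]), `features` (GFF3-style data
#'   frame) and `truth` (list with `repeats`, `origin`, `genes` tables).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    L <- spec$length
    s <- random_dna(L, spec$gc)
    occ <- data.frame(start = integer(0), end = integer(0), what = character(0))
    fail <- function(what) stop_ctx("generate_genome: infeasible packing: ",
                                    "could not place ", what,
                                    " (conflicts: ",
                                    paste(unique(occ$what), collapse = ", "), ")")

    origin_truth <- NULL
    if (!is.null(spec$origin)) {
      w <- as.integer(spec$origin$width)
      at <- spec$origin$at %||% 0.85
      st <- spec$origin$start
      if (is.null(st)) {
        pos <- place_interval(L, w, occ, margin = 50L)
        if (is.null(pos)) fail("origin")
        st <- pos[1L]
      }
      # exact composition so the realised AT fraction honours the request
      n_at <- round(at * w)
      win <- sample(c(sample(c("A", "T"), n_at, replace = TRUE),
                      sample(c("C", "G"), w - n_at, replace = TRUE)))
      s <- str_assign(s, st, paste(win, collapse = ""))
      occ <- rbind(occ, data.frame(start = st, end = st + w - 1L, what = "origin"))
      origin_truth <- data.frame(start = st, end = st + w - 1L, at = at)
    }

    gene_truth <- data.frame()
    if (!is.null(spec$genes)) {
      plan <- rbind(
        if ((spec$genes$n_cds %||% 0) > 0)
          data.frame(type = "CDS",
                     len = 3L * round(stats::runif(spec$genes$n_cds,
                                                   spec$genes$cds_len[1],
                                                   spec$genes$cds_len[2]) / 3))
        else NULL,
        if ((spec$genes$n_trna %||% 0) > 0)
          data.frame(type = "tRNA",
                     len = rep(spec$genes$trna_len %||% 75L, spec$genes$n_trna))
        else NULL,
        if ((spec$genes$n_rrna %||% 0) > 0)
          data.frame(type = "rRNA",
                     len = rep(spec$genes$rrna_len %||% 1500L, spec$genes$n_rrna))
        else NULL)
      for (i in seq_len(nrow(plan))) {
        len <- as.integer(plan$len[i])
        pos <- place_interval(L, len, occ, margin = 30L)
        if (is.null(pos)) fail(paste0(plan$type[i], " gene"))
        strand <- sample(c("+", "-"), 1L)
        body <- if (plan$type[i] == "CDS") random_cds(len) else random_dna(len, spec$gc)
        s <- str_assign(s, pos[1L],
                        if (strand == "+") body else revcomp(body))
        occ <- rbind(occ, data.frame(start = pos[1L], end = pos[2L],
                                     what = plan$type[i]))
        gene_truth <- rbind(gene_truth,
                            data.frame(id = sprintf("gene%02d", i),
                                       type = plan$type[i], start = pos[1L],
                                       end = pos[2L], strand = strand,
                                       motif = FALSE))
      }
      # scrub chance ribosome-binding motifs from every upstream window so
      # the motif truth table is exact, then plant the requested ones
      scrub_window <- function(s, from, width) {
        if (from < 1L || from + width - 1L > L) return(s)  # wraps: leave as is
        win <- substr(s, from, from + width - 1L)
        repeat {
          p <- regexpr("GGAGG", win, fixed = TRUE)
          pr <- regexpr("CCTCC", win, fixed = TRUE)
          if (p < 0L && pr < 0L) break
          at <- if (p > 0L) as.integer(p) + 2L else as.integer(pr) + 2L
          substr(win, at, at) <- if (p > 0L) "C" else "G"
        }
        str_assign(s, from, win)
      }
      for (i in seq_len(nrow(gene_truth))) {
        if (gene_truth$strand[i] == "+")
          s <- scrub_window(s, gene_truth$start[i] - 20L, 20L)
        else
          s <- scrub_window(s, gene_truth$end[i] + 1L, 20L)
      }
      n_motif <- min(spec$genes$motif_n %||% 0L, nrow(gene_truth))
      if (n_motif > 0) {
        pick <- sample(nrow(gene_truth), n_motif)
        for (i in pick) {
          if (gene_truth$strand[i] == "+") {
            at <- gene_truth$start[i] - 12L
            if (at < 1L) next
            s <- str_assign(s, at, "GGAGG")
          } else {
            at <- gene_truth$end[i] + 8L
            if (at + 4L > L) next
            s <- str_assign(s, at, revcomp("GGAGG"))
          }
          gene_truth$motif[i] <- TRUE
        }
      }
    }

    rep_truth <- data.frame()
    for (i in seq_along(spec$repeats)) {
      r <- spec$repeats[[i]]
      len <- as.integer(r$length)
      sA <- r$startA; sB <- r$startB
      if (is.null(sA)) {
        pos <- place_interval(L, len, occ, margin = 2000L)
        if (is.null(pos)) fail(paste0(r$kind, " repeat copy A"))
        sA <- pos[1L]
        occ <- rbind(occ, data.frame(start = sA, end = sA + len - 1L,
                                     what = "repeat"))
      }
      if (is.null(sB)) {
        pos <- place_interval(L, len, occ, margin = 2000L)
        if (is.null(pos)) fail(paste0(r$kind, " repeat copy B"))
        sB <- pos[1L]
        occ <- rbind(occ, data.frame(start = sB, end = sB + len - 1L,
                                     what = "repeat"))
      }
      copyA <- substr(s, sA, sA + len - 1L)
      s <- str_assign(s, sB, if (r$kind == "direct") copyA else revcomp(copyA))
      rep_truth <- rbind(rep_truth,
                         data.frame(pair = sprintf("rep%d", i), kind = r$kind,
                                    startA = sA, lenA = len, startB = sB,
                                    lenB = len))
    }

    genome <- circ_seq(s, circular = TRUE, id = "synthetic_circle")
    features <- synthetic_features(rep_truth, origin_truth, gene_truth)
    list(genome = genome, features = features,
         truth = list(repeats = rep_truth, origin = origin_truth,
                      genes = gene_truth))
  })
}

# CDS body: ATG + non-stop codons + stop.
random_cds <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  codons <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                              c("T", "C", "A", "G")), 1L, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG",
         paste(sample(sense, len / 3 - 2L, replace = TRUE), collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

synthetic_features <- function(rep_truth, origin_truth, gene_truth) {
  rows <- list()
  if (nrow(gene_truth))
    rows$genes <- data.frame(seqid = "synthetic_circle", type = gene_truth$type,
                             start = gene_truth$start, end = gene_truth$end,
                             strand = gene_truth$strand, phase = ".",
                             ID = gene_truth$id, stringsAsFactors = FALSE)
  if (nrow(rep_truth)) {
    rows$reps <- data.frame(
      seqid = "synthetic_circle", type = "repeat",
      start = c(rep_truth$startA, rep_truth$startB),
      end = c(rep_truth$startA + rep_truth$lenA - 1L,
              rep_truth$startB + rep_truth$lenB - 1L),
      strand = rep(ifelse(rep_truth$kind == "inverted", "-", "+"),
                   times = 2)[order(rep(seq_len(nrow(rep_truth)), 2))],
      phase = ".",
      ID = paste0(rep(rep_truth$pair, 2L), c(rep("A", nrow(rep_truth)),
                                             rep("B", nrow(rep_truth)))),
      stringsAsFactors = FALSE)
  }
  if (!is.null(origin_truth))
    rows$ori <- data.frame(seqid = "synthetic_circle", type = "origin",
                           start = origin_truth$start, end = origin_truth$end,
                           strand = ".", phase = ".", ID = "oriC",
                           stringsAsFactors = FALSE)
  if (!length(rows))
    return(data.frame(seqid = character(0), type = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), phase = character(0),
                      ID = character(0)))
  do.call(rbind, unname(rows))
}

## ---- read libraries ---------------------------------------------------

#' Specification of a simulated sequencing library
#'
#' The three presets mirror the historical organellar sequencing designs:
#' `"pe36"` (36 bp paired-end, ~390 bp inserts, FR), `"mp3k"` (75 bp
#' mate-pair, ~3 kb inserts, RF, with a minor ~220 bp FR shadow component)
#' and `"pe100"` (100 bp paired-end, ~350 bp inserts, FR). Insert standard
#' deviation defaults to 10% of the mean.
#'
#' @param preset One of `"pe36"`, `"mp3k"`, `"pe100"`, or `"custom"`.
#' @param read_length,insert_mean,insert_sd,n_pairs,orientation,error_rate
#'   Library parameters; override any preset value.
#' @param shadow_fraction Proportion of pairs drawn from the shadow insert
#'   distribution (mate-pair contamination).
#' @param shadow_mean,shadow_sd Shadow insert distribution (bp).
#' @param seed Integer RNG seed.
#' @return A `library_spec` list.
#' @export
library_spec <- function(preset = c("custom", "pe36", "mp3k", "pe100"),
                         read_length = NULL, insert_mean = NULL,
                         insert_sd = NULL, n_pairs = 1000L,
                         orientation = NULL, error_rate = 0,
                         shadow_fraction = 0, shadow_mean = 220L,
                         shadow_sd = NULL, seed = 1L) {
  preset <- match.arg(preset)
  base <- switch(preset,
    pe36 = list(read_length = 36L, insert_mean = 390, orientation = "FR"),
    mp3k = list(read_length = 75L, insert_mean = 3000, orientation = "RF",
                shadow_fraction = 0.1),
    pe100 = list(read_length = 100L, insert_mean = 350, orientation = "FR"),
    custom = list())
  spec <- list(read_length = read_length %||% base$read_length,
               insert_mean = insert_mean %||% base$insert_mean,
               insert_sd = insert_sd, n_pairs = as.integer(n_pairs),
               orientation = orientation %||% base$orientation %||% "FR",
               error_rate = error_rate,
               shadow_fraction = if (missing(shadow_fraction) &&
                                     !is.null(base$shadow_fraction))
                 base$shadow_fraction else shadow_fraction,
               shadow_mean = shadow_mean, shadow_sd = shadow_sd,
               seed = as.integer(seed))
  if (is.null(spec$read_length) || is.null(spec$insert_mean))
    stop_ctx("library_spec: read_length and insert_mean are required")
  spec$insert_sd <- spec$insert_sd %||% (0.10 * spec$insert_mean)
  spec$shadow_sd <- spec$shadow_sd %||% (0.10 * spec$shadow_mean)
  stopifnot(spec$read_length <= spec$insert_mean,
            spec$error_rate >= 0, spec$error_rate < 0.1,
            spec$shadow_fraction >= 0, spec$shadow_fraction <= 1)
  structure(spec, class = "library_spec")
}

#' Simulate a paired-read library from a circular genome
#'
#' Fragment midlocations are uniform on the circle (wrapping allowed);
#' insert lengths are Normal(mean, sd) truncated below at the read length;
#' a `shadow_fraction` subset is drawn from the shadow insert distribution.
#' Substitution errors are i.i.d. per base. Qualities are constant.
#'
#' @param genome A [circ_seq()] (circular).
#' @param spec A [library_spec()].
#' @return List with `reads` (a [read_library()]) and `truth` (per-read
#'   source interval and strand on the genome, plus per-pair fragment
#'   coordinates).
#' @export
simulate_read_library <- function(genome, spec) {
  stopifnot(inherits(genome, "circ_seq"), genome$circular,
            inherits(spec, "library_spec"))
  L <- nchar(genome$seq)
  if (L <= spec$insert_mean + 6 * spec$insert_sd)
    stop_ctx("simulate_read_library: genome shorter than insert mean + 6 sd")
  with_seed(spec$seed, {
    n <- spec$n_pairs
    rl <- spec$read_length
    shadow <- stats::runif(n) < spec$shadow_fraction
    ins <- ifelse(shadow,
                  stats::rnorm(n, spec$shadow_mean, spec$shadow_sd),
                  stats::rnorm(n, spec$insert_mean, spec$insert_sd))
    ins <- pmax(as.integer(round(ins)), rl)
    ins <- pmin(ins, L - 1L)
    fs <- sample.int(L, n, replace = TRUE)         # fragment start, 1-based
    fstrand <- sample(c("+", "-"), n, replace = TRUE)
    dbl <- doubled(genome)
    frag <- substr(rep(dbl, n), fs, fs + ins - 1L) # forward-strand fragment
    frag <- ifelse(fstrand == "+", frag, revcomp(frag))
    left <- substr(frag, 1L, rl)
    right <- substr(frag, nchar(frag) - rl + 1L, nchar(frag))
    # shadow pairs in a mate-pair library are FR regardless of the main chemistry
    ori <- ifelse(rep(spec$orientation == "RF", n) & !shadow, "RF", "FR")
    r1 <- ifelse(ori == "FR", left, revcomp(left))
    r2 <- ifelse(ori == "FR", revcomp(right), right)
    if (spec$error_rate > 0) {
      r1 <- mutate_reads(r1, spec$error_rate)
      r2 <- mutate_reads(r2, spec$error_rate)
    }
    pid <- sprintf("frag%07d", seq_len(n))
    lib <- read_library(id = c(paste0(pid, "/1"), paste0(pid, "/2")),
                        seq = c(r1, r2),
                        pair_id = c(pid, pid),
                        mate = rep(c(1L, 2L), each = n))
    # truth: genome-forward coordinates of each read's source window
    wrap1 <- function(p) ((p - 1L) %% L) + 1L
    lstart <- fs                            # leftmost base of left read window
    rstart <- fs + ins - rl
    r1_src <- ifelse(fstrand == "+", lstart, rstart)
    r2_src <- ifelse(fstrand == "+", rstart, lstart)
    # read strand relative to genome forward
    flip <- function(x) ifelse(x == "+", "-", "+")
    r1_strand <- fstrand
    r2_strand <- flip(fstrand)
    if (spec$orientation == "RF") {
      r1_strand <- ifelse(shadow, r1_strand, flip(r1_strand))
      r2_strand <- ifelse(shadow, r2_strand, flip(r2_strand))
    }
    truth_reads <- data.frame(
      read_id = c(paste0(pid, "/1"), paste0(pid, "/2")),
      start = wrap1(c(r1_src, r2_src)),
      width = rl,
      strand = c(r1_strand, r2_strand),
      stringsAsFactors = FALSE)
    truth_pairs <- data.frame(pair_id = pid, frag_start = fs, insert = ins,
                              frag_strand = fstrand, shadow = shadow,
                              stringsAsFactors = FALSE)
    list(reads = lib, truth = list(reads = truth_reads, pairs = truth_pairs))
  })
}

mutate_reads <- function(reads, rate) {
  if (!length(reads) || rate <= 0) return(reads)
  rl <- nchar(reads[1L])
  total <- length(reads) * rl
  hit <- which(stats::runif(total) < rate)
  if (!length(hit)) return(reads)
  ri <- ((hit - 1L) %/% rl) + 1L
  pos <- ((hit - 1L) %% rl) + 1L
  for (k in seq_along(hit)) {
    old <- substr(reads[ri[k]], pos[k], pos[k])
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    substr(reads[ri[k]], pos[k], pos[k]) <- new
  }
  reads
}

## ---- edited transcripts ----------------------------------------------

#' Simulate transcript reads carrying C-to-U edits
#'
#' Each sequenced fragment is drawn from an independent transcript copy
#' that carries each edit site with probability `efficiency` (C->T in the
#' DNA reading). Fragments are placed uniformly along each CDS (linear);
#' read strand is random (unstranded protocol).
#'
#' @param cds Data frame with `id`, `seq` columns (coding-strand CDS).
#' @param edit_sites Named list: per-CDS integer vector of 1-based edit
#'   positions (position 1 = first base of the start codon); every position
#'   must be a `C`.
#' @param efficiency Editing efficiency in `[0,1]`.
#' @param depth Target fold-coverage per CDS.
#' @param spec A [library_spec()] supplying read length, insert
#'   distribution and error rate.
#' @return List with `reads` (a [read_library()]) and `truth` (per-site
#'   true edited/covering read counts, and per-read source coordinates).
#' @export
simulate_edited_transcripts <- function(cds, edit_sites, efficiency, depth,
                                        spec) {
  stopifnot(inherits(spec, "library_spec"), efficiency >= 0, efficiency <= 1)
  for (cid in names(edit_sites)) {
    sq <- cds$seq[match(cid, cds$id)]
    bad <- edit_sites[[cid]][substring(sq, edit_sites[[cid]],
                                       edit_sites[[cid]]) != "C"]
    if (length(bad))
      stop_ctx("simulate_edited_transcripts: site ", bad[1L], " in '", cid,
               "' is not a C")
  }
  with_seed(spec$seed, {
    rl <- spec$read_length
    out_id <- out_seq <- out_pid <- character(0)
    out_mate <- integer(0)
    site_truth <- data.frame()
    read_truth <- data.frame()
    for (i in seq_len(nrow(cds))) {
      cid <- cds$id[i]
      sq <- cds$seq[i]
      len <- nchar(sq)
      sites <- edit_sites[[cid]] %||% integer(0)
      ins_max <- max(rl, min(len, spec$insert_mean))
      nfrag <- max(1L, ceiling(depth * len / (2 * rl)))
      ins <- pmax(rl, pmin(len, as.integer(round(
        stats::rnorm(nfrag, ins_max, spec$insert_sd)))))
      fs <- vapply(len - ins + 1L, function(m) sample.int(m, 1L), 1L)
      edited <- matrix(stats::runif(nfrag * length(sites)) < efficiency,
                       nrow = nfrag)
      pid <- sprintf("%s_t%05d", cid, seq_len(nfrag))
      r1 <- r2 <- character(nfrag)
      for (f in seq_len(nfrag)) {
        tseq <- sq
        if (length(sites)) {
          on <- sites[edited[f, ]]
          for (p in on) substr(tseq, p, p) <- "T"
        }
        frag <- substr(tseq, fs[f], fs[f] + ins[f] - 1L)
        r1[f] <- substr(frag, 1L, rl)
        r2[f] <- revcomp(substr(frag, nchar(frag) - rl + 1L, nchar(frag)))
      }
      if (spec$error_rate > 0) {
        r1 <- mutate_reads(r1, spec$error_rate)
        r2 <- mutate_reads(r2, spec$error_rate)
      }
      out_id <- c(out_id, paste0(pid, "/1"), paste0(pid, "/2"))
      out_seq <- c(out_seq, r1, r2)
      out_pid <- c(out_pid, pid, pid)
      out_mate <- c(out_mate, rep(1L, nfrag), rep(2L, nfrag))
      if (length(sites)) {
        r1_cov <- outer(fs, sites, function(a, p) p >= a & p <= a + rl - 1L)
        r2_start <- fs + ins - rl
        r2_cov <- outer(r2_start, sites, function(a, p) p >= a & p <= a + rl - 1L)
        covering <- colSums(r1_cov) + colSums(r2_cov)
        edited_n <- colSums(r1_cov & edited) + colSums(r2_cov & edited)
        site_truth <- rbind(site_truth,
                            data.frame(cds = cid, pos = sites,
                                       covering = covering,
                                       edited = edited_n))
      }
      read_truth <- rbind(read_truth, data.frame(
        read_id = c(paste0(pid, "/1"), paste0(pid, "/2")),
        cds = cid, start = c(fs, fs + ins - rl), width = rl,
        strand = rep(c("+", "-"), each = nfrag), stringsAsFactors = FALSE))
    }
    list(reads = read_library(out_id, out_seq, pair_id = out_pid,
                              mate = out_mate),
         truth = list(sites = site_truth, reads = read_truth))
  })
}
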