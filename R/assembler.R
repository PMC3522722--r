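# Offset-bounded exact-overlap assembly. Two reads of the common working
# length are joined by an edge when their offset -- the total length of
# their non-overlapping parts -- does not exceed a maximum, i.e. when a
# suffix of one exactly equals a prefix of the other with overlap
# >= readlength - offset. Two maxima govern the pipeline: the naive offset
# bounds edges used to seed unambiguous contig walks, and the larger
# extension offset bounds edges consulted only where a walk would otherwise
# terminate. Sequencing error is handled downstream by depth (pileup
# polishing), keeping the graph exact and testable against a brute-force
# all-pairs oracle.

#' Assembly parameters
#'
#' @param naive_offset Maximum offset for initial graph edges (bp).
#' @param extension_offset Maximum offset accepted when extending contigs
#'   across junctions where the naive graph ends (bp);
#'   `naive_offset <= extension_offset < readlength`.
#' @param readlength Uniform working read length (bp); reads of any other
#'   length are discarded before graph construction.
#' @return An `assembly_params` list.
#' @export
assembly_params <- function(naive_offset = 4L, extension_offset = 12L,
                            readlength) {
  stopifnot(naive_offset >= 0, naive_offset <= extension_offset,
            extension_offset < readlength)
  structure(list(naive_offset = as.integer(naive_offset),
                 extension_offset = as.integer(extension_offset),
                 readlength = as.integer(readlength)),
            class = "assembly_params")
}

rc_id <- function(o, n) ifelse(o > n, o - n, o + n)
canon_id <- function(o, n) ifelse(o > n, o - n, o)

#' Build the offset-bounded exact-overlap graph
#'
#' Reads are deduplicated under the canonical representation (the
#' lexicographically smaller of a read and its reverse complement) with
#' multiplicity counts. For each ordered pair of oriented reads with an
#' exact suffix-prefix match of length `>= readlength - extension_offset`,
#' one edge with the minimal offset is recorded; edges with offset
#' `<= naive_offset` form the naive graph.
#'
#' @param reads A [read_library()] (or character vector of sequences).
#' @param params An [assembly_params()].
#' @return An `overlap_graph`: `nodes` (canonical sequences, sorted),
#'   `count` (multiplicities), and `edges` over oriented node ids
#'   (ids `1..n` forward, `n+1..2n` reverse complement).
#' @export
build_overlap_graph <- function(reads, params) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  L <- params$readlength
  keep <- nchar(seqs) == L
  if (any(!keep))
    message("build_overlap_graph: discarded ", sum(!keep),
            " read(s) not of the working readlength")
  seqs <- seqs[keep]
  if (!length(seqs)) stop_ctx("build_overlap_graph: no reads of readlength ", L)
  rc <- revcomp(seqs)
  canon <- ifelse(seqs <= rc, seqs, rc)
  nodes <- sort(unique(canon))
  count <- tabulate(match(canon, nodes), length(nodes))
  n <- length(nodes)
  oseq <- c(nodes, revcomp(nodes))
  ef <- et <- eo <- vector("list", params$extension_offset)
  for (d in seq_len(params$extension_offset)) {
    k <- L - d
    pre <- substr(oseq, 1L, k)
    suf <- substr(oseq, d + 1L, L)
    dup <- duplicated(pre) | duplicated(pre, fromLast = TRUE)
    m <- match(suf, pre)
    ok <- !is.na(m)
    simple <- ok & !dup[ifelse(ok, m, 1L)]
    from <- which(simple)
    to <- m[simple]
    if (any(dup)) {
      grp <- split(which(dup), pre[dup])
      hit <- ok & !simple
      if (any(hit)) {
        lst <- grp[suf[hit]]
        from <- c(from, rep(which(hit), lengths(lst)))
        to <- c(to, unlist(lst, use.names = FALSE))
      }
    }
    sel <- from != to
    ef[[d]] <- from[sel]; et[[d]] <- to[sel]
    eo[[d]] <- rep.int(d, sum(sel))
  }
  edges <- data.frame(from = unlist(ef), to = unlist(et), offset = unlist(eo))
  # minimal offset per ordered pair: built in ascending d, keep first
  key <- (edges$from - 1) * (2 * n) + edges$to
  edges <- edges[!duplicated(key), , drop = FALSE]
  structure(list(nodes = nodes, count = count, n = n, edges = edges,
                 params = params),
            class = "overlap_graph")
}

#' @export
print.overlap_graph <- function(x, ...) {
  cat(sprintf("<overlap_graph> %d nodes (%d reads), %d edges (naive <= %d, extension <= %d)\n",
              x$n, sum(x$count), nrow(x$edges),
              x$params$naive_offset, x$params$extension_offset))
  invisible(x)
}

# Directed link table over oriented nodes. The successor of a node is the
# target of its minimal-offset edge, but the link is only trusted when the
# whole consulted edge set is consistent: every out-edge's implied
# extension string (the last `offset` characters of its target) must be a
# prefix of the longest one, i.e. all overlap evidence must describe a
# single genomic continuation. (Symmetrically for predecessors, with
# suffix agreement.) This makes junction detection robust to individual
# missing read-start positions: a repeat boundary is flagged as ambiguous
# as soon as any edge within the extension offset disagrees.
link_table <- function(edges, oseq, L, n2, incoming = FALSE) {
  to <- rep(0L, n2); off <- rep(NA_integer_, n2); ok <- logical(n2)
  if (nrow(edges)) {
    a <- if (incoming) edges$to else edges$from
    b <- if (incoming) edges$from else edges$to
    ord <- order(a, edges$offset, b)
    a <- a[ord]; b <- b[ord]; o <- edges$offset[ord]
    ext <- if (incoming) substr(oseq[b], 1L, o)
           else substr(oseq[b], L - o + 1L, L)
    glast <- which(!duplicated(a, fromLast = TRUE))
    sizes <- diff(c(0L, glast))
    longest <- ext[rep.int(glast, sizes)]
    consistent <- if (incoming) endsWith(longest, ext)
                  else startsWith(longest, ext)
    bad <- unique(a[!consistent])
    first <- which(!duplicated(a))
    to[a[first]] <- b[first]
    off[a[first]] <- o[first]
    ok[a[first]] <- TRUE
    ok[bad] <- FALSE
  }
  list(to = to, off = off, ok = ok)
}

#' Walk maximal unambiguous paths into contigs
#'
#' A walk continues from an oriented node to its unique minimal-offset
#' naive successor when that successor's unique minimal-offset naive
#' predecessor is the current node; where the naive graph ends, the same
#' rule is applied once over the extension-offset edge set. Every walk and
#' its reverse complement are represented once. Consensus is the exact
#' splice of the constituent reads (overlaps are exact by construction).
#' Output order is lexicographic by consensus sequence.
#'
#' @param graph An [build_overlap_graph()] result.
#' @param params An [assembly_params()] (defaults to the graph's).
#' @param min_count Minimum node multiplicity; nodes below it are removed
#'   before walking (depth support threshold).
#' @return A `contig_set`: `contigs` data frame (`id`, `seq`, `length`,
#'   `n_nodes`, `mean_depth`, `cyclic`) and `placements` (`node`,
#'   `contig`, `pos`, `strand`) locating every canonical node.
#' @export
walk_contigs <- function(graph, params = graph$params, min_count = 1L) {
  n <- graph$n
  n2 <- 2L * n
  L <- params$readlength
  oseq <- c(graph$nodes, revcomp(graph$nodes))
  edges <- graph$edges
  if (min_count > 1L) {
    drop <- which(graph$count < min_count)
    if (length(drop)) {
      bad <- c(drop, drop + n)
      edges <- edges[!(edges$from %in% bad | edges$to %in% bad), , drop = FALSE]
    }
  }
  nv <- link_table(edges, oseq, L, n2)
  pv <- link_table(edges, oseq, L, n2, incoming = TRUE)
  idx <- seq_len(n2)
  safe_to <- pmax(nv$to, 1L)
  nav <- nv$ok & nv$to > 0L & pv$ok[safe_to] & (pv$to[safe_to] == idx)
  next_of <- ifelse(nav, nv$to, 0L)
  off_of <- ifelse(nav, nv$off, NA_integer_)
  next_of[next_of == idx] <- 0L                 # guard against self-loops
  prev_of <- integer(n2)
  has_next <- next_of > 0L
  prev_of[next_of[has_next]] <- idx[has_next]

  visited <- logical(n)
  if (min_count > 1L) visited[graph$count < min_count] <- TRUE
  paths <- list()
  walk_from <- function(u) {
    path <- integer(0); offs <- integer(0)
    cur <- u
    repeat {
      path <- c(path, cur)
      visited[canon_id(cur, n)] <<- TRUE
      v <- next_of[cur]
      if (v == 0L) return(list(path = path, offs = offs, cyclic = FALSE))
      if (v == u) return(list(path = path, offs = c(offs, off_of[cur]),
                              cyclic = TRUE))
      if (visited[canon_id(v, n)])
        return(list(path = path, offs = offs, cyclic = FALSE))
      offs <- c(offs, off_of[cur])
      cur <- v
    }
  }
  for (u in which(prev_of == 0L)) {
    if (visited[canon_id(u, n)]) next
    paths[[length(paths) + 1L]] <- walk_from(u)
  }
  for (u in idx) {                               # leftover cycles
    if (visited[canon_id(u, n)]) next
    paths[[length(paths) + 1L]] <- walk_from(u)
  }

  contigs <- vector("list", length(paths))
  placements <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    m <- length(p$path)
    joins <- if (m > 1L) p$offs[seq_len(m - 1L)] else integer(0)
    pieces <- c(oseq[p$path[1L]],
                substr(oseq[p$path[-1L]], L - joins + 1L, L))
    cseq <- paste(pieces, collapse = "")
    pos <- 1L + c(0L, cumsum(joins))
    strand <- ifelse(p$path <= n, "+", "-")
    node <- canon_id(p$path, n)
    clen <- nchar(cseq)
    rcseq <- revcomp(cseq)
    if (rcseq < cseq) {
      cseq <- rcseq
      pos <- clen - (pos + L - 1L) + 1L
      strand <- ifelse(strand == "+", "-", "+")
      ordi <- order(pos)
      pos <- pos[ordi]; strand <- strand[ordi]; node <- node[ordi]
    }
    contigs[[i]] <- data.frame(
      seq = cseq, length = clen, n_nodes = m,
      mean_depth = sum(graph$count[node]) * L / clen,
      cyclic = p$cyclic, stringsAsFactors = FALSE)
    placements[[i]] <- data.frame(node = node, contig = i, pos = pos,
                                  strand = strand)
  }
  ctab <- do.call(rbind, contigs)
  ptab <- do.call(rbind, placements)
  ord <- order(ctab$seq)
  ctab <- ctab[ord, , drop = FALSE]
  remap <- match(seq_along(paths), ord)
  ptab$contig <- remap[ptab$contig]
  ctab <- cbind(id = sprintf("ctg%04d", seq_len(nrow(ctab))), ctab)
  rownames(ctab) <- NULL
  ptab <- ptab[order(ptab$contig, ptab$pos), , drop = FALSE]
  rownames(ptab) <- NULL
  structure(list(contigs = ctab, placements = ptab,
                 readlength = L, nodes = graph$nodes),
            class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("<contig_set> %d contig(s), total %d bp, N-longest %d bp\n",
              nrow(x$contigs), sum(x$contigs$length), max(x$contigs$length)))
  invisible(x)
}

#' Per-position read depth of one contig
#'
#' @param cset A [walk_contigs()] result.
#' @param graph The originating [build_overlap_graph()] (for multiplicities).
#' @param contig Contig index (row in `cset$contigs`).
#' @return Integer vector of per-position depth.
#' @export
contig_depth <- function(cset, graph, contig = 1L) {
  pl <- cset$placements[cset$placements$contig == contig, , drop = FALSE]
  clen <- cset$contigs$length[contig]
  L <- cset$readlength
  d <- numeric(clen + 1L)
  cnt <- graph$count[pl$node]
  for (i in seq_len(nrow(pl))) {
    d[pl$pos[i]] <- d[pl$pos[i]] + cnt[i]
    d[pl$pos[i] + L] <- d[pl$pos[i] + L] - cnt[i]
  }
  cumsum(d)[seq_len(clen)]
}

## ---- scaffolding ------------------------------------------------------

# Place uniform-length reads onto contigs by exact window match.
# Returns one row per uniquely placed read: contig, pos, strand.
place_reads_on_contigs <- function(cseqs, reads) {
  rl <- unique(nchar(reads$seq))
  if (length(rl) != 1L)
    stop_ctx("scaffold_pairs: reads must share one length (run trim_and_cut first)")
  nw <- pmax(nchar(cseqs) - rl + 1L, 0L)
  wctg <- rep.int(seq_along(cseqs), nw)
  wpos <- sequence(nw)
  wins <- substring(cseqs[wctg], wpos, wpos + rl - 1L)
  dup <- duplicated(wins) | duplicated(wins, fromLast = TRUE)
  mf <- match(reads$seq, wins)
  mr <- match(revcomp(reads$seq), wins)
  use_f <- !is.na(mf)
  m <- ifelse(use_f, mf, mr)
  placed <- !is.na(m)
  amb <- placed & dup[ifelse(placed, m, 1L)]
  ok <- placed & !amb
  data.frame(read = which(ok),
             contig = wctg[m[ok]],
             pos = wpos[m[ok]],
             strand = ifelse(use_f[ok], "+", "-"),
             stringsAsFactors = FALSE)
}

#' Scaffold contigs with paired-read links
#'
#' Reads are placed on contigs by exact match; a pair whose mates land on
#' two different contigs votes for an ordered, oriented adjacency with an
#' implied gap. Contigs are linked when at least `min_links` pairs agree on
#' order and orientation with plausible implied gaps; conflicting links are
#' resolved by majority, ties lexicographically. Gap estimates are the
#' median implied gap. Only "backbone" contigs (length >= `min_backbone`,
#' default the insert mean) are ordered; shorter contigs (typically repeat
#' copies) are placed back during [scaffold_sequence()].
#'
#' @param contigs A `contig_set` (or character vector of contig sequences).
#' @param reads A paired [read_library()].
#' @param insert_mean,insert_sd Library insert distribution (bp).
#' @param min_links Minimum concordant pairs to accept a link.
#' @param orientation Library orientation, `"FR"` or `"RF"`.
#' @param min_backbone Minimum contig length to take part in ordering.
#' @return A `scaffold_set`: list of scaffolds, each a data frame
#'   (`contig`, `orient`, `gap_after`, `links_after`) with a `circular`
#'   attribute; the full link table is attached as `attr(,"links")`.
#' @export
scaffold_pairs <- function(contigs, reads, insert_mean, insert_sd,
                           min_links = 5L, orientation = c("FR", "RF"),
                           min_backbone = NULL) {
  orientation <- match.arg(orientation)
  cseqs <- if (inherits(contigs, "contig_set")) contigs$contigs$seq
           else as.character(contigs)
  clen <- nchar(cseqs)
  min_backbone <- min_backbone %||% insert_mean
  rl <- nchar(reads$seq[1L])
  pl <- place_reads_on_contigs(cseqs, reads)
  pl$pair_id <- reads$pair_id[pl$read]
  pl$mate <- reads$mate[pl$read]
  if (orientation == "RF")
    pl$strand <- ifelse(pl$strand == "+", "-", "+")
  m1 <- pl[pl$mate == 1L, ]
  m2 <- pl[pl$mate == 2L, ]
  j <- match(m1$pair_id, m2$pair_id)
  okj <- !is.na(j)
  m1 <- m1[okj, ]; m2 <- m2[j[okj], ]
  diffc <- m1$contig != m2$contig
  m1 <- m1[diffc, ]; m2 <- m2[diffc, ]
  links <- data.frame(cA = integer(0), oA = character(0), cB = integer(0),
                      oB = character(0), n = integer(0), gap = numeric(0))
  if (nrow(m1)) {
    # orient A so mate 1 reads forward, B so mate 2 reads reverse
    oA <- ifelse(m1$strand == "+", "+", "-")
    posA <- ifelse(oA == "+", m1$pos,
                   clen[m1$contig] - (m1$pos + rl - 1L) + 1L)
    oB <- ifelse(m2$strand == "-", "+", "-")
    posB <- ifelse(oB == "+", m2$pos,
                   clen[m2$contig] - (m2$pos + rl - 1L) + 1L)
    gap <- insert_mean - (clen[m1$contig] - posA + 1L) - (posB + rl - 1L)
    sane <- gap >= -2L * rl & gap <= insert_mean + 3 * insert_sd
    lk <- data.frame(cA = m1$contig[sane], oA = oA[sane],
                     cB = m2$contig[sane], oB = oB[sane], gap = gap[sane])
    # mirrored direction (B' precedes A' when both are flipped)
    flip <- function(o) ifelse(o == "+", "-", "+")
    lk <- rbind(lk, data.frame(cA = lk$cB, oA = flip(lk$oB),
                               cB = lk$cA, oB = flip(lk$oA), gap = lk$gap))
    key <- paste(lk$cA, lk$oA, lk$cB, lk$oB)
    agg <- lapply(split(lk, key), function(g)
      data.frame(cA = g$cA[1L], oA = g$oA[1L], cB = g$cB[1L], oB = g$oB[1L],
                 n = nrow(g), gap = stats::median(g$gap)))
    links <- do.call(rbind, agg)
    rownames(links) <- NULL
    links <- links[links$n >= min_links, , drop = FALSE]
  }
  backbone <- which(clen >= min_backbone)
  if (!length(backbone)) backbone <- which.max(clen)
  bl <- links[links$cA %in% backbone & links$cB %in% backbone, , drop = FALSE]
  # majority successor per oriented backbone contig
  succ <- list()
  if (nrow(bl)) {
    for (kA in unique(paste(bl$cA, bl$oA))) {
      g <- bl[paste(bl$cA, bl$oA) == kA, , drop = FALSE]
      g <- g[order(-g$n, g$cB, g$oB), , drop = FALSE]
      succ[[kA]] <- g[1L, ]
    }
  }
  used <- logical(length(cseqs))
  scaffolds <- list()
  for (s0 in backbone[order(cseqs[backbone])]) {
    if (used[s0]) next
    chain <- data.frame(contig = s0, orient = "+", gap_after = NA_real_,
                        links_after = NA_integer_, stringsAsFactors = FALSE)
    used[s0] <- TRUE
    circular <- FALSE
    repeat {
      lastc <- chain$contig[nrow(chain)]
      lasto <- chain$orient[nrow(chain)]
      nx <- succ[[paste(lastc, lasto)]]
      if (is.null(nx)) break
      chain$gap_after[nrow(chain)] <- nx$gap
      chain$links_after[nrow(chain)] <- nx$n
      if (nx$cB == chain$contig[1L] && nx$oB == chain$orient[1L]) {
        circular <- TRUE
        break
      }
      if (used[nx$cB]) break
      chain <- rbind(chain, data.frame(contig = nx$cB, orient = nx$oB,
                                       gap_after = NA_real_,
                                       links_after = NA_integer_))
      used[nx$cB] <- TRUE
    }
    attr(chain, "circular") <- circular
    scaffolds[[length(scaffolds) + 1L]] <- chain
  }
  structure(scaffolds, class = "scaffold_set", links = links)
}

# Head/tail oriented node ids of each contig in each orientation.
contig_ends <- function(cset) {
  n <- length(cset$nodes)
  pl <- cset$placements
  ends <- lapply(seq_len(nrow(cset$contigs)), function(i) {
    p <- pl[pl$contig == i, , drop = FALSE]
    h <- p[which.min(p$pos), ]
    t <- p[which.max(p$pos), ]
    oid <- function(row) if (row$strand == "+") row$node else row$node + n
    head_f <- oid(h); tail_f <- oid(t)
    list(head = c("+" = head_f, "-" = rc_id(tail_f, n)),
         tail = c("+" = tail_f, "-" = rc_id(head_f, n)))
  })
  ends
}

#' Lay a scaffold out as one sequence
#'
#' Consecutive contigs are spliced over their exact junction overlap where
#' the overlap graph provides a path between their terminal reads (allowing
#' short non-backbone contigs, e.g. repeat copies, to be re-used along the
#' way); otherwise the estimated gap is written as `N`s. For a circular
#' scaffold the closing junction content is appended so that the returned
#' linear sequence ends with the overlap that [circularize()] merges.
#'
#' @param cset The `contig_set` the scaffold indexes into.
#' @param scaffold One scaffold from [scaffold_pairs()].
#' @param graph The originating overlap graph (junction edges).
#' @param max_hops Maximum intermediate contigs along a junction path.
#' @return A linear sequence string.
#' @export
scaffold_sequence <- function(cset, scaffold, graph, max_hops = 12L) {
  n <- graph$n
  ends <- contig_ends(cset)
  cseqs <- cset$contigs$seq
  oriented_seq <- function(ci, o) if (o == "+") cseqs[ci] else revcomp(cseqs[ci])
  in_scaffold <- scaffold$contig
  # oriented head lookup: oriented node id -> list of (contig, orient)
  heads <- list()
  for (ci in seq_along(cseqs)) for (o in c("+", "-")) {
    key <- as.character(ends[[ci]]$head[[o]])
    heads[[key]] <- rbind(heads[[key]],
                          data.frame(contig = ci, orient = o))
  }
  tail_ids <- unique(unlist(lapply(ends, function(e) e$tail)))
  tail_edges <- graph$edges[graph$edges$from %in% tail_ids, , drop = FALSE]
  edge_to_heads <- function(oid) {
    e <- tail_edges[tail_edges$from == oid, , drop = FALSE]
    if (!nrow(e)) return(NULL)
    out <- NULL
    for (r in seq_len(nrow(e))) {
      h <- heads[[as.character(e$to[r])]]
      if (!is.null(h)) {
        h$offset <- e$offset[r]
        out <- rbind(out, h)
      }
    }
    out
  }
  # BFS from tail of (cA,oA) to head of (cB,oB) through non-scaffold contigs
  junction_path <- function(cA, oA, cB, oB) {
    start <- ends[[cA]]$tail[[oA]]
    frontier <- list(list(tail_oid = start, steps = list()))
    seen <- character(0)
    for (hop in 0:max_hops) {
      nxt <- list()
      for (st in frontier) {
        cand <- edge_to_heads(st$tail_oid)
        if (is.null(cand)) next
        cand <- cand[order(cand$offset, cand$contig, cand$orient), ,
                     drop = FALSE]
        for (r in seq_len(nrow(cand))) {
          ci <- cand$contig[r]; o <- cand$orient[r]
          if (ci == cB && o == oB)
            return(c(st$steps, list(list(contig = ci, orient = o,
                                         offset = cand$offset[r]))))
          if (ci %in% in_scaffold) next
          key <- paste(ci, o)
          if (key %in% seen) next
          seen <- c(seen, key)
          nxt[[length(nxt) + 1L]] <-
            list(tail_oid = ends[[ci]]$tail[[o]],
                 steps = c(st$steps, list(list(contig = ci, orient = o,
                                               offset = cand$offset[r]))))
        }
      }
      if (!length(nxt)) break
      frontier <- nxt
    }
    NULL
  }
  L <- cset$readlength
  b <- nrow(scaffold)
  pieces <- oriented_seq(scaffold$contig[1L], scaffold$orient[1L])
  junctions <- if (isTRUE(attr(scaffold, "circular"))) seq_len(b) else
    seq_len(max(b - 1L, 0L))
  for (i in junctions) {
    cA <- scaffold$contig[i]; oA <- scaffold$orient[i]
    ni <- if (i == b) 1L else i + 1L
    cB <- scaffold$contig[ni]; oB <- scaffold$orient[ni]
    path <- junction_path(cA, oA, cB, oB)
    if (is.null(path)) {
      gap <- max(round(scaffold$gap_after[i] %||% 0), 0)
      pieces <- c(pieces, strrep("N", gap),
                  if (ni != 1L) oriented_seq(cB, oB))
      next
    }
    closing <- (ni == 1L)
    for (s in seq_along(path)) {
      st <- path[[s]]
      if (closing && s == length(path)) break  # stop before re-adding contig 1
      k <- L - st$offset
      sq <- oriented_seq(st$contig, st$orient)
      pieces <- c(pieces, substr(sq, k + 1L, nchar(sq)))
    }
  }
  paste(pieces, collapse = "")
}

#' Close a linear assembly into a circle
#'
#' If the two ends share an exact overlap of at least `min_overlap` bp the
#' sequence is merged into a circle (largest such overlap wins) and rotated
#' to canonical form (lexicographically least rotation over both strands),
#' unless an `anchor` subsequence is supplied to set position 1. Without a
#' terminal overlap the input is returned unchanged, linear, with a warning.
#'
#' @param x Sequence string or `circ_seq` (linear).
#' @param min_overlap Minimum terminal overlap to accept (bp); the natural
#'   assembler setting is `readlength - extension_offset`.
#' @param max_overlap Largest overlap searched (default half the length).
#' @param anchor Optional subsequence rotated to position 1.
#' @return A `circ_seq`, circular on success.
#' @export
circularize <- function(x, min_overlap, max_overlap = NULL, anchor = NULL) {
  s <- as_seq(x)
  nch <- nchar(s)
  max_overlap <- min(max_overlap %||% (nch %/% 2L), nch - 1L)
  if (max_overlap < min_overlap) {
    warning("circularize: sequence too short for a terminal overlap search",
            call. = FALSE)
    return(circ_seq(s, circular = FALSE, id = "unclosed"))
  }
  found <- 0L
  for (ov in seq(max_overlap, min_overlap, by = -1L)) {
    if (substr(s, 1L, ov) == substr(s, nch - ov + 1L, nch)) {
      found <- ov
      break
    }
  }
  if (found == 0L) {
    warning("circularize: no terminal overlap >= ", min_overlap,
            " bp; returning linear sequence", call. = FALSE)
    return(circ_seq(s, circular = FALSE, id = "unclosed"))
  }
  circ <- circ_seq(substr(s, 1L, nch - found), circular = TRUE,
                   id = "assembled_circle")
  if (!is.null(anchor)) {
    hit <- regexpr(anchor, doubled(circ), fixed = TRUE)
    if (hit > 0L) return(rotate(circ, as.integer(hit) - 1L))
    warning("circularize: anchor not found; using canonical rotation",
            call. = FALSE)
  }
  out <- canonical_rotation(circ)
  out$id <- "assembled_circle"
  out
}

#' Assemble a circular genome from a paired short-read library
#'
#' End-to-end driver: overlap graph, contig walk, paired-read scaffolding,
#' junction splicing through repeat contigs, and circular closure. For
#' error-free libraries whose repeats are all shorter than
#' `insert_mean - 2 * readlength`, this reproduces the source circle
#' exactly up to rotation and strand.
#'
#' @param reads A paired [read_library()] of uniform-length reads.
#' @param params An [assembly_params()].
#' @param insert_mean,insert_sd Library insert distribution (bp).
#' @param orientation Library orientation (`"FR"` or `"RF"`).
#' @param min_links Minimum pairs per scaffold link.
#' @param min_count Depth-support threshold for graph nodes.
#' @return List: `circle` (a [circ_seq()]), `contigs`, `scaffolds`, `graph`.
#' @export
assemble_circle <- function(reads, params, insert_mean, insert_sd,
                            orientation = "FR", min_links = 5L,
                            min_count = 1L) {
  g <- build_overlap_graph(reads, params)
  cs <- walk_contigs(g, params, min_count = min_count)
  min_ov <- params$readlength - params$extension_offset
  if (nrow(cs$contigs) == 1L) {
    circ <- circularize(cs$contigs$seq[1L], min_overlap = min_ov,
                        max_overlap = params$readlength)
    return(list(circle = circ, contigs = cs, scaffolds = NULL, graph = g))
  }
  sc <- scaffold_pairs(cs, reads, insert_mean, insert_sd,
                       min_links = min_links, orientation = orientation)
  lin <- scaffold_sequence(cs, sc[[1L]], g)
  circ <- circularize(lin, min_overlap = min_ov,
                      max_overlap = params$readlength)
  list(circle = circ, contigs = cs, scaffolds = sc, graph = g)
}

## ---- mapping and polishing -------------------------------------------

#' Map reads to a reference by exact seeding
#'
#' Seeds of length `seed_len` are taken at successive non-overlapping
#' offsets along the read until one matches the reference exactly (both
#' strands; the doubled sequence is scanned for circular references), then
#' candidate placements are scored by full-read mismatch count. Reads with
#' several placements at `<= max_mismatch` are assigned to the lowest
#' coordinate and flagged as multi-mapped.
#'
#' @param reference A [circ_seq()] or sequence string (then linear).
#' @param reads A [read_library()] or character vector.
#' @param seed_len Exact seed length (default
#'   `min(32, readlength - 4)`).
#' @param max_mismatch Maximum mismatches for a reported placement.
#' @return Alignment data frame: `read_id`, `ref_id`, `pos` (1-based),
#'   `width`, `strand`, `mismatches`, `multi`, `mapped`.
#' @export
map_reads <- function(reference, reads, seed_len = NULL, max_mismatch = 2L) {
  circular <- inherits(reference, "circ_seq") && reference$circular
  refseq <- as_seq(reference)
  ref_id <- if (inherits(reference, "circ_seq")) reference$id else "ref"
  Lr <- nchar(refseq)
  dbl <- if (circular) paste0(refseq, refseq) else refseq
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  ids <- if (is.data.frame(reads)) reads$id else
    sprintf("read%d", seq_along(seqs))
  m <- nchar(seqs)
  rl_max <- max(m)
  k <- seed_len %||% max(8L, min(32L, min(m) - 4L))
  nwin <- if (circular) Lr else nchar(dbl) - k + 1L
  wpos <- seq_len(nwin)
  wins <- substring(dbl, wpos, wpos + k - 1L)
  dup <- duplicated(wins) | duplicated(wins, fromLast = TRUE)
  dup_grp <- split(which(dup), wins[dup])

  seed_hits <- function(sub) {                  # list of window positions
    h <- match(sub, wins)
    lapply(seq_along(sub), function(i) {
      if (is.na(h[i])) return(integer(0))
      if (dup[h[i]]) dup_grp[[sub[i]]] else h[i]
    })
  }
  n <- length(seqs)
  out <- data.frame(read_id = ids, ref_id = ref_id, pos = NA_integer_,
                    width = m, strand = NA_character_,
                    mismatches = NA_integer_, multi = FALSE, mapped = FALSE,
                    stringsAsFactors = FALSE)
  fwd <- seqs
  rev <- revcomp(seqs)
  for (i in seq_len(n)) {
    mi <- m[i]
    offsets <- unique(c(seq(0L, mi - k, by = k), mi - k))
    best <- NULL
    for (strand in c("+", "-")) {
      rs <- if (strand == "+") fwd[i] else rev[i]
      cands <- integer(0)
      for (off in offsets) {
        h <- seed_hits(substr(rs, off + 1L, off + k))[[1L]]
        cands <- c(cands, h - off)
        if (length(cands)) break
      }
      cands <- unique(cands)
      cands <- cands[cands >= 1L & (cands + mi - 1L) <= nchar(dbl)]
      if (circular) cands <- unique(((cands - 1L) %% Lr) + 1L)
      else cands <- cands[(cands + mi - 1L) <= Lr]
      if (!length(cands)) next
      segs <- substring(dbl, cands, cands + mi - 1L)
      mm <- ifelse(segs == rs, 0L, NA_integer_)
      need <- is.na(mm)
      if (any(need)) mm[need] <- mismatch_counts(segs[need], rep(rs, sum(need)))
      ok <- mm <= max_mismatch
      if (!any(ok)) next
      cands <- cands[ok]; mm <- mm[ok]
      o <- order(mm, cands)
      hit <- list(pos = cands[o[1L]], mm = mm[o[1L]], strand = strand,
                  nhits = length(cands))
      if (is.null(best) || hit$mm < best$mm ||
          (hit$mm == best$mm && hit$pos < best$pos)) {
        hit$nhits <- hit$nhits + if (is.null(best)) 0L else best$nhits
        best <- hit
      } else best$nhits <- best$nhits + hit$nhits
    }
    if (!is.null(best)) {
      out$pos[i] <- best$pos
      out$strand[i] <- best$strand
      out$mismatches[i] <- best$mm
      out$multi[i] <- best$nhits > 1L
      out$mapped[i] <- TRUE
    }
  }
  out
}

# Per-read polish evidence: left/right anchored placement, breakpoint
# classification (substitution / reference-extra-base / reference-missing-
# base). Returns votes plus per-read covered spans for the depth track.
polish_evidence <- function(refseq, circular, seqs, seed_len) {
  Lr <- nchar(refseq)
  dbl <- if (circular) paste0(refseq, refseq) else refseq
  k <- seed_len
  # one window per circular position, so a repeated window marks a genuine
  # ambiguity rather than the doubled-string duplicate
  nwin <- if (circular) Lr else nchar(dbl) - k + 1L
  wins <- substring(dbl, seq_len(nwin), seq_len(nwin) + k - 1L)
  dup <- duplicated(wins) | duplicated(wins, fromLast = TRUE)
  safe_match <- function(sub) {
    h <- match(sub, wins)
    ifelse(!is.na(h) & dup[ifelse(is.na(h), 1L, h)], NA_integer_, h)
  }
  m <- nchar(seqs[1L])
  votes <- list()
  spans <- list()
  for (strand in c("+", "-")) {
    rs <- if (strand == "+") seqs else revcomp(seqs)
    a <- safe_match(substr(rs, 1L, k))                    # left anchor
    bhit <- safe_match(substr(rs, m - k + 1L, m))         # right anchor
    b <- bhit - (m - k)
    ok <- !is.na(a) & !is.na(b) & abs(b - a) <= 1L
    if (strand == "-") {
      # a read placed on "-" here was not placed on "+" with both anchors
      prev <- spans[["+"]]
      if (!is.null(prev)) ok <- ok & !(seq_along(seqs) %in% prev$read)
    }
    if (!any(ok)) next
    ai <- a[ok]; bi <- b[ok]; ri <- which(ok)
    rss <- rs[ok]
    delta <- bi - ai
    seg_len <- m + delta
    segs <- substring(dbl, ai, ai + seg_len - 1L)
    for (j in seq_along(ri)) {
      rd <- rss[j]; sg <- segs[j]
      if (delta[j] == 0L) {
        if (rd != sg) {
          x <- charToRaw(rd); y <- charToRaw(sg)
          diffp <- which(x != y)
          for (p in diffp)
            votes[[length(votes) + 1L]] <-
              c(pos = ai[j] + p - 1L, type = 1L,
                base = utf8ToInt(substr(rd, p, p)))
        }
      } else {
        # longest common prefix
        x <- charToRaw(rd); y <- charToRaw(sg)
        lcp <- 0L
        while (lcp < min(length(x), length(y)) && x[lcp + 1L] == y[lcp + 1L])
          lcp <- lcp + 1L
        if (delta[j] == 1L) {
          votes[[length(votes) + 1L]] <-
            c(pos = ai[j] + lcp, type = 2L, base = 0L)       # delete ref base
        } else {
          votes[[length(votes) + 1L]] <-
            c(pos = ai[j] + lcp - 1L, type = 3L,             # insert after pos
              base = utf8ToInt(substr(rd, lcp + 1L, lcp + 1L)))
        }
      }
    }
    spans[[strand]] <- data.frame(read = ri, start = ai, end = ai + seg_len - 1L)
  }
  list(votes = votes, spans = do.call(rbind, spans), Lr = Lr)
}

#' Polish an assembly by pileup majority
#'
#' Reads are re-anchored on the reference (exact seeds at both read ends);
#' disagreements are classified as substitutions, spurious reference bases
#' or missing reference bases, and an edit is applied wherever the
#' alternative is supported by at least `min_fraction` of at least
#' `min_depth` informatively covering reads. Iterates to fixpoint (at most
#' `max_rounds` rounds); the edit count is non-increasing across rounds.
#'
#' @param reference A [circ_seq()] (or string, treated as linear).
#' @param reads A [read_library()] or character vector of reads.
#' @param min_fraction Minimum supporting fraction of covering reads.
#' @param min_depth Minimum covering reads at the position.
#' @param max_rounds Maximum correction rounds.
#' @param seed_len Anchor seed length (default a third of the read length).
#' @return The polished reference, same class as supplied, with
#'   `attr(,"polish_edits")` giving per-round edit counts.
#' @export
polish <- function(reference, reads, min_fraction = 0.8, min_depth = 5L,
                   max_rounds = 3L, seed_len = NULL) {
  circular <- inherits(reference, "circ_seq") && reference$circular
  refseq <- as_seq(reference)
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  m <- nchar(seqs[1L])
  stopifnot(all(nchar(seqs) == m))
  k <- seed_len %||% max(8L, m %/% 3L)
  rounds <- integer(0)
  for (round in seq_len(max_rounds)) {
    ev <- polish_evidence(refseq, circular, seqs, k)
    Lr <- nchar(refseq)
    if (!length(ev$votes)) { rounds <- c(rounds, 0L); break }
    # depth from spans shrunk by one base at each end: a read that merely
    # abuts a breakpoint (e.g. ends level with an indel in a repetitive
    # context) is consistent with either allele and must not dilute the
    # supporting fraction
    depth <- numeric(2L * Lr + 2L)
    if (!is.null(ev$spans)) {
      s1 <- ev$spans$start + 1L
      e1 <- ev$spans$end - 1L
      keep <- e1 >= s1
      for (r in which(keep)) {
        depth[s1[r]] <- depth[s1[r]] + 1
        depth[e1[r] + 1L] <- depth[e1[r] + 1L] - 1
      }
      depth <- cumsum(depth)
    }
    wrap <- function(p) if (circular) ((p - 1L) %% Lr) + 1L else p
    vt <- do.call(rbind, ev$votes)
    vdf <- data.frame(pos = wrap(vt[, "pos"]), type = vt[, "type"],
                      base = vt[, "base"])
    key <- paste(vdf$pos, vdf$type, vdf$base)
    n_sup <- as.integer(table(key)[key])
    vdf <- vdf[!duplicated(key), , drop = FALSE]
    vdf$n <- n_sup[!duplicated(key)]
    # depth at the voted position: sum of linear track at p and p + Lr
    dp <- function(p) depth[p] + if (circular) depth[p + Lr] else 0
    vdf$depth <- vapply(vdf$pos, dp, 0)
    vdf <- vdf[vdf$depth >= min_depth & vdf$n / vdf$depth >= min_fraction, ,
               drop = FALSE]
    if (!nrow(vdf)) { rounds <- c(rounds, 0L); break }
    vdf <- vdf[order(-vdf$pos, -vdf$n), , drop = FALSE]
    vdf <- vdf[!duplicated(vdf$pos), , drop = FALSE]
    for (r in seq_len(nrow(vdf))) {
      p <- vdf$pos[r]
      if (vdf$type[r] == 1L) {
        substr(refseq, p, p) <- intToUtf8(vdf$base[r])
      } else if (vdf$type[r] == 2L) {
        refseq <- paste0(substr(refseq, 1L, p - 1L),
                         substr(refseq, p + 1L, nchar(refseq)))
      } else {
        refseq <- paste0(substr(refseq, 1L, p), intToUtf8(vdf$base[r]),
                         substr(refseq, p + 1L, nchar(refseq)))
      }
    }
    rounds <- c(rounds, nrow(vdf))
  }
  out <- if (inherits(reference, "circ_seq")) {
    reference$seq <- refseq
    reference
  } else refseq
  attr(out, "polish_edits") <- rounds
  out
}
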