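# Assembly diagnostics: per-position coverage, paired-fragment insert
# midpoints, breakpoint flags (a simultaneous break in coverage or
# midpoint density across all libraries indicates mis-assembly), and the
# AT-rich low-coverage window scan used to nominate a chloroplast
# replication origin (oriC).

#' Per-position read depth over a reference
#'
#' Wrap-aware for circular references: an alignment running past the end
#' contributes to the positions it wraps onto.
#'
#' @param alignments Alignment data frame (`pos`, `width`, `mapped`), e.g.
#'   from [map_reads()] or [read_sam()].
#' @param reference A [circ_seq()], or an integer reference length
#'   (then linear).
#' @return Numeric vector of depth, one entry per reference position.
#' @export
coverage_track <- function(alignments, reference) {
  circular <- inherits(reference, "circ_seq") && reference$circular
  L <- if (inherits(reference, "circ_seq")) nchar(reference$seq)
       else as.integer(reference)
  a <- alignments[alignments$mapped, , drop = FALSE]
  if (!nrow(a)) return(numeric(L))
  if (any(a$pos < 1L) || (!circular && any(a$pos + a$width - 1L > L)))
    stop_ctx("coverage_track: alignment outside the linear reference bounds")
  d <- numeric(2L * L + 1L)
  s <- a$pos
  e <- a$pos + a$width - 1L
  for (i in seq_along(s)) {
    d[s[i]] <- d[s[i]] + 1
    d[e[i] + 1L] <- d[e[i] + 1L] - 1
  }
  cov <- cumsum(d)
  out <- cov[seq_len(L)]
  if (circular) out <- out + cov[L + seq_len(L)]
  out
}

#' Insert midpoints of properly paired fragments
#'
#' Each concordant pair contributes one point: the middle of the fragment,
#' `floor((leftmost start + rightmost end)/2)` taken on the minor arc
#' containing both reads for circular references, and the outer distance
#' (insert) spanned on that arc. Discordant pairs (one mate unmapped, or
#' both mates on the same strand) are excluded and counted in
#' `attr(,"discordant")`.
#'
#' @param alignments Alignment data frame carrying `read_id`, `pos`,
#'   `width`, `strand`, `mapped`; mates are joined through `pair_id`/`mate`
#'   columns of `reads`.
#' @param reads The [read_library()] the alignments came from.
#' @param reference A [circ_seq()] or integer length (linear).
#' @return Data frame `pair_id`, `midpoint`, `insert`, with positions on
#'   the 1-based circle.
#' @export
midpoint_track <- function(alignments, reads, reference) {
  circular <- inherits(reference, "circ_seq") && reference$circular
  L <- if (inherits(reference, "circ_seq")) nchar(reference$seq)
       else as.integer(reference)
  a <- merge(alignments,
             data.frame(read_id = reads$id, pair_id = reads$pair_id,
                        mate = reads$mate, stringsAsFactors = FALSE),
             by = "read_id")
  a <- a[!is.na(a$pair_id), , drop = FALSE]
  m1 <- a[a$mate == 1L, ]
  m2 <- a[a$mate == 2L, ]
  j <- match(m1$pair_id, m2$pair_id)
  ok <- !is.na(j)
  m1 <- m1[ok, ]; m2 <- m2[j[ok], ]
  concordant <- m1$mapped & m2$mapped & (m1$strand != m2$strand)
  discordant <- sum(!concordant)
  m1 <- m1[concordant, ]; m2 <- m2[concordant, ]
  if (!nrow(m1)) {
    out <- data.frame(pair_id = character(0), midpoint = integer(0),
                      insert = integer(0))
    attr(out, "discordant") <- discordant
    return(out)
  }
  s1 <- m1$pos; e1 <- m1$pos + m1$width - 1L
  s2 <- m2$pos; e2 <- m2$pos + m2$width - 1L
  if (circular) {
    # two unwrappings; the minor arc (smaller outer distance) wins
    b1 <- e2 + ifelse(e2 < s1, L, 0L)          # mate 1 leftmost
    b2 <- e1 + ifelse(e1 < s2, L, 0L)          # mate 2 leftmost
    span1 <- b1 - s1
    span2 <- b2 - s2
    use1 <- span1 <= span2
    aL <- ifelse(use1, s1, s2)
    bR <- ifelse(use1, b1, b2)
  } else {
    aL <- pmin(s1, s2)
    bR <- pmax(e1, e2)
  }
  insert <- bR - aL
  midpoint <- (aL + bR) %/% 2L
  if (circular) midpoint <- ((midpoint - 1L) %% L) + 1L
  out <- data.frame(pair_id = m1$pair_id, midpoint = midpoint,
                    insert = insert, stringsAsFactors = FALSE)
  attr(out, "discordant") <- discordant
  out
}

#' Flag candidate mis-assembly breakpoints
#'
#' A position is flagged in one library when its coverage is zero, when no
#' fragment midpoint falls within a `window`-bp bin around it, or -- if
#' the library's expected insert distribution is supplied -- when the
#' median observed insert of the midpoints in its bin deviates from the
#' expected mean by more than three standard deviations (a break in the
#' insert-size distribution). Flags present in every library
#' (`all-libraries`) are the mis-assembly signal; flags confined to one
#' library are reported as `single-library`.
#'
#' @param tracks List, one element per library, each
#'   `list(coverage = <vector>, midpoints = <midpoint_track>,
#'   insert_mean =, insert_sd =)` (the insert fields are optional).
#' @param window Bin width for midpoint density (bp).
#' @param circular Is the reference circular?
#' @return Data frame of flagged intervals: `start`, `end`, `label`
#'   (`all-libraries` / `single-library`), `n_libraries`.
#' @export
detect_breakpoints <- function(tracks, window = 100L, circular = TRUE) {
  stopifnot(length(tracks) >= 1L)
  L <- length(tracks[[1L]]$coverage)
  flag_lib <- function(tr) {
    f <- tr$coverage == 0
    if (!is.null(tr$midpoints) && nrow(tr$midpoints)) {
      nbin <- max(1L, L %/% window)
      bin <- pmin(((tr$midpoints$midpoint - 1L) %/% window) + 1L, nbin)
      dens <- tabulate(bin, nbin)
      bad_bins <- which(dens == 0L)
      if (!is.null(tr$insert_mean) && !is.null(tr$insert_sd)) {
        med <- rep(NA_real_, nbin)
        agg <- tapply(tr$midpoints$insert, bin, stats::median)
        med[as.integer(names(agg))] <- agg
        off <- which(!is.na(med) &
                       abs(med - tr$insert_mean) > 3 * tr$insert_sd)
        bad_bins <- union(bad_bins, off)
      }
      for (b in bad_bins) {
        lo <- (b - 1L) * window + 1L
        hi <- min(b * window, L)
        f[lo:hi] <- TRUE
      }
    }
    f
  }
  flags <- vapply(tracks, flag_lib, logical(L))
  if (is.null(dim(flags))) flags <- matrix(flags, ncol = length(tracks))
  nlib <- rowSums(flags)
  lab <- rep(NA_character_, L)
  lab[nlib == length(tracks)] <- "all-libraries"
  lab[nlib >= 1L & nlib < length(tracks)] <- "single-library"
  flagged <- which(!is.na(lab))
  if (!length(flagged))
    return(data.frame(start = integer(0), end = integer(0),
                      label = character(0), n_libraries = integer(0)))
  brk <- c(0L, which(diff(flagged) > 1L | diff(nlib[flagged]) != 0L),
           length(flagged))
  out <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(i) {
    run <- flagged[(brk[i] + 1L):brk[i + 1L]]
    data.frame(start = run[1L], end = run[length(run)],
               label = lab[run[1L]], n_libraries = nlib[run[1L]])
  }))
  rownames(out) <- NULL
  out
}

#' Scan for AT-rich, low-coverage origin-of-replication candidates
#'
#' Slides a window around the circle and reports windows whose AT fraction
#' is at least `at_min` and whose mean coverage lies in the lowest
#' `cov_quantile` of all window means, ranked by (AT fraction descending,
#' relative coverage ascending). Candidates are descriptive; origin
#' assignment additionally needs external sequence comparison.
#'
#' @param genome A [circ_seq()].
#' @param coverage Per-position coverage (e.g. [coverage_track()]).
#' @param window Window width in bp (>= 50).
#' @param step Window step (default `window %/% 4`).
#' @param at_min Minimum AT fraction for a candidate.
#' @param cov_quantile Coverage quantile below which a window qualifies.
#' @return Data frame `start`, `end`, `at_fraction`, `rel_coverage`,
#'   ranked best first.
#' @export
at_rich_scan <- function(genome, coverage, window = 200L, step = NULL,
                         at_min = 0.80, cov_quantile = 0.05) {
  stopifnot(window >= 50L)
  step <- step %||% max(1L, window %/% 4L)
  s <- as_seq(genome)
  L <- nchar(s)
  stopifnot(length(coverage) == L)
  at <- as.integer(strsplit(s, "", fixed = TRUE)[[1L]] %in% c("A", "T"))
  at2 <- cumsum(c(0L, rep(at, 2L)))
  cov2 <- cumsum(c(0, rep(coverage, 2L)))
  starts <- seq(1L, L, by = step)
  at_frac <- (at2[starts + window] - at2[starts]) / window
  cov_mean <- (cov2[starts + window] - cov2[starts]) / window
  thr <- stats::quantile(cov_mean, cov_quantile, names = FALSE)
  keep <- at_frac >= at_min & cov_mean <= thr
  out <- data.frame(start = starts[keep],
                    end = ((starts[keep] + window - 2L) %% L) + 1L,
                    at_fraction = at_frac[keep],
                    rel_coverage = if (mean(coverage) > 0)
                      cov_mean[keep] / mean(coverage) else cov_mean[keep])
  out[order(-out$at_fraction, out$rel_coverage, out$start), , drop = FALSE]
}
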