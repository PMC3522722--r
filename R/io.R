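# Readers and writers for the standard formats the pipeline touches
# (FASTA, FASTQ, GFF3, a SAM subset, TSV hit tables), plus the per-library
# hit-length filter. Coordinates are 1-based inclusive in all files and in
# every exported data frame; any 0-based arithmetic is confined to function
# internals.

FEATURE_TYPES <- c("CDS", "tRNA", "rRNA", "pseudogene", "repeat", "origin")

## ---- read libraries ---------------------------------------------------

#' Construct a read library
#'
#' A read library is a data frame with one row per read: `id`, `seq`,
#' `qual`, `pair_id` (NA for unpaired reads) and `mate` (1 or 2).
#'
#' @param id,seq,qual Character vectors (qualities default to constant "I").
#' @param pair_id Pairing key; reads sharing a `pair_id` are mates.
#' @param mate Mate index within the pair (1 or 2).
#' @return A `read_library` data frame.
#' @export
read_library <- function(id, seq, qual = NULL, pair_id = NA_character_,
                         mate = NA_integer_) {
  n <- length(seq)
  if (is.null(qual)) qual <- vapply(nchar(seq), function(w) strrep("I", w), "")
  stopifnot(length(id) == n, length(qual) == n)
  if (any(nchar(qual) != nchar(seq)))
    stop_ctx("read_library: sequence/quality length mismatch")
  structure(
    data.frame(id = as.character(id), seq = toupper(seq), qual = qual,
               pair_id = rep_len(as.character(pair_id), n),
               mate = rep_len(as.integer(mate), n),
               stringsAsFactors = FALSE),
    class = c("read_library", "data.frame"))
}

empty_read_library <- function() {
  read_library(character(0), character(0), character(0))
}

#' @export
print.read_library <- function(x, ...) {
  cat(sprintf("<read_library> %d reads (%d paired), lengths %s\n",
              nrow(x), sum(!is.na(x$pair_id)),
              paste(range(c(nchar(x$seq), 0L))[if (nrow(x)) 1:2 else 1],
                    collapse = "-")))
  invisible(x)
}

## ---- FASTA ------------------------------------------------------------

#' Read a FASTA file
#'
#' Sequences are upper-cased and `U` is mapped to `T`. Malformed headers,
#' empty sequences and duplicate ids are rejected with the offending line.
#'
#' @param path File path.
#' @return Data frame with columns `id`, `seq`, `circular` (FALSE).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_ctx("read_fasta: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  hdr <- startsWith(lines, ">")
  if (any(keep) && !hdr[which(keep)[1L]])
    stop_ctx("read_fasta: ", path, " line ", which(keep)[1L],
             ": expected '>' header")
  bad <- which(hdr & !nzchar(sub("^>", "", trimws(lines))))
  if (length(bad))
    stop_ctx("read_fasta: ", path, " line ", bad[1L], ": empty header")
  # empty record = header followed by header/EOF
  h <- which(hdr)
  nxt <- c(h[-1L], length(lines) + 1L)
  body_len <- mapply(function(a, b) {
    if (a + 1L > b - 1L) 0L else sum(nchar(trimws(lines[(a + 1L):(b - 1L)])))
  }, h, nxt)
  if (any(body_len == 0L))
    stop_ctx("read_fasta: ", path, " line ", h[body_len == 0L][1L],
             ": record has empty sequence")
  # normalise U/u to T/t before handing the file to the DNA parser
  norm <- lines
  norm[!hdr] <- chartr("Uu", "Tt", norm[!hdr])
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  writeLines(norm, tmp)
  x <- Biostrings::readDNAStringSet(tmp, format = "fasta")
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop_ctx("read_fasta: ", path, ": duplicate id '",
             ids[duplicated(ids)][1L], "'")
  data.frame(id = ids,
             seq = toupper(as.character(x)),
             circular = FALSE, stringsAsFactors = FALSE)
}

#' Write a FASTA file
#'
#' @param records Data frame with `id` and `seq` (as from [read_fasta()]),
#'   or a `circ_seq`.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "circ_seq"))
    records <- data.frame(id = records$id, seq = records$seq)
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

## ---- FASTQ ------------------------------------------------------------

#' Read a FASTQ file into a read library
#'
#' Supports a single unpaired file, an interleaved pair file, or two
#' parallel mate files.
#'
#' @param path Path to the (first) FASTQ file.
#' @param path2 Optional second mate file.
#' @param interleaved If TRUE, consecutive records in `path` are mates.
#' @return A [read_library()].
#' @export
read_fastq <- function(path, path2 = NULL, interleaved = FALSE) {
  parse_one <- function(p) {
    if (!file.exists(p)) stop_ctx("read_fastq: no such file: ", p)
    if (file.size(p) == 0L)
      return(read_library(character(0), character(0), character(0)))
    lines <- readLines(p, warn = FALSE)
    if (length(lines) %% 4L != 0L)
      stop_ctx("read_fastq: ", p, " line ", length(lines),
               ": truncated record (line count not a multiple of 4)")
    i <- seq(1L, length(lines), by = 4L)
    if (!all(startsWith(lines[i], "@")))
      stop_ctx("read_fastq: ", p, " line ", i[!startsWith(lines[i], "@")][1L],
               ": expected '@' header")
    seq <- toupper(lines[i + 1L]); qual <- lines[i + 3L]
    bad <- which(nchar(seq) != nchar(qual))
    if (length(bad))
      stop_ctx("read_fastq: ", p, " line ", i[bad[1L]] + 3L,
               ": sequence/quality length mismatch")
    list(id = sub("\\s.*$", "", sub("^@", "", lines[i])), seq = seq, qual = qual)
  }
  a <- parse_one(path)
  if (!is.null(path2)) {
    b <- parse_one(path2)
    if (length(a$id) != length(b$id))
      stop_ctx("read_fastq: mate files have different record counts")
    pid <- sprintf("p%d", seq_along(a$id))
    return(read_library(c(a$id, b$id), c(a$seq, b$seq), c(a$qual, b$qual),
                        pair_id = c(pid, pid),
                        mate = rep(c(1L, 2L), each = length(a$id))))
  }
  if (interleaved) {
    n <- length(a$id)
    if (n %% 2L != 0L) stop_ctx("read_fastq: odd record count in interleaved file")
    pid <- rep(sprintf("p%d", seq_len(n / 2)), each = 2L)
    return(read_library(a$id, a$seq, a$qual, pair_id = pid,
                        mate = rep(c(1L, 2L), n / 2)))
  }
  read_library(a$id, a$seq, a$qual)
}

#' Write a read library to FASTQ
#'
#' Paired reads are written interleaved (mate 1 then mate 2).
#'
#' @param lib A [read_library()].
#' @param path Output path.
#' @export
write_fastq <- function(lib, path) {
  ord <- order(is.na(lib$pair_id), lib$pair_id, lib$mate)
  lib <- lib[ord, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(lib))
    writeLines(paste0("@", lib$id, "\n", lib$seq, "\n+\n", lib$qual), con)
  invisible(path)
}

## ---- GFF3 -------------------------------------------------------------

#' Read a GFF3 feature table
#'
#' Thin wrapper over `rtracklayer::import`; types outside the pipeline's
#' vocabulary (CDS, tRNA, rRNA, pseudogene, repeat, origin) are kept
#' verbatim with a warning. Features wrapping the circular origin are
#' encoded as two parts sharing a `part_of` attribute.
#'
#' @param path File path.
#' @return Data frame: `seqid`, `type`, `start`, `end`, `strand`, `phase`,
#'   plus attribute columns (`ID`, `gene`, `product`, ... as present).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop_ctx("read_gff3: no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  body <- which(!startsWith(raw, "#") & nzchar(trimws(raw)))
  for (ln in body) {
    f <- strsplit(raw[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop_ctx("read_gff3: ", path, " line ", ln, ": expected 9 tab-separated columns")
    st <- suppressWarnings(as.integer(f[4L])); en <- suppressWarnings(as.integer(f[5L]))
    if (is.na(st) || is.na(en) || en < st || st < 1L)
      stop_ctx("read_gff3: ", path, " line ", ln, ": invalid coordinates ",
               f[4L], "..", f[5L])
  }
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  unknown <- setdiff(unique(type), FEATURE_TYPES)
  if (length(unknown))
    warning("read_gff3: unknown feature type(s) kept verbatim: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  df <- data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
                   type = type,
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   phase = if (!is.null(meta$phase)) as.character(meta$phase)
                           else ".",
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  extras <- setdiff(colnames(meta), c("type", "phase", "source", "score"))
  for (cn in extras) {
    v <- meta[[cn]]
    if (!is.atomic(v)) v <- vapply(as.list(v), function(e)
      if (length(e)) paste(e, collapse = ",") else NA_character_, "")
    df[[cn]] <- as.character(v)
  }
  df
}

#' Write a GFF3 feature table
#'
#' @param features Data frame as returned by [read_gff3()].
#' @param path Output path.
#' @export
write_gff3 <- function(features, path) {
  if (any(features$end < features$start))
    stop_ctx("write_gff3: end < start in feature ",
             which(features$end < features$start)[1L])
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = ifelse(features$strand %in% c("+", "-"), features$strand, "*"))
  meta <- S4Vectors::DataFrame(source = "mastercircle", type = features$type)
  ph <- features$phase %||% "."
  meta$phase <- suppressWarnings(as.integer(ph))
  extras <- setdiff(colnames(features),
                    c("seqid", "type", "start", "end", "strand", "phase"))
  for (cn in extras) meta[[cn]] <- features[[cn]]
  S4Vectors::mcols(gr) <- meta
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

## ---- SAM (read-only subset) ------------------------------------------

#' Read a SAM file (subset)
#'
#' Accepts alignments from external mappers. Only the fields the pipeline
#' consumes are retained: QNAME, FLAG, RNAME, POS, CIGAR (reduced to a
#' reference-space match length), strand, mate position and TLEN.
#'
#' @param path Path to a SAM file with `@SQ` headers.
#' @return An alignment data frame (`read_id`, `ref_id`, `pos`, `width`,
#'   `strand`, `mate_pos`, `isize`, `mapped`).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop_ctx("read_sam: no such file: ", path)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "cigar", "strand", "mpos", "isize"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  mapped <- !bitwAnd(b$flag, 4L)
  width <- rep(NA_integer_, length(b$qname))
  ok <- mapped & !is.na(b$cigar)
  if (any(ok))
    width[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar[ok])
  data.frame(read_id = b$qname,
             ref_id = as.character(b$rname),
             pos = b$pos,
             width = width,
             strand = ifelse(bitwAnd(b$flag, 16L) > 0L, "-", "+"),
             mate_pos = b$mpos,
             isize = b$isize,
             mapped = mapped,
             stringsAsFactors = FALSE)
}

#' Write alignments as SAM
#'
#' Emits the same subset [read_sam()] consumes, with `@SQ` headers taken
#' from the reference lengths.
#'
#' @param aln Alignment data frame (see [map_reads()]).
#' @param ref_lengths Named integer vector of reference lengths.
#' @param path Output path.
#' @param seqs Optional named character vector of read sequences (SEQ column).
#' @export
write_sam <- function(aln, ref_lengths, path, seqs = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  flag <- ifelse(!aln$mapped, 4L, ifelse(aln$strand == "-", 16L, 0L))
  seqcol <- if (is.null(seqs)) "*" else unname(seqs[aln$read_id])
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t%d\t%d\t%s\t*",
                  aln$read_id, flag,
                  ifelse(aln$mapped, aln$ref_id, "*"),
                  ifelse(aln$mapped, aln$pos, 0L),
                  ifelse(aln$mapped, 60L, 0L),
                  ifelse(aln$mapped, sprintf("%dM", aln$width), "*"),
                  ifelse(is.na(aln$mate_pos), 0L, aln$mate_pos),
                  ifelse(is.na(aln$isize), 0L, aln$isize),
                  ifelse(is.na(seqcol), "*", seqcol))
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---- hit tables -------------------------------------------------------

#' Read a TSV hit table
#'
#' Columns: `query_id`, `subject_id`, `identity` (percent),
#' `alignment_length` (bp) and optionally `origin_class`.
#'
#' @param path File path.
#' @return Data frame of hits.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop_ctx("read_hits: no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_id", "subject_id", "identity", "alignment_length")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_ctx("read_hits: ", path, ": missing column(s) ",
             paste(miss, collapse = ", "))
  if (any(df$alignment_length < 1L))
    stop_ctx("read_hits: ", path, ": alignment_length < 1 at row ",
             which(df$alignment_length < 1L)[1L])
  if (any(df$identity < 0 | df$identity > 100))
    stop_ctx("read_hits: ", path, ": identity outside [0,100] at row ",
             which(df$identity < 0 | df$identity > 100)[1L])
  df
}

#' Write a TSV hit table
#' @param hits Data frame of hits.
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter hits by minimum alignment length
#'
#' Retains exactly the hits with `alignment_length >= min_alignment_length`
#' ("minimum filter" read inclusively), preserving input order. Typical
#' per-library settings are 60 bp for mate-pair libraries and 30 bp for a
#' short paired-end library.
#'
#' @param hits Hit data frame (see [read_hits()]).
#' @param min_alignment_length Minimum alignment length in bp (>= 1).
#' @return The retained sublist of `hits`.
#' @export
filter_hits <- function(hits, min_alignment_length) {
  stopifnot(min_alignment_length >= 1)
  hits[hits$alignment_length >= min_alignment_length, , drop = FALSE]
}

## ---- config -----------------------------------------------------------

#' Default configuration
#'
#' Nested list, keyed by module, of every numeric default used by the
#' pipeline; a YAML config file with the same shape overrides any subset.
#'
#' @return Nested list of defaults.
#' @export
config_defaults <- function() {
  list(
    read_prep = list(trim_length = 36, out_readlength = 35, start_offset = 4,
                     trim_end = "3p"),
    assembler = list(naive_offset = 4, extension_offset = 12, readlength = 35,
                     min_links = 5, min_count = 1),
    assembly_qc = list(breakpoint_window = 100, at_window = 200,
                       at_min = 0.80, cov_quantile = 0.05),
    repeat_structure = list(min_repeat_len = 1000, exhaustive_min_len = 100,
                            min_identity = 100, motif = "GGAGG",
                            motif_window = 20),
    seq_divergence = list(match = 1, mismatch = -1, gap_open = -5,
                          gap_extend = -1),
    editing_expression = list(min_abr = 0.40, min_cov = 3,
                              fold_threshold = 2.5, eps = 0.01),
    synthetic_data = list(insert_sd_frac = 0.10)
  )
}

#' Read a YAML config file over the package defaults
#'
#' @param path Optional YAML file; NULL returns the defaults.
#' @return Nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_ctx("read_config: no such file: ", path)
  user <- yaml::read_yaml(path)
  for (mod in names(user)) {
    cfg[[mod]] <- utils::modifyList(cfg[[mod]] %||% list(), user[[mod]])
  }
  cfg
}
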