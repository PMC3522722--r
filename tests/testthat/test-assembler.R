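# Overlap graph, contig walking, scaffolding, circular closure,
# mapping and polishing.

test_that("offset edges follow the overlap definition on a toy pair", {
  p <- assembly_params(2, 2, readlength = 6)
  g <- build_overlap_graph(c("ACGTAC", "GTACGG"), p)
  # overlap "GTAC" (length 4) -> offset 2
  i <- match("ACGTAC", g$nodes)
  j <- match(min("GTACGG", revcomp("GTACGG")), g$nodes)
  e <- g$edges
  hit <- e[e$offset == 2 & (e$from %in% c(i, i + g$n)) &
             (e$to %in% c(j, j + g$n)), ]
  expect_gte(nrow(hit), 1L)

  p1 <- assembly_params(1, 1, readlength = 6)
  g1 <- build_overlap_graph(c("ACGTAC", "GTACGG"), p1)
  expect_equal(nrow(g1$edges), 0L)
})

test_that("the graph equals a brute-force all-pairs oracle", {
  set.seed(40)
  for (rep in 1:3) {
    # overlapping reads from a random source to guarantee edges
    src <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    starts <- sort(sample(1:(120 - 12), 60, TRUE))
    reads <- substring(src, starts, starts + 11L)
    flip <- runif(length(reads)) < 0.5
    reads[flip] <- revcomp(reads[flip])
    p <- assembly_params(3, 5, readlength = 12)
    g <- build_overlap_graph(reads, p)
    want <- oracle_overlap_edges(reads, 12L, 5L)
    got <- g$edges[order(g$edges$from, g$edges$to), ]
    want <- want[order(want$from, want$to), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("a linear chain of overlapping reads becomes its superstring", {
  src <- "ACGGTTACAGGCTTAGCATCAGGACA"
  reads <- substring(src, c(1, 4, 8, 12, 16), c(1, 4, 8, 12, 16) + 10L)
  p <- assembly_params(4, 4, readlength = 11)
  g <- build_overlap_graph(reads, p)
  cs <- walk_contigs(g, p)
  expect_equal(nrow(cs$contigs), 1L)
  got <- cs$contigs$seq[1]
  want <- substr(src, 1, 26)
  expect_true(got == want || got == revcomp(want))
})

test_that("error-free coverage of a repeat-free circle reassembles it exactly", {
  g <- toy_circle(10000, seed = 41)
  sim <- toy_library(g$genome, seed = 42)
  p <- assembly_params(4, 12, readlength = 36)
  asm <- assemble_circle(sim$reads, p, insert_mean = 390, insert_sd = 39)
  expect_true(asm$circle$circular)
  expect_true(same_circle(asm$circle, g$genome))
})

test_that("contig walks stop at the flanks of a long exact repeat", {
  g <- toy_circle(20000, seed = 43, repeat_len = 2000)
  sim <- toy_library(g$genome, seed = 44)
  p <- assembly_params(4, 12, readlength = 36)
  gr <- build_overlap_graph(sim$reads, p)
  cs <- walk_contigs(gr, p)
  expect_gte(nrow(cs$contigs), 3L)
  # at least two contig ends fall inside the repeat margins
  tr <- g$truth$repeats
  margins <- c(tr$startA, tr$startA + tr$lenA, tr$startB, tr$startB + tr$lenB)
  dbl <- paste0(g$genome$seq, g$genome$seq)
  ends_in_margin <- 0L
  for (i in seq_len(nrow(cs$contigs))) {
    for (sq in c(cs$contigs$seq[i], revcomp(cs$contigs$seq[i]))) {
      hit <- regexpr(sq, dbl, fixed = TRUE)
      if (hit > 0) {
        epos <- c(as.integer(hit), as.integer(hit) + nchar(sq) - 1L) %% 20000L
        ends_in_margin <- ends_in_margin +
          sum(vapply(epos, function(e) any(abs(e - margins) < 100), TRUE))
      }
    }
  }
  expect_gte(ends_in_margin, 2L)
})

test_that("scaffolding links contigs with enough concordant pairs and a sane gap", {
  # two known contigs cut from a reference with a 200 bp gap
  set.seed(45)
  ref <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  ctgA <- substr(ref, 1, 2000)
  ctgB <- substr(ref, 2201, 4200)
  # pairs spanning the gap: mate1 in A, mate2 (reverse) in B
  starts <- seq(1850, 1960, by = 6)
  r1 <- substring(ref, starts, starts + 35L)
  r2 <- revcomp(substring(ref, starts + 354L, starts + 389L))
  lib <- read_library(c(sprintf("p%d/1", seq_along(r1)),
                        sprintf("p%d/2", seq_along(r2))),
                      c(r1, r2),
                      pair_id = rep(sprintf("p%d", seq_along(r1)), 2),
                      mate = rep(c(1L, 2L), each = length(r1)))
  sc <- scaffold_pairs(c(ctgA, ctgB), lib, insert_mean = 390, insert_sd = 39,
                       min_links = 5)
  expect_equal(length(sc), 1L)
  expect_equal(nrow(sc[[1]]), 2L)
  expect_lt(abs(sc[[1]]$gap_after[1] - 200), 39)

  # below min_links the contigs stay unscaffolded
  lib2 <- lib[lib$pair_id %in% c("p1", "p2"), ]
  sc2 <- scaffold_pairs(c(ctgA, ctgB), lib2, insert_mean = 390,
                        insert_sd = 39, min_links = 5)
  expect_true(all(vapply(sc2, nrow, 1L) == 1L))
})

test_that("contradictory link sets are resolved by majority", {
  set.seed(46)
  ref <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  ctgA <- substr(ref, 1, 2000)
  ctgB <- substr(ref, 2201, 4200)
  starts <- seq(1850, 1920, by = 6)                  # 12 true links
  r1 <- substring(ref, starts, starts + 35L)
  r2 <- revcomp(substring(ref, starts + 354L, starts + 389L))
  # 3 contradictory links claiming B precedes A
  fs <- seq(3900, 3912, by = 6)
  w1 <- substring(ref, fs, fs + 35L)
  w2 <- revcomp(substring(ref, fs - 3850L, fs - 3815L))
  n1 <- length(r1)
  nw <- length(w1)
  lib <- read_library(
    c(sprintf("t%d/1", 1:n1), sprintf("x%d/1", 1:nw),
      sprintf("t%d/2", 1:n1), sprintf("x%d/2", 1:nw)),
    c(r1, w1, r2, w2),
    pair_id = c(sprintf("t%d", 1:n1), sprintf("x%d", 1:nw),
                sprintf("t%d", 1:n1), sprintf("x%d", 1:nw)),
    mate = rep(c(1L, 2L), c(n1 + nw, n1 + nw)))
  sc <- scaffold_pairs(c(ctgA, ctgB), lib, insert_mean = 390, insert_sd = 39,
                       min_links = 2)
  links <- attr(sc, "links")
  best <- links[order(-links$n), ][1, ]
  expect_equal(best$n, 12L)                           # majority orientation wins
})

test_that("circularize merges a terminal repeat and is canonical", {
  s <- "TACGGATCCGATTACGATACG"                       # ends share "TACG"
  circ <- circularize(s, min_overlap = 4)
  expect_true(circ$circular)
  expect_equal(nchar(circ$seq), nchar(s) - 4L)
  expect_identical(circ$seq, canonical_rotation(circ)$seq)
  expect_warning(lin <- circularize("ACGTACTG", min_overlap = 4), "overlap")
  expect_false(lin$circular)
})

test_that("reads map back to their truth coordinates, repeats flagged multi", {
  g <- toy_circle(8000, seed = 47)
  sim <- toy_library(g$genome, seed = 48, coverage = 5)
  aln <- map_reads(g$genome, sim$reads)
  tr <- sim$truth$reads
  agree <- mean(aln$mapped & aln$pos == tr$start & aln$strand == tr$strand)
  expect_gte(agree, 0.99)

  g2 <- toy_circle(20000, seed = 49, repeat_len = 500)
  tr2 <- g2$truth$repeats
  inner <- substr(g2$genome$seq, tr2$startA + 50L, tr2$startA + 85L)
  a2 <- map_reads(g2$genome, inner)
  expect_true(a2$mapped && a2$multi)
  expect_equal(a2$pos, min(tr2$startA, tr2$startB) + 50L)
})

test_that("polish restores planted lesions and is a fixpoint on clean input", {
  g <- toy_circle(8000, seed = 50)
  true <- g$genome
  sim <- toy_library(true, seed = 51)
  lesion <- true
  substr(lesion$seq, 2000, 2000) <- chartr("ACGT", "GTAC",
                                           substr(true$seq, 2000, 2000))
  lesion$seq <- paste0(substr(lesion$seq, 1, 4999),
                       substr(lesion$seq, 5001, 8000))        # 1 bp deletion
  lesion$seq <- paste0(substr(lesion$seq, 1, 6499), "A",
                       substr(lesion$seq, 6500, nchar(lesion$seq)))  # insertion
  pol <- polish(lesion, sim$reads)
  expect_identical(pol$seq, true$seq)
  rounds <- attr(pol, "polish_edits")
  expect_true(all(diff(rounds) <= 0))                 # never diverges

  clean <- polish(true, sim$reads)
  expect_identical(clean$seq, true$seq)
  expect_equal(attr(clean, "polish_edits"), 0L)
})

test_that("assembly output is byte-identical across runs", {
  g <- toy_circle(12000, seed = 52, repeat_len = 150)
  sim <- toy_library(g$genome, seed = 53)
  p <- assembly_params(4, 12, readlength = 36)
  a1 <- assemble_circle(sim$reads, p, insert_mean = 390, insert_sd = 39)
  a2 <- assemble_circle(sim$reads, p, insert_mean = 390, insert_sd = 39)
  expect_identical(a1$circle$seq, a2$circle$seq)
  expect_identical(a1$contigs$contigs, a2$contigs$contigs)
})
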