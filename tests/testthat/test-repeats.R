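# Repeat discovery, genome accounting, motif scan, recombination products.

test_that("planted repeat pairs are recovered with their kinds", {
  g <- generate_genome(genome_spec(
    30000, repeats = list(list(kind = "direct", length = 2000L),
                          list(kind = "inverted", length = 600L)),
    origin = NULL, seed = 70))
  rp <- find_repeats(g$genome, min_len = 100)
  tr <- g$truth$repeats
  expect_equal(nrow(rp), 2L)
  covers <- function(found_s, found_l, s, l)
    found_s <= s && found_s + found_l >= s + l
  for (i in seq_len(nrow(tr))) {
    sA <- min(tr$startA[i], tr$startB[i]); sB <- max(tr$startA[i], tr$startB[i])
    row <- rp[rp$kind == tr$kind[i], ]
    expect_equal(nrow(row), 1L)
    # found pair covers the planted copies (chance end-extension allowed)
    expect_true(covers(row$startA, row$lenA, sA, tr$lenA[i]))
    expect_true(covers(row$startB, row$lenB, sB, tr$lenB[i]))
    expect_lte(row$lenA, tr$lenA[i] + 30L)
  }
  # the inverted pair really is reverse-complement-equal
  s <- g$genome$seq
  ir <- rp[rp$kind == "inverted", ]
  expect_identical(substr(s, ir$startB, ir$startB + ir$lenB - 1L),
                   revcomp(substr(s, ir$startA, ir$startA + ir$lenA - 1L)))
})

test_that("a repeat spanning the circle origin is still found", {
  g <- generate_genome(genome_spec(
    20000, repeats = list(list(kind = "direct", length = 800L)),
    origin = NULL, seed = 71))
  tr <- g$truth$repeats
  # rotate so copy A straddles position 1
  rot <- rotate(g$genome, tr$startA + 400L - 1L)
  rp <- find_repeats(rot, min_len = 200)
  expect_gte(nrow(rp), 1L)
  expect_gte(max(rp$lenA), 800L)
})

test_that("direct repeat discovery matches the rotation-comparison oracle", {
  set.seed(72)
  for (rep in 1:2) {
    base <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
    # plant one 60 bp direct pair
    piece <- substr(base, 101, 160)
    s <- paste0(substr(base, 1, 350), piece, substr(base, 411, 600))
    got <- find_repeats(circ_seq(s), min_len = 40, seed_k = 20)
    got <- got[got$kind == "direct", ]
    want <- oracle_direct_repeats(s, 40L)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      o1 <- got[order(got$startA), c("startA", "lenA", "startB")]
      o2 <- want[order(want$startA), ]
      expect_equal(o1$startA, o2$startA)
      expect_equal(o1$lenA, o2$len)
      expect_equal(o1$startB, o2$startB)
    }
  }
})

test_that("repeat fraction reproduces the printed inventories", {
  expect_equal(repeat_fraction(c(6229, 2274, 13319, 3919), 425718), 12.09)
  expect_equal(repeat_fraction(c(4460, 18971), 380861), 12.30)
  expect_equal(repeat_fraction(numeric(0), 1000), 0)
})

test_that("subcircle sizes follow the modular arithmetic and conserve length", {
  rp <- data.frame(kind = "direct", startA = 10L, lenA = 5L,
                   startB = 40L, lenB = 5L, identity = 100)
  pr <- recombination_products(100L, rp)
  expect_setequal(pr$size, c(30L, 70L))
  # conservation on randomized architectures
  set.seed(73)
  for (rep in 1:200) {
    L <- sample(1000:500000, 1)
    s1 <- sample(L, 1)
    len <- sample(50:200, 1)
    s2 <- ((s1 + len + sample(L - 2L * len - 100L, 1) - 1L) %% L) + 1L
    rp <- data.frame(kind = "direct", startA = min(s1, s2), lenA = len,
                     startB = max(s1, s2), lenB = len, identity = 100)
    if (rp$startB - rp$startA <= len) next           # overlapping copies
    pr <- recombination_products(L, rp)
    expect_equal(sum(pr$size), L)
  }
})

test_that("overlapping copies of one pair are rejected", {
  rp <- data.frame(kind = "direct", startA = 10L, lenA = 50L,
                   startB = 30L, lenB = 50L, identity = 100)
  expect_error(recombination_products(1000L, rp), "overlap")
})

test_that("a large-genome architecture yields the expected subcircles and isoforms", {
  L <- 425718L
  rp <- data.frame(
    kind = c("direct", "inverted"),
    startA = c(1L, 50000L), lenA = c(13319L, 6229L),
    startB = c(264797L, 150000L), lenB = c(13319L, 6229L),
    identity = 100)
  pr <- recombination_products(L, rp)
  sub <- pr[pr$kind == "subcircle", ]
  expect_setequal(sub$size, c(264796L, 160922L))
  # the larger subcircle contains both inverted copies -> two isoforms
  expect_equal(sub$n_isoforms[sub$size == 264796L], 2L)
  expect_equal(sub$n_isoforms[sub$size == 160922L], 1L)
})

test_that("gene density uses per-class span unions", {
  feats <- data.frame(seqid = "g", type = c("CDS", "CDS", "rRNA"),
                      start = c(100L, 200L, 500L), end = c(300L, 400L, 599L),
                      strand = "+", phase = ".")
  d <- gene_density(feats, 1000L)
  expect_equal(unname(d["protein-coding"]), 30.1)      # union 100..400
  expect_equal(unname(d["rRNA"]), 10.0)
  expect_equal(unname(d["tRNA"]), 0)
  one <- data.frame(seqid = "g", type = "CDS", start = 1L, end = 500L,
                    strand = "+", phase = ".")
  expect_equal(unname(gene_density(one, 1000L)["protein-coding"]), 50.0)
  expect_error(gene_density(data.frame(seqid = "g", type = "CDS",
                                       start = 900L, end = 1100L,
                                       strand = "+", phase = "."), 1000L),
               "outside")
})

test_that("upstream motif scanning is strand-aware and finds planted motifs", {
  s <- strrep("ACGT", 100)
  s <- paste0(substr(s, 1, 89), "GGAGG", substr(s, 95, 400))
  g <- circ_seq(s)
  feats <- data.frame(seqid = "g", type = "CDS", start = c(100L, 300L),
                      end = c(200L, 360L), strand = c("+", "+"), phase = "0",
                      ID = c("with", "without"))
  hit <- upstream_motif_scan(g, feats, "GGAGG", window = 20)
  expect_equal(hit$ID, "with")
  # same motif position but gene on the minus strand: not upstream any more
  featsm <- feats
  featsm$strand <- "-"
  expect_equal(nrow(upstream_motif_scan(g, featsm, "GGAGG", window = 20)), 0L)
})

test_that("generator-planted motifs are recovered exactly", {
  spec <- genome_spec(40000, genes = list(n_cds = 30L, cds_len = c(300, 900),
                                          motif_n = 10L),
                      origin = NULL, seed = 74)
  g <- generate_genome(spec)
  planted <- g$truth$genes$id[g$truth$genes$motif]
  hits <- upstream_motif_scan(g$genome, g$features, "GGAGG", window = 20)
  expect_setequal(hits$ID, planted)
})
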