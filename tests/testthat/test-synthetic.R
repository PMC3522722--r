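# Synthetic-data generators: planted architecture, determinism, and
# read/edit truth consistency.

test_that("planted repeats are exact copies and the AT window hits its target", {
  spec <- genome_spec(50000, gc = 0.45,
                      repeats = list(list(kind = "direct", length = 2000L),
                                     list(kind = "inverted", length = 800L)),
                      origin = list(start = NULL, width = 200L, at = 0.85),
                      seed = 21)
  g <- generate_genome(spec)
  tr <- g$truth$repeats
  s <- g$genome$seq
  dr <- tr[tr$kind == "direct", ]
  expect_identical(substr(s, dr$startA, dr$startA + dr$lenA - 1L),
                   substr(s, dr$startB, dr$startB + dr$lenB - 1L))
  ir <- tr[tr$kind == "inverted", ]
  expect_identical(substr(s, ir$startB, ir$startB + ir$lenB - 1L),
                   revcomp(substr(s, ir$startA, ir$startA + ir$lenA - 1L)))
  ori <- g$truth$origin
  win <- substr(s, ori$start, ori$end)
  at_frac <- 1 - gc_content(win) / 100
  expect_lt(abs(at_frac - 0.85), 0.02)
})

test_that("genome generation is deterministic in the seed", {
  spec <- genome_spec(20000, repeats = list(list(kind = "direct", length = 500L)),
                      seed = 7)
  expect_identical(generate_genome(spec)$genome$seq,
                   generate_genome(spec)$genome$seq)
  spec2 <- spec
  spec2$seed <- 8L
  expect_false(identical(generate_genome(spec)$genome$seq,
                         generate_genome(spec2)$genome$seq))
})

test_that("infeasible packing is reported as an error", {
  spec <- genome_spec(5000, repeats = list(list(kind = "direct", length = 2400L)),
                      origin = NULL, seed = 1)
  expect_error(generate_genome(spec), "infeasible packing")
})

test_that("error-free reads are exact genome substrings at their truth coordinates", {
  g <- toy_circle(15000, seed = 3)
  sim <- toy_library(g$genome, seed = 4, coverage = 10)
  dbl <- paste0(g$genome$seq, g$genome$seq)
  tr <- sim$truth$reads
  ext <- substring(dbl, tr$start, tr$start + tr$width - 1L)
  ext <- ifelse(tr$strand == "+", ext, revcomp(ext))
  expect_identical(ext, sim$reads$seq)
})

test_that("observed insert means and shadow weights match the library spec", {
  g <- toy_circle(30000, seed = 5)
  lib <- library_spec("custom", read_length = 50L, insert_mean = 400,
                      insert_sd = 40, n_pairs = 10000L, seed = 6)
  sim <- simulate_read_library(g$genome, lib)
  ins <- sim$truth$pairs$insert
  expect_lt(abs(mean(ins) - 400), 3 * 40 / sqrt(10000))

  lib2 <- library_spec("custom", read_length = 50L, insert_mean = 2000,
                       insert_sd = 200, n_pairs = 10000L,
                       shadow_fraction = 0.3, shadow_mean = 220,
                       seed = 7)
  sim2 <- simulate_read_library(g$genome, lib2)
  w_shadow <- mean(sim2$truth$pairs$insert < 1000)
  expect_lt(abs(w_shadow - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("library simulation is deterministic and respects the precondition", {
  g <- toy_circle(15000, seed = 8)
  lib <- library_spec("pe36", n_pairs = 100L, seed = 9)
  expect_identical(simulate_read_library(g$genome, lib)$reads$seq,
                   simulate_read_library(g$genome, lib)$reads$seq)
  small <- circ_seq(substr(g$genome$seq, 1, 500))
  expect_error(simulate_read_library(small, lib), "insert mean")
})

test_that("edited transcripts carry edits at the requested efficiency", {
  set.seed(10)
  cds <- data.frame(id = "c1", seq = paste0(
    "ATG", paste(sample(c("GCT", "GAA", "CCT", "TCA", "CGT"), 150, TRUE),
                 collapse = ""), "TAA"))
  cpos <- which(strsplit(cds$seq, "")[[1]] == "C")
  sites <- cpos[c(3, 10, 25)]
  lib <- library_spec("custom", read_length = 75L, insert_mean = 220,
                      n_pairs = 1L, seed = 11)

  # efficiency 1: every covering read shows T
  et1 <- simulate_edited_transcripts(cds, list(c1 = sites), 1.0, 40, lib)
  expect_equal(et1$truth$sites$edited, et1$truth$sites$covering)
  # efficiency 0: none do
  et0 <- simulate_edited_transcripts(cds, list(c1 = sites), 0.0, 40, lib)
  expect_equal(sum(et0$truth$sites$edited), 0L)
  # efficiency 0.5: binomial fraction
  et5 <- simulate_edited_transcripts(cds, list(c1 = sites), 0.5, 100, lib)
  frac <- sum(et5$truth$sites$edited) / sum(et5$truth$sites$covering)
  n <- sum(et5$truth$sites$covering)
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / n))
  # non-C site is an error
  notc <- which(strsplit(cds$seq, "")[[1]] != "C")[5]
  expect_error(simulate_edited_transcripts(cds, list(c1 = notc), 1, 10, lib),
               "not a C")
})

test_that("edit truth counts match a recount from the generated reads", {
  set.seed(12)
  cds <- data.frame(id = "c1", seq = paste0(
    "ATG", paste(sample(c("GCT", "GAA", "CCT", "TCA"), 120, TRUE),
                 collapse = ""), "TAA"))
  cpos <- which(strsplit(cds$seq, "")[[1]] == "C")
  sites <- cpos[c(2, 12)]
  lib <- library_spec("custom", read_length = 75L, insert_mean = 220,
                      n_pairs = 1L, seed = 13)
  et <- simulate_edited_transcripts(cds, list(c1 = sites), 0.7, 60, lib)
  tr <- et$truth$reads
  for (sidx in seq_along(sites)) {
    p <- sites[sidx]
    cov <- tr$start <= p & p <= tr$start + tr$width - 1L
    reads_cov <- et$reads$seq[cov]
    oriented <- ifelse(tr$strand[cov] == "+", reads_cov, revcomp(reads_cov))
    base <- substr(oriented, p - tr$start[cov] + 1L, p - tr$start[cov] + 1L)
    expect_equal(sum(base == "T"), et$truth$sites$edited[sidx])
    expect_equal(sum(cov), et$truth$sites$covering[sidx])
  }
})
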