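# RNA-editing application, codon usage, pileup confirmation, expression.

test_that("edits are applied with correct effect classification", {
  r <- apply_edits("ACGGAATAG", 2L)
  expect_equal(r$seq, "ATGGAATAG")
  expect_equal(r$effects$effect, "start-creation")

  r2 <- apply_edits("ATGGGACAA", 7L)                  # CAA -> TAA at last codon
  expect_equal(substr(r2$seq, 7, 9), "TAA")
  expect_equal(r2$effects$effect, "stop-creation")
  expect_false(r2$effects$internal_stop)

  r3 <- apply_edits("ATGCAAGGGTAA", 4L)               # internal CAA -> TAA
  expect_equal(r3$effects$effect, "stop-creation")
  expect_true(r3$effects$internal_stop)

  r4 <- apply_edits("ATGTCATGA", 5L)                  # TCA -> TTA: S -> L
  expect_equal(r4$effects$effect, "nonsynonymous")
  r5 <- apply_edits("ATGCCCTGA", 6L)                  # CCC -> CCT: both P
  expect_equal(r5$effects$effect, "silent")

  expect_identical(apply_edits("ATGAAA", integer(0))$seq, "ATGAAA")
  expect_error(apply_edits("ATGAAA", 2L), "not a C")
})

test_that("the internal-stop checker reports violations rather than accepting them", {
  cds <- data.frame(id = c("okgene", "badgene"),
                    seq = c("ATGACGGGGTAA", "ATGCAAGGGTAA"))
  sites <- list(okgene = 5L, badgene = 4L)
  v <- check_internal_stops(cds, sites)
  expect_equal(v$cds, "badgene")
  v2 <- check_internal_stops(cds[1, ], sites["okgene"])
  expect_equal(nrow(v2), 0L)
})

test_that("codon usage is scored per thousand coding bp and normalises", {
  cu <- codon_usage("ATGATG")
  expect_equal(cu$score[cu$codon == "ATG"], 333.33)
  set.seed(90)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 3 * sample(50:90, 1), TRUE),
          collapse = ""), "")
  cu2 <- codon_usage(seqs)
  expect_lt(abs(sum(cu2$score) * 3 - 1000), 0.5)

  # editing one TCA codon moves exactly 1000/total_bp of score
  cds <- data.frame(id = "c", seq = "ATGTCAGGGCCCAAATTTTGA")
  after <- apply_edits(cds, 5L)$seq
  before_u <- codon_usage(cds$seq)
  after_u <- codon_usage(after)
  shift <- 1000 / nchar(cds$seq)
  expect_equal(before_u$score[before_u$codon == "TCA"] -
                 after_u$score[after_u$codon == "TCA"], round(shift, 2))
  expect_equal(after_u$score[after_u$codon == "TTA"] -
                 before_u$score[before_u$codon == "TTA"], round(shift, 2))
})

test_that("the ABR/coverage filter passes exactly at its boundaries", {
  # synthetic pileup through the public interface: 5 reads, 2 edited
  cds <- data.frame(id = "c1", seq = "ATGCCTGGTGCAAGTCATGGATCCTGA")
  rl <- 20L
  mk <- function(seq, n, edit_at = NULL) {
    s <- substr(seq, 1, rl)
    if (!is.null(edit_at)) substr(s, edit_at, edit_at) <- "T"
    rep(s, n)
  }
  reads <- read_library(sprintf("r%d", 1:5),
                        c(mk(cds$seq, 3), mk(cds$seq, 2, edit_at = 4L)))
  obs <- confirm_edits(cds, reads, seed_len = 8L)
  site <- obs[obs$pos == 4L, ]
  expect_equal(site$coverage, 5L)
  expect_equal(site$edited, 2L)
  expect_equal(site$abr, 0.40)
  expect_true(site$pass)                               # ABR 0.40 passes

  reads2 <- read_library(sprintf("r%d", 1:2), mk(cds$seq, 2, edit_at = 4L))
  obs2 <- confirm_edits(cds, reads2, seed_len = 8L)
  expect_false(obs2$pass[obs2$pos == 4L])              # coverage 2 < 3

  reads3 <- read_library(sprintf("r%d", 1:10),
                         c(mk(cds$seq, 7), mk(cds$seq, 3, edit_at = 4L)))
  obs3 <- confirm_edits(cds, reads3, seed_len = 8L)
  expect_false(obs3$pass[obs3$pos == 4L])              # ABR 0.30 fails
})

test_that("simulated edit sites are recovered with no false positives", {
  set.seed(91)
  codons <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                              c("T", "C", "A", "G")), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  cds <- data.frame(
    id = c("c1", "c2"),
    seq = vapply(1:2, function(i)
      paste0("ATG", paste(sample(sense, 150, TRUE), collapse = ""), "TAA"), ""))
  sites <- lapply(cds$seq, function(s) {
    cp <- which(strsplit(s, "")[[1]] == "C")
    sort(sample(cp, 5))
  })
  names(sites) <- cds$id
  lib <- library_spec("custom", read_length = 75L, insert_mean = 220,
                      n_pairs = 1L, seed = 92)
  et <- simulate_edited_transcripts(cds, sites, efficiency = 0.8, depth = 50,
                                    lib)
  obs <- confirm_edits(cds, et$reads)
  hit <- obs[obs$pass, ]
  truth <- data.frame(cds = rep(names(sites), lengths(sites)),
                      pos = unlist(sites))
  found <- paste(hit$cds, hit$pos)
  want <- paste(truth$cds, truth$pos)
  expect_gte(mean(want %in% found), 0.95)              # sensitivity
  expect_equal(setdiff(found, want), character(0))     # no false sites
})

test_that("RPKM follows its formula and scaling law", {
  expect_equal(rpkm(1000, 1000, 1e6), 1000)
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_equal(rpkm(100, 2000, 2e6), rpkm(100, 2000, 1e6) / 2)
  expect_error(rpkm(10, 0, 1e6), "length")
  expect_error(rpkm(10, 100, 0), "positive")
})

test_that("fold-change flags are inclusive at 2.5 and combine across tissues", {
  expect_true(flag_fold_change(10, 25))
  expect_false(flag_fold_change(10, 24))
  expect_true(flag_fold_change(0, 1))                  # eps rescues zero
  tab <- expression_table(
    genes = c("g1", "g2"), lengths = c(1000, 1000),
    counts = list(leaf_fresh = c(100, 100), leaf_salt = c(260, 110),
                  root_fresh = c(100, 100), root_salt = c(300, 90)),
    total_mapped = c(leaf_fresh = 1e6, leaf_salt = 1e6,
                     root_fresh = 1e6, root_salt = 1e6))
  expect_true(tab$dual_tissue[1])                      # flagged in both tissues
  expect_false(tab$dual_tissue[2])
})
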