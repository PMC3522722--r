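# Coverage and midpoint diagnostics, breakpoint flags, oriC scanning.

test_that("coverage tracks follow the per-position definition", {
  aln <- data.frame(read_id = sprintf("r%d", 1:10), pos = 1L, width = 100L,
                    mapped = TRUE)
  expect_equal(coverage_track(aln, 100L), rep(10, 100))
  expect_equal(coverage_track(aln[0, ], 100L), rep(0, 100))

  # brute-force per-position recount, wrap-aware
  set.seed(60)
  L <- 500L
  a <- data.frame(read_id = sprintf("r%d", 1:100),
                  pos = sample(L, 100, TRUE), width = sample(20:50, 100, TRUE),
                  mapped = TRUE)
  got <- coverage_track(a, circ_seq(strrep("A", L)))
  want <- vapply(seq_len(L), function(p) {
    sum(vapply(seq_len(nrow(a)), function(i) {
      span <- ((a$pos[i] + seq_len(a$width[i]) - 2L) %% L) + 1L
      p %in% span
    }, TRUE))
  }, 0)
  expect_equal(got, want)
  expect_equal(sum(got), sum(a$width))                 # conservation
})

test_that("alignments beyond a linear reference are an error", {
  aln <- data.frame(read_id = "r", pos = 90L, width = 20L, mapped = TRUE)
  expect_error(coverage_track(aln, 100L), "bounds")
})

test_that("midpoints and inserts follow the minor-arc arithmetic", {
  lib <- read_library(c("p/1", "p/2", "q/1", "q/2", "u/1", "u/2"),
                      rep("A", 6),
                      pair_id = rep(c("p", "q", "u"), each = 2),
                      mate = rep(c(1L, 2L), 3))
  aln <- data.frame(
    read_id = c("p/1", "p/2", "q/1", "q/2", "u/1", "u/2"),
    pos = c(100L, 415L, 990L, 30L, 10L, 10L),
    width = c(36L, 36L, 11L, 36L, 36L, 36L),
    strand = c("+", "-", "+", "-", "+", "-"),
    mapped = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  mt <- midpoint_track(aln, lib, circ_seq(strrep("ACGT", 250)))
  expect_equal(mt$midpoint[mt$pair_id == "p"], 275L)
  expect_equal(mt$insert[mt$pair_id == "p"], 350L)
  expect_equal(mt$midpoint[mt$pair_id == "q"], 27L)     # wraps the origin
  expect_equal(mt$insert[mt$pair_id == "q"], 75L)
  expect_false("u" %in% mt$pair_id)                     # one mate unmapped
  expect_equal(attr(mt, "discordant"), 1L)
})

test_that("simulated midpoints are uniform on the circle", {
  g <- toy_circle(30000, seed = 61)
  lib <- library_spec("pe36", n_pairs = 10000L, seed = 62)
  sim <- simulate_read_library(g$genome, lib)
  mids <- ((sim$truth$pairs$frag_start +
              sim$truth$pairs$insert %/% 2L - 1L) %% 30000L) + 1L
  ct <- table(cut(mids, seq(0, 30000, by = 1500)))
  p <- stats::chisq.test(as.vector(ct))$p.value
  expect_gt(p, 0.01)
})

test_that("a planted deletion is flagged in all libraries near the lesion", {
  g <- toy_circle(20000, seed = 63)
  true <- g$genome
  broken <- circ_seq(paste0(substr(true$seq, 1, 9999),
                            substr(true$seq, 10500, 20000)))
  lib_specs <- list(library_spec("pe36", n_pairs = 6000L, seed = 64),
                    library_spec("custom", read_length = 36L,
                                 insert_mean = 800, insert_sd = 80,
                                 n_pairs = 6000L, seed = 65))
  tracks_ok <- list()
  tracks_bad <- list()
  for (i in seq_along(lib_specs)) {
    sim <- simulate_read_library(true, lib_specs[[i]])
    for (ref in list(true, broken)) {
      aln <- map_reads(ref, sim$reads)
      tr <- list(coverage = coverage_track(aln, ref),
                 midpoints = midpoint_track(aln, sim$reads, ref),
                 insert_mean = lib_specs[[i]]$insert_mean,
                 insert_sd = lib_specs[[i]]$insert_sd)
      if (identical(ref$seq, true$seq)) tracks_ok[[i]] <- tr
      else tracks_bad[[i]] <- tr
    }
  }
  ok_flags <- detect_breakpoints(tracks_ok)
  expect_false(any(ok_flags$label == "all-libraries"))
  bad_flags <- detect_breakpoints(tracks_bad)
  allb <- bad_flags[bad_flags$label == "all-libraries", ]
  expect_gte(nrow(allb), 1L)
  sd_max <- 80                                        # larger library sd
  dist <- pmax(allb$start - 10000, 10000 - allb$end, 0)
  expect_true(any(dist <= sd_max))
})

test_that("single-library dropouts get a single-library flag", {
  t1 <- list(coverage = c(rep(5, 400), rep(0, 50), rep(5, 550)),
             midpoints = NULL)
  t2 <- list(coverage = rep(5, 1000), midpoints = NULL)
  fl <- detect_breakpoints(list(t1, t2), circular = FALSE)
  expect_equal(fl$label, "single-library")
  expect_equal(c(fl$start, fl$end), c(401L, 450L))
})

test_that("an AT-rich low-coverage window is the top origin candidate", {
  spec <- genome_spec(20000, gc = 0.45,
                      origin = list(start = 14401L, width = 200L, at = 0.90),
                      seed = 66)
  g <- generate_genome(spec)
  cov <- rep(50, 20000)
  cov[14300:14700] <- 3                                # depressed coverage
  cand <- at_rich_scan(g$genome, cov, window = 200)
  expect_gte(nrow(cand), 1L)
  top <- cand[1, ]
  expect_true(top$start < 14601 && top$end > 14400)    # overlaps the plant

  # uniform GC + uniform coverage: nothing qualifies
  flat <- generate_genome(genome_spec(20000, gc = 0.5, origin = NULL, seed = 67))
  expect_equal(nrow(at_rich_scan(flat$genome, rep(50, 20000), window = 200)), 0L)
})

test_that("an all-AT genome ranks origin candidates by coverage alone", {
  g <- circ_seq(strrep("AT", 5000))
  cov <- rep(50, 10000)
  cov[3001:3200] <- 1
  cand <- at_rich_scan(g, cov, window = 200)
  expect_true(all(cand$at_fraction == 1))
  expect_true(cand$start[1] >= 2850 && cand$start[1] <= 3200)
})
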