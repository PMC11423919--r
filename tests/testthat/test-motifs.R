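# Build a ResidueProfile directly from per-fragment scores on a simple
# tiling; lets peak tests control the profile shape exactly.
profileFrom <- function(scoreByFragment, L = 100, window = 10, step = 10,
                        seed = 1) {
  bait <- generateBait(L, seed = seed)
  tiles <- tileSequence(bait, window, step, tailPolicy = "anchor_tail")
  scores <- data.frame(fragment_id = fragmentIds(tiles),
                       weighted_score = scoreByFragment)
  list(tiles = tiles,
       profile = buildResidueProfile(scores, tiles))
}

test_that("one plateau per half yields one peak per half", {
  # fragments of width 10: high scores on fragments 2 (11-20) and 8 (71-80)
  x <- profileFrom(c(0, 100, 0, 0, 0, 0, 0, 80, 0, 0))
  peaks <- callPeaks(x$profile)
  expect_equal(peaks$half, c("N", "C"))
  expect_equal(peaks$start, c(11L, 71L))
  expect_equal(peaks$end, c(20L, 80L))
  expect_equal(peaks$peak_score, c(100, 80))
  expect_true(all(c("frag02") %in% unlist(peaks$supporting_fragments[1])))
})

test_that("a uniform profile degenerates to whole-half peaks under mean_plus_k_sd", {
  x <- profileFrom(rep(5, 10))
  # sd = 0 so the threshold equals the mean and every residue qualifies;
  # the documented outcome is one run spanning each entire half
  peaks <- callPeaks(x$profile)
  expect_equal(peaks$start, c(1L, 51L))
  expect_equal(peaks$end, c(50L, 100L))
})

test_that("a half with no qualifying residues warns and is dropped", {
  x <- profileFrom(c(0, 100, 0, 0, 0, 0, 0, 80, 0, 0))
  expect_warning(p <- callPeaks(x$profile,
                                policy = thresholdPolicy("absolute", v = 90)),
                 "C-terminal half")
  expect_equal(p$half, "N")
})

test_that("raising an absolute threshold never widens a peak", {
  set.seed(99)
  x <- profileFrom(runif(10, 0, 100))
  widths <- sapply(c(10, 30, 50, 70), function(v) {
    p <- suppressWarnings(
      callPeaks(x$profile, policy = thresholdPolicy("absolute", v = v)))
    n <- p[p$half == "N", ]
    if (nrow(n) == 0) 0L else n$end - n$start + 1L
  })
  expect_true(all(diff(widths) <= 0))
})

test_that("motif refinement extracts the planted contact run exactly", {
  bait <- generateBait(315, seed = 41)
  tiles <- tileSequence(bait, 50, 25)
  # fragment frag08 spans 176-225; contacts exactly at 197-209
  cs <- madeContactSet("frag08", 176:225,
                       data.frame(bait_res = 197:209, receptor_res = 1:13))
  scores <- data.frame(fragment_id = "frag08", weighted_score = 1000)
  peak <- list(start = 176L, end = 225L,
               supporting_fragments = list("frag08"))
  call <- refineMotif(peak, list(frag08 = cs), scores, tiles,
                      gapTolerance = 1, minMotifLength = 5,
                      name = "MotifB")
  expect_equal(call$start, 197L)
  expect_equal(call$end, 209L)
  expect_equal(call$length, 13L)
  expect_equal(call$sequence,
               as.character(Biostrings::subseq(baitSeq(tiles), 197, 209)))
  expect_equal(call$source_fragment, "frag08")
})

test_that("gap tolerance controls run merging and totals pick the winner", {
  bait <- generateBait(100, seed = 42)
  tiles <- tileSequence(bait, 50, 25, tailPolicy = "drop_tail")
  pairs <- data.frame(bait_res = c(30:33, 35:36),
                      receptor_res = 1:6)
  cs <- madeContactSet("frag01", 1:50, pairs)
  scores <- data.frame(fragment_id = "frag01", weighted_score = 100)
  peak <- list(start = 26L, end = 40L, supporting_fragments = list("frag01"))
  merged <- refineMotif(peak, list(frag01 = cs), scores, tiles,
                        gapTolerance = 1, minMotifLength = 2)
  expect_equal(c(merged$start, merged$end), c(30L, 36L))
  splitRuns <- refineMotif(peak, list(frag01 = cs), scores, tiles,
                           gapTolerance = 0, minMotifLength = 2)
  expect_equal(c(splitRuns$start, splitRuns$end), c(30L, 33L))
})

test_that("runs shorter than the minimum motif length are rejected", {
  bait <- generateBait(100, seed = 43)
  tiles <- tileSequence(bait, 50, 25, tailPolicy = "drop_tail")
  cs <- madeContactSet("frag01", 1:50,
                       data.frame(bait_res = 10:12, receptor_res = 1:3))
  scores <- data.frame(fragment_id = "frag01", weighted_score = 10)
  peak <- list(start = 1L, end = 50L, supporting_fragments = list("frag01"))
  expect_error(refineMotif(peak, list(frag01 = cs), scores, tiles,
                           minMotifLength = 5), "shorter than")
})

test_that("the highest-scoring supporting fragment is chosen, ties leftmost", {
  bait <- generateBait(100, seed = 44)
  tiles <- tileSequence(bait, 50, 25, tailPolicy = "drop_tail")
  csA <- madeContactSet("frag01", 1:50,
                        data.frame(bait_res = 30:36, receptor_res = 1:7))
  csB <- madeContactSet("frag02", 26:75,
                        data.frame(bait_res = 40:46, receptor_res = 1:7))
  scores <- data.frame(fragment_id = c("frag01", "frag02"),
                       weighted_score = c(500, 500))
  peak <- list(start = 26L, end = 50L,
               supporting_fragments = list(c("frag01", "frag02")))
  call <- refineMotif(peak, list(frag01 = csA, frag02 = csB), scores,
                      tiles, minMotifLength = 5)
  expect_equal(call$source_fragment, "frag01")  # leftmost on tie
  scores$weighted_score <- c(400, 500)
  call2 <- refineMotif(peak, list(frag01 = csA, frag02 = csB), scores,
                       tiles, minMotifLength = 5)
  expect_equal(call2$source_fragment, "frag02")
})

test_that("motif calling is deterministic for fixed inputs", {
  x <- profileFrom(c(0, 100, 0, 0, 0, 0, 0, 80, 0, 0))
  p1 <- callPeaks(x$profile)
  p2 <- callPeaks(x$profile)
  expect_identical(as.data.frame(p1[1:5]), as.data.frame(p2[1:5]))
})

test_that("motif reports round-trip through TSV and FASTA", {
  bait <- generateBait(60, seed = 45, id = "bait1")
  calls <- data.frame(
    name = c("MotifA", "MotifB"), start = c(5L, 40L), end = c(13L, 52L),
    length = c(9L, 13L),
    sequence = c(as.character(Biostrings::subseq(baitSeq(bait), 5, 13)),
                 as.character(Biostrings::subseq(baitSeq(bait), 40, 52))),
    mean_per_residue_contacts = c(2.5, 1.9),
    source_fragment = c("frag01", "frag02"))
  dir <- withr::local_tempdir()
  paths <- reportMotifs(calls, bait, dir)
  fa <- Biostrings::readAAStringSet(paths[["fasta"]])
  expect_equal(length(fa), 2L)
  expect_equal(Biostrings::width(fa), c(9L, 13L))
  expect_match(names(fa)[1], "MotifA bait1:5-13")
  tab <- read.delim(paths[["tsv"]])
  expect_equal(tab$start, c(5L, 40L))

  # zero calls: header-only TSV, empty FASTA
  paths0 <- reportMotifs(NULL, bait, file.path(dir, "empty"))
  tab0 <- read.delim(paths0[["tsv"]])
  expect_equal(nrow(tab0), 0L)
  expect_equal(length(readLines(paths0[["fasta"]])), 0L)

  # sequence/coordinate mismatch is caught
  calls$sequence[1] <- "WWWWWWWWW"
  expect_error(reportMotifs(calls, bait, dir), "do not match")
})
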