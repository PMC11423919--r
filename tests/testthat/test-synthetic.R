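test_that("bait generation is seed-deterministic", {
  b1 <- generateBait(315, seed = 1)
  b2 <- generateBait(315, seed = 1)
  expect_identical(as.character(b1), as.character(b2))
  expect_equal(length(b1), 315L)
  expect_false(as.character(generateBait(315, seed = 2)) ==
               as.character(b1))
  expect_equal(length(generateBait(1, seed = 1)), 1L)
})

test_that("generated complexes contact exactly the planted residues", {
  bait <- generateBait(315, seed = 6)
  tiles <- tileSequence(bait, 50, 25)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  # fragment frag08 spans 176-225; plant 197-209, no decoys
  gt <- generateComplex(tiles, "frag08",
                        plants = list(plantSpec(c(197, 209))),
                        receptorLength = 119, seed = 8, path = pdb)
  cx <- parseComplex(pdb, "A", "B", globalStart = 176)
  oracle <- bruteContacts(cx, cutoff = 4.0)
  gotRes <- sort(unique(as.integer(sub(" .*", "", oracle$keys))))
  expect_equal(gotRes, 197:209)
  # oracle pairs equal the generator's recorded ground truth exactly
  expect_setequal(oracle$keys,
                  paste(gt$contacts$bait_res, gt$contacts$receptor_res))
  # and the packaged counter agrees with both
  cs <- countContacts(cx)
  expect_equal(sort(paste(contactPairs(cs)$bait_res,
                          contactPairs(cs)$receptor_res)), oracle$keys)
})

test_that("a plant outside the fragment yields a contact-free complex", {
  bait <- generateBait(315, seed = 7)
  tiles <- tileSequence(bait, 50, 25)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  expect_warning(
    generateComplex(tiles, "frag12", plants = list(plantSpec(c(28, 36))),
                    receptorLength = 119, seed = 9, path = pdb),
    "contact-free")
  cx <- parseComplex(pdb, "A", "B", globalStart = 266)
  expect_equal(contactCount(countContacts(cx)), 0L)
})

test_that("complex generation is byte-deterministic under its seed", {
  bait <- generateBait(315, seed = 10)
  tiles <- tileSequence(bait, 50, 25)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  plants <- list(plantSpec(c(28, 36), decoyRate = 0.1, plddtNoiseSd = 4,
                           coordNoiseSd = 0.1))
  generateComplex(tiles, "frag02", plants = plants, seed = 5, path = p1)
  generateComplex(tiles, "frag02", plants = plants, seed = 5, path = p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("decoy contacts are recorded in the ground truth exactly", {
  bait <- generateBait(315, seed = 12)
  tiles <- tileSequence(bait, 50, 25)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  gt <- generateComplex(tiles, "frag02",
                        plants = list(plantSpec(c(28, 36),
                                                decoyRate = 0.25)),
                        receptorLength = 119, seed = 13, path = pdb)
  expect_true(any(gt$contacts$type == "decoy"))
  cx <- parseComplex(pdb, "A", "B", globalStart = 26)
  oracle <- bruteContacts(cx)
  expect_setequal(oracle$keys,
                  paste(gt$contacts$bait_res, gt$contacts$receptor_res))
})

test_that("coordinate noise preserves the planted classification", {
  bait <- generateBait(315, seed = 14)
  tiles <- tileSequence(bait, 50, 25)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  gt <- generateComplex(tiles, "frag08",
                        plants = list(plantSpec(c(197, 209),
                                                coordNoiseSd = 0.15)),
                        receptorLength = 119, seed = 15, path = pdb)
  cx <- parseComplex(pdb, "A", "B", globalStart = 176)
  oracle <- bruteContacts(cx)
  expect_setequal(oracle$keys,
                  paste(gt$contacts$bait_res, gt$contacts$receptor_res))
})

test_that("planted pLDDT levels land in the B-factor column per residue", {
  bait <- generateBait(315, seed = 16)
  tiles <- tileSequence(bait, 50, 25)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  generateComplex(tiles, "frag02",
                  plants = list(plantSpec(c(28, 36), plddtPlanted = 95,
                                          plddtBackground = 60)),
                  seed = 17, path = pdb)
  cx <- parseComplex(pdb, "A", "B", globalStart = 26)
  pl <- extractPlddt(cx, "A")
  glob <- 26:75
  expect_true(all(pl[glob >= 28 & glob <= 36] == 95))
  expect_true(all(pl[glob < 28 | glob > 36] == 60))
})

test_that("dataset generation emits one structure per fragment plus metadata", {
  dir <- withr::local_tempdir()
  ds <- generateDataset(dir, seed = 18)
  expect_equal(length(list.files(dir, pattern = "\\.pdb$")), 12L)
  man <- readManifest(ds$manifest)
  expect_equal(nrow(man), 12L)
  expect_equal(man$fragment_id, fragmentIds(ds$tiles))
  gt <- jsonlite::read_json(ds$groundTruthPath, simplifyVector = TRUE)
  expect_equal(gt$planted$start, c(28L, 197L))
  expect_equal(gt$planted$end, c(36L, 209L))
  # rerun reproduces files and ground truth byte-for-byte
  dir2 <- withr::local_tempdir()
  generateDataset(dir2, seed = 18)
  for (f in c("manifest.tsv", "bait.fasta", "ground_truth.json",
              "frag01.pdb", "frag07.pdb"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)), label = f)
})
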