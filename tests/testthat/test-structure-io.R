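test_that("a generated complex round-trips through PDB parsing", {
  bait <- generateBait(60, seed = 5)
  tiles <- tileSequence(bait, 50, 25)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  generateComplex(tiles, "frag01", plants = list(plantSpec(c(10, 15))),
                  receptorLength = 30, seed = 3, path = pdb)
  cx <- parseComplex(pdb, baitChain = "A", receptorChain = "B",
                     globalStart = 1)
  expect_s4_class(cx, "ComplexStructure")
  expect_setequal(unique(cx@atoms$chain), c("A", "B"))
  expect_equal(length(cx@plddt), 50L)
  # idempotence: parse -> write -> parse gives the same atom multiset
  pdb2 <- withr::local_tempfile(fileext = ".pdb")
  writeComplexPdb(cx, pdb2)
  cx2 <- parseComplex(pdb2, "A", "B", globalStart = 1)
  ord <- function(a) a[order(a$chain, a$resno, a$elety), ]
  a1 <- ord(cx@atoms); a2 <- ord(cx2@atoms)
  rownames(a1) <- rownames(a2) <- NULL
  expect_equal(a1[c("chain", "resno", "elety", "b")],
               a2[c("chain", "resno", "elety", "b")])
  expect_equal(a1$x, a2$x, tolerance = 1e-3)
})

test_that("PDB and mmCIF carrying the same content parse identically", {
  atoms <- rbind(
    atomRow("A", rep(1:5, each = 2), rep(c("CA", "CB"), 5),
            x = rep(seq(0, 15.2, by = 3.8), each = 2),
            y = rep(c(0, -1.5), 5), z = 0, b = rep(c(91, 82, 73, 64, 55),
                                                   each = 2)),
    atomRow("B", rep(1:3, each = 2), rep(c("CA", "CB"), 3),
            x = rep(c(0, 3.8, 7.6), each = 2), y = rep(c(3.3, 4.8), 3),
            z = 0, b = 70))
  cxMem <- toyComplex(atoms)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  cif <- withr::local_tempfile(fileext = ".cif")
  writeComplexPdb(cxMem, pdb)
  writeMinimalCif(atoms, cif)
  cxPdb <- parseComplex(pdb, "A", "B", globalStart = 1)
  cxCif <- parseComplex(cif, "A", "B", globalStart = 1)
  expect_equal(cxPdb@plddt, cxCif@plddt)
  keep <- c("chain", "resno", "elety", "x", "y", "z", "b")
  expect_equal(cxPdb@atoms[keep], cxCif@atoms[keep], tolerance = 1e-3)
  # format=auto picked mmcif from the extension
  expect_equal(contactCount(countContacts(cxCif)),
               contactCount(countContacts(cxPdb)))
})

test_that("extra chains are excluded with a warning, missing chains error", {
  atoms <- rbind(atomRow("A", 1, "CA", 0, 0, 0),
                 atomRow("B", 1, "CA", 3.5, 0, 0),
                 atomRow("C", 1, "CA", 2, 0, 0))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = pdb, xyz = as.numeric(t(atoms[c("x", "y", "z")])),
                   resno = atoms$resno, resid = atoms$resid,
                   chain = atoms$chain, elety = atoms$elety,
                   eleno = 1:3, b = atoms$b, elesy = atoms$elesy)
  expect_warning(cx <- parseComplex(pdb, "A", "B", globalStart = 1),
                 "additional chain")
  expect_false("C" %in% cx@atoms$chain)
  # chain C's atom at x=2 must not contribute contacts
  expect_equal(contactCount(countContacts(cx)), 1L)
  expect_error(parseComplex(pdb, "A", "Z", globalStart = 1), "chain 'Z'")
})

test_that("hydrogens and heteroatom records are filtered out", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = pdb,
                   xyz = as.numeric(t(matrix(c(0, 0, 0,
                                               0.5, 0, 0,
                                               3.0, 0, 0,
                                               3.6, 0, 0), ncol = 3,
                                             byrow = TRUE))),
                   type = c("ATOM", "ATOM", "ATOM", "HETATM"),
                   resno = c(1L, 1L, 1L, 2L),
                   resid = c("ALA", "ALA", "ALA", "HOH"),
                   chain = c("A", "A", "B", "B"),
                   elety = c("CA", "H", "CA", "O"),
                   eleno = 1:4, b = rep(80, 4),
                   elesy = c("C", "H", "C", "O"))
  cx <- parseComplex(pdb, "A", "B", globalStart = 1)
  expect_equal(nrow(cx@atoms), 2L)            # H and HOH gone
  expect_equal(contactCount(countContacts(cx)), 1L)  # 3.0 A CA-CA only
})

test_that("alternate locations resolve to the highest occupancy", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = pdb,
                   xyz = as.numeric(t(matrix(c(0, 0, 0,
                                               1.0, 0, 0,
                                               3.2, 0, 0), ncol = 3,
                                             byrow = TRUE))),
                   resno = c(1L, 1L, 1L), resid = rep("ALA", 3),
                   chain = c("A", "A", "B"), elety = c("CA", "CA", "CA"),
                   alt = c("A", "B", NA), o = c(0.3, 0.7, 1.0),
                   eleno = 1:3, b = c(50, 60, 70), elesy = rep("C", 3))
  expect_warning(cx <- parseComplex(pdb, "A", "B", globalStart = 1),
                 "occupancy|duplicated")
  aA <- cx@atoms[cx@atoms$chain == "A", ]
  expect_equal(nrow(aA), 1L)
  expect_equal(aA$b, 60)   # the occupancy-0.7 altloc won
})

test_that("pLDDT extraction honours ca and atom_mean modes", {
  atoms <- rbind(
    atomRow("A", 1, "CA", 0, 0, 0, b = 90),
    atomRow("A", 1, "CB", 0, 1.5, 0, b = 10),
    atomRow("A", 1, "CG", 0, 3.0, 0, b = 20),
    atomRow("A", 2, "CB", 3.8, 0, 0, b = 42),   # no CA: fallback to mean
    atomRow("B", 1, "CA", 20, 0, 0, b = 70))
  cx <- toyComplex(atoms)
  ca <- extractPlddt(cx, "A", mode = "ca")
  expect_equal(unname(ca), c(90, 42))
  am <- extractPlddt(cx, "A", mode = "atom_mean")
  expect_equal(unname(am), c(mean(c(90, 10, 20)), 42))
  # uniform per-residue B-factors make the modes agree
  uni <- toyComplex(rbind(atomRow("A", 1, "CA", 0, 0, 0, b = 70),
                          atomRow("A", 1, "CB", 0, 1.5, 0, b = 70),
                          atomRow("B", 1, "CA", 30, 0, 0, b = 70)))
  expect_equal(extractPlddt(uni, "A", "ca"),
               extractPlddt(uni, "A", "atom_mean"))
})

test_that("out-of-range B-factors pass through with a warning", {
  atoms <- rbind(atomRow("A", 1, "CA", 0, 0, 0, b = 120),
                 atomRow("B", 1, "CA", 30, 0, 0, b = 70))
  expect_warning(cx <- toyComplex(atoms), "outside \\[0, 100\\]")
  expect_equal(unname(cx@plddt), 120)
})

test_that("manifest reading enforces the exact schema", {
  dir <- withr::local_tempdir()
  pdb <- file.path(dir, "f.pdb")
  writeLines("ATOM", pdb)
  good <- data.frame(fragment_id = "frag01", structure_path = "f.pdb",
                     bait_chain = "A", receptor_chain = "B",
                     global_start = 1L)
  p <- file.path(dir, "manifest.tsv")
  write.table(good, p, sep = "\t", quote = FALSE, row.names = FALSE)
  man <- readManifest(p)
  # relative path resolved against the manifest directory
  expect_equal(man$structure_path, file.path(dir, "f.pdb"))

  bad <- good
  names(bad)[1] <- "fragment"
  write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readManifest(p), "header must be exactly")

  dup <- rbind(good, good)
  write.table(dup, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readManifest(p), "unique")
})

test_that("multi-record bait FASTA is rejected", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKV", ">b", "MML"), fa)
  expect_error(readBaitFasta(fa), "exactly one record")
  writeLines(c(">solo desc", "MKVT"), fa)
  b <- readBaitFasta(fa)
  expect_equal(baitId(b), "solo")
  expect_equal(as.character(b), "MKVT")
})
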