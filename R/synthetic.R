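#' Create a plant specification for the synthetic generator
#'
#' @param segment global `c(start, end)` of the planted interface.
#' @param contactDensity expected contacting receptor residues per planted
#'   bait residue (>= 1 guaranteed per residue; default 2).
#' @param decoyRate expected spurious contacts per non-planted residue
#'   (default 0).
#' @param plddtPlanted,plddtBackground pLDDT written inside / outside the
#'   segment (default 80, uniform).
#' @param plddtNoiseSd,coordNoiseSd Gaussian noise levels (defaults 0).
#' @return a [PlantSpec-class].
#' @export
plantSpec <- function(segment, contactDensity = 2, decoyRate = 0,
                      plddtPlanted = 80, plddtBackground = 80,
                      plddtNoiseSd = 0, coordNoiseSd = 0) {
  new("PlantSpec", segment = as.integer(segment),
      contactDensity = as.numeric(contactDensity),
      decoyRate = as.numeric(decoyRate),
      plddtPlanted = as.numeric(plddtPlanted),
      plddtBackground = as.numeric(plddtBackground),
      plddtNoiseSd = as.numeric(plddtNoiseSd),
      coordNoiseSd = as.numeric(coordNoiseSd))
}

#' Generate a random bait sequence
#'
#' Uniform draw over the 20 standard amino acids; deterministic under the
#' seed and independent of the caller's random state.
#'
#' @param L bait length in residues.
#' @param seed integer seed.
#' @param id bait label.
#' @return a [BaitSequence-class].
#' @export
generateBait <- function(L, seed, id = "synthetic_bait") {
  stopifnot(L >= 1L)
  letters <- withSeed(seed,
    sample(Biostrings::AA_STANDARD, L, replace = TRUE))
  baitSequence(paste(letters, collapse = ""), id = id)
}

# Contact-slot directions (radians in the y-z plane, bait axis along x).
# Limited so a contact atom stays > 4 A from every non-target bait atom
# with >= 0.39 A margin; at most 5 contacting receptor residues per bait
# residue.
.contactThetas <- c(0, 0.45, -0.45, 0.9, -0.9)

#' Generate one synthetic two-chain complex with a planted interface
#'
#' Builds a coarse CA+CB bait chain along the x axis (3.8 A CA spacing)
#' and a receptor chain whose bulk sits >= 8 A away. For every bait
#' residue inside a planted segment (and for sampled decoy residues), one
#' or more receptor residues are relocated so one heavy atom lies 3.3 A
#' from the bait residue's CA — within the 4 A cutoff — while staying
#' > 4 A from all other bait residues. pLDDT values are written into the
#' B-factor column per residue. Gaussian coordinate noise, if requested,
#' is applied last and redrawn until the planted/decoy contact
#' classification is exactly preserved.
#'
#' @param tiles a [FragmentSet-class].
#' @param fragmentId which fragment to model.
#' @param plants list of [PlantSpec-class]; decoy and background settings
#'   are taken from the first.
#' @param receptorLength receptor chain length in residues (default 119).
#' @param seed integer seed (byte-identical output under the same seed).
#' @param contactSeed seed for the per-interface contact multiplicities.
#'   The number of receptor residues contacting a planted bait residue is
#'   a property of the interface, so overlapping fragments covering the
#'   same residue should agree on it; [generateDataset()] passes one
#'   dataset-wide value here while `seed` varies per fragment.
#' @param path output PDB file.
#' @param baitChain,receptorChain chain ids written to the file.
#' @return invisibly, a list: `path`, `contacts` (data.frame `bait_res`,
#'   `receptor_res`, `type` = planted/decoy — the ground truth), `plddt`
#'   (per-residue values written).
#' @export
generateComplex <- function(tiles, fragmentId, plants, receptorLength = 119L,
                            seed = 1L, contactSeed = seed, path,
                            baitChain = "A", receptorChain = "B") {
  stopifnot(is(tiles, "FragmentSet"), length(plants) >= 1L)
  for (p in plants) stopifnot(is(p, "PlantSpec"))
  r <- tiles@ranges[fragmentId]
  if (length(r) != 1L)
    stop("unknown fragment '", fragmentId, "'", call. = FALSE)
  fstart <- IRanges::start(r); fend <- IRanges::end(r)
  n <- fend - fstart + 1L
  globals <- fstart:fend
  receptorLength <- as.integer(receptorLength)

  plantOf <- rep(NA_integer_, n)   # which plant governs each residue
  for (k in seq_along(plants)) {
    seg <- plants[[k]]@segment
    inside <- globals >= seg[1] & globals <= seg[2]
    plantOf[inside & is.na(plantOf)] <- k
  }
  if (all(is.na(plantOf)))
    warning("no planted segment overlaps fragment '", fragmentId,
            "': generating a contact-free complex", call. = FALSE)

  base <- plants[[1]]
  fragSeq <- strsplit(as.character(Biostrings::subseq(
    tiles@bait@seq, fstart, fend)), "")[[1]]

  # Contact multiplicity per planted residue, drawn once per interface in
  # a fragment-independent order so every window covering a residue sees
  # the same count (>= 1 per planted residue, capped by the slot geometry).
  plantedGlobals <- unlist(lapply(plants, function(p)
    p@segment[1]:p@segment[2]))
  densities <- unlist(lapply(plants, function(p)
    rep(p@contactDensity, p@segment[2] - p@segment[1] + 1L)))
  keep <- !duplicated(plantedGlobals)
  plantedGlobals <- plantedGlobals[keep]
  densities <- densities[keep]
  countByGlobal <- withSeed(contactSeed, setNames(
    pmin(length(.contactThetas),
         pmax(1L, stats::rpois(length(plantedGlobals), densities))),
    plantedGlobals))

  withSeed(seed, {
    # pLDDT per local residue
    lv <- ifelse(is.na(plantOf), base@plddtBackground,
                 vapply(plantOf, function(k)
                   if (is.na(k)) base@plddtBackground
                   else plants[[k]]@plddtPlanted, numeric(1)))
    nsd <- ifelse(is.na(plantOf), base@plddtNoiseSd,
                  vapply(plantOf, function(k)
                    if (is.na(k)) base@plddtNoiseSd
                    else plants[[k]]@plddtNoiseSd, numeric(1)))
    plddt <- pmin(100, pmax(0, lv + stats::rnorm(n, 0, 1) * nsd))

    # contact assignment: planted residues first, then decoys
    slots <- list()  # each: local l, receptor j, theta
    nextRec <- 1L
    for (l in seq_len(n)) {
      k <- plantOf[l]
      if (is.na(k)) next
      nc <- min(receptorLength - nextRec + 1L,
                countByGlobal[[as.character(globals[l])]])
      if (nc < 1L) next
      for (s in seq_len(nc)) {
        slots[[length(slots) + 1L]] <-
          list(l = l, j = nextRec, theta = .contactThetas[s],
               type = "planted")
        nextRec <- nextRec + 1L
      }
    }
    if (base@decoyRate > 0) {
      for (l in seq_len(n)) {
        if (!is.na(plantOf[l])) next
        nd <- min(length(.contactThetas), stats::rpois(1L, base@decoyRate))
        nd <- min(nd, receptorLength - nextRec + 1L)
        if (nd < 1L) next
        for (s in seq_len(nd)) {
          slots[[length(slots) + 1L]] <-
            list(l = l, j = nextRec, theta = .contactThetas[s],
                 type = "decoy")
          nextRec <- nextRec + 1L
        }
      }
    }

    buildAtoms <- function(noiseSd) {
      bx <- (seq_len(n) - 1L) * 3.8
      bait <- data.frame(
        chain = baitChain,
        resno = rep(seq_len(n), each = 2L),
        resid = rep(vapply(fragSeq, bio3d::aa123, character(1)), each = 2L),
        elety = rep(c("CA", "CB"), n),
        elesy = "C",
        x = rep(bx, each = 2L),
        y = rep(c(0, -1.5), n),
        z = 0,
        b = rep(plddt, each = 2L), stringsAsFactors = FALSE)
      rx <- (seq_len(receptorLength) - 1L) * 3.8
      rec <- data.frame(
        chain = receptorChain,
        resno = rep(seq_len(receptorLength), each = 2L),
        resid = "ALA",
        elety = rep(c("CA", "CB"), receptorLength),
        elesy = "C",
        x = rep(rx, each = 2L),
        y = rep(c(40, 41.5), receptorLength),
        z = 0,
        b = 70, stringsAsFactors = FALSE)
      for (sl in slots) {
        xl <- (sl$l - 1L) * 3.8
        dy <- cos(sl$theta); dz <- sin(sl$theta)
        sel <- rec$resno == sl$j
        rec$x[sel] <- xl
        rec$y[sel] <- c(4.8 * dy, 3.3 * dy)  # CA outward, CB contacts
        rec$z[sel] <- c(4.8 * dz, 3.3 * dz)
      }
      atoms <- rbind(bait, rec)
      if (noiseSd > 0) {
        atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, noiseSd)
        atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, noiseSd)
        atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, noiseSd)
      }
      atoms
    }

    expected <- if (length(slots))
      unique(data.frame(
        bait_res = vapply(slots, function(s) globals[s$l], integer(1)),
        receptor_res = vapply(slots, function(s) s$j, integer(1)),
        type = vapply(slots, function(s) s$type, character(1)),
        stringsAsFactors = FALSE))
    else data.frame(bait_res = integer(), receptor_res = integer(),
                    type = character(), stringsAsFactors = FALSE)

    atoms <- buildAtoms(base@coordNoiseSd)
    if (base@coordNoiseSd > 0) {
      ok <- FALSE
      for (try in 1:100) {
        if (classificationIntact(atoms, baitChain, receptorChain,
                                 fstart, expected)) { ok <- TRUE; break }
        atoms <- buildAtoms(base@coordNoiseSd)
      }
      if (!ok)
        stop("could not apply coordinate noise of sd ",
             base@coordNoiseSd,
             " A without disturbing the planted contacts", call. = FALSE)
    }

    cx <- complexStructure(atoms, fragmentId = fragmentId,
                           baitChain = baitChain,
                           receptorChain = receptorChain,
                           globalStart = fstart)
    writeComplexPdb(cx, path)
    invisible(list(path = path, contacts = expected,
                   plddt = setNames(plddt, globals)))
  })
}

# TRUE iff the residue-pair contacts of the noised atom table equal the
# expected planted/decoy set exactly (4.0 A cutoff).
classificationIntact <- function(atoms, baitChain, receptorChain,
                                 globalStart, expected) {
  cx <- complexStructure(atoms, fragmentId = "check",
                         baitChain = baitChain,
                         receptorChain = receptorChain,
                         globalStart = globalStart)
  got <- suppressWarnings(countContacts(cx, cutoff = 4.0))@pairs
  key <- function(d) sort(paste(d$bait_res, d$receptor_res))
  identical(key(got), key(expected))
}

#' Generate a complete synthetic dataset
#'
#' Tiles a random bait, writes one planted two-chain PDB per fragment, a
#' manifest, the bait FASTA and a `ground_truth.json` recording the
#' planted segments and every planted/decoy contact — so recovery tests
#' can be exact rather than statistical.
#'
#' @param outDir output directory (created).
#' @param L bait length (default 315).
#' @param window,step,tailPolicy tiling geometry (defaults 50 / 25 /
#'   anchor_tail).
#' @param plants list of [PlantSpec-class], typically one per bait half;
#'   default plants at 28-36 and 197-209.
#' @param receptorLength receptor chain length (default 119).
#' @param seed master seed; every per-fragment seed derives from it.
#' @param baitId label for the generated bait.
#' @return invisibly, a list: `bait`, `tiles`, `manifest` (path),
#'   `baitFasta` (path), `groundTruth` (list), `groundTruthPath`.
#' @export
generateDataset <- function(outDir, L = 315L, window = 50L, step = 25L,
                            tailPolicy = "anchor_tail",
                            plants = list(plantSpec(c(28L, 36L)),
                                          plantSpec(c(197L, 209L))),
                            receptorLength = 119L, seed = 1L,
                            baitId = "synthetic_bait") {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  for (p in plants)
    if (p@segment[2] > L)
      stop("planted segment exceeds bait length", call. = FALSE)
  bait <- generateBait(L, seed = childSeed(seed, 0L), id = baitId)
  tiles <- tileSequence(bait, window = window, step = step,
                        tailPolicy = tailPolicy)
  tab <- fragmentTable(tiles)
  fragGT <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    pdb <- file.path(outDir, paste0(tab$fragment_id[i], ".pdb"))
    gt <- suppressWarnings(
      generateComplex(tiles, tab$fragment_id[i], plants = plants,
                      receptorLength = receptorLength,
                      seed = childSeed(seed, i),
                      contactSeed = childSeed(seed, 0L), path = pdb))
    fragGT[[i]] <- list(fragment_id = tab$fragment_id[i],
                        contacts = gt$contacts)
  }
  man <- data.frame(fragment_id = tab$fragment_id,
                    structure_path = paste0(tab$fragment_id, ".pdb"),
                    bait_chain = "A", receptor_chain = "B",
                    global_start = tab$start, stringsAsFactors = FALSE)
  manifestPath <- file.path(outDir, "manifest.tsv")
  writeTsv(man, manifestPath)
  baitFasta <- file.path(outDir, "bait.fasta")
  aas <- Biostrings::AAStringSet(as.character(bait))
  names(aas) <- baitId(bait)
  Biostrings::writeXStringSet(aas, baitFasta)
  groundTruth <- list(
    seed = seed, L = L, window = window, step = step,
    receptor_length = receptorLength,
    planted = lapply(plants, function(p)
      list(start = p@segment[1], end = p@segment[2])),
    fragments = fragGT)
  gtPath <- file.path(outDir, "ground_truth.json")
  jsonlite::write_json(groundTruth, gtPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(bait = bait, tiles = tiles, manifest = manifestPath,
                 baitFasta = baitFasta, groundTruth = groundTruth,
                 groundTruthPath = gtPath))
}
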