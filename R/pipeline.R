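#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with defaults reproducing the
#' reference analysis conditions: 50-residue windows, 25-residue step,
#' 4.0 A contact cutoff, residue-pair counting, CA-read pLDDT,
#' mean + 1 sd peak threshold, half split at `floor(L/2)`, motif
#' refinement with gap tolerance 1 and minimum length 5.
#'
#' @param window,step tiling geometry in residues.
#' @param cutoff contact distance cutoff in Angstrom.
#' @param contactUnit `"residue_pair"` or `"atom_pair"`.
#' @param plddtMode `"ca"` or `"atom_mean"`.
#' @param tailPolicy `"anchor_tail"` or `"drop_tail"`.
#' @param policy a [thresholdPolicy()].
#' @param split `"auto"` (floor(L/2)) or a residue index.
#' @param gapTolerance,minMotifLength motif refinement parameters.
#' @param seed seed for synthetic runs.
#' @return a validated `runConfig` list.
#' @export
runConfig <- function(window = 50L, step = 25L, cutoff = 4.0,
                      contactUnit = c("residue_pair", "atom_pair"),
                      plddtMode = c("ca", "atom_mean"),
                      tailPolicy = c("anchor_tail", "drop_tail"),
                      policy = thresholdPolicy("mean_plus_k_sd", k = 1),
                      split = "auto", gapTolerance = 1L,
                      minMotifLength = 5L, seed = 1L) {
  cfg <- list(window = as.integer(window), step = as.integer(step),
              cutoff = as.numeric(cutoff),
              contactUnit = match.arg(contactUnit),
              plddtMode = match.arg(plddtMode),
              tailPolicy = match.arg(tailPolicy),
              policy = policy, split = split,
              gapTolerance = as.integer(gapTolerance),
              minMotifLength = as.integer(minMotifLength),
              seed = as.integer(seed))
  if (cfg$step < 1L || cfg$step > cfg$window)
    stop("need 1 <= step <= window (got step=", cfg$step, ", window=",
         cfg$window, ")", call. = FALSE)
  if (cfg$cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  if (!inherits(cfg$policy, "thresholdPolicy"))
    stop("policy must be a thresholdPolicy()", call. = FALSE)
  if (!identical(cfg$split, "auto")) {
    cfg$split <- as.integer(cfg$split)
    if (is.na(cfg$split)) stop("split must be 'auto' or an integer",
                               call. = FALSE)
  }
  structure(cfg, class = "runConfig")
}

#' @export
print.runConfig <- function(x, ...) {
  cat("runConfig:\n")
  for (line in configEcho(x)) cat(" ", line, "\n")
  invisible(x)
}

configEcho <- function(cfg) {
  pol <- switch(cfg$policy$type,
                mean_plus_k_sd = sprintf("mean_plus_k_sd(k=%g)",
                                         cfg$policy$k),
                quantile = sprintf("quantile(q=%g)", cfg$policy$q),
                absolute = sprintf("absolute(v=%g)", cfg$policy$v))
  c(sprintf("window=%d step=%d tailPolicy=%s", cfg$window, cfg$step,
            cfg$tailPolicy),
    sprintf("cutoff=%g contactUnit=%s plddtMode=%s", cfg$cutoff,
            cfg$contactUnit, cfg$plddtMode),
    sprintf("thresholdPolicy=%s split=%s", pol, as.character(cfg$split)),
    sprintf("gapTolerance=%d minMotifLength=%d seed=%d",
            cfg$gapTolerance, cfg$minMotifLength, cfg$seed))
}

#' Run the full motif-discovery pipeline
#'
#' Tiles the bait, scores every manifest complex (contacts within the
#' cutoff weighted by mean fragment pLDDT), averages scores into the
#' per-residue profile, calls the best peak per half, refines each peak
#' to a minimal motif, and writes all outputs under `outDir`:
#' `fragments.tsv`, `fragments.fasta`, `fragment_scores.tsv`,
#' `residue_profile.tsv`, `profile.bedgraph`, `motifs.tsv`,
#' `motifs.fasta`, `run.log`.
#'
#' @param baitFasta single-record FASTA of the bait.
#' @param manifest manifest TSV path (see [readManifest()]).
#' @param outDir output directory.
#' @param config a [runConfig()].
#' @return invisibly, a list: `status` (0 on success), `tiles`, `scores`,
#'   `contactSets`, `profile`, `peaks`, `motifs`, `files`.
#' @export
runPipeline <- function(baitFasta, manifest, outDir,
                        config = runConfig()) {
  stopifnot(inherits(config, "runConfig"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  logCon <- file(logPath, "w")
  on.exit(close(logCon))
  logMsg("fragmap ", as.character(utils::packageVersion("fragmap")),
         " | R ", getRversion(), con = logCon)
  for (line in configEcho(config)) logMsg("config: ", line, con = logCon)
  logMsg("bait: ", baitFasta, " | manifest: ", manifest, con = logCon)

  bait <- readBaitFasta(baitFasta)
  tiles <- tileSequence(bait, window = config$window, step = config$step,
                        tailPolicy = config$tailPolicy)
  logMsg("tiled ", length(bait), " residues into ", length(tiles),
         " fragments", con = logCon)
  writeFragments(tiles, outDir)

  man <- readManifest(manifest)
  bad <- setdiff(man$fragment_id, fragmentIds(tiles))
  if (length(bad))
    stop("manifest fragment id(s) not present in the tiling: ",
         paste(bad, collapse = ", "), call. = FALSE)
  sm <- scoreManifest(man, cutoff = config$cutoff,
                      unit = config$contactUnit,
                      plddtMode = config$plddtMode)
  tab <- fragmentTable(tiles)
  scoresOut <- merge(tab[c("fragment_id", "start", "end")], sm$scores,
                     by = "fragment_id", sort = FALSE)
  scoresOut <- scoresOut[order(scoresOut$start), ]
  fs <- scoresOut
  fs$mean_plddt <- fmtNum(fs$mean_plddt)
  fs$weighted_score <- fmtNum(fs$weighted_score)
  writeTsv(fs, file.path(outDir, "fragment_scores.tsv"))
  logMsg("scored ", nrow(sm$scores), " fragment complexes", con = logCon)

  profile <- buildResidueProfile(sm$scores, tiles)
  writeTsv(data.frame(residue = seq_len(profile@L),
                      coverage = profile@coverage,
                      score = fmtNum(profile@score)),
           file.path(outDir, "residue_profile.tsv"))
  writeBedGraph(profile, file.path(outDir, "profile.bedgraph"),
                name = baitId(bait))

  split <- if (identical(config$split, "auto")) NULL else config$split
  peaks <- callPeaks(profile, split = split, policy = config$policy)
  for (i in seq_len(nrow(peaks)))
    logMsg(sprintf("peak %s-half: %d-%d (max %.6g, threshold %.6g)",
                   peaks$half[i], peaks$start[i], peaks$end[i],
                   peaks$peak_score[i], peaks$threshold[i]), con = logCon)

  calls <- list()
  for (i in seq_len(nrow(peaks))) {
    nm <- if (peaks$half[i] == "N") "MotifA" else "MotifB"
    call <- tryCatch(
      refineMotif(peaks[i, ], sm$contactSets, sm$scores, tiles,
                  gapTolerance = config$gapTolerance,
                  minMotifLength = config$minMotifLength, name = nm),
      error = function(e) {
        logMsg("no motif for ", peaks$half[i], "-half peak: ",
               conditionMessage(e), con = logCon)
        NULL
      })
    if (!is.null(call)) {
      logMsg(sprintf("motif %s: %d-%d %s (fragment %s)", call$name,
                     call$start, call$end, call$sequence,
                     call$source_fragment), con = logCon)
      calls[[length(calls) + 1L]] <- call
    }
  }
  motifs <- if (length(calls)) do.call(rbind, calls) else NULL
  files <- reportMotifs(motifs, bait, outDir)
  logMsg("done; outputs in ", outDir, con = logCon)

  invisible(list(status = 0L, bait = bait, tiles = tiles,
                 scores = sm$scores, contactSets = sm$contactSets,
                 profile = profile, peaks = peaks, motifs = motifs,
                 files = files))
}

#' Generate a synthetic dataset and run the pipeline on it
#'
#' Chains [generateDataset()] and [runPipeline()], then compares the
#' called motifs with the planted ground truth and reports the Jaccard
#' overlap per half.
#'
#' @param outDir output directory; the dataset goes to
#'   `file.path(outDir, "dataset")`, pipeline outputs to `outDir`.
#' @param config a [runConfig()] (its `seed` drives all randomness).
#' @param plants,L,receptorLength,baitId passed to [generateDataset()].
#' @param quiet suppress the recovery summary printout.
#' @return invisibly, a list: the [runPipeline()] result plus
#'   `groundTruth` and `recovery` (data.frame half/planted/called/
#'   jaccard).
#' @export
runSynthetic <- function(outDir, config = runConfig(),
                         plants = list(plantSpec(c(28L, 36L)),
                                       plantSpec(c(197L, 209L))),
                         L = 315L, receptorLength = 119L,
                         baitId = "synthetic_bait", quiet = FALSE) {
  stopifnot(inherits(config, "runConfig"))
  ds <- generateDataset(file.path(outDir, "dataset"), L = L,
                        window = config$window, step = config$step,
                        tailPolicy = config$tailPolicy, plants = plants,
                        receptorLength = receptorLength,
                        seed = config$seed, baitId = baitId)
  res <- runPipeline(ds$baitFasta, ds$manifest, outDir, config = config)
  planted <- lapply(ds$groundTruth$planted, function(p)
    c(p$start, p$end))
  halves <- vapply(planted, function(p) {
    if (p[2] <= L %/% 2L) "N" else "C"
  }, character(1))
  rec <- do.call(rbind, lapply(seq_along(planted), function(i) {
    h <- halves[i]
    m <- res$motifs
    row <- if (!is.null(m))
      m[(h == "N" & m$name == "MotifA") |
        (h == "C" & m$name == "MotifB"), , drop = FALSE]
    else NULL
    if (is.null(row) || nrow(row) == 0L)
      data.frame(half = h, planted_start = planted[[i]][1],
                 planted_end = planted[[i]][2], called_start = NA_integer_,
                 called_end = NA_integer_, jaccard = 0)
    else
      data.frame(half = h, planted_start = planted[[i]][1],
                 planted_end = planted[[i]][2], called_start = row$start,
                 called_end = row$end,
                 jaccard = jaccardInterval(planted[[i]],
                                           c(row$start, row$end)))
  }))
  if (!quiet) {
    cat("recovery summary (called vs planted):\n")
    for (i in seq_len(nrow(rec)))
      cat(sprintf("  %s-half: planted %d-%d, called %s, Jaccard %.3f\n",
                  rec$half[i], rec$planted_start[i], rec$planted_end[i],
                  if (is.na(rec$called_start[i])) "none" else
                    sprintf("%d-%d", rec$called_start[i],
                            rec$called_end[i]),
                  rec$jaccard[i]))
  }
  jsonlite::write_json(rec, file.path(outDir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(res, list(groundTruth = ds$groundTruth, recovery = rec)))
}
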