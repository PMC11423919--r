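#' Threshold policy for peak calling
#'
#' Constructs the rule that turns a residue profile into a qualifying set
#' of residues. `"mean_plus_k_sd"` (default, `k = 1`) is scale-free: the
#' profile is only defined up to the pLDDT scale, and mean + k*sd moves
#' with it. `"quantile"` keeps the top `1 - q` fraction; `"absolute"`
#' fixes a raw score value.
#'
#' @param type one of `"mean_plus_k_sd"`, `"quantile"`, `"absolute"`.
#' @param k,q,v parameter of the respective policy.
#' @return an object of class `thresholdPolicy`.
#' @export
thresholdPolicy <- function(type = c("mean_plus_k_sd", "quantile",
                                     "absolute"), k = 1, q = NULL,
                            v = NULL) {
  type <- match.arg(type)
  if (type == "quantile" && (is.null(q) || q < 0 || q > 1))
    stop("quantile policy needs q in [0, 1]", call. = FALSE)
  if (type == "absolute" && is.null(v))
    stop("absolute policy needs a value v", call. = FALSE)
  structure(list(type = type, k = k, q = q, v = v),
            class = "thresholdPolicy")
}

#' @export
print.thresholdPolicy <- function(x, ...) {
  cat("thresholdPolicy:", switch(x$type,
    mean_plus_k_sd = sprintf("mean + %g * sd", x$k),
    quantile = sprintf("quantile(%g)", x$q),
    absolute = sprintf("absolute(%g)", x$v)), "\n")
  invisible(x)
}

resolveThreshold <- function(policy, values) {
  values <- values[!is.na(values)]
  switch(policy$type,
         mean_plus_k_sd = mean(values) +
           policy$k * ifelse(length(values) > 1, stats::sd(values), 0),
         quantile = unname(stats::quantile(values, policy$q)),
         absolute = policy$v)
}

#' Call the best peak in each half of the residue profile
#'
#' The profile is split into N- and C-terminal halves (default split at
#' `floor(L/2)`). Within each half, residues at or above the threshold are
#' grouped into maximal contiguous runs, and the run containing the half's
#' maximum value is that half's best peak (ties on the maximum resolved to
#' the leftmost run). A half whose values all fall below the threshold
#' yields no peak, with a warning.
#'
#' By default the threshold is computed per half (`scope = "per_half"`):
#' each half is screened for its own best peak, so a strong interface in
#' one half cannot push the other half's true peak below threshold.
#' `scope = "global"` computes one threshold over the whole profile.
#'
#' @param profile a [ResidueProfile-class].
#' @param split last residue of the N-terminal half; `NULL` for
#'   `floor(L/2)`.
#' @param policy a [thresholdPolicy()].
#' @param scope `"per_half"` (default) or `"global"` threshold scope.
#' @return [S4Vectors::DataFrame] with columns `half` ("N"/"C"), `start`,
#'   `end`, `peak_score`, `threshold` and a `supporting_fragments`
#'   [IRanges::CharacterList] (scored fragments overlapping the peak).
#' @export
callPeaks <- function(profile, split = NULL,
                      policy = thresholdPolicy("mean_plus_k_sd", k = 1),
                      scope = c("per_half", "global")) {
  scope <- match.arg(scope)
  stopifnot(is(profile, "ResidueProfile"))
  L <- profile@L
  if (is.null(split)) split <- L %/% 2L
  split <- as.integer(split)
  if (split <= 1L || split >= L)
    stop("split must lie strictly inside (1, L)", call. = FALSE)
  v <- profile@score
  if (all(is.na(v[1:split])) || all(is.na(v[(split + 1L):L])))
    stop("each half needs at least one defined profile value",
         call. = FALSE)
  thrGlobal <- resolveThreshold(policy, v)
  halves <- list(N = c(1L, split), C = c(split + 1L, L))
  rows <- list()
  for (h in names(halves)) {
    lo <- halves[[h]][1]; hi <- halves[[h]][2]
    vv <- v[lo:hi]
    thr <- if (scope == "global") thrGlobal else
      resolveThreshold(policy, vv)
    qual <- !is.na(vv) & vv >= thr
    if (!any(qual)) {
      warning("no residues reach the threshold in the ", h,
              "-terminal half", call. = FALSE)
      next
    }
    runs <- qualRuns(qual)
    hmax <- max(vv, na.rm = TRUE)
    # leftmost position attaining the half maximum (must qualify if any do)
    argmax <- which(!is.na(vv) & vv == hmax & qual)[1]
    if (is.na(argmax)) { # maximum itself below threshold: cannot happen
      next               # for mean/quantile policies, guard for absolute
    }
    sel <- runs[runs$start <= argmax & runs$end >= argmax, ]
    start <- lo + sel$start - 1L
    end <- lo + sel$end - 1L
    r <- profile@ranges
    supp <- names(r)[IRanges::start(r) <= end & IRanges::end(r) >= start]
    rows[[h]] <- S4Vectors::DataFrame(
      half = h, start = start, end = end,
      peak_score = max(vv[sel$start:sel$end], na.rm = TRUE),
      threshold = thr,
      supporting_fragments = IRanges::CharacterList(list(supp)))
  }
  if (length(rows)) do.call(rbind, unname(rows)) else
    S4Vectors::DataFrame(half = character(), start = integer(),
                         end = integer(), peak_score = numeric(),
                         threshold = numeric(),
                         supporting_fragments =
                           IRanges::CharacterList())
}

# maximal runs of TRUE in a logical vector -> data.frame(start, end)
qualRuns <- function(q) {
  r <- rle(q)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Refine a peak region to a minimal contiguous motif
#'
#' Formalizes the per-peak structural follow-up as contact-run extraction:
#' among the peak's supporting fragments, the one with the highest
#' weighted score is selected (ties resolved to the leftmost fragment);
#' within it, residues with at least one inter-chain contact are grouped
#' into runs tolerating internal gaps of up to `gapTolerance` contact-free
#' residues; runs shorter than `minMotifLength` are discarded, and of the
#' remainder the run with the largest total contact count (ties leftmost)
#' becomes the motif.
#'
#' @param peak one row of the [callPeaks()] result (or any list with
#'   `start`, `end` and `supporting_fragments`).
#' @param contactSets named list of [ContactSet-class], covering the
#'   supporting fragments.
#' @param scores score table as given to [buildResidueProfile()] (needs
#'   `fragment_id`, `weighted_score`).
#' @param tiles the [FragmentSet-class] (for coordinates and sequence).
#' @param gapTolerance maximum internal gap, in residues (default 1).
#' @param minMotifLength minimum motif span, in residues (default 5).
#' @param name motif name for the report.
#' @return one-row `data.frame`: `name`, `start`, `end`, `length`,
#'   `sequence`, `mean_per_residue_contacts`, `source_fragment`.
#' @export
refineMotif <- function(peak, contactSets, scores, tiles,
                        gapTolerance = 1L, minMotifLength = 5L,
                        name = "Motif") {
  supp <- unlist(peak$supporting_fragments)
  supp <- supp[supp %in% names(contactSets)]
  if (length(supp) == 0L)
    stop("peak has no supporting fragment with a contact set",
         call. = FALSE)
  s <- setNames(scores$weighted_score, scores$fragment_id)[supp]
  starts <- IRanges::start(tiles@ranges[supp])
  best <- supp[order(-s, starts)][1]
  counts <- perResidueContacts(contactSets[[best]])
  pos <- as.integer(names(counts))[counts >= 1L]
  if (length(pos) == 0L)
    stop("no contacting residues in fragment '", best,
         "': no motif for this peak", call. = FALSE)
  gapTolerance <- as.integer(gapTolerance)
  grp <- cumsum(c(1L, diff(pos) > gapTolerance + 1L))
  runs <- do.call(rbind, lapply(split(pos, grp), function(p) {
    data.frame(start = min(p), end = max(p),
               total = sum(counts[as.character(min(p):max(p))]))
  }))
  runs$len <- runs$end - runs$start + 1L
  runs <- runs[runs$len >= minMotifLength, , drop = FALSE]
  if (nrow(runs) == 0L)
    stop("all contact runs shorter than minMotifLength (",
         minMotifLength, "): no motif for this peak", call. = FALSE)
  runs <- runs[order(-runs$total, runs$start), , drop = FALSE]
  L <- length(tiles@bait)
  start <- max(1L, runs$start[1]); end <- min(L, runs$end[1])
  seq <- as.character(Biostrings::subseq(tiles@bait@seq, start, end))
  data.frame(name = name, start = start, end = end,
             length = end - start + 1L, sequence = seq,
             mean_per_residue_contacts =
               mean(counts[as.character(start:end)]),
             source_fragment = best, stringsAsFactors = FALSE)
}

#' Write the motif report
#'
#' Emits `motifs.tsv` and `motifs.fasta` (headers encode the global
#' coordinates). With zero calls the TSV keeps its header row and the
#' FASTA is empty.
#'
#' @param calls `data.frame` of motif calls ([refineMotif()] rows
#'   rbind-ed), possibly empty.
#' @param bait the [BaitSequence-class].
#' @param dir output directory.
#' @return invisibly, the two file paths.
#' @export
reportMotifs <- function(calls, bait, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "motifs.tsv")
  fa <- file.path(dir, "motifs.fasta")
  cols <- c("name", "start", "end", "length", "sequence",
            "mean_per_residue_contacts", "source_fragment")
  if (is.null(calls) || nrow(calls) == 0L) {
    writeLines(paste(cols, collapse = "\t"), tsv)
    file.create(fa)
    return(invisible(c(tsv = tsv, fasta = fa)))
  }
  stopifnot(all(cols %in% names(calls)))
  bad <- calls$sequence != vapply(seq_len(nrow(calls)), function(i)
    as.character(Biostrings::subseq(bait@seq, calls$start[i],
                                    calls$end[i])), character(1))
  if (any(bad))
    stop("motif sequence(s) do not match the bait at their coordinates: ",
         paste(calls$name[bad], collapse = ", "), call. = FALSE)
  out <- calls[cols]
  out$mean_per_residue_contacts <- fmtNum(out$mean_per_residue_contacts)
  writeTsv(out, tsv)
  aas <- Biostrings::AAStringSet(calls$sequence)
  names(aas) <- sprintf("%s %s:%d-%d", calls$name, baitId(bait),
                        calls$start, calls$end)
  Biostrings::writeXStringSet(aas, fa)
  invisible(c(tsv = tsv, fasta = fa))
}
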