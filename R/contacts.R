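#' Count inter-chain contacts within a distance cutoff
#'
#' An interaction is a bait-residue/receptor-residue pair with at least one
#' heavy-atom distance less than or equal to `cutoff` (inclusive, matching
#' the "within" convention). Under `unit = "residue_pair"` (default) each
#' qualifying residue pair is counted once; under `unit = "atom_pair"`
#' every qualifying atom pair counts. Bait residues are reported in global
#' bait coordinates via the structure's `globalStart`.
#'
#' Candidate atom pairs are pre-filtered by per-axis separation (a pair
#' further than the cutoff along any axis cannot be within it in 3D), then
#' checked with exact Euclidean distances, so the result is identical to an
#' exhaustive all-pairs scan.
#'
#' @param structure a [ComplexStructure-class].
#' @param cutoff distance cutoff in Angstrom (default 4.0).
#' @param unit `"residue_pair"` or `"atom_pair"`.
#' @return a [ContactSet-class].
#' @examples
#' tiles <- tileSequence(generateBait(315, seed = 1))
#' ps <- plantSpec(c(28, 36))
#' pdb <- tempfile(fileext = ".pdb")
#' generateComplex(tiles, "frag02", plants = list(ps), seed = 7, path = pdb)
#' cs <- countContacts(parseComplex(pdb, "A", "B", globalStart = 26))
#' contactCount(cs)
#' @export
countContacts <- function(structure, cutoff = 4.0,
                          unit = c("residue_pair", "atom_pair")) {
  unit <- match.arg(unit)
  stopifnot(is(structure, "ComplexStructure"), cutoff > 0)
  a <- structure@atoms
  ba <- a[a$chain == structure@baitChain, , drop = FALSE]
  ra <- a[a$chain == structure@receptorChain, , drop = FALSE]
  baitRes <- structure@globalStart +
    seq_len(max(ba$resno, 0L)) - 1L
  if (nrow(ba) == 0L || nrow(ra) == 0L) {
    warning("empty chain: zero contacts for fragment '",
            structure@fragmentId, "'", call. = FALSE)
    return(new("ContactSet", fragmentId = structure@fragmentId,
               cutoff = cutoff, unit = unit, pairs = emptyPairs(),
               baitResidues = as.integer(baitRes)))
  }
  hits <- closeAtomPairs(as.matrix(ba[, c("x", "y", "z")]),
                         as.matrix(ra[, c("x", "y", "z")]), cutoff)
  if (nrow(hits) == 0L) {
    pairs <- emptyPairs()
  } else {
    bres <- structure@globalStart + ba$resno[hits[, 1L]] - 1L
    rres <- ra$resno[hits[, 2L]]
    key <- paste(bres, rres)
    pairs <- data.frame(
      bait_res = as.integer(tapply(bres, key, `[`, 1L)),
      receptor_res = as.integer(tapply(rres, key, `[`, 1L)),
      min_distance = as.numeric(tapply(hits[, 3L], key, min)),
      n_atom_pairs = as.integer(tapply(key, key, length)))
    pairs <- pairs[order(pairs$bait_res, pairs$receptor_res), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  new("ContactSet", fragmentId = structure@fragmentId, cutoff = cutoff,
      unit = unit, pairs = pairs, baitResidues = as.integer(baitRes))
}

emptyPairs <- function() {
  data.frame(bait_res = integer(), receptor_res = integer(),
             min_distance = numeric(), n_atom_pairs = integer())
}

# All atom pairs (i from A, j from B) with euclidean distance <= cutoff.
# Per-axis bounding prune first, exact distances on the survivors; chunked
# over A to bound the candidate matrix size.
closeAtomPairs <- function(A, B, cutoff) {
  n1 <- nrow(A); n2 <- nrow(B)
  out <- vector("list", 0L)
  chunk <- max(1L, floor(4e6 / n2))
  for (lo in seq.int(1L, n1, by = chunk)) {
    hi <- min(lo + chunk - 1L, n1)
    idx <- lo:hi
    cand <- abs(outer(A[idx, 1L], B[, 1L], "-")) <= cutoff &
            abs(outer(A[idx, 2L], B[, 2L], "-")) <= cutoff &
            abs(outer(A[idx, 3L], B[, 3L], "-")) <= cutoff
    w <- which(cand, arr.ind = TRUE)
    if (nrow(w)) {
      ai <- idx[w[, 1L]]
      bj <- w[, 2L]
      d <- sqrt((A[ai, 1L] - B[bj, 1L])^2 + (A[ai, 2L] - B[bj, 2L])^2 +
                (A[ai, 3L] - B[bj, 3L])^2)
      keep <- d <= cutoff
      if (any(keep))
        out[[length(out) + 1L]] <- cbind(ai[keep], bj[keep], d[keep])
    }
  }
  if (length(out)) do.call(rbind, out) else matrix(numeric(), ncol = 3L)
}
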