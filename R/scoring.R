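#' Score one fragment: contact count weighted by mean pLDDT
#'
#' The fragment's interaction score is its inter-chain contact count
#' multiplied by the unweighted arithmetic mean pLDDT over *all* residues
#' of the bait fragment (not only the contacting ones). A fragment with
#' zero contacts scores exactly zero whatever its confidence.
#'
#' @param contactSet a [ContactSet-class] from [countContacts()].
#' @param plddt named numeric of per-residue pLDDT covering every bait
#'   residue of the fragment (local or global names; only the values are
#'   averaged).
#' @return one-row `data.frame`: `fragment_id`, `contact_count`,
#'   `mean_plddt`, `weighted_score`.
#' @examples
#' # 7 contacts at uniform confidence 80 -> score 560
#' @export
scoreFragment <- function(contactSet, plddt) {
  stopifnot(is(contactSet, "ContactSet"))
  plddt <- plddt[!is.na(plddt)]
  if (length(plddt) == 0L)
    stop("empty pLDDT map for fragment '", contactSet@fragmentId, "'",
         call. = FALSE)
  if (length(plddt) < length(contactSet@baitResidues))
    stop("pLDDT must be defined for every residue of fragment '",
         contactSet@fragmentId, "' (", length(plddt), " of ",
         length(contactSet@baitResidues), ")", call. = FALSE)
  C <- contactCount(contactSet)
  P <- mean(plddt)
  data.frame(fragment_id = contactSet@fragmentId,
             contact_count = as.integer(C), mean_plddt = P,
             weighted_score = as.numeric(C) * P,
             stringsAsFactors = FALSE)
}

#' Aggregate fragment scores into the per-residue interaction profile
#'
#' Each residue's value is the average weighted score of the scored
#' fragments covering it. Fragments present in the tiling but absent from
#' `scores` (e.g. failed predictions) are excluded from both numerator and
#' coverage, with a message; residues covered by no scored fragment are
#' undefined (`NA`), never zero.
#'
#' @param scores `data.frame` with columns `fragment_id` and
#'   `weighted_score` (one row per scored fragment, e.g. rbind-ed output
#'   of [scoreFragment()]).
#' @param tiles the [FragmentSet-class] the fragments came from.
#' @param L bait length; must match the tiling's bait.
#' @return a [ResidueProfile-class].
#' @export
buildResidueProfile <- function(scores, tiles, L = length(tiles@bait)) {
  stopifnot(is(tiles, "FragmentSet"),
            all(c("fragment_id", "weighted_score") %in% names(scores)))
  L <- as.integer(L)
  if (L != length(tiles@bait))
    stop("L (", L, ") does not match the tiling's bait length (",
         length(tiles@bait), ")", call. = FALSE)
  if (anyDuplicated(scores$fragment_id))
    stop("each fragment must be scored exactly once", call. = FALSE)
  unknown <- setdiff(scores$fragment_id, fragmentIds(tiles))
  if (length(unknown))
    stop("scored fragment(s) not in the tiling: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(fragmentIds(tiles), scores$fragment_id)
  if (length(missing))
    message("fragment(s) without scores excluded from coverage: ",
            paste(missing, collapse = ", "))
  r <- tiles@ranges[scores$fragment_id]
  s <- setNames(as.numeric(scores$weighted_score), scores$fragment_id)
  total <- numeric(L)
  cov <- integer(L)
  for (k in seq_along(r)) {
    idx <- IRanges::start(r)[k]:IRanges::end(r)[k]
    total[idx] <- total[idx] + s[k]
    cov[idx] <- cov[idx] + 1L
  }
  val <- ifelse(cov > 0L, total / pmax(cov, 1L), NA_real_)
  new("ResidueProfile", L = L, score = val, coverage = cov,
      ranges = r, fragmentScores = s)
}

#' Fragments contributing to a residue's profile value
#'
#' @param profile a [ResidueProfile-class].
#' @param residue 1-based global residue position.
#' @return character vector of fragment ids covering the residue.
#' @export
contributingFragments <- function(profile, residue) {
  stopifnot(is(profile, "ResidueProfile"),
            residue >= 1L, residue <= profile@L)
  r <- profile@ranges
  names(r)[IRanges::start(r) <= residue & IRanges::end(r) >= residue]
}

#' Score every manifest entry of a run
#'
#' Convenience loop over the manifest: parse each complex, count contacts,
#' and score. Returns the per-fragment score table together with the
#' contact sets (needed later for motif refinement).
#'
#' @param manifest `data.frame` from [readManifest()].
#' @param cutoff,unit passed to [countContacts()].
#' @param plddtMode passed to [parseComplex()].
#' @return list with `scores` (data.frame, one row per fragment) and
#'   `contactSets` (named list of [ContactSet-class]).
#' @export
scoreManifest <- function(manifest, cutoff = 4.0,
                          unit = c("residue_pair", "atom_pair"),
                          plddtMode = c("ca", "atom_mean")) {
  unit <- match.arg(unit)
  plddtMode <- match.arg(plddtMode)
  contactSets <- vector("list", nrow(manifest))
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    cx <- parseComplex(m$structure_path, baitChain = m$bait_chain,
                       receptorChain = m$receptor_chain,
                       globalStart = m$global_start,
                       fragmentId = m$fragment_id, plddtMode = plddtMode)
    cs <- countContacts(cx, cutoff = cutoff, unit = unit)
    rows[[i]] <- scoreFragment(cs, cx@plddt)
    contactSets[[i]] <- cs
  }
  names(contactSets) <- manifest$fragment_id
  list(scores = do.call(rbind, rows), contactSets = contactSets)
}
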