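#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges IRanges CharacterList coverage start end width
#' @importFrom Biostrings AAString AAStringSet readAAStringSet
#'   writeXStringSet subseq AA_STANDARD
NULL

#' Bait protein sequence with a 1-based global coordinate frame
#'
#' Holds the full-length bait protein that is tiled into fragments. All
#' residue coordinates in the package are 1-based inclusive positions on
#' this sequence.
#'
#' @slot id single character label for the bait.
#' @slot seq an [Biostrings::AAString] with the one-letter sequence.
#'
#' @seealso [baitSequence()], [readBaitFasta()], [generateBait()]
#' @exportClass BaitSequence
setClass("BaitSequence",
  representation(id = "character", seq = "AAString"))

setValidity("BaitSequence", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@seq) < 1L)
    msg <- c(msg, "sequence must contain at least one residue")
  if (length(msg)) msg else TRUE
})

#' Overlapping fragment tiling of a bait sequence
#'
#' The result of [tileSequence()]: an ordered set of fixed-width windows
#' over the bait, stored as an [IRanges::IRanges] whose names are the
#' fragment identifiers.
#'
#' @slot bait the tiled [BaitSequence].
#' @slot window window width in residues.
#' @slot step step between consecutive window starts, in residues.
#' @slot tailPolicy `"anchor_tail"` or `"drop_tail"`.
#' @slot ranges named [IRanges::IRanges] of fragment intervals, sorted by
#'   start; names are unique fragment ids.
#'
#' @seealso [tileSequence()], [fragments()], [fragmentTable()]
#' @exportClass FragmentSet
setClass("FragmentSet",
  representation(bait = "BaitSequence", window = "integer",
                 step = "integer", tailPolicy = "character",
                 ranges = "IRanges"))

setValidity("FragmentSet", function(object) {
  msg <- character()
  L <- length(object@bait@seq)
  r <- object@ranges
  if (length(r)) {
    if (min(IRanges::start(r)) < 1L || max(IRanges::end(r)) > L)
      msg <- c(msg, "fragment coordinates fall outside [1, L]")
    if (any(IRanges::width(r) > object@window))
      msg <- c(msg, "fragment wider than the window size")
    if (is.null(names(r)) || anyDuplicated(names(r)))
      msg <- c(msg, "fragment ids must be present and unique")
    if (is.unsorted(IRanges::start(r)))
      msg <- c(msg, "fragments must be ordered by start")
  }
  if (!object@tailPolicy %in% c("anchor_tail", "drop_tail"))
    msg <- c(msg, "tailPolicy must be 'anchor_tail' or 'drop_tail'")
  if (length(msg)) msg else TRUE
})

#' Parsed two-chain predicted complex structure
#'
#' Heavy atoms of a predicted bait-fragment/receptor complex, with the
#' per-residue pLDDT confidence of the bait chain (read from the B-factor
#' column, as AlphaFold-style models store it) and the mapping of the bait
#' chain's file-local residue numbers onto global bait coordinates.
#'
#' @slot fragmentId fragment identifier this complex models.
#' @slot baitChain,receptorChain chain identifiers within the file.
#' @slot globalStart global bait coordinate of bait-chain local residue 1.
#'   The manifest, not any numbering embedded in the structure file, is the
#'   authority for this mapping.
#' @slot atoms `data.frame` with columns `chain`, `resno` (file-local),
#'   `resid`, `elety`, `elesy`, `x`, `y`, `z`, `b`.
#' @slot plddt named numeric, per bait-chain residue (names are local
#'   residue numbers), on the native 0-100 scale.
#'
#' @seealso [parseComplex()], [complexStructure()], [extractPlddt()],
#'   [countContacts()]
#' @exportClass ComplexStructure
setClass("ComplexStructure",
  representation(fragmentId = "character", baitChain = "character",
                 receptorChain = "character", globalStart = "integer",
                 atoms = "data.frame", plddt = "numeric"))

setValidity("ComplexStructure", function(object) {
  msg <- character()
  a <- object@atoms
  need <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z", "b")
  if (!all(need %in% names(a)))
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  else {
    if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
      msg <- c(msg, "atom positions must be finite")
    present <- unique(a$chain)
    if (!setequal(present, c(object@baitChain, object@receptorChain)))
      msg <- c(msg, "atoms must contain exactly the bait and receptor chains")
  }
  if (object@globalStart < 1L)
    msg <- c(msg, "globalStart must be >= 1")
  if (object@baitChain == object@receptorChain)
    msg <- c(msg, "bait and receptor chains must be distinct")
  if (length(msg)) msg else TRUE
})

#' Inter-chain contacts of one fragment complex
#'
#' The set of bait-residue/receptor-residue pairs whose minimum heavy-atom
#' distance lies within the cutoff, as found by [countContacts()]. Bait
#' residues are stored in global bait coordinates; receptor residues keep
#' their file-local numbering.
#'
#' @slot fragmentId fragment identifier.
#' @slot cutoff distance cutoff in Angstrom (inclusive comparison).
#' @slot unit `"residue_pair"` (each residue pair counted once) or
#'   `"atom_pair"` (every qualifying atom pair counted).
#' @slot pairs `data.frame` with columns `bait_res` (global), `receptor_res`
#'   (local), `min_distance` (Angstrom), `n_atom_pairs`.
#' @slot baitResidues integer vector of all global bait residues the
#'   fragment spans (so zero-contact residues are representable).
#'
#' @seealso [countContacts()], [contactCount()], [perResidueContacts()]
#' @exportClass ContactSet
setClass("ContactSet",
  representation(fragmentId = "character", cutoff = "numeric",
                 unit = "character", pairs = "data.frame",
                 baitResidues = "integer"))

setValidity("ContactSet", function(object) {
  msg <- character()
  p <- object@pairs
  need <- c("bait_res", "receptor_res", "min_distance", "n_atom_pairs")
  if (!all(need %in% names(p)))
    msg <- c(msg, paste("pairs must have columns:", paste(need, collapse = ", ")))
  else if (nrow(p)) {
    if (any(p$min_distance > object@cutoff + 1e-12))
      msg <- c(msg, "a contact pair exceeds the cutoff")
    if (anyDuplicated(p[c("bait_res", "receptor_res")]))
      msg <- c(msg, "residue pairs must be unique")
    if (!all(p$bait_res %in% object@baitResidues))
      msg <- c(msg, "contact bait residues must lie within the fragment")
  }
  if (!object@unit %in% c("residue_pair", "atom_pair"))
    msg <- c(msg, "unit must be 'residue_pair' or 'atom_pair'")
  if (object@cutoff <= 0) msg <- c(msg, "cutoff must be positive")
  if (length(msg)) msg else TRUE
})

#' Per-residue normalized interaction profile
#'
#' For each bait residue, the average of the weighted interaction scores of
#' all scored fragments covering it. Residues covered by no scored fragment
#' carry `NA` (undefined), never zero: zero is a meaningful score.
#'
#' @slot L bait length in residues.
#' @slot score numeric length `L`; `NA` where coverage is zero.
#' @slot coverage integer length `L`; number of scored fragments covering
#'   each residue.
#' @slot ranges named [IRanges::IRanges] of the scored fragments.
#' @slot fragmentScores named numeric of weighted fragment scores, names
#'   matching `names(ranges)`.
#'
#' @seealso [buildResidueProfile()], [profileScores()], [callPeaks()]
#' @exportClass ResidueProfile
setClass("ResidueProfile",
  representation(L = "integer", score = "numeric", coverage = "integer",
                 ranges = "IRanges", fragmentScores = "numeric"))

setValidity("ResidueProfile", function(object) {
  msg <- character()
  if (length(object@score) != object@L || length(object@coverage) != object@L)
    msg <- c(msg, "score and coverage must have length L")
  else {
    und <- object@coverage == 0L
    if (any(!is.na(object@score[und])))
      msg <- c(msg, "zero-coverage residues must be NA, not a number")
    if (any(is.na(object@score[!und])))
      msg <- c(msg, "covered residues must have a defined score")
  }
  if (!setequal(names(object@ranges), names(object@fragmentScores)))
    msg <- c(msg, "ranges and fragmentScores must name the same fragments")
  if (length(msg)) msg else TRUE
})

#' Synthetic interface plant specification
#'
#' Parameters controlling one planted binding segment in the synthetic
#' complex generator: where the true interface lies, how many contacts each
#' planted residue makes, how often spurious (decoy) contacts appear
#' elsewhere, and the pLDDT values written into the B-factor column.
#'
#' @slot segment integer length-2, global `[start, end]` of the planted
#'   interface on the bait.
#' @slot contactDensity expected contacting receptor residues per planted
#'   bait residue (each planted residue is guaranteed at least one).
#' @slot decoyRate expected spurious contacts per non-planted residue.
#' @slot plddtPlanted,plddtBackground pLDDT written for residues inside /
#'   outside the planted segment, 0-100.
#' @slot plddtNoiseSd standard deviation of Gaussian noise added to the
#'   per-residue pLDDT (clamped back to \[0, 100\]).
#' @slot coordNoiseSd standard deviation (Angstrom) of Gaussian coordinate
#'   noise; applied last, with redraws so the planted/non-planted contact
#'   classification is preserved exactly.
#'
#' @seealso [plantSpec()], [generateComplex()], [generateDataset()]
#' @exportClass PlantSpec
setClass("PlantSpec",
  representation(segment = "integer", contactDensity = "numeric",
                 decoyRate = "numeric", plddtPlanted = "numeric",
                 plddtBackground = "numeric", plddtNoiseSd = "numeric",
                 coordNoiseSd = "numeric"))

setValidity("PlantSpec", function(object) {
  msg <- character()
  s <- object@segment
  if (length(s) != 2L || any(is.na(s)) || s[1] < 1L || s[2] < s[1])
    msg <- c(msg, "segment must be c(start, end) with 1 <= start <= end")
  if (object@contactDensity <= 0)
    msg <- c(msg, "contactDensity must be > 0")
  if (object@decoyRate < 0)
    msg <- c(msg, "decoyRate must be >= 0")
  for (f in c("plddtPlanted", "plddtBackground")) {
    v <- slot(object, f)
    if (v < 0 || v > 100) msg <- c(msg, paste(f, "must lie in [0, 100]"))
  }
  if (object@plddtNoiseSd < 0 || object@coordNoiseSd < 0)
    msg <- c(msg, "noise standard deviations must be >= 0")
  if (length(msg)) msg else TRUE
})
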