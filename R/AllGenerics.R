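#' @rdname BaitSequence-class
#' @param object,x a package object.
#' @export
setGeneric("baitId", function(x) standardGeneric("baitId"))

#' @rdname BaitSequence-class
#' @export
setGeneric("baitSeq", function(x) standardGeneric("baitSeq"))

#' @rdname FragmentSet-class
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname FragmentSet-class
#' @export
setGeneric("fragmentIds", function(x) standardGeneric("fragmentIds"))

#' @rdname FragmentSet-class
#' @export
setGeneric("fragmentTable", function(x) standardGeneric("fragmentTable"))

#' @rdname ContactSet-class
#' @export
setGeneric("contactCount", function(x, ...) standardGeneric("contactCount"))

#' @rdname ContactSet-class
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))

#' @rdname ContactSet-class
#' @export
setGeneric("perResidueContacts",
           function(x) standardGeneric("perResidueContacts"))

#' @rdname ResidueProfile-class
#' @export
setGeneric("profileScores", function(x) standardGeneric("profileScores"))

#' @rdname ResidueProfile-class
#' @export
setGeneric("profileCoverage", function(x) standardGeneric("profileCoverage"))

# ---- BaitSequence ----------------------------------------------------------

#' @rdname BaitSequence-class
#' @export
setMethod("baitId", "BaitSequence", function(x) x@id)

#' @rdname BaitSequence-class
#' @export
setMethod("baitSeq", "BaitSequence", function(x) x@seq)

#' @rdname BaitSequence-class
#' @export
setMethod("length", "BaitSequence", function(x) length(x@seq))

#' @rdname BaitSequence-class
#' @export
setMethod("as.character", "BaitSequence", function(x) as.character(x@seq))

setMethod("show", "BaitSequence", function(object) {
  cat("BaitSequence '", object@id, "': ", length(object@seq),
      " residues\n", sep = "")
  s <- as.character(object@seq)
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat("  ", s, "\n", sep = "")
})

# ---- FragmentSet -----------------------------------------------------------

#' @rdname FragmentSet-class
#' @export
setMethod("fragments", "FragmentSet", function(x) x@ranges)

#' @rdname FragmentSet-class
#' @export
setMethod("fragmentIds", "FragmentSet", function(x) names(x@ranges))

#' @rdname FragmentSet-class
#' @export
setMethod("baitSeq", "FragmentSet", function(x) x@bait@seq)

#' @rdname FragmentSet-class
#' @export
setMethod("length", "FragmentSet", function(x) length(x@ranges))

#' Fragment intervals and sequences as a data.frame
#'
#' @return `data.frame` with columns `fragment_id`, `start`, `end`,
#'   `sequence` (one row per tiled fragment, ordered by start).
#' @rdname FragmentSet-class
#' @export
setMethod("fragmentTable", "FragmentSet", function(x) {
  r <- x@ranges
  seqs <- as.character(Biostrings::subseq(
    rep(Biostrings::AAStringSet(x@bait@seq), length(r)),
    start = IRanges::start(r), end = IRanges::end(r)))
  data.frame(fragment_id = names(r), start = IRanges::start(r),
             end = IRanges::end(r), sequence = unname(seqs),
             stringsAsFactors = FALSE)
})

setMethod("show", "FragmentSet", function(object) {
  cat("FragmentSet: ", length(object@ranges), " fragments of bait '",
      object@bait@id, "' (L=", length(object@bait@seq), ")\n",
      "  window=", object@window, " step=", object@step,
      " tailPolicy=", object@tailPolicy, "\n", sep = "")
})

# ---- ComplexStructure ------------------------------------------------------

setMethod("show", "ComplexStructure", function(object) {
  a <- object@atoms
  nb <- sum(a$chain == object@baitChain)
  nr <- sum(a$chain == object@receptorChain)
  cat("ComplexStructure for fragment '", object@fragmentId, "'\n",
      "  bait chain ", object@baitChain, ": ", nb, " atoms, ",
      length(object@plddt), " residues (globalStart=", object@globalStart,
      ")\n  receptor chain ", object@receptorChain, ": ", nr, " atoms\n",
      sep = "")
})

# ---- ContactSet ------------------------------------------------------------

#' Number of inter-chain interactions in a ContactSet
#'
#' @param unit override the set's configured counting unit.
#' @param ... passed on to methods.
#' @rdname ContactSet-class
#' @export
setMethod("contactCount", "ContactSet", function(x, unit = x@unit) {
  unit <- match.arg(unit, c("residue_pair", "atom_pair"))
  if (unit == "residue_pair") nrow(x@pairs) else
    as.integer(sum(x@pairs$n_atom_pairs))
})

#' @rdname ContactSet-class
#' @export
setMethod("contactPairs", "ContactSet", function(x) x@pairs)

#' Per-residue contact counts over the fragment's global residues
#'
#' @return named integer vector over every global bait residue the fragment
#'   spans (zeros included); counts follow the set's unit.
#' @rdname ContactSet-class
#' @export
setMethod("perResidueContacts", "ContactSet", function(x) {
  out <- integer(length(x@baitResidues))
  names(out) <- x@baitResidues
  if (nrow(x@pairs)) {
    w <- if (x@unit == "atom_pair") x@pairs$n_atom_pairs else
      rep(1L, nrow(x@pairs))
    tab <- tapply(w, factor(x@pairs$bait_res, levels = x@baitResidues), sum)
    tab[is.na(tab)] <- 0L
    out[] <- as.integer(tab)
  }
  out
})

setMethod("show", "ContactSet", function(object) {
  cat("ContactSet for fragment '", object@fragmentId, "': ",
      nrow(object@pairs), " residue pairs (",
      sum(object@pairs$n_atom_pairs), " atom pairs) within ",
      object@cutoff, " A; unit=", object@unit, "\n", sep = "")
})

# ---- ResidueProfile --------------------------------------------------------

#' @rdname ResidueProfile-class
#' @export
setMethod("profileScores", "ResidueProfile", function(x) x@score)

#' @rdname ResidueProfile-class
#' @export
setMethod("profileCoverage", "ResidueProfile", function(x) x@coverage)

#' @rdname ResidueProfile-class
#' @export
setMethod("length", "ResidueProfile", function(x) x@L)

setMethod("show", "ResidueProfile", function(object) {
  def <- !is.na(object@score)
  cat("ResidueProfile over ", object@L, " residues; ",
      length(object@ranges), " scored fragments; ",
      sum(!def), " undefined position(s)\n", sep = "")
  if (any(def))
    cat(sprintf("  score range: %.4g .. %.4g\n",
                min(object@score[def]), max(object@score[def])))
})

setMethod("show", "PlantSpec", function(object) {
  cat("PlantSpec: segment [", object@segment[1], ", ", object@segment[2],
      "], contactDensity=", object@contactDensity,
      ", decoyRate=", object@decoyRate, "\n",
      "  pLDDT planted/background: ", object@plddtPlanted, "/",
      object@plddtBackground, " (noise sd ", object@plddtNoiseSd,
      "); coord noise sd ", object@coordNoiseSd, " A\n", sep = "")
})
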