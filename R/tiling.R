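#' Construct a bait sequence
#'
#' @param sequence character string of one-letter amino-acid codes, or an
#'   [Biostrings::AAString].
#' @param id label for the bait.
#' @return a [BaitSequence-class] object.
#' @examples
#' baitSequence("MSITIHRNTP", id = "toy")
#' @export
baitSequence <- function(sequence, id = "bait") {
  if (!is(sequence, "AAString"))
    sequence <- Biostrings::AAString(as.character(sequence))
  new("BaitSequence", id = as.character(id), seq = sequence)
}

#' Read a bait sequence from a single-record FASTA file
#'
#' Multi-record files are rejected: the pipeline's coordinate frame is a
#' single bait protein.
#'
#' @param path FASTA file with exactly one record.
#' @return a [BaitSequence-class].
#' @export
readBaitFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) != 1L)
    stop("bait FASTA must contain exactly one record, found ", length(aa),
         " in '", path, "'", call. = FALSE)
  id <- sub("\\s.*$", "", names(aa)[1])
  baitSequence(aa[[1]], id = id)
}

#' Tile a bait sequence into overlapping fragments
#'
#' Generates fixed-width windows starting at 1, 1+step, 1+2*step, ... while
#' a full window fits. Under `tailPolicy = "anchor_tail"` (the default),
#' if the last full-step window does not end at the C-terminus, one extra
#' full-width window anchored at `[L - window + 1, L]` is appended so every
#' residue is covered; `"drop_tail"` keeps only the exact-grid windows.
#' Tail windows are always full-width, never truncated.
#'
#' @param bait a [BaitSequence-class].
#' @param window window width in residues (default 50).
#' @param step step between window starts in residues (default 25).
#' @param tailPolicy `"anchor_tail"` or `"drop_tail"`.
#' @return a [FragmentSet-class] with fragments ordered by start.
#' @examples
#' bait <- generateBait(315, seed = 1)
#' tiles <- tileSequence(bait)       # 11 grid windows + anchored tail
#' fragmentTable(tiles)[1:3, ]
#' @export
tileSequence <- function(bait, window = 50L, step = 25L,
                         tailPolicy = c("anchor_tail", "drop_tail")) {
  tailPolicy <- match.arg(tailPolicy)
  stopifnot(is(bait, "BaitSequence"))
  window <- as.integer(window); step <- as.integer(step)
  L <- length(bait)
  if (is.na(window) || is.na(step) || step < 1L)
    stop("step must be a positive integer", call. = FALSE)
  if (step > window)
    stop("step (", step, ") must not exceed window (", window, ")",
         call. = FALSE)
  if (window > L)
    stop("window (", window, ") exceeds bait length (", L, ")",
         call. = FALSE)
  starts <- seq.int(1L, L - window + 1L, by = step)
  if (tailPolicy == "anchor_tail") {
    tail_start <- L - window + 1L
    if (starts[length(starts)] != tail_start)
      starts <- c(starts, tail_start)
  }
  ids <- sprintf("frag%0*d", max(2L, nchar(length(starts))),
                 seq_along(starts))
  r <- IRanges::IRanges(start = starts, width = window, names = ids)
  new("FragmentSet", bait = bait, window = window, step = step,
      tailPolicy = tailPolicy, ranges = r)
}

#' Per-residue fragment coverage
#'
#' How many fragments contain each residue of the bait. Used as the
#' denominator when averaging fragment scores per residue.
#'
#' @param x a [FragmentSet-class] or a named [IRanges::IRanges] of
#'   fragment intervals.
#' @param L bait length; taken from the fragment set when omitted.
#' @return integer vector of length `L`.
#' @export
coverageCount <- function(x, L = NULL) {
  if (is(x, "FragmentSet")) {
    if (is.null(L)) L <- length(x@bait)
    r <- x@ranges
  } else if (is(x, "IRanges")) {
    if (is.null(L)) stop("L is required when passing a raw IRanges",
                         call. = FALSE)
    r <- x
  } else stop("x must be a FragmentSet or IRanges", call. = FALSE)
  L <- as.integer(L)
  if (length(r) == 0L) return(integer(L))
  if (min(IRanges::start(r)) < 1L || max(IRanges::end(r)) > L)
    stop("fragment coordinates fall outside [1, ", L, "]", call. = FALSE)
  as.integer(IRanges::coverage(r, width = L))
}

#' Write fragment outputs for downstream structure prediction
#'
#' Writes `fragments.tsv` (fragment_id, start, end, sequence) and
#' `fragments.fasta`, the inputs a user would hand to a structure
#' predictor together with the receptor.
#'
#' @param tiles a [FragmentSet-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
writeFragments <- function(tiles, dir = ".") {
  stopifnot(is(tiles, "FragmentSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- fragmentTable(tiles)
  tsv <- file.path(dir, "fragments.tsv")
  fa <- file.path(dir, "fragments.fasta")
  writeTsv(tab, tsv)
  aas <- Biostrings::AAStringSet(tab$sequence)
  names(aas) <- sprintf("%s %d-%d", tab$fragment_id, tab$start, tab$end)
  Biostrings::writeXStringSet(aas, fa)
  invisible(c(tsv = tsv, fasta = fa))
}
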