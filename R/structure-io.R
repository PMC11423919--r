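#' Construct a ComplexStructure from an atom table
#'
#' Low-level constructor used by [parseComplex()] and by the synthetic
#' generator; useful when atoms come from a source other than a PDB/mmCIF
#' file. Atoms outside the two named chains are dropped; pLDDT is taken
#' from the B-factor column via [extractPlddt()].
#'
#' @param atoms `data.frame` with columns `chain`, `resno`, `resid`,
#'   `elety`, `elesy`, `x`, `y`, `z`, `b`.
#' @param fragmentId fragment identifier.
#' @param baitChain,receptorChain chain ids of the bait fragment and the
#'   receptor.
#' @param globalStart global bait coordinate of the bait chain's first
#'   residue.
#' @param plddtMode `"ca"` (per-residue CA B-factor, the AlphaFold
#'   convention) or `"atom_mean"`.
#' @return a [ComplexStructure-class].
#' @export
complexStructure <- function(atoms, fragmentId, baitChain, receptorChain,
                             globalStart, plddtMode = c("ca", "atom_mean")) {
  plddtMode <- match.arg(plddtMode)
  atoms <- atoms[atoms$chain %in% c(baitChain, receptorChain), , drop = FALSE]
  rownames(atoms) <- NULL
  obj <- new("ComplexStructure", fragmentId = as.character(fragmentId),
             baitChain = baitChain, receptorChain = receptorChain,
             globalStart = as.integer(globalStart), atoms = atoms,
             plddt = numeric())
  obj@plddt <- extractPlddt(obj, chain = baitChain, mode = plddtMode)
  obj
}

# Normalize a bio3d atom data.frame: ATOM records only (drops waters and
# other heteroatoms), hydrogens out, alternate locations resolved to the
# highest occupancy (ties -> first encountered), duplicated atoms (e.g.
# extra models) collapsed to the first with a warning.
cleanAtoms <- function(atom) {
  atom <- atom[atom$type == "ATOM", , drop = FALSE]
  elesy <- atom$elesy
  miss <- is.na(elesy) | !nzchar(trimws(elesy))
  # fall back to the first alphabetic character of the atom name
  elesy[miss] <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                     atom$elety[miss]), 1, 1))
  atom$elesy <- trimws(elesy)
  atom <- atom[!atom$elesy %in% c("H", "D"), , drop = FALSE]
  key <- paste(atom$chain, atom$resno, atom$elety, sep = "\r")
  if (anyDuplicated(key)) {
    if (any(!is.na(atom$alt[key %in% key[duplicated(key)]])))
      warning("alternate locations resolved to highest occupancy",
              call. = FALSE)
    else
      warning("duplicated atom records (multiple models?); first kept",
              call. = FALSE)
    occ <- atom$o
    occ[is.na(occ)] <- 1
    # within each (chain, residue, atom name) keep the highest occupancy,
    # first encountered on ties; then restore file order
    pick <- order(key, -occ, seq_len(nrow(atom)))
    keep <- pick[!duplicated(key[pick])]
    atom <- atom[sort(keep), , drop = FALSE]
  }
  rownames(atom) <- NULL
  atom
}

#' Parse a predicted two-chain complex from PDB or mmCIF
#'
#' Reads the structure, keeps the heavy (non-hydrogen) `ATOM` records of
#' the two named chains, resolves alternate locations to the highest
#' occupancy, and attaches the bait chain's per-residue pLDDT read from
#' the B-factor column. The bait chain's residue numbering is mapped onto
#' global bait coordinates through `globalStart` (the manifest is the
#' numbering authority, since structure predictors renumber each chain
#' from 1).
#'
#' @param path structure file.
#' @param baitChain,receptorChain chain ids in the file.
#' @param globalStart global bait coordinate of bait-chain residue 1.
#' @param format `"auto"` (by file extension), `"pdb"` or `"mmcif"`.
#' @param fragmentId label; defaults to the file base name.
#' @param plddtMode passed to [extractPlddt()].
#' @return a [ComplexStructure-class].
#' @export
parseComplex <- function(path, baitChain, receptorChain, globalStart,
                         format = c("auto", "pdb", "mmcif"),
                         fragmentId = NULL,
                         plddtMode = c("ca", "atom_mean")) {
  format <- match.arg(format)
  plddtMode <- match.arg(plddtMode)
  if (!file.exists(path))
    stop("structure file not found: '", path, "'", call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE,
                                         verbose = FALSE)
    else withCallingHandlers(bio3d::read.cif(path, verbose = FALSE),
      warning = function(w) {
        if (grepl("beta version|helix/sheet", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) stop("could not parse '", path, "' as ", format,
                             ": ", conditionMessage(e), call. = FALSE))
  atom <- cleanAtoms(parsed$atom)
  for (ch in c(baitChain, receptorChain))
    if (!ch %in% atom$chain)
      stop("chain '", ch, "' not found in '", path, "' (chains present: ",
           paste(unique(atom$chain), collapse = ", "), ")", call. = FALSE)
  extra <- setdiff(unique(atom$chain), c(baitChain, receptorChain))
  if (length(extra))
    warning("ignoring additional chain(s) ", paste(extra, collapse = ", "),
            " in '", path, "'", call. = FALSE)
  atom <- atom[atom$chain %in% c(baitChain, receptorChain), , drop = FALSE]
  if (nrow(atom) == 0L)
    stop("no atoms left after filtering in '", path, "'", call. = FALSE)
  # renormalize bait-chain numbering so local residue 1 <-> globalStart
  for (ch in c(baitChain, receptorChain)) {
    sel <- atom$chain == ch
    atom$resno[sel] <- atom$resno[sel] - min(atom$resno[sel]) + 1L
  }
  atoms <- data.frame(chain = atom$chain, resno = as.integer(atom$resno),
                      resid = atom$resid, elety = atom$elety,
                      elesy = atom$elesy, x = atom$x, y = atom$y,
                      z = atom$z, b = atom$b, stringsAsFactors = FALSE)
  if (is.null(fragmentId))
    fragmentId <- tools::file_path_sans_ext(basename(path))
  complexStructure(atoms, fragmentId = fragmentId, baitChain = baitChain,
                   receptorChain = receptorChain, globalStart = globalStart,
                   plddtMode = plddtMode)
}

#' Extract per-residue pLDDT from the B-factor column
#'
#' AlphaFold-style models store the per-residue pLDDT (0-100) in every
#' atom's B-factor. `mode = "ca"` reads the CA atom's value (falling back
#' to the residue's atom mean where CA is absent); `mode = "atom_mean"`
#' averages over the residue's atoms. Values outside \[0, 100\] are passed
#' through with a warning, since they indicate a file that does not follow
#' the pLDDT convention.
#'
#' @param structure a [ComplexStructure-class].
#' @param chain chain to extract; defaults to the bait chain.
#' @param mode `"ca"` or `"atom_mean"`.
#' @return named numeric vector, names = local residue numbers.
#' @export
extractPlddt <- function(structure, chain = structure@baitChain,
                         mode = c("ca", "atom_mean")) {
  mode <- match.arg(mode)
  a <- structure@atoms[structure@atoms$chain == chain, , drop = FALSE]
  if (nrow(a) == 0L)
    stop("chain '", chain, "' has no atoms", call. = FALSE)
  res <- sort(unique(a$resno))
  val <- vapply(res, function(r) {
    ra <- a[a$resno == r, , drop = FALSE]
    if (mode == "ca") {
      ca <- ra$b[ra$elety == "CA"]
      if (length(ca)) ca[1] else mean(ra$b)
    } else mean(ra$b)
  }, numeric(1))
  names(val) <- res
  out <- val[!is.na(val)]
  if (any(out < 0 | out > 100))
    warning("pLDDT value(s) outside [0, 100] passed through for chain '",
            chain, "'", call. = FALSE)
  val
}

#' Read a fragment-to-structure manifest
#'
#' The manifest maps each tiled fragment to its predicted complex file.
#' Required header (exactly): `fragment_id`, `structure_path`,
#' `bait_chain`, `receptor_chain`, `global_start`. Relative structure
#' paths are resolved against the manifest's own directory.
#'
#' @param path manifest TSV.
#' @param checkPaths verify that every structure file exists.
#' @return `data.frame`, one row per fragment complex.
#' @export
readManifest <- function(path, checkPaths = TRUE) {
  man <- readTsv(path)
  need <- c("fragment_id", "structure_path", "bait_chain",
            "receptor_chain", "global_start")
  if (!identical(names(man), need))
    stop("manifest header must be exactly: ", paste(need, collapse = ", "),
         " (got: ", paste(names(man), collapse = ", "), ")", call. = FALSE)
  if (anyDuplicated(man$fragment_id))
    stop("manifest fragment_ids must be unique", call. = FALSE)
  man$global_start <- as.integer(man$global_start)
  if (any(is.na(man$global_start) | man$global_start < 1L))
    stop("manifest global_start must be positive integers", call. = FALSE)
  rel <- !grepl("^(/|[A-Za-z]:)", man$structure_path)
  man$structure_path[rel] <- file.path(dirname(path),
                                       man$structure_path[rel])
  if (checkPaths) {
    miss <- !file.exists(man$structure_path)
    if (any(miss))
      stop("manifest structure file(s) not found: ",
           paste(man$structure_path[miss], collapse = ", "), call. = FALSE)
  }
  man
}

#' Write a ComplexStructure to a PDB file
#'
#' Round-trip writer used by the synthetic generator and by tests.
#'
#' @param structure a [ComplexStructure-class].
#' @param path output PDB file.
#' @return invisibly, `path`.
#' @export
writeComplexPdb <- function(structure, path) {
  a <- structure@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety, eleno = seq_len(nrow(a)), b = a$b,
                   elesy = a$elesy)
  invisible(path)
}
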