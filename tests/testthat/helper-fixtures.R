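# Fixture builders used across the suite. Everything is generated in code;
# nothing is stored on disk.

# Atom table row(s) in the ComplexStructure layout.
atomRow <- function(chain, resno, elety, x, y, z, b = 80,
                    resid = "ALA", elesy = "C") {
  data.frame(chain = chain, resno = as.integer(resno), resid = resid,
             elety = elety, elesy = elesy, x = x, y = y, z = z, b = b,
             stringsAsFactors = FALSE)
}

# Two-chain complex from explicit atom rows.
toyComplex <- function(atoms, globalStart = 1L, fragmentId = "toy",
                       baitChain = "A", receptorChain = "B",
                       plddtMode = "ca") {
  complexStructure(atoms, fragmentId = fragmentId, baitChain = baitChain,
                   receptorChain = receptorChain,
                   globalStart = globalStart, plddtMode = plddtMode)
}

# Minimal two single-atom chains separated by `d` along x.
twoAtomComplex <- function(d) {
  toyComplex(rbind(atomRow("A", 1, "CA", 0, 0, 0),
                   atomRow("B", 1, "CA", d, 0, 0)))
}

# Random complex: atoms uniform in a cubic box, residues in groups of
# `atomsPerRes`, constant pLDDT.
randomComplex <- function(seed, n1 = 120, n2 = 120, box = 40,
                          atomsPerRes = 3L) {
  set.seed(seed)
  mk <- function(chain, n) {
    atomRow(chain, resno = rep(seq_len(ceiling(n / atomsPerRes)),
                               each = atomsPerRes)[seq_len(n)],
            elety = rep(c("CA", "CB", "CG"), length.out = n),
            x = runif(n, 0, box), y = runif(n, 0, box),
            z = runif(n, 0, box))
  }
  toyComplex(rbind(mk("A", n1), mk("B", n2)))
}

# A minimal mmCIF writer for format-equivalence fixtures (atom_site loop
# only; single model, no altlocs).
writeMinimalCif <- function(atoms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_fixture", "loop_",
               paste0("_atom_site.",
                      c("group_PDB", "id", "type_symbol", "label_atom_id",
                        "label_alt_id", "label_comp_id", "label_asym_id",
                        "label_entity_id", "label_seq_id",
                        "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                        "Cartn_z", "occupancy", "B_iso_or_equiv",
                        "pdbx_formal_charge", "auth_seq_id",
                        "auth_comp_id", "auth_asym_id", "auth_atom_id",
                        "pdbx_PDB_model_num"))), con)
  ent <- as.integer(factor(atoms$chain, levels = unique(atoms$chain)))
  writeLines(sprintf(
    "ATOM %d %s %s . %s %s %d %d ? %.3f %.3f %.3f 1.00 %.2f ? %d %s %s %s 1",
    seq_len(nrow(atoms)), atoms$elesy, atoms$elety, atoms$resid,
    atoms$chain, ent, atoms$resno, atoms$x, atoms$y, atoms$z, atoms$b,
    atoms$resno, atoms$resid, atoms$chain, atoms$elety), con)
  invisible(path)
}

# A ContactSet built directly (bypassing geometry) for scoring tests.
madeContactSet <- function(fragmentId, baitResidues, pairs,
                           unit = "residue_pair", cutoff = 4.0) {
  if (nrow(pairs) && !"min_distance" %in% names(pairs))
    pairs$min_distance <- 3.5
  if (nrow(pairs) && !"n_atom_pairs" %in% names(pairs))
    pairs$n_atom_pairs <- 1L
  new("ContactSet", fragmentId = fragmentId, cutoff = cutoff, unit = unit,
      pairs = as.data.frame(pairs),
      baitResidues = as.integer(baitResidues))
}

noPairs <- function() {
  data.frame(bait_res = integer(), receptor_res = integer(),
             min_distance = numeric(), n_atom_pairs = integer())
}
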