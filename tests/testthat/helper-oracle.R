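# Independent brute-force contact oracle: plain double loop over atoms,
# no pruning, no shared code with countContacts(). Returns residue-pair
# and atom-pair counts plus the sorted residue-pair keys.
bruteContacts <- function(structure, cutoff = 4.0) {
  a <- structure@atoms
  ba <- a[a$chain == structure@baitChain, , drop = FALSE]
  ra <- a[a$chain == structure@receptorChain, , drop = FALSE]
  pairKeys <- character()
  atomPairs <- 0L
  for (i in seq_len(nrow(ba))) {
    for (j in seq_len(nrow(ra))) {
      d <- sqrt((ba$x[i] - ra$x[j])^2 + (ba$y[i] - ra$y[j])^2 +
                (ba$z[i] - ra$z[j])^2)
      if (d <= cutoff) {
        atomPairs <- atomPairs + 1L
        g <- structure@globalStart + ba$resno[i] - 1L
        pairKeys <- c(pairKeys, paste(g, ra$resno[j]))
      }
    }
  }
  list(residue_pairs = length(unique(pairKeys)),
       atom_pairs = atomPairs,
       keys = sort(unique(pairKeys)))
}
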