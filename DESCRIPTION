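Package: fragmap
Title: Fragment Tiling and Confidence-Weighted Interface Scoring for
    Minimal Binding-Motif Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies minimal receptor-binding motifs within a bait
    protein from predicted two-chain complex structures. The bait is tiled
    into overlapping fragments with a sliding window, each fragment's
    predicted complex with the receptor is scored by counting inter-chain
    heavy-atom contacts within a distance cutoff and weighting the count by
    the fragment's mean pLDDT confidence, fragment scores are averaged into
    a per-residue interaction profile, and contiguous peak regions are
    refined to minimal motifs using per-residue contact runs. Includes a
    synthetic complex generator that plants ground-truth interfaces so the
    whole pipeline can be exercised and validated without external
    structure predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    Biostrings,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
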