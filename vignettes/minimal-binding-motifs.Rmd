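---
title: "Mapping minimal receptor-binding motifs by fragment tiling and confidence-weighted interface scoring"
author: "fragmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping minimal receptor-binding motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragmap)
```

## The problem

Large ligand proteins often bind their receptors through short linear
stretches of sequence. A concrete example is vitellogenin (Vtg), the yolk
precursor that developing oocytes internalize through receptor-mediated
endocytosis: its N-terminal receptor-binding domain (RBD) engages the
LDL-type repeats of the vitellogenin receptor (VtgR), and a peptide of
roughly ten residues from that domain is enough to route a fused cargo
protein into the oocyte. Finding such a minimal motif experimentally means
truncation after truncation; finding it computationally means asking a
structure predictor which short stretch of the bait keeps touching the
receptor.

`fragmap` implements the computational side as a reproducible pipeline.
The inputs are (i) the bait sequence, (ii) one predicted two-chain
complex per tiled bait fragment (e.g. AlphaFold-Multimer models of each
fragment with the receptor), listed in a manifest, and (iii) nothing
else. The outputs are per-fragment interaction scores, a per-residue
interaction profile, and one refined minimal motif per sequence half.

## The procedure

**Tiling.** The bait of length $L$ is cut into overlapping windows of
`window` residues every `step` residues (defaults 50 and 25). Full
windows start at $1, 1+s, 1+2s, \dots$ while they fit. When the last
grid window does not end at residue $L$, the default `anchor_tail`
policy appends one extra full-width window anchored at
$[L - w + 1,\, L]$, so every residue — including the C-terminal stretch
shorter than a step — is covered by at least one fragment. Tail windows
are always full width; the alternative `drop_tail` keeps the exact grid
only. For $L = 315$, $w = 50$, $s = 25$ this yields 11 grid windows
starting at 1, 26, ..., 251 plus the anchored tail 266–315, i.e. 12
fragments.

**Contact counting.** For each fragment's predicted complex, an
interaction is a bait-residue/receptor-residue pair with at least one
heavy-atom (non-hydrogen) distance $\le$ `cutoff` (default 4.0 Å,
inclusive — "within 4 Å"). Each residue pair counts once by default
(`unit = "residue_pair"`, the standard interface-contact convention,
robust to side-chain completeness); `atom_pair` counting is available.
Candidate atom pairs are pre-filtered by per-axis separation before the
exact Euclidean check, which cannot change the answer — the test suite
holds the counter to exact equality with an exhaustive all-pairs oracle.

**Confidence weighting.** Each fragment's score is

$$S_f = C_f \times \bar{P}_f,$$

where $C_f$ is the contact count and $\bar{P}_f$ is the unweighted mean
pLDDT over *all* residues of the bait fragment (not just contacting
ones), read from the B-factor column where AlphaFold-style models store
it (per-residue constant; the default `plddt_mode = "ca"` reads the CA
atom, `atom_mean` averages the residue's atoms — identical on
AlphaFold's own outputs). pLDDT stays on its native 0–100 scale: peak
calling only uses relative values, and the suite verifies exact
linearity — scaling all pLDDT by $\alpha$ scales every $S_f$ and every
profile value by exactly $\alpha$. A fragment with zero contacts scores
exactly zero whatever its confidence.

**Per-residue profile.** Residue $i$'s value is the mean score of the
scored fragments covering it,

$$r_i = \frac{1}{c_i} \sum_{f \ni i} S_f,$$

with $c_i$ the coverage. Fragments without a usable structure are
excluded from both sums; residues with $c_i = 0$ are reported as
missing (`NA`), never as zero, because zero is a meaningful score. The
bookkeeping identity $\sum_i c_i r_i = \sum_f S_f\,\mathrm{len}(f)$ is
asserted to $10^{-9}$ relative tolerance.

**Peak calling.** The profile is split into N- and C-terminal halves at
$\lfloor L/2 \rfloor$ (the split is configurable; the halves of a
315-residue bait are 1–157 and 158–315). Within each half, residues at
or above a threshold form maximal contiguous runs, and the run holding
the half's maximum is that half's best peak (ties go to the leftmost
run). The default threshold is mean + 1 sd of the half's own defined
values. We compute the threshold per half rather than globally: the two
halves are screened independently for their best peak, and with a
global threshold a strong interface in one half raises the bar enough
to suppress the other half's genuine peak — in planted simulations a
13-residue interface in the C-half routinely pushed the global mean +
1 sd above the N-half's 9-residue peak. A global scope remains
available (`scope = "global"`), as do quantile and absolute threshold
policies. Two degenerate behaviours are worth knowing: on a perfectly
uniform profile the sd is zero, every residue qualifies, and each half
returns one run spanning it entirely; and when nearly a whole half
carries signal (short baits tiled by few windows), mean + 1 sd can
exceed the half maximum and that half legitimately returns no peak —
for such geometries use a quantile or absolute policy.

**Motif refinement.** The peak's supporting fragment with the highest
$S_f$ is selected (ties: leftmost fragment). Within it, residues with at
least one contact are grouped into runs that tolerate internal gaps of
up to `gap_tolerance` contact-free residues (default 1); runs shorter
than `min_motif_length` (default 5) are discarded; among the rest the
run with the largest total contact count (ties: leftmost) becomes the
motif, reported with its sequence, coordinates, and mean per-residue
contact count. The defaults are sized so that motifs in the 9–13
residue range typical of short receptor-binding peptides are
recoverable. All tie-breaks in the pipeline are leftmost, making every
stage deterministic for fixed inputs.

## The synthetic generator

Real inputs are GPU-scale structure predictions, so validation uses a
generator that emulates their geometry. Each fragment complex is a
coarse heavy-atom model: the bait as CA+CB beads along the x axis with
the canonical 3.8 Å CA spacing, the receptor (default 119 residues,
matching a three-LDL-repeat receptor fragment) as a parallel chain
whose bulk sits 40 Å away. For each bait residue inside a planted
segment, one or more receptor residues are relocated so that one atom
sits 3.3 Å from the bait residue's CA — inside the 4 Å cutoff — at
angles chosen so every *other* bait residue stays > 4 Å away with at
least a 0.39 Å margin. Adjacent bait residues are only 3.8 Å apart, so
an atom within 4 Å of one residue is necessarily closer than 8 Å to its
neighbours; the generator's guarantee is therefore exact contact
*classification* (planted and decoy pairs are the only pairs within the
cutoff), with the receptor's unused bulk kept ≥ 8 Å from everything.

The number of receptor residues contacting a planted bait residue is
drawn once per dataset (Poisson with mean `contactDensity`, floor 1,
cap 5) keyed to the global residue, not per fragment: a contact pattern
is a property of the interface, and overlapping predictions of the same
interface should agree on it. This also makes the fully-covering
fragment's contact count a superset sum of any partial overlap, so
clean-recovery is exact rather than merely likely. Decoy contacts
(Poisson per non-planted residue at `decoyRate`), per-residue pLDDT
levels, pLDDT noise, and coordinate noise are drawn per fragment from
its own derived seed. Coordinate noise is applied last and redrawn (up
to 100 times) until the contact classification is preserved exactly, so
ground truth stays exact, not statistical. Every random draw flows from
one explicit dataset seed; regenerated datasets are byte-identical.

Default study conditions: $L = 315$, windows 50/25, receptor length
119, planted segments 28–36 (9 residues, N-half) and 197–209 (13
residues, C-half), contact density 2, uniform pLDDT 80, no decoys, no
noise. The stressed conditions used by the validation suite add
`decoyRate = 0.05`, pLDDT noise sd 5, and coordinate noise sd 0.1 Å.

What the generator does *not* emulate: folded receptor topology,
side-chain packing, predictor-correlated pLDDT (confidence tracking
contact quality), partially-correct interfaces, or register errors.
Passing the planted-recovery tests therefore shows the pipeline's
bookkeeping and calling logic are correct under controlled geometry; it
does not show that any particular predictor's output will yield
recoverable motifs for a given receptor.

## Numerical choices and degenerate inputs

* Distance comparison is inclusive (`d <= cutoff`); distances are exact
  doubles, and the pruning pre-filter is conservative per axis, so no
  boundary case can differ from the brute-force answer.
* Coordinates are 1-based inclusive everywhere; only the bedGraph
  export converts to 0-based half-open intervals.
* Chain-local residue numbering in structure files is renormalized so
  the first bait residue maps to the manifest's `global_start`: the
  manifest, not the file, is the coordinate authority, since predictors
  renumber every chain from 1.
* Alternate locations resolve to the highest occupancy (first on ties);
  hydrogens and heteroatom records are excluded before any distance is
  measured; duplicated atom records (e.g. multiple models) collapse to
  the first with a warning.
* pLDDT outside [0, 100] is passed through with a warning rather than
  clamped — it flags a file that does not follow the convention.
* TSV outputs round numeric columns to 6 significant digits; missing
  values are written as `NA`; all writers are deterministic, and two
  runs from one seed are byte-identical.

## Worked example

The sizes here (one 315-residue bait, 12 complexes of ~360 atoms) keep
a full run under a second, so the whole validation suite — including 20
stressed replicates — runs in well under a minute.

```{r example, eval = FALSE}
library(fragmap)
out <- runSynthetic(tempfile("demo_"), config = runConfig(seed = 1))
#> recovery summary (called vs planted):
#>   N-half: planted 28-36, called 28-36, Jaccard 1.000
#>   C-half: planted 197-209, called 197-209, Jaccard 1.000
out$motifs[, c("name", "start", "end", "sequence")]
```

With real predictions the entry point is `runPipeline()` on a bait
FASTA and a manifest TSV mapping each fragment to its structure file;
`inst/scripts/fragmap.R` wraps both modes for the shell.

## Known limitations

* One motif per half by design; baits with more than two binding sites
  need a custom split or repeated runs on sub-ranges.
* The mean + k·sd threshold assumes most of a half is background; very
  short baits (a handful of windows per half) can fail to call a peak —
  use `thresholdPolicy("quantile", q = ...)` there.
* $\bar{P}_f$ averages over bait-fragment residues only; a predictor
  that is confident about the bait but not the receptor can still score
  highly. PAE-style cross-chain confidence is not parsed.
* Fragments whose structures are missing are excluded from coverage
  rather than scored zero; if most fragments are missing the profile is
  mostly undefined and peak calling will warn accordingly.
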