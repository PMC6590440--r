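---
title: "Comparative plastome evolution with plastevol: models, assumptions, design"
author: "plastevol maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome evolution with plastevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

plastevol implements a comparative analysis of plastid genome (plastome)
structural and molecular evolution, motivated by the lycophytes: clubmosses
(Lycopodiaceae), quillworts (*Isoetes*) and spikemosses (*Selaginella*).
These lineages span the extremes of land-plant plastome evolution — from
near-total stasis since the land-plant ancestor to genomes in which the
canonical large inverted repeat (IR) has been converted into a direct
repeat (DR) by large-scale inversion, with heavy gene, tRNA and intron
loss and strongly elevated substitution rates. The package provides the
full computational chain for that style of analysis: quadripartite
structure detection, gene/intron content scoring with parsimony mapping of
losses, exact inversion-scenario inference over signed gene orders, codon
and nucleotide divergence estimation, and a simulator that generates all
of these data types with known ground truth.

# The quadripartite model and repeat detection

A photosynthetic land-plant plastome is modeled as a circular molecule
tiled exactly by four regions: a large and a small single-copy region
(LSC, SSC) separated by two copies of a large repeat. The two copies may
be in inverted (IR, reverse-complement) or direct (DR, same-strand)
relative orientation; the orientation class is the central structural
character of the analysis.

`findLargeRepeat()` detects the repeat by seed-and-extend: exact k-mer
matches (k = 21 by default) of the sequence against itself and its
reverse complement are grouped into collinear diagonals, the longest
seeded candidate is extended outward base by base under an X-drop rule
(+1 per match, −3 per mismatch, stop when the running score falls 12
below its maximum, then trim back to the best-scoring endpoint). The
defaults `minLen = 1000` bp and `minIdentity = 0.98` sit far below the
7.3–18 kb repeats of real lycophyte plastomes while excluding
tRNA-scale repeats; the X-drop trim keeps boundaries of exact planted
repeats within a few bases of truth (the package treats boundaries
within ±20 bp as concordant, since annotation-based and first-mismatch
conventions differ by about that much in practice). N bases count as
mismatches and are excluded from both the numerator and denominator of
GC content. A genome with no repeat above threshold degenerates to a
single-region partition with an explicit flag rather than an error.

`partitionRegions()` assigns the longer inter-repeat arc to the LSC; the
tiling identity `LSC + SSC + 2×repeat = total` is enforced exactly by the
class validity method, and `regionStats()` reports per-region lengths, GC
and unique gene counts (second repeat copies, `copy_index > 0`, are not
counted).

# Signed gene orders and the canonical linearization

`extractGeneOrder()` reduces a genome to an ordered list of signed gene
identifiers. Because plastomes are circular and sequencing projects
linearize them arbitrarily, orders are canonicalized: among all rotations
of the order and of its reflection, the lexicographically smallest
(by block name, ignoring duplicate-copy suffixes, then sign) is chosen,
and duplicate copies are relabeled in order of appearance. This makes the
result provably invariant to rotation and to reverse-complementing the
input, which the test suite checks directly.

With `collapseRepeat = TRUE` the second repeat copy is dropped and the
repeat becomes one signed block (`REP`) carrying an IR/DR flag. The sign
of `REP` follows the majority strand of the genes annotated inside copy
A, so that the block orientation is meaningful relative to the repeat's
internal gene content — without this convention two genomes differing by
an inversion of one repeat copy would collapse to identical orders.

# Inversion scenarios

Rearrangement inference works on signed permutations. The target order is
renamed to the identity; circular orders are linearized by fixing the
source's leading block (for a circular genome a reversal spanning the
fixed block is equivalent to the reversal of the complementary interval,
so no optimal scenario is lost). Distances and explicit event sequences
come from iterative-deepening A* over reversals with the admissible
breakpoint-graph bound `max(ceil(b/2), n+1−c)` (b breakpoints, c cycles
of the breakpoint graph). The search is exact for any input; the bound is
tight for hurdle-free permutations, which is the overwhelming majority at
the problem sizes this package targets (≤ ~40 blocks after collapsing
shared strips, scenarios ≤ 12 events). We deliberately did not implement
the hurdle/fortress corrections of the closed-form reversal-distance
formula: they buy speed the package does not need and would not change
any result, since the search itself is exact. An independent breadth-first
search oracle (in the test suite, reimplemented separately in the
acceptance script) verifies exactness exhaustively for all 384 signed
permutations of n ≤ 4 and on random n ≤ 7 instances.

Events are annotated `spansRepeat` when their interval contains the
collapsed repeat block; each such event toggles IR↔DR, and the parity of
spanning events must equal the orientation difference between source and
target — among co-optimal scenarios (enumerated to a cap of 64, ordered
lexicographically by leftmost endpoint then interval length) the reported
one is the first with consistent parity. Tandem duplications (a block or
short run occurring twice adjacently) are extracted by
`collapseToBlocks()` before distance computation, mirroring how a tandem
trnQ–psbK duplication must be set aside before inversion counting;
non-tandem duplicates raise an error asking for manual curation rather
than guessing. IR boundary shifts (expansion/contraction) are not
inversions in this vocabulary: blocks are trimmed to shared single-copy
content during collapse, and shifts surface as private-block warnings
rather than events.

`placeEventsOnTree()` maps events onto a fixed rooted topology by pushing
any first event shared — with identical interval in the current ancestral
frame, supported by some co-optimal scenario for every descendant tip —
onto the deepest consistent branch, then recursing with the updated
ancestral order. This is a greedy parsimony heuristic, not a median-genome
optimization (an explicit non-goal); it recovers planted histories in the
simulator and places the shared IR→DR inversion of the encoded
*Selaginella* orders on the *Selaginella* stem, exactly as manual
reconstruction does.

# Content scoring and loss mapping

Genes are scored `intact`, `pseudogene` or `absent` against a fixed
land-plant catalog (87 proteins including ycf94, 4 rRNAs, 32 tRNAs, 22
introns with host linkage). The pseudogene rules are: a frameshift
(summed exon length not divisible by 3); a substantial truncation, which
we quantify as spliced length below 0.5× the cross-taxon median reference
length (the source analyses leave "substantial" unquantified; 0.5 is
conservative and configurable); and — only in taxa flagged as lacking
U-to-C RNA editing, as in *Selaginella* — an internal stop codon under
the plastid genetic code (NCBI table 11), because without U-to-C editing
a genomic premature stop cannot be rescued at the RNA level. Intron
presence additionally requires the host gene to be present.

Losses are mapped onto a fixed rooted topology by a per-element Sankoff
dynamic program with a quasi-Dollo cost scheme: intact→pseudogene 1,
pseudogene→absent 1, intact→absent 2, any gain 10. Gene regain in
plastomes is implausible, so gains are near-prohibited while remaining
finite for degenerate inputs. All minimum-cost assignments are enumerated
(capped at 64); events present in every optimum are flagged unambiguous.
Ties at the root resolve toward the functional state, encoding the prior
that the land-plant ancestor carried the full catalog. The DP is verified
against exhaustive enumeration over all internal-state assignments on
trees of up to 8 tips.

The package ships an encoded content matrix for the 14 lycophyte
plastomes plus an all-present outgroup (`lycophyteContentMatrix()`).
Every element-level statement in the source literature is encoded exactly
(the Lycopodiaceae-wide trnT-GGU absence; the ndh-complex absence in
*S. tamariscina* and *S. lepidophylla*; matK absence in *S. kraussiana*
and *S. lepidophylla*; accD/infA/rps2/rps16 pseudogenes and ycf94 absence
in *Isoetes*; infA intact in *S. uncinata* but pseudogenized in
*S. moellendorffii*; the rps16 intron following its host; clpP/ycf3
intron losses from intact hosts). The remaining cells are filler chosen
once so that per-category totals match the published per-genome counts;
they are plausible but not data, and conclusions should only be drawn
from the pinned cells and the totals. The species topology fixes
Lycopodiaceae sister to (*Isoetes*, *Selaginella*) and unites
*S. moellendorffii*, *S. tamariscina* and *S. uncinata* (the clade
sharing the rps4-capturing IR expansion); the remaining *Selaginella*
arrangement follows the consensus of recent lycophyte phylogenies. The
outgroup tip makes stem placements (e.g. the trnT-GGU loss on the
Lycopodiaceae stem) unambiguous under parsimony.

# Divergence estimation

## Codon model

Synonymous divergence d~S~ is estimated under an MG94-style codon model:
61 sense codons (plastid code), single-nucleotide changes only, rate
θ~class~·π~pos~(target) for synonymous and ω~branch~·θ~class~·π~pos~(target)
for nonsynonymous changes. Codon frequencies are the F3x4 construction
from empirical per-position nucleotide frequencies, never optimized
(frequencies are floored at 10^-4^ per position so degenerate alignments
cannot zero out codon frequencies). Exchangeabilities are shared across
the six nucleotide pairs according to a 6-digit class string —
`"012232"`, `"012312"` and `"012012"` are the strings used for the three
protein data sets in the motivating analysis; the strings are inputs, not
searched. The model is local: each branch carries its own (t, ω).

Only the unrooted branch set is identifiable under a reversible model, so
the topology is unrooted before fitting. Optimization alternates global
exchangeabilities (Nelder-Mead on the log scale) with per-branch Brent
profiles for ω and log t, stopping when the log-likelihood improves by
less than 10^-4^ (default; tighten via `tol` if needed — at the data
sizes involved the d~S~ estimates move by far less than the Monte Carlo
noise below this threshold). The default is a single deterministic start;
`restarts` adds jittered starts. Likelihood evaluation uses Felsenstein
pruning over site patterns with per-column rescaling, and the transition
matrices come from the symmetrized eigendecomposition available for
reversible chains.

The printed d~S~ depends on a normalization convention the field does not
fully standardize. The default (`dsConvention = "persite"`) is synonymous
substitutions per synonymous site: per branch,
d~S~ = (expected synonymous substitutions per codon) divided by the
proportion of neutral (ω = 1) flux that is synonymous, with the same θ
and π. A `"raw"` switch returns the per-codon synonymous component
instead. The simulator computes true d~S~ with the identical formula, so
recovery experiments are convention-consistent.

## Nucleotide model

Total divergence d for rRNA-style data uses GTR with 4 discrete mean-one
Gamma categories and an invariant-site proportion. This is a standard
model fit, so it is delegated to phangorn (`pml`/`optim.pml`) on the
fixed topology; a two-taxon special case (where tree-based engines do not
apply) is fitted by direct pairwise maximum likelihood under the same
family. In the equal-rates, equal-frequencies limit the estimate matches
the Jukes–Cantor closed form −(3/4)·ln(1 − 4p/3) to 10^-4^, which both
the unit tests and the acceptance script verify.

`compareRates()` forms the repeat-versus-single-copy contrast: the ratio
of a species' terminal branch value estimated from repeat-resident genes
to that from single-copy genes. A ratio well below 1 is the signature of
copy-dependent repair.

# The simulator

`simulateHistory()` builds a root quadripartite genome (40 genes by
default, 4 rRNA-style genes in the repeat, ~38 kb — a deliberately
desk-scale plastome that preserves all structural features of the real
120–160 kb molecules), then walks a tree applying inversions
(repeat-spanning ones toggle IR↔DR), gene losses, frameshifting
pseudogenizations, intron splice-outs, and point mutations, and assembles
fully annotated tip genomes whose second repeat copy is written in IR or
DR orientation according to the current flag. All randomness derives from
the config seed; fixture directories are byte-identical across runs with
the same seed, which is tested.

`evolveSequences()` generates codon and nucleotide alignments with known
per-branch truth. Repeat-resident sites evolve as a two-copy system at
rate r (`rateReduction`) relative to single-copy sites; each mutation is
followed, with probability γ (`conversionProb`), by instantaneous
homogenization of the two copies, the direction chosen uniformly. This is
the minimal parameterization that produces the observable of interest — a
reduced repeat substitution rate — without modeling conversion tracts
(noted as an extension). Two consequences matter for interpretation:
with γ = 1 the copies are identical at every tip and the shared sequence
accumulates substitutions at rate r relative to single-copy sequence; and
the marginal substitution rate of one copy is r·(1 − γ/2) + r·γ/2 = r
for every γ, so the expected d~S~ of a repeat gene is r times the
single-copy value regardless of γ — γ controls only the correlation
between copies. Orientation (IR vs DR) does not enter the conversion
model at all, encoding the finding that copy-dependent repair is not
disrupted by a DR arrangement. γ has no literature-anchored default; the
default γ = 1 represents fully effective copy correction and should be
varied in sensitivity analyses.

What the simulator does **not** emulate: realistic intergenic sequence,
indels, IR boundary expansion/contraction (boundary events are inputs,
not outputs), rate heterogeneity among genes, and base-compositional
drift along branches. Passing recovery tests on simulated data therefore
demonstrates correctness of the inference machinery under the stated
model, not robustness to every feature of real plastomes.

# Problem sizes and verification scale

The shipped test and acceptance runs use sizes chosen so the whole
verification completes in minutes on one CPU while keeping Monte Carlo
noise inside the stated tolerances: simulated clades of 7 taxa with
40-gene genomes; 200 simulated genomes for orientation calling; all 384
signed permutations of n ≤ 4 plus 200 random n ≤ 7 permutations against
the breadth-first-search oracle; codon recovery at 6700 codons (~20 kb)
per data set, where terminal-branch d~S~ is recovered within 10%; and the
r = 0.3 copy-correction experiment at 6700 codons per partition, where
the repeat/single-copy ratio is recovered within ±0.05. Larger runs only
tighten the Monte Carlo component.

# Known limitations

- The exact scenario search is exponential in the worst case; beyond
  `maxEvents = 12` (or ~40 blocks) it refuses rather than degrades.
- Event placement on trees is greedy-parsimony over shared first events;
  co-optimal placements that disagree across tips are reported on
  terminal branches rather than globally optimized.
- The GenBank parser covers the feature-table subset plastome records
  use (gene/CDS/tRNA/rRNA/intron keys, join/complement locations);
  records with origin-wrapping features should be rotated upstream.
- The encoded lycophyte content matrix is a reconstruction: totals and
  pinned cells are published values, the rest is documented filler.
- Codon recovery tolerances assume the generating model; model
  misspecification (e.g. true rate variation among sites) biases d~S~ in
  ways the recovery experiments do not probe.
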