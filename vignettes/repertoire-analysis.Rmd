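---
title: "Methods: amplicon repertoire analysis with vdjmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon repertoire analysis with vdjmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the computational model behind the package: what
each stage assumes, the tunable parameters and their defaults, what the
simulator does and does not emulate, and the numerical and design choices
made where more than one convention was defensible.

## The assay being modeled

The input is a multiplexed paired-end Illumina run over ~400 bp amplicons
of expressed IgH (or TRB) transcripts. The forward primer sits in V
framework region 2, so the amplicon spans from just 5' of CDR2 through
the V(D)J junction into the constant region; the constant-region mate
carries a sample barcode at its 5' end. Because the forward primer
overwrites genuine template sequence 5' of CDR2, mutation analysis is
restricted to the window from the CDR2 start to the CDR3 start.

All coordinates in the package are 0-based, half-open. Germline references
are supplied as an ungapped FASTA plus a tab-separated anchor table giving,
per segment, the locus, the gene type, and (for V) the CDR2 start and the
first base of the conserved-Cys codon, or (for J) the first base after the
conserved Phe/Trp codon. A deterministic bundled toy reference
(`builtin_toy_reference()`) covers both loci, with one IgH constant
segment per isotype (IgM, IgD, IgG3, IgG1, IgG2b, IgG2c, IgE, IgA); the
IgG2b/IgG2c constants intentionally share their first 20 nt so the
subclass-ambiguity path is exercised. Only A/C/G/T are accepted in
references: the alignment scoring model is defined on the four-letter
alphabet, and `N` in reads never matches anything.

## Preprocessing

**Demultiplexing.** The barcode is compared against the prefix of the
constant-side mate; `max_mismatch` (default 0) Hamming mismatches are
tolerated. A prefix within tolerance of two or more barcodes is binned as
ambiguous rather than guessed. Assigned + unassigned + ambiguous always
equals the input pair count.

**Quality trimming.** Windows of `window` = 2 bases slide in 1-base steps
from the 5' end; at the first window containing any quality below
`qmin` = 20, the window's first base and everything 3' of it are removed.
The literal "from the window" reading (rather than from the offending
base) is used, so a failing window at 0-based index k leaves k bases.
Reads shorter than the window are left alone — the downstream
`min_length` = 50 filter (applied to both mates symmetrically) removes
anything that short anyway. The rule is idempotent.

**Merging.** The reverse mate is reverse-complemented and the best
gap-free end-free overlap with the forward mate is sought: every overlap
length is scored as matches minus mismatches, ties preferring fewer
mismatches, then longer overlap. A pair merges only when the best overlap
is a *perfect* character match at least `min_overlap` = 10 nt long
(default chosen as the shortest overlap with negligible chance identity,
4^-10; it is configurable). Anything else is discarded and counted by
reason. Gaps are not modeled in the overlap: since any imperfect overlap
is discarded anyway, only the best exact-overlap offset can ever produce
output, and a gap-free scan finds it directly. An `N` surviving into the
overlap forces a discard, which is the conservative reading of "perfectly
matched".

**Collapsing.** Exact string identity within a sample; the representative
id is the lexicographically smallest contributing read id, making the
result order-independent. Copy count — the number of identical merged
reads — is the quantity the downstream copy filter acts on. Whether
"copies" should instead mean clonotype membership is genuinely ambiguous
in assay descriptions of this kind; exact duplicates are used here
because the filter exists to suppress sequencing error, and only exact
duplication provides that evidence.

## Germline assignment

Each unique transcript is aligned to every germline segment of its locus
with an affine-gap Smith–Waterman (Rcpp). Scoring defaults: match +2,
mismatch −2, gap open −3, gap extend −1, with a gap of length L costing
`gap_open + L*gap_extend` (so a 1-base gap costs −4). This convention
matches `Biostrings::pairwiseAlignment`, which the test suite uses as an
independent cross-check of scores; correctness is additionally checked
against a brute-force DP oracle on short random strings. Among co-optimal
alignments the one with the smallest (query start, ref start) is
returned, then the smallest endpoint, with a match-state-preferred
traceback; `N` scores as a mismatch against everything.

Per-gene-type minimum scores (V 40, D 10, J 16, C 16) gate the calls;
ties on score break to the lexicographically smallest segment id. D is
searched only between the read projection of the V CDR3 anchor and the J
alignment start, because short D matches elsewhere are spurious; an
absent D is legal. Calls violating the v ≤ d ≤ j ≤ c read order are
demoted (D first, then C). No V or no J call makes the sequence
unassignable (counted, excluded from annotation). Reads are oriented
V→C by the assay design, so no reverse-complement search is performed.
When two constant segments tie exactly (shared subclass 5' ends), the
lexicographically first is reported and an ambiguity flag is set.

## CDR3, clonotypes, SHM

CDR3 runs from the first base of the V conserved-Cys codon to the end of
the J conserved Phe/Trp codon, both obtained by walking the alignment
operations (`migrate_boundary`): a reference position inside a read
deletion maps immediately 3' of it; positions outside the aligned
reference interval are uncovered and flag the sequence. The J anchor is
an exclusive end, so the last CDR3 base is migrated and 1 added —
this keeps the boundary defined even when the alignment ends exactly at
the anchor. Translation uses the standard code; *productive* means an
in-frame CDR3 with no stop codon inside it (full-sequence frame is not
assessed, since only the CDR3 is reliably covered by the design).

Clonotypes are keyed by (V gene, J gene, CDR3 nucleotide sequence) by
default; `clonotype_key = "cdr3"` collapses across V/J instead. Copies
and per-isotype copies are summed; output order is descending copies then
lexicographic key, so tables are reproducible.

SHM counts substitutions only — the statistic is defined on mismatches,
and indels within the window are instead flagged (`indel_in_window`) with
read bases not covered by M operations excluded from the examined length.
The summary keeps records with copies ≥ `min_copies` = 5 ("more than four
copies") and reports, copy-weighted by default: the fraction of
transcripts with more than `gt_threshold` = 5 changes, and
1000 × Σ(w·mismatches) / Σ(w·examined bases). Copy weighting is the
headline because each copy is one sequenced transcript; unique weighting
is available for sensitivity analysis. No sequencing-error floor is
subtracted: the copy filter is the error control.

## D50

With ranked clone abundances r_1 ≥ … ≥ r_S summing to J, C is the
smallest prefix with Σ_{i≤C} r_i ≥ J/2, and D50 = 100·C/S. The
implementation compares 2×(prefix sum) against J so J/2 stays exact for
odd J; there is no additional tie convention to choose — the two
inequalities of the definition decide every case, which the test suite
verifies against a linear prefix-scan oracle. D50 is invariant to
uniformly scaling abundances and to input order, and lies in
[100/S, 100]. Subsampling to a common depth before D50 is exposed as a
config hook but off by default.

## Tree-maps

The hierarchy is V → V-J → V-J-CDR3 with copy-weighted frequencies. The
published construction fixes the subdivision semantics and the ordering
(areas proportional to frequency; largest at the bottom right, smallest
at the top left; rounded, randomly colored rectangles) but not the
geometry, so the layout is a squarified tiling — chosen for readable
aspect ratios — whose placement is point-reflected within each parent so
the largest sibling lands bottom-right. Only the stated invariants are
promised: exact nesting, area ∝ frequency (relative error < 1e-6 in
tests), no sibling overlap, deterministic output under a fixed seed. Leaf
colors are seeded uniform hues at fixed saturation/value, re-drawn when
two consecutive leaves would be near-identical. SVG output is plain
deterministic text.

## The simulator

`simulate_repertoire()` + `emit_reads()` generate what the pipeline
assumes: clones drawn with configurable V usage and clone-size law
(geometric, discrete power law, or fixed size), V(D)J junctions built
from V 3' trims (0–3), random inserts (0–6 each side), a D fragment of at
least 4 nt (IGH), and J 5' trims (0–4); an isotype per clone from a
configurable mixture; ~380 nt amplicons from 110 nt 5' of CDR2 into the
first 60 nt of the constant segment; 2×250 nt reads with the barcode
prepended to the constant-side mate; per-base sequencing errors (default
0.001) and a constant-Phred quality model with an optional low-quality
tail. Defaults mirror the assay scale (MiSeq 2×250 over ~400 bp products)
and a resting, IgM-dominated mixture.

SHM is injected *per clone*, uniformly over the V portion 5' of the CDR3
start, and every copy of the clone carries the same mutated sequence.
This is deliberate: transcripts of one expanded clone share their
mutations, and that sharing is exactly what lets identical copies
accumulate and pass the more-than-four-copies filter. Independently
mutated copies would almost never collapse into duplicates, and the copy
filter would discard the entire repertoire. The truth table records every
substitution position per copy, plus the exact CDR3 and boundary
coordinates, so recovery can be asserted base by base.

What the simulator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: PCR amplification bias and chimeras,
position- or motif-dependent error and quality profiles (no WRCY hotspot
structure in SHM), indel SHM (available behind the substitution-only
default but off), allelic variation and novel polymorphisms, and primer
artifacts. Real germline repertoires are also far larger than the toy
reference, which makes real V-gene discrimination harder than it is here.

## Problem sizes and numerical checks

The test suite verifies: D50 against a brute-force oracle on 500 random
repertoires (S ≤ 50) plus the worked cases [10] → 100, [1,1,1,1] → 50,
[5,1,1,1] → 25, [3,1,1] → 33.33; the aligner against an independent DP on
200 random pairs (length ≤ 10) and against Biostrings on longer pairs;
perfect reconstruction of 10^4 error-free simulated pairs and 100%
mismatch-discard when one substitution is planted in every overlap; exact
end-to-end truth recovery for a 500-clone error-free run; recovery of a
simulated 0.025/base window mutation rate within ±15% of 25/kb at 1000
clones with planted 4-copy clones proven excluded; isotype and V-usage
mixtures within 3σ multinomial at 10^4 single-copy clones (single-copy so
the copies are i.i.d. draws and the bound is exact); tree-map geometry on
50 random hierarchies; and byte-identical outputs across two identically
seeded end-to-end runs. These sizes were chosen to make the statistical
bounds sharp at desk scale.

## Degenerate inputs and edge cases

Empty repertoires raise an explicit "empty repertoire" error from
rank-abundance construction; an SHM summary with no surviving records is
returned *flagged undefined*, never as zero; a run whose trimming removes
everything completes with an explicit zero-sequence report rather than
crashing; a failing sample aborts only that sample. Config validation
resolves defaults, rejects unknown keys (typo safety), and reports all
problems at once.

## Known limitations

Allele-level calling, junction-probability annotation, lineage
reconstruction, hotspot/selection analysis, Shannon/Simpson/Chao
diversity families, and rarefaction are out of scope. The aligner is
exact but O(mn) per segment; very large germline sets would want a
seeded heuristic front end. The copy filter deliberately confounds
sequencing depth with confidence: at very low depth, few transcripts
exceed four copies and the SHM summary may be undefined.
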