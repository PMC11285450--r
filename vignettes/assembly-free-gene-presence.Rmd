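---
title: "Assembly-free detection of gene presence, degradation and loss from raw reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly-free detection of gene presence, degradation and loss from raw reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Whether a species still carries a functional copy of a protein-coding gene
is usually answered from an annotated genome assembly. For many taxa only
raw shotgun sequencing libraries exist, and for borderline cases —
pseudogenes, partially deleted loci, fast-evolving families such as the
rodent CD1 lipid-antigen-presenting genes — assembly and annotation are
themselves the unreliable step. `genescout` implements an assembly-free
alternative: align a well-annotated protein query from a related species
directly against the raw reads, and decide presence, degradation or loss
from the pattern of read-level homology.

## The method

### Translated search

Each read is translated in all six reading frames (three per strand) with
the standard genetic code; codons containing `N` become `X` so coordinates
stay aligned, and stop codons are kept as `*`. Every frame's peptide is
aligned to the protein query by Smith–Waterman local alignment with affine
gaps (BLOSUM62, gap open 11, gap extend 1; a gap of length $k$ costs
$11 + k$). Only the best frame's alignment is kept, one hit per
(query, read), mirroring the best-hit usage of translated-search tools.
Significance is assessed with the Karlin–Altschul formula

$$E = K\,m\,n\,e^{-\lambda S},$$

with $K = 0.041$, $\lambda = 0.267$ (the BLOSUM62/11/1 gapped parameters),
$m$ the query length and $n$ the total translated residue count of the read
set, uncorrected for edge effects. Hits are emitted in the 12-column
BLAST/DIAMOND `outfmt 6` dialect, and externally produced `outfmt 6` tables
(e.g. real DIAMOND output) are accepted interchangeably; percent identity
uses the BLAST-tabular convention, identical columns over alignment length
including gaps.

The dynamic-programming kernel is validated against an exhaustive
enumerator (`local_align_score_naive()`) that recurses over every local
alignment path with an explicit affine gap state — exponential, but exact,
and independent of the DP recurrences.

### Tiers, profiles and calls

Hits are filtered into two tiers: *tolerable* similarity
(E-value $< 10^{-4}$ and identity $> 40$) and *low* similarity
($30 <$ identity $\le 40$, with no E-value condition — note the asymmetry
and the strict/inclusive boundaries: identity exactly 40 is low, exactly
30 is rejected). Reconstruction and, by default, profiling use the
tolerable tier only.

For each query position the covering hits are summarized by four values:
the best hit's percent identity, its mismatch and gap-open counts, and the
minimum E-value over all covering hits (tracked independently of the
best-identity hit). "Best" ranks identity first, then lower E-value,
longer alignment, and read id — the primary value is the identity, with
E-value as tie-breaker. Two summary statistics drive presence calling:

* **median best identity** over covered positions (an option imputes
  uncovered positions as 0 instead), and
* **position loss**, the percentage of query positions covered by no hit.

A gene is called `likely_lost` when the median identity falls below 60 or
the loss exceeds 30; `present` when identity is at least 70 and loss at
most 20; the bands in between (identity 60–70, loss 20–30) are reported as
`ambiguous` rather than forced into either state. A query with no coverage
has an undefined median and is collapsed to `likely_lost` (its loss is
already 100).

### Reconstruction

A query-length protein is rebuilt by tiling the tolerable-tier hits: at
each position the residue comes from the best covering hit (identity, then
E-value, then majority vote among tied hits, then alphabetical). Positions
with no residue evidence are written `-`, deliberately distinct from `X`
(unknown residue): absence of evidence, not evidence of an unknown. Read
deletions contribute `-` evidence but do not count toward coverage depth.
The per-residue table carries depth, best identity, mismatches, gap opens
and minimum E-value, so downstream structural work can see how well each
residue is supported.

### Stop-codon statistics

Coverage statistics cannot see premature stop codons — a read containing a
stop still aligns well. The dedicated statistic is the **normalized
stop-free peptide length**: the longest `*`-free segment of the translated
matched region, multiplied by the read's identity fraction. Pseudogenes
with planted stops produce stochastically shorter values than intact
genes; the comparison is a one-sided Mann–Whitney U test (exact by
enumeration for tie-free samples up to 20 per group, normal approximation
with continuity and tie corrections otherwise). The stop-free length is
computed on the matched region, not the whole read, so off-target sequence
cannot inflate it.

### Region trees and structure confidence

Antigen-presenting regions (the alpha-1/alpha-2 helices and beta-sheet
platform of MHC-like folds) are extracted as residue windows on the
reference coordinates, compared by column identity (columns with `-` in
either sequence are excluded from the denominator), converted to distances
as $d = 100 - \mathrm{identity}$ (no model correction; the trees are
descriptive), and clustered by neighbor joining. Negative NJ branches are
clamped to zero with the deficit moved to the sister branch. A full
progressive multiple alignment is out of scope; the functions accept
externally aligned FASTA when reference-coordinate extracts are not
appropriate.

Structure-prediction confidence files are consumed directly: per-residue
pLDDT from the B-factor column of AlphaFold-style PDB files (CA atom,
falling back to the residue mean) and PAE matrices from the published
AlphaFold JSON layouts. A secondary-structure region is flagged unreliable
when its mean pLDDT falls strictly below 70 (exactly 70.0 is reliable); a
`min` aggregator is available since the visual band rule could be read
either way. PAE is summarized per region pair as the mean over both
orientations.

## The synthetic-data generator

Every stage is testable without downloads because the generator produces
ground-truthed inputs: a query protein is back-translated with uniform
synonymous codon choice, diverged by nonsynonymous swaps at a controlled
per-residue rate, optionally pseudogenized (premature stops, 1–2 nt
frameshifts, segmental deletions — all positioned on original coordinates
and applied 3' to 5'), embedded in random flanks, and sheared into reads
with Poisson count (mean $\text{coverage} \times L / \text{read length}$),
uniform placement on both strands and uniform substitution errors.
Everything is deterministic given the scenario seed.

The default conditions — 20× coverage, 100 nt reads, 0.1% per-base error,
150 nt flanks — emulate a modest short-read shotgun library over a
single-exon gene neighbourhood. What the generator does **not** emulate:
codon-usage bias, indel sequencing errors (available behind a flag in
concept but substitution-only by default), paired-end structure,
intron/exon architecture, and repetitive genomic background. Passing tests
therefore demonstrate correctness of the machinery under clean shotgun
assumptions, not robustness to every artifact of real libraries.

## What the statistics can and cannot detect

Implementation made one property of the method concrete enough to deserve
its own section: **single frameshifts are invisible to the coverage
statistics.** A frameshift garbles the downstream protein, but the
underlying nucleotides still encode the original residues in a shifted
frame — and a six-frame read-level search happily finds them there. Only
reads spanning the frameshift point lose part of their alignment. A
frameshifted gene therefore profiles with loss near 0 and identity near
100. Frameshift and stop-codon degradation is instead caught by the
normalized stop-free peptide length comparison and by downstream structure
evidence. The benchmark suite reflects this division of labor: its
pseudogenized scenarios carry segmental deletions (50–100%, including
full-gene loss) and compound deletion+stop/divergence events, the
signatures the loss statistic is designed for, while stop-codon scenarios
exercise the U-test.

A second, smaller effect: at a deletion breakpoint, the optimal local
alignment of a junction-spanning read can extend a dozen or so residues
into the deleted region on chance matches (net-positive score, typically
60–70% identity with gap opens). This shaves a few points off the measured
loss. Profiling on the tolerable tier (the default) suppresses the worst
of these, and deletion-size recovery stays within a few percentage points.
The same mechanism defines a small-deletion blind spot: when a deletion is
short enough that a single affine gap bridges it while keeping identity
above 40% (roughly, fewer deleted codons than 1.5 times the residues a
read contributes — about 49 codons for 100 nt reads), bridging hits enter
the tolerable tier and span-based coverage under-reports the loss. The
reconstruction's depth-based loss, which only counts residue evidence, is
the robust statistic in that regime, and the per-residue tables make the
disagreement visible.

## Numerical choices

* Alignment traceback ties: diagonal > up (gap in read) > left (gap in
  query); among equal-scoring end cells the first in row-major order.
  Output is therefore deterministic and independent of read input order.
* Consensus ties: identity, then E-value, then majority vote, then
  alphabetical residue.
* Tier and call boundaries are exactly as stated above (strict vs
  inclusive); boundary behavior is pinned by tests.
* The E-value search space is the raw $m \times n$ product; no
  effective-length correction is applied, so E-values are conservative for
  short reads.
* NJ on a non-additive matrix can produce negative branches; they are
  clamped to zero with the deficit shifted to the sister branch, which
  preserves path lengths as closely as possible. Additive matrices are
  recovered exactly (to $10^{-9}$ in tests).
* Degenerate inputs: empty read sets produce empty (but valid) hit tables;
  fully uncovered queries report `NA` medians; empty peptides have
  stop-free length 0.

## Problem sizes used in the test battery

The suite validates on 180-residue queries at 20× coverage (about 160
reads of 100 nt per scenario), a 20-scenario presence-call benchmark,
100-pair alignment-oracle checks at peptide lengths up to 8, 50-trial
exact U-test enumeration at up to 8 observations per group, and 50 random
additive trees of up to 8 taxa. These sizes were chosen so each property
is exercised well past its edge cases while the whole battery runs in a
few minutes on one CPU.

## Limitations

* One hit per (query, read): multi-HSP reporting is deferred, so a read
  genuinely matching two distant query segments contributes only its
  better segment.
* Numeric parity with DIAMOND is not a goal; interface parity
  (`outfmt 6`) is. Scores and E-values differ from DIAMOND's
  double-indexed heuristics.
* Reads are treated as single-ended and independent; paired-end
  information is ignored.
* Survey-scale application (terabytes of SRA libraries per species) is
  out of scope here; this package is the per-locus analysis engine with a
  generator standing in for the data.
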