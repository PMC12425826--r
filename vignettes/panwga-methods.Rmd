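---
title: "Reference-free pangenome alignment and polymorphism characterization with panwga"
author: "panwga authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free pangenome alignment and polymorphism characterization with panwga}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panwga)
```

## The problem

Population samples of chromosome-level genome assemblies — such as natural
inbred lines of *Arabidopsis thaliana* — make it possible, in principle, to
see every difference between individual genomes. In practice the hard part
is deciding how to align the genomes and how to interpret the differences.
Mapping everything onto a single reference genome biases every downstream
quantity towards the reference: sequence absent from the reference is
invisible, duplicated loci collapse, and SNP, expression and methylation
estimates all inherit the bias.

panwga implements a reference-free alternative. All genomes are aligned
into a single **matrix of corresponding positions**: rows are accessions,
columns are homologous positions, and the column index is a coordinate
system — the pangenome coordinate system — that grows beyond any single
genome as accession-specific sequence is incorporated. From this matrix the
package extracts SNPs, presence/absence structural variants (SVs),
mobile-element families, saturation curves and reference-bias audits.

## The alignment procedure

The construction has three steps.

**1. Pairwise correspondence by block anchoring.** Each query genome is cut
into consecutive blocks of 5,000 bp (`chop_blocks()`; a trailing block
shorter than 100 bp is merged into its predecessor). Every block is aligned
to the reference genome with an internal seed-and-extend aligner — exact
15-mer seeds merged into maximal exact runs, colinear runs chained by
sparse dynamic programming, and the short gaps between chained runs
resolved by affine-gap Needleman–Wunsch (Biostrings) — and exactly one best
hit is retained per block (`anchor_blocks()`), with ties broken
deterministically towards the lower reference chromosome and start. Hits
that are not in close proximity to a colinear neighbour in *both* genomes
are removed; an isolated off-diagonal hit (typically repeat-induced) is
dropped and the chain re-linked through its region; chains of a single hit
are discarded. The sequence between consecutive kept hits is aligned by a
second local-search pass (`chain_and_fill()`). Minus-strand chains are
reported as inversions and excluded from the base-level matrix: inversions
are a small, separate class of variation and their columns cannot be
ordered consistently with the plus-strand coordinate system.

**2. Reference rotation and intersection.** A single pairwise map is still
biased by its reference, so several accessions are rotated as references
(`build_reference_matrices()`). By default `min(4, n)` accessions chosen to
be maximally spread out by 6-mer profile distance are used: spread-out
vantage points catch reference-specific artefacts best, and adding more
references costs linearly while removing progressively fewer errors. Each
draft is a matrix whose columns are that reference's positions. A column —
the full tuple of per-accession positions — survives only if the identical
tuple appears in **every** draft (`intersect_matrices()`). Ambiguous
pairings (paralogous repeat copies, satellite arrays) are paired
differently under different references and are therefore eliminated; the
result is deliberately a conservative skeleton.

**3. Gap-block resolution.** The genome segments not captured by the
skeleton are grouped into blocks between flanking skeleton columns
(chromosome ends count as flanks; runs from different accessions are
grouped by the overlap of their flanking-column intervals, because an
accession gapped at the shared flank sees a wider interval). Each block is
aligned with an internal progressive center-star aligner: the longest
segment is the template, every other segment is aligned to it with the
chain/fill aligner, and unmatched sub-runs that splice at the same template
position are co-aligned among themselves in a second pass, so identical
insertions carried by several accessions merge even when the template is an
unrelated longer segment. Two numerical safeguards matter here:

* *Consensus support.* Template 13-mers that recur in at least 70% of the
  other segments mark the orthologous backbone of the block; chained runs
  through the backbone are weighted tenfold, so a long paralogous pairing
  (two different insertions of the same transposon family) cannot outscore
  the shared flanking sequence.
* *Sub-seed-length runs.* Segments shorter than 26 nt cannot be seeded;
  they are matched positionally against the equal-length template prefix or
  suffix (at most one mismatch in three tolerated). These segments arise
  from breakpoint wobble at insertion sites and, left unmatched, would
  fragment SNP columns near indels.

Blocks in which any accession's segment exceeds 30 kb are considered highly
diverged and are retained as accession-private columns rather than aligned;
this keeps pan-genome length accounting conservative without spending
unbounded time on sequence (satellite arrays, in the simulations) that has
no meaningful alignment.

Monotonicity is enforced with a weighted longest-increasing-subsequence
filter over maximal mapped runs (both on pairwise maps and on skeleton
columns): when a repeat-induced pairing conflicts with the surrounding
colinear signal, the lighter side is dropped. A greedy first-wins rule is
deliberately avoided — it would let one spurious far-mapping run invalidate
everything that follows it — and small boundary overlaps between adjacent
runs (double-claims where two fills meet) are trimmed rather than treated
as conflicts, since an all-or-nothing rule would discard long runs over a
few base pairs.

Finally `sort_and_index()` orders columns by the first accession's
positions and builds the bidirectional genome-position/column index. The
class invariants — strictly increasing positions per accession, every
position in at most one column, no empty columns — are asserted after
construction (`validate_alignment()`).

## Variants

SNPs are gap-free columns with at least two distinct bases
(`call_snps(mode = "all")`). Because local alignment ambiguity can
masquerade as substitution, a stricter mode keeps only *isolated*
differences whose immediate neighbour columns are gap-free and monomorphic
(`mode = "isolated"`); the isolated count is never above the all count.
Columns containing N never qualify (N is never evidence of a match), and a
flank width of one column operationalises "isolated".

SV loci are maximal runs of columns that each contain at least one gap,
flanked by fully aligned columns or chromosome ends
(`extract_sv_loci()`). Terminal loci are flagged and excluded from
frequency statistics (their boundaries are unresolvable). Each accession's
allele is its sequence across the run; the SV length L is the maximum
allele length — the natural scale of the presence allele. The locus is a
**simple** presence/absence polymorphism (sSV) iff every allele is either
shorter than (1 − s)·L (absence) or longer than s·L (presence), with
s = 0.9 by default; any intermediate allele makes it **complex** (cSV).
s is restricted to (0.5, 1]: at or below 0.5 the absence and presence
intervals overlap and the rule is ill-posed. Relaxing s is monotone — it
can only reclassify complex loci as simple.

Polarity follows presence-allele frequency: a presence allele in at most 3
accessions is a *likely insertion*, an absence allele in at most 3 a
*likely deletion*, anything else unpolarized. With n accessions the two
rules are unambiguous when n ≥ 2·3 + 1. The consensus allele of a locus is
the medoid presence allele (maximal mean global-alignment identity to the
others), so one representative sequence exists even when carriers differ by
a few substitutions.

## The mobile-ome

Mobile elements that were recently active left similar sequences at
different genomic locations. The package looks for them directly, without
any TE annotation, by clustering sSV presence alleles in a **graph of
nestedness**: a directed edge A → B means the merged local hits of A
against B cover at least 85% of A at at least 85% identity
(`pairwise_nestedness()`). Hits are maximal exact matches of at least
16 nt, so hit identity is exact and short polymorphic interruptions only
reduce coverage; sequences shorter than 100 nt are excluded (shorter
variants are too sensitive to alignment parameters). Exact containment is
transitive, mutual nestedness at the same threshold merges nodes into
larger ones (`merge_nodes()`), and weakly connected components approximate
element families.

TE content against a known library is categorised along two coverage axes
(`te_content_category()`): (a) how much of the sequence is covered by TE
hits and (b) how much of the best-matching element is covered. High/high is
a complete element; low/high contains a complete element plus extra
sequence; high/low is a pure fragment; low/low contains a fragment. The
0.85 coverage threshold reuses the nestedness threshold for coherence.
Unannotated graph members are probed by a six-frame ORF scan
(`orf_scan()`): all stop-free stretches longer than 100 codons, or — when
none exists — the single longest stretch if it exceeds 30 codons
(standard genetic code, no initiator-codon special-casing; ambiguous codons
translate to X). Protein-hit descriptions obtained externally are
classified by keyword lists into TE-like, undefined, defined, or
no-protein (`classify_protein_hits()`).

## Saturation, dilation and divergence

`pan_core_curve()` draws, for each sample size k, up to 20 unique accession
subsets and counts pan columns (any subset member aligned) and core columns
(all members aligned), reporting mean ± sample standard deviation (0 when
only one subset exists, e.g. k = n). Pan is non-decreasing and core
non-increasing in k, and pan(1) = core(1) = the single genome's aligned
length. `dilation_curve()` emits the (column, reference position) pairs for
a chosen accession; insertions absent from that accession appear as
horizontal plateaus and the slope against the reference is never 1 as soon
as any other accession contributes sequence. `pairwise_divergence()` counts
SNP differences and the simple loci where exactly one of the two accessions
carries the presence allele, binned by the fixed length classes
1, 15, 100, 500, 1000, 5000, 20000 nt (with a final open class), which
partition the loci exactly.

## Reference-bias auditing

`classify_calls()` implements the six-way taxonomy for comparing a
reference-based call set against whole-genome-alignment truth. Truth SNPs
are TP if called, *uncalled* if their site has no read coverage, FN
otherwise. Test calls are FP_het when heterozygous — the accessions are
completely inbred, so heterozygous calls are false by construction and take
precedence even at truth sites — otherwise TP if in truth, FP_non_snp at
aligned sites, FP_unaligned elsewhere. FDR = FP/(TP + FP) over calls;
FNR = FN/(TP + FN) over covered truth (uncalled sites deliberately do not
enter the FNR). With zero calls the FDR is reported as missing, never 0.
The accompanying generator `simulate_call_set()` plants target FDR/FNR
values so the taxonomy can be checked against exact binomial intervals.

Expression concordance between a common-reference mapping and an own-genome
mapping excludes genes whose larger count is below 6 and calls a gene
discordant when min/max ≤ 0.7 (a >30% difference). Methylation levels are
computed as methylated/(methylated + unmethylated) reads — the ratio must
lie in [0, 1] to feed the min/max rule, which resolves the ambiguity
between the two possible readings of "ratio between methylated and
unmethylated reads" — and methylation concordance uses min/max ≤ 0.5, with
two zero levels equal and hence concordant. `quantile_normalize()` maps
x to (x − q20)/(q80 − q20) with type-7 (linearly interpolated) quantiles —
the estimator matters because q20/q80 depend on it — pinning the 20% and
80% quantiles to 0 and 1 and making the transform invariant to affine
changes of the input.

## Gene ancestry

Gene groups ordered by pangenome position are assigned an outgroup homolog
when one outgroup gene is hit by at least 50% of members at ≥80% identity
over ≥80% of the focal coding sequence (`assign_group_homolog()`; ties
break by share, then mean identity, then gene id). Consecutive assigned
groups join a colinear segment when their homologs are separated by fewer
than six genes in outgroup order (strictly fewer; separation is the rank
difference, orientation ignored); unassigned groups break segments
(`build_colinear_segments()`). Groups in segments of at least two are
*ancestral in position and sequence*; groups with a homolog but no segment
are *similar*; groups without a homolog are *non-ancestral*
(`classify_ancestry()`).

## The synthetic pangenome and what it does (not) show

`simulate_pangenome()` generates the package's standard study conditions:
8 accessions derived independently (star genealogy) from a random ancestor
of 2 chromosomes × 300 kb, with

* per-lineage substitution rate 5×10⁻⁴ per site (SNP sites are sampled
  outside structural events and de-duplicated across lineages so each
  ancestor site carries one derived base);
* 60 TE insertions drawn from a generated 6-family library (consensus
  lengths 400–6,000 nt, pairwise identity verified < 0.6 by global
  alignment at generation); 70% are complete copies, 30% truncated to a
  uniform 0.2–0.8 fraction;
* 40 deletions of 15–2,000 nt;
* 4 unalignable satellite blocks: tandem arrays (unit ≤ 180 nt) replaced in
  every accession by an independently mutated (15% per site) array with
  ±30% copy-number jitter, which reliably defeats exact 15-mer seeding and
  the 0.85 identity floor;
* carrier sets drawn mostly (85%) of size 1–3 so that presence-frequency
  polarity is informative, with the remainder spread over larger sizes to
  populate the frequency spectrum.

Events are placed non-overlapping with at least 300 nt spacing and 2 kb
end margins. The truth ledger records every event (including each
accession's satellite array), so `apply_truth()` reproduces each genome
byte-for-byte and `truth_coord_maps()` yields exact coordinate maps for
scoring. A star genealogy is the simplest model under which "presence in
few accessions ≈ insertion" holds while shared derived alleles still occur
through multi-carrier events.

The simulation deliberately omits several features of real genomes:
inversions and translocations are never planted (inversion handling is
detection-only), base composition is uniform, there is no nested insertion
of one element inside another, no recombination, and divergence is far
below that of pericentromeric regions. Passing the planted-truth tests
therefore demonstrates that the machinery is correct under colinear,
moderately diverged conditions — not that real centromeres would align.

## Problem sizes and tolerances

The packaged analyses run at desk scale: the standard simulation
(8 × 600 kb) aligns in roughly two minutes on one core, and the test suite
scores SNP sensitivity/precision, SV recovery within ±20 columns of the
planted breakpoints, polarity accuracy, nestedness-component purity
against planted family labels (adjusted Rand index), classifier/ORF
brute-force agreement, exact pan/core combinatorics on constructed
alignments, binomial recovery of planted FDR/FNR, and the ancestry rules
under permutation decay. One boundary case is worth noting: for a single
genome the core equals the pan (an intersection over one set), so the
constructed core+private design yields core(1) = core + private, and the
flat shared-core value holds from k = 2 on.

## Known limitations

* Inversions are reported but not genotyped, and their interiors stay
  out of the coordinate matrix.
* Translocations are not handled; a genuinely translocated block would be
  dropped by the proximity filter and re-enter as private columns.
* cSVs are not sub-decomposed; they are a recognised mixture of overlapping
  events and alignment ambiguity.
* The nestedness graph uses exact-match hit coverage; highly diverged
  copies of a family (identity well below 0.9) fragment into separate
  components.
* All-against-all nestedness is quadratic in the number of presence
  alleles; it is intended for the ≥100 nt sSV set, not for millions of
  sequences.
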