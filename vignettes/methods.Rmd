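---
title: "Calling non-reference retrotransposon insertions: model and methods"
author: "MEIdetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling non-reference retrotransposon insertions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Retrotransposons (Alu, L1, SVA and LTR elements) are still mobile in human
and other genomes, and an insertion present in a sequenced individual but
absent from the reference genome (a retrotransposon insertion polymorphism,
RIP) leaves a characteristic footprint in paired-end whole-genome
alignments: read pairs with one mate anchored uniquely on the reference and
the other mate matching transposable-element (TE) consensus sequence, and
reads whose alignments are soft-clipped exactly at the insertion junction,
the clipped tail being inserted-sequence-derived. Because target-primed
reverse transcription duplicates a short stretch of the target site, a real
insertion shows two junctions a few bases apart flanking the target site
duplication (TSD), and a poly-A (or, on the opposite strand, poly-T) tail.

MEIdetect turns this footprint into calls in two steps, mirroring the way
dedicated mobile-element callers are organized: (1) a streaming scan that
classifies read pairs into discordant-evidence categories against a TE
consensus library, and (2) clustering of that evidence into candidate loci
followed by breakpoint resolution, TSD recovery, genotyping, and annotation
of subfamily, orientation and inserted length. The package also contains
the validation machinery needed to trust such a caller: a TE-insertion
simulator with exact ground truth, a provenance ("perfect") aligner, an
evaluation harness, and allele-frequency-spectrum utilities for
population-level analyses of the calls.

## Evidence categories

A pair contributes evidence if it satisfies one of three criteria, checked
in the order (ii), (iii), (i) — clip-bearing evidence carries a breakpoint
and is never downgraded to the coarser category:

* **CLIP_PAIR (ii)** — one mate maps uniquely and is soft-clipped, the
  clipped part maps to the TE library, and the other mate is placed on the
  reference.
* **CLIP_ONLY (iii)** — a uniquely mapped soft-clipped read whose clipped
  part maps to the library, while its mate is *not* unique on the
  reference (multi-mapped or unmapped) and itself matches the library.
  A `lenientIii` switch drops the mate's library-hit requirement.
* **RAM_PAIR (i)** — a repeat-anchored mate pair: one mate unique on the
  reference, the other not unique there but matching the library.

"Uniquely mapped" is operationalized as MAPQ at or above 30 (inclusive);
multi-mappers conventionally carry MAPQ 0, so any threshold in 1–30 behaves
identically for standard aligners. Every emitted record's anchor passes
this test, which is asserted as a suite invariant. Requiring a *placed*
mate in (ii) is what keeps (iii) a reachable category under the anchor-
uniqueness invariant; the two categories then split clip evidence by
whether the mate corroborates the insertion.

TE hits are best local alignments across all consensuses and both strands
(match +1, mismatch −2, gap open −5, gap extend −2), accepted at score ≥ 16,
identity ≥ 0.90 and aligned query length ≥ 20 bp — one sequencing error in a
20 bp clip still passes. Exact substrings are recognized by direct string
search before any dynamic programming; a full-length exact hit cannot be
beaten under this scoring, so the fast path is exact, not approximate.
Near-pure poly-A/T queries (≥ 80% one base) are dismissed without
alignment: a tail is diagnostic of orientation, not of family, and scoring
it against the consensus A-tails would only ever produce family-ambiguous
hits. Those clips still shape breakpoints, which use raw clip positions.

## Clustering and the streaming release rule

Each record predicts an interval that must contain the insertion point:
the anchor extended by `mean + 3·sd` of the insert size toward its
insertion side (clip-bearing records are pinned at their clip position).
Insert-size statistics come from the first 10,000 proper pairs (population
standard deviation, so degenerate fixtures give exact values). A single
pass over the records in interval order merges overlapping intervals into
clusters, capped at a window of `2·(mean + 3·sd) + tsdMax`; the `tsdMax`
allowance exists because the two flanks of one insertion predict points up
to one TSD apart, and without it every true locus splits in two. A cluster
is *valid* when it has at least `minSupport = 3` records and either
anchors on both flanks or at least `minClipSupport = 2` clip records.
The family vote is the majority over member hits, ties giving
`"ambiguous"` (resolved later by annotation, never invalidating the
cluster).

Breakpoint resolution can start before the scan ends: a cluster is
released exactly when the scan position has passed its window end by more
than `mean + 3·sd`, since no later read's predicted interval can reach
back that far. The suite asserts that chunked streaming with this release
rule reproduces batch clustering identically, and that clustering matches
an independent interval-graph connected-components oracle on dense
fixtures.

## Breakpoints, TSD, genotype

All primary reads over the cluster window (padded by one read length) are
collected, including fully concordant ones — genotyping needs them. Clip
points come from three sources: soft-clip boundaries in the CIGARs; reads
whose CIGAR carries a small deletion (< 10 bp) followed by aligned bases
that mostly disagree with the reference, which are collapsed so the
boundary moves to the deletion start; and terminal-mismatch rescue — an
unclipped read end whose last 10 aligned bases are more than half
mismatches contributes a synthetic clip at the first mismatch of that run.
The 10 bp window is a package choice: the mismatch-majority rule needs a
denominator, and 10 bp makes "more than half" mean ≥ 6 errors, far beyond
what sequencing noise produces at 0.1–1% error rates.

A candidate clip point must pass three rules: (1) more than half of its
clipped sequences are discordant with the reference continuation
(gap-free identity < 0.8 — the threshold is a package choice, as are all
quantifications in this paragraph); (2) the local alignment of the
clipped-sequence consensus to the reference continuation is less than 30%
gapped; (3) the junction is crisp — the consecutive-mismatch run on the
*aligned* flank adjacent to the junction is shorter than 5 bp — unless the
clipped consensus begins (junction side) with a poly-A/T run, which
excuses rule (3). Measuring rule (3) on the aligned flank rather than on
the clipped sequence itself is deliberate: the clipped tail of a true
insertion is TE sequence and *should* mismatch the reference (a random
25% match rate makes a ≥ 5 bp initial mismatch run a ~24% event), whereas
the aligned flank of a clean junction matches the reference essentially
always, so the rule rejects sloppy junctions without rejecting true ones.
Poly-A/T is defined as ≥ 8 consecutive A (or T) allowing one interruption,
shared with orientation annotation.

The insertion's left breakpoint `bpLeft` is the highest-support clip at
read 3' ends; `bpRight` the highest-support clip at read 5' ends (ties:
higher support, then lower coordinate). When both exist, `bpRight ≤
bpLeft`, and they are at most `tsdMax = 50` bp apart, the reference
between them is the TSD; a larger separation keeps the call but flags it
and drops the TSD. Clusters with no validated clip still yield a call at
the window midpoint, flagged imprecise — sensitivity should not depend on
clip luck at low coverage.

Genotype thresholds the reference-allele fraction
`spanning / (spanning + supporting)` at `homMaxRefFraction = 0.15` (HOM at
or below). `spanning` counts clean full-match reads covering both
breakpoints with a 5 bp margin. For `supporting` the driver passes the
junction-local clip support, falling back to the RAM count only when no
clip survived validation: clip support counts the same junction-
overlapping read population as the spanning count, so the two arms of the
fraction are on one scale, whereas RAM counts grow with the insert size
rather than the allele balance and would push heterozygous loci below any
fixed threshold. The 0.15 boundary itself is a package choice calibrated
by the diploid recovery experiment in the test suite (50 HET + 50 HOM at
×40), not a published constant.

## Annotation

Supporting sequences (clipped parts and reference-oriented repeat-anchored
mates) are assembled per locus by a deterministic greedy overlap assembler:
repeatedly merge the pair with the longest exact suffix/prefix overlap
≥ 20 bp, containments first, ties broken lexicographically. An external
assembler can be substituted by passing its contigs directly — the
built-in one exists so the whole package runs without external binaries
and deterministically, at the price of splitting contigs across sequencing
errors (unmerged fragments still annotate; they just shorten the covered
span).

Subfamily: the best library alignment fixes the family (identity ≥ 0.85
required, else `"unknown"`); within the family, each subfamily is scored
by the fraction of its *diagnostic nucleotides* covered by the contig
alignment that the contig matches; ties go to the higher raw alignment
score, and a contig covering no diagnostic column is `"unresolved"` at
subfamily level. Diagnostic nucleotides are derived from a progressive
center-star alignment of the family's consensuses (match +1, mismatch −1,
gap −2): a column is diagnostic for a subfamily when that subfamily's
(non-gap) base differs from the single base shared by all others. With
two subfamilies both get a site at every differing column. Subfamily
consensuses are typically > 95% identical, so any reasonable multiple
alignment agrees on these columns; the suite checks recovery of planted
private substitutions against a direct column scan.

Orientation: majority vote over the strands of the TE hits of
reference-oriented evidence, cross-checked against the tail — a "+"
insertion should show poly-A at its right junction, a "−" insertion
poly-T at its left junction. A tie, or a contradicting tail when the vote
margin is below 2, gives `"unknown"`, which is a first-class value:
orientation from short-read evidence is known to carry a substantial
error rate, and forcing a call would only hide it.

Inserted length is the *span* of consensus positions covered by any
evidence alignment, `L = max − min + 1` — a span, not a coverage sum, so
interior gaps (uncovered TE middle at long elements) do not shrink it.
It is bounded by the consensus length and blurred at the 3' end by at
most the planted-tail/consensus-tail length difference.

## The simulator and what it does (not) emulate

`plantInsertions` draws insertion sites uniformly, at least 2 kb apart and
1 kb clear of chromosome ends; each insertion is a library element,
possibly 5'-truncated (Alu/SVA/LTR full-length with probability 0.7, L1
with probability 0.2 — most genomic L1 copies are 5'-truncated), possibly
reverse-complemented, followed by a poly-A tail (uniform 8–30 bp; none for
LTR elements, whose integration mechanism leaves no tail) and a duplicate
of the 5–20 reference bases left of the site (the TSD). Heterozygous
insertions (an exact `round(hetFraction·n)` of loci, default half) go to
haplotype 1 only. `generateReads` samples fragments uniformly per
haplotype at half the total depth each, lengths Normal(500, 50) truncated
to [200, 700], 100 bp reads from either end with independent substitution
errors (default 0.1%), constant Q30 qualities. Everything is
seed-deterministic to the byte.

The provenance aligner places each read where its fragment came from:
full matches over reference blocks, correct soft clips at junctions
(extending the alignment through the duplicated TSD copy, as a real
aligner would), unmapped-at-mate-position for reads fully inside inserted
sequence, requiring ≥ 20 aligned bases to place a junction read. It writes
a coordinate-sorted, indexed BAM via Rsamtools, so the complete pipeline
runs with no external aligner; any standard aligner's BAM can be used
instead.

What passing these simulations shows — and what it does not: the
simulator reproduces the *structural* footprint of retrotransposition
(junction geometry, TSDs, tails, truncation, zygosity, coverage) on a
random genome with uniform errors. It does not emulate repetitive
reference context (the dominant source of false calls in real genomes),
alignment ambiguity, indel sequencing errors, GC-dependent coverage, or
chimeric library artifacts. Sensitivity and FDR measured here are
therefore upper bounds on real-data performance; the detection logic, the
coordinate arithmetic, and the genotype model are what the suite actually
validates.

## Problem sizes and numerical choices

The headline experiment plants 150 insertions in a 5 Mb two-chromosome
genome and sequences it at ×30 — large enough that per-locus evidence
counts match a whole-genome run at the same depth, and that binomial noise
on sensitivity over 150 loci is ~1.5 points. The depth-monotonicity check
runs three seeds at ×5 vs ×30 on 0.7 Mb / 16 loci; genotype recovery uses
100 loci (exactly 50 HET / 50 HOM) at ×40 on 1.3 Mb; TSD exactness uses
50 error-free loci on 1.6 Mb. The bundled TE library is synthetic —
random family ancestors with planted subfamily-private substitutions and
A-tails, at representative (L1 shortened) lengths — which makes every
diagnostic site known by construction; any user FASTA with
`family#subfamily` headers substitutes for it.

Degenerate inputs are handled explicitly: empty BAMs and empty evidence
streams produce empty (typed) results; clusters with one flank only are
invalid unless clip-supported; blunt insertions give an empty (not
missing) TSD; genotyping with zero reads on both arms is an error, not a
guess. Ties everywhere break deterministically (support, then coordinate;
score, then identity, then library order; lexicographic sequence order in
assembly), so identical inputs give byte-identical outputs, which the
suite asserts.

## Known limitations

Somatic calling, CRAM input, transductions, 5' inversions and assembly of
the full inserted sequence are out of scope. Reference-genome insertions
(present in the reference, absent from the sample) are a different
detection problem (deletion-like signatures) and are not attempted. The
allele-frequency utilities compute the spectrum and the neutral `θ/i`
expectation; demographic model fitting and selection-coefficient
estimation are deliberately not included.
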