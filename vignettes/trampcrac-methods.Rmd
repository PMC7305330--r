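---
title: "Methods: mapping TRAMP substrate specificity from CRAC, RNAseq and pull-down proteomics"
author: "trampcrac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping TRAMP substrate specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trampcrac)
```

## The problem

The yeast TRAMP complexes (Trf4/5–Air1/2–Mtr4) mark nuclear RNAs for
degradation by the exosome, adding short non-templated oligo(A) tails to
their substrates. Which RNAs each complex variant targets, and where along
a transcript each component binds, can be read out from UV crosslinking
(CRAC) libraries: sequenced footprints of RNA bound by a tagged protein,
complemented by RNAseq for expression changes and label-free (iBAQ)
proteomics for the protein-interaction side. `trampcrac` implements the
complete computational path from raw reads to those readouts as a tested,
reusable package, and pairs it with a synthetic-data module that generates
toy datasets with known truth so every step can be validated end to end.

All coordinates inside the package are 0-based half-open (the BED
convention); GFF3 input/output is converted at the boundary. Reads are
single-end, as CRAC libraries are.

## Pre-processing model

**PCR-duplicate collapsing.** CRAC libraries carry a 5' random barcode
(3 nt by default). Reads with identical mapped ends — identical
`(chrom, strand, start, end)` — and identical barcode are counted as one
molecule. Collapsing is idempotent and order-invariant; the report
satisfies `reads_in = unique_molecules + duplicates_removed` exactly.

**Low-complexity filter.** A read is discarded when more than 70% of its
content is a single nucleotide. The comparison is strict (`> 0.7`), so a
read at exactly 70% is kept.

**Toy aligner.** Real pipelines use a production aligner; here a
deliberately minimal exact aligner provides the plumbing: the longest
read prefix with an exact genomic match on either strand wins (seeded by
the first 18 nt; candidates are extended and ties broken by lowest
chromosome index, then genomic position, then `+` before `-`). The
unmatched suffix is handed to tail analysis. No mismatches, no indels.

**Oligo(A) calls.** Because alignment is maximal-prefix, any genomically
templated A-run at the 3' junction is consumed by the alignment and can
never be counted as tail — a conservative rule. The recorded tail is the
whole unmatched suffix; it is called oligo(A) when it consists only of A
and is at least `min_tail` long. The published pipelines do not state
their minimum tail length or their treatment of mixed-base suffixes, so
the defaults here (`min_tail = 2`, mixed suffixes never called) are
declared choices, not inferred ones.

## Quantification

Each read is assigned to exactly one feature: among same-strand
overlapping features (one overlapping nucleotide suffices) the class
earliest in a configurable priority list wins (default: small structured
RNAs and ncRNA classes before mRNA, so features nested in host genes keep
their reads). A read overlapping only the opposite strand of an mRNA is
`antisense`; a read overlapping nothing is `intergenic`. RPM and RPKM are
the usual `1e6 * n / N` and `1e9 * n / (N * L)`.

Two correlation modes compare factors: *co-targeting* correlates
per-transcript counts, *co-localization* correlates counts in fixed 50-nt
genome windows tiled from position 0 per chromosome and strand,
independently of transcripts. A read increments every window it overlaps
(a 5'-end-only mode is provided); the final short window is kept.
Replicates are averaged first, then Pearson's r is computed on the
averaged vectors, on raw counts — the source material does not state a
log transform, and that choice is recorded here. Zero-variance vectors
yield missing values rather than zero.

## Profiles and peaks

Pileups count hits per transcript position (full-read coverage, 5'→3' in
transcript orientation). Metagene profiles align per-gene pileups at the
TSS or pA site and sum across genes; by default only genes of at least
500 nt enter, and density is scaled to reads per million mapped to mRNAs.
Offsets beyond a gene's length are simply unsupported by that gene
(ragged alignment — no padding, no averaging).

The peak caller detects maximal runs of at least 15 contiguous positions
whose value strictly exceeds 50 on a track restricted to RNAPII
transcripts and RPM-normalized to RNAPII-mapped reads. Each qualifying
run yields one peak at the run maximum; plateau ties break to the 5'-most
position (lowest coordinate on `+`, highest on `-`) — the source
material does not specify a tie rule, so this one is declared. Runs
longer than 15 still yield a single peak. Peak-anchored alignment
extracts another factor's coverage in a window around each reference peak
inside a gene set, orients it 5'→3', and sums across peaks; coverage
(not peak counts) is summed, resolving an ambiguity in the source
figures' description.

## Occupancy clustering

For the union of top-bound mRNAs (per-factor top-N by replicate-averaged
RPKM, ties at the cutoff broken by gene id), each gene is divided into
five equal-length bins from TSS to pA (remainder nucleotides to the last
bin) and each bin holds the fraction of that gene's binding for that
factor (per-gene total set to 1). Genes with zero coverage for a factor
contribute a zero block rather than dropping out — union membership is
driven by the other factors.

Clustering is k-medians with Euclidean assignment distance, k = 6:
Lloyd-style alternation of nearest-centre assignment and per-dimension
median update, empty clusters re-seeded with the row farthest from its
centre, best of 10 restarts by within-cluster summed distance, fully
seed-deterministic. Two numerical choices deserve note:

* *Initialization.* Uniform sampling of k rows proved unreliable on
  well-separated archetype mixtures — for some seeds all restarts
  converged to local optima that merge one archetype pair and split
  another. Centres are therefore seeded ++-style (first centre uniform,
  subsequent centres sampled with probability proportional to squared
  distance from the nearest chosen centre), which recovers planted
  archetypes essentially always while remaining seed-deterministic.
* *Monotonicity.* The per-dimension median minimizes L1 distance, not
  the Euclidean assignment objective, so an update step can in principle
  raise the objective. The implementation records the objective after
  each assignment step and stops — keeping the previous state — if an
  update would increase it; the reported trace is therefore
  non-increasing by construction.

Cluster ids are canonicalized by descending size. Heat-map rows are
grouped by cluster and ordered within a cluster by distance to the
median; held-out tables are re-indexed to the identical row order, with
missing genes as NA rows.

## Differential analyses

Stratified fold change ranks genes descending by a metric (e.g. Trf5
binding RPKM, so bin 1 = most bound), cuts consecutive bins of 200 genes,
and reports the per-bin mean of per-gene `log2((mut + c)/(wt + c))` on
replicate-averaged RPKM, with pseudocount `c = 5`. The positional
pseudocount of 5 is reused for the per-gene ratio because the source
material states it only for positional enrichment; a ratio-of-sums
summary is exposed as an alternative. Positional log2 enrichment averages
RPM tracks per condition and computes `log2((a + 5)/(b + 5))` at every
position, so positions empty in both conditions are exactly 0 and
swapping conditions negates the track.

pA-aligned group profiles are metagenes at the pA site over a gene group,
divided by their own total (area = 1) so profile shapes are comparable
between genotypes with different depths and replicate counts.

## Proteomics and qPCR

riBAQ divides each protein's iBAQ by the sum of non-contaminant iBAQ in
its sample; contaminants get a value on the same denominator but never
enter it, so non-contaminant riBAQ sums to exactly 1. Enrichment is the
pull-down/mock riBAQ ratio; a ratio strictly below 2 is "not enriched"
(exactly 2 is enriched), and a protein absent from the mock gets an
infinite ratio with a flag. Bait-relative recovery divides every
protein's iBAQ by the bait's per replicate, then reports mean and n−1 SD.

Complex stoichiometry uses water-filling under the observed interaction
pattern (Trf5 pairs only with Air1; Trf4 with both Air proteins):
`TRAMP5-1 = min(Trf5, Air1)`, the remaining Air1 pairs with Trf4 as
TRAMP4-1 (capped by available Trf4), and remaining Trf4 pairs with Air2
as TRAMP4-2. Outputs are reported raw and rounded to the nearest hundred,
with unpaired surpluses. Only the TRAMP5-1 figure is a firm check — the
published TRAMP4-1/TRAMP4-2 values do not follow from any simple
arithmetic on the published per-protein medians, and the rule used here
is declared as such.

qPCR fold change averages triplicate Ct per gene and condition and
applies the standard efficiency-corrected ratio
`E_t^(ΔCt_t) / E_ref^(ΔCt_ref)` against the SCR1 reference; the exact
formula is a declared choice since only its literature source is cited.

## The synthetic-data generator

The generator defines the study conditions for every test. It emulates:

* a small multi-chromosome genome (i.i.d. uniform ACGT);
* transcripts of the classes the analyses distinguish, placed without
  same-strand overlap, with 80% of mRNAs longer than 500 nt (metagene
  eligibility);
* factor archetypes: expected binding fraction per fifth of a transcript
  (`bin_weights`), optional TSS/pA-anchored Gaussian components with
  configurable offset (default 50 nt inside the transcript) and spread,
  per-gene lognormal affinities shared between factors of the same
  archetype (so co-binding factors correlate over genes, as co-members
  of a complex do), and per-factor oligo(A) tailing probability with a
  short-tail length distribution;
* CRAC reads centred on the sampled position, carrying a 5' random 3-nt
  barcode and, with probability `oligoA_frac`, a planted pure-A tail;
* PCR duplicates emitted by resampling molecules with identical span
  *and* barcode; biological molecules that coincide on a span are forced
  onto distinct barcodes (resampled; a warning is raised if a span
  exhausts the 4^3 barcode space, in which case collapsing merges them
  exactly as it would in real data);
* RNAseq as barcode- and tail-free uniform libraries, with an optional
  per-gene 3' truncation fraction to emulate loss of 3' signal in a
  mutant;
* bait/mock iBAQ table pairs with flagged contaminants, lognormal
  abundances and multiplicative noise.

Two constructions make truth exact rather than approximate. First,
anchored positions are drawn from a *truncated* Gaussian (rejection
sampling) rather than clamped, so short transcripts do not accumulate an
artificial pile of reads at a clamp boundary. Second, when the genomic
base just 3' of a tailed molecule's end is an A, the mapped span is
extended until a non-A base before the tail is appended — a planted tail
therefore never overlaps a templated A-run, and the maximal-prefix
aligner recovers exactly the planted tail. This is why oligo(A)
precision/recall against truth is exactly 1, not approximately 1: it
validates the detector's logic, not its robustness to ambiguity.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: sequencing errors and quality
variation, adapters, indels and mismatched alignments, spliced reads,
multimapping, fragment-length distributions, genomic A-repeats adjacent
to genuine tails (real oligo(A) calling is ambiguous at such junctions),
and compositional biases of real genomes.

## Problem sizes and determinism

The shipped tests and the acceptance script exercise the pipeline at
desk scale, chosen to give each property comfortable statistical margin:
genomes of 2 × 30–50 kb; 25–60 transcripts per class set; CRAC libraries
of 1.5–50 k molecules; RNAseq of 60 k reads across 4 + 3 replicates;
2000 genes for clustering recovery; 200 random 100 k-position tracks for
the peak-caller oracle; 100-protein iBAQ tables. Every stochastic step
takes an explicit seed and regenerating with the same configuration and
seed is byte-identical across all outputs.

## Known limitations

The toy aligner is plumbing, not a contribution — results on real data
require a production aligner upstream. Counting is not splice-aware and
multimapping reads are resolved by the deterministic tie-break, not
redistributed. The peak caller has no significance model (none exists in
the source method; the thresholds are the method). k = 6 is fixed by the
method being reimplemented, with no model selection. qPCR and RNAseq
fold changes need not agree numerically (they normalize differently);
no reconciliation is attempted.
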