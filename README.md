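# trampcrac

Computational pipeline for mapping the RNA substrate specificity of the
yeast TRAMP complexes (Trf4/5–Air1/2–Mtr4, the nuclear exosome's
adaptor/oligo-adenylation cofactors) from three data types:

* **CRAC** (UV crosslinking and analysis of cDNA): sequenced footprints of
  RNA bound by a tagged protein, carrying 5' random barcodes and —
  on surveillance targets — short non-templated oligo(A) tails;
* **RNAseq** for expression and 3'-end changes between genotypes;
* **iBAQ pull-down proteomics** for the protein-interaction side of the
  complexes.

It is written for computational biologists who want the paper-style
analyses as tested, reusable functions rather than one-off scripts:
barcode-aware PCR-duplicate collapsing, non-encoded oligo(A)-tail
identification, transcript-class counting with RPM/RPKM, co-targeting and
co-localization Pearson matrices, TSS/pA-anchored metagenes, a run-length
peak caller with peak-anchored cross-factor alignment, five-bin occupancy
k-medians clustering, rank-stratified differential fold changes, and
riBAQ enrichment with complex-stoichiometry inference. A synthetic-data
module generates toy genomes, annotations, reads and iBAQ tables with
complete truth tables, so the whole pipeline is exercised end to end
against known ground truth.

## The core computations

* **Duplicate collapsing** — reads with identical mapped ends
  (chrom, strand, start, end) and identical 5' random barcode count as one
  molecule.
* **Oligo(A) detection** — after maximal-prefix alignment, the unmatched
  3' suffix is the non-templated tail; it is called oligo(A) when all-A
  and ≥ `min_tail` (default 2). Templated A-runs are consumed by the
  alignment, never counted.
* **Normalization** — RPM = 10⁶·n/N; RPKM = 10⁹·n/(N·L); peak calling uses
  RPM over RNAPII-mapped reads on RNAPII-masked tracks.
* **Peak calling** — maximal runs of ≥ 15 contiguous positions with value
  > 50; one peak per run at the argmax, plateau ties 5'-most.
* **Occupancy clustering** — per gene and factor, fraction of binding in
  each of 5 equal bins (gene total = 1); k-medians, k = 6, Euclidean
  assignment, seeded ++-style initialization, best of 10 restarts.
* **Differential** — genes ranked by Trf5 binding RPKM, bins of 200, mean
  per-gene log₂((mut+5)/(wt+5)); positional log₂ enrichment with 5
  pseudocounts; pA-aligned area-normalized group profiles.
* **Proteomics** — riBAQ = iBAQ / Σ(non-contaminant iBAQ); enrichment =
  pull-down/mock riBAQ ratio, < 2 ⇒ not enriched; stoichiometry by
  water-filling with TRAMP5-1 = min(Trf5, Air1).

See `vignettes/trampcrac-methods.Rmd` for the full model, parameter
defaults, and design choices.

## Worked example

Simulate a TSS-proximal factor's CRAC library with PCR duplicates and
planted oligo(A) tails, run the pre-processing pipeline, and quantify:

```r
library(trampcrac)

genome <- make_genome(n_chrom = 2, chrom_len = 30000, seed = 1)
ann <- make_annotation(genome, c(mRNA = 30, snoRNA = 6), seed = 2)
arch <- archetype_tss_peaked("Trf5", oligoA_frac = 0.3, affinity_seed = 10)
sim <- simulate_crac_reads(genome, ann, arch, n_reads = 5000,
                           pcr_dup_rate = 0.5, seed = 3)

pp <- preprocess_fastq(sim$seqs, genome, barcode_len = 3, min_tail = 2)
str(pp$report)
#> List of 3
#>  $ reads_in          : int 7500
#>  $ unique_molecules  : int 5000
#>  $ duplicates_removed: int 2500
```

The 2500 PCR duplicates are removed exactly — they share span *and*
barcode with their template molecule, and nothing else does. The called
tails match the planted truth perfectly (the generator guarantees planted
tails never abut a templated A-run):

```r
key_t <- with(sim$truth, paste(chrom, strand, start, end, barcode))
key_r <- with(pp$reads,  paste(chrom, strand, start, end, barcode))
called <- nchar(pp$reads$tail) >= 2
truth  <- sim$truth$tail_len[match(key_r, key_t)] >= 2
c(precision = sum(called & truth) / sum(called),
  recall    = sum(called & truth) / sum(sim$truth$tail_len >= 2))
#> precision    recall
#>         1         1

round(class_distribution(count_overlaps(pp$reads, ann)), 3)
#>   mRNA snoRNA
#>  0.843  0.157
```

Complex stoichiometry from per-protein copies-per-cell medians
(Air1 1851, Air2 1750, Trf4 2659, Trf5 1329), under the interaction
pattern that Trf5 pairs only with Air1:

```r
infer_complex_abundance(c(Air1 = 1851, Air2 = 1750,
                          Trf4 = 2659, Trf5 = 1329))$rounded
#> TRAMP4_1 TRAMP4_2 TRAMP5_1
#>      500     1800     1300
```

TRAMP5-1 = min(Trf5, Air1) = 1329 ≈ 1300 copies/cell.

## The analysis workflow

`analysis/` holds the study as numbered drivers over the package; each
step reads only files written by earlier steps and writes tables under
`results/`:

```sh
Rscript analysis/01_simulate.R        # toy genome + 5 factors x 2 CRAC reps
Rscript analysis/02_preprocess.R      # align, tails, collapse -> BED + report
Rscript analysis/03_quantify.R        # class distributions, RPKM, correlations
Rscript analysis/04_profiles_peaks.R  # metagenes, peaks, Air1-anchored profiles
Rscript analysis/05_cluster.R         # 5-bin occupancy, k-medians, heat-map order
Rscript analysis/06_differential.R    # wt vs trf5-null RNAseq comparisons
Rscript analysis/07_proteomics.R      # riBAQ enrichment, stoichiometry, qPCR
```

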