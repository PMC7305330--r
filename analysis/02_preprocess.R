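#!/usr/bin/env Rscript
# Step 2: CRAC pre-processing - strip 5' barcodes, align with the toy
# exact aligner, call non-templated oligo(A) tails, collapse PCR
# duplicates. Emits per-library BED6 (barcode|tail names), an oligo(A)-
# only BED, and a collapse-report table.

source("analysis/00_config.R")

g <- read_fasta("results/sim/genome.fa")
dir <- results_dir("preprocessed")

reports <- list()
for (f in factor_names()) {
  for (r in seq_len(N_REPS)) {
    lib <- sprintf("%s_rep%d", f, r)
    seqs <- read_fastq(file.path("results/sim", paste0(lib, ".fastq")))
    keep <- low_complexity_filter(seqs, threshold = 0.7)
    if (any(!keep))
      message(lib, ": ", sum(!keep), " low-complexity read(s) filtered")
    seqs <- seqs[keep]
    pp <- preprocess_fastq(seqs, g, barcode_len = 3, min_tail = 2,
                           collapse = TRUE)
    write_reads(pp$reads, file.path(dir, paste0(lib, ".bed")))
    tailed <- pp$reads[pp$reads$tail != "", , drop = FALSE]
    write_reads(tailed, file.path(dir, paste0(lib, ".oligoA.bed")))
    reports[[lib]] <- data.frame(
      library = lib, reads_in = pp$report$reads_in,
      unique_molecules = pp$report$unique_molecules,
      duplicates_removed = pp$report$duplicates_removed,
      unmapped = pp$n_unmapped, oligoA_molecules = nrow(tailed))
    message(sprintf(
      "%s: %d reads -> %d molecules (%d dups removed), %d oligo(A)",
      lib, pp$report$reads_in, pp$report$unique_molecules,
      pp$report$duplicates_removed, nrow(tailed)))
  }
}
write_tsv(do.call(rbind, reports), file.path(dir, "collapse_report.tsv"))
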