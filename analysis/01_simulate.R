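#!/usr/bin/env Rscript
# Step 1: generate the toy study - genome, annotation, and two CRAC
# replicates per TRAMP factor, each with a complete truth table. All
# downstream steps read only the files written here.

source("analysis/00_config.R")

g <- study_genome()
ann <- study_annotation(g)
archs <- study_archetypes()

dir <- results_dir("sim")
write_fasta(g, file.path(dir, "genome.fa"))
write_annotation(ann, file.path(dir, "annotation.gff3"))
message("genome: ", length(g$seq), " chromosomes, ",
        sum(g$chrom_len), " bp; annotation: ", nrow(ann), " transcripts")

for (f in factor_names()) {
  for (r in seq_len(N_REPS)) {
    sim <- simulate_crac_reads(
      g, ann, archs[[f]], n_reads = N_READS, read_len = 40,
      pcr_dup_rate = 0.4, seed = lib_seed(f, r),
      fastq = file.path(dir, sprintf("%s_rep%d.fastq", f, r)))
    write_tsv(sim$truth, file.path(dir, sprintf("%s_rep%d.truth.tsv", f, r)))
    message(sprintf("%s rep%d: %d molecules, %d reads emitted, %.1f%% tailed",
                    f, r, nrow(sim$truth), length(sim$seqs),
                    100 * mean(sim$truth$tail_len > 0)))
  }
}
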