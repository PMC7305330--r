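#!/usr/bin/env Rscript
# Step 4: metagene profiles, RNAPII-restricted peak calling, and
# Air1-peak-anchored alignment of the other factors. Metagenes are
# TSS- and pA-anchored over mRNAs of at least 500 nt, normalized per
# million mRNA-mapped reads; peaks use the run-length rule (>= 15
# contiguous positions above 50) on RNAPII-masked RPM tracks.

source("analysis/00_config.R")

g <- read_fasta("results/sim/genome.fa")
ann <- read_annotation("results/sim/annotation.gff3")
mrna <- ann[ann$class_label == "mRNA", ]
rnap2 <- ann[ann$class_label %in% RNAP2_CLASSES, ]
dir <- results_dir("profiles_peaks")

load_reads <- function(f, r)
  read_reads(file.path("results/preprocessed",
                       sprintf("%s_rep%d.bed", f, r)))

avg_factor_pileups <- function(f, tx) {
  pls <- lapply(seq_len(N_REPS), function(r)
    pileup_all(load_reads(f, r), tx))
  out <- pls[[1]]
  for (id in names(out))
    out[[id]] <- Reduce(`+`, lapply(pls, `[[`, id)) / length(pls)
  out
}

## metagenes
meta_rows <- list()
for (f in factor_names()) {
  pl <- avg_factor_pileups(f, mrna)
  mrna_mapped <- mean(vapply(seq_len(N_REPS), function(r) {
    co <- count_overlaps(load_reads(f, r), ann)
    sum(co$table$count[co$table$class_label == "mRNA"])
  }, numeric(1)))
  for (anchor in c("tss", "pa")) {
    mg <- metagene(pl, anchor = anchor, min_len = 500,
                   per_million = mrna_mapped)
    meta_rows[[paste(f, anchor)]] <-
      data.frame(factor = f, anchor = anchor, mg)
    if (anchor == "tss")
      message(f, ": TSS metagene argmax at offset ",
              mg$offset[which.max(mg$value)])
  }
}
write_tsv(do.call(rbind, meta_rows), file.path(dir, "metagene_profiles.tsv"))

## RNAPII-restricted peak calling
tracks <- list()
peaks <- list()
for (f in factor_names()) {
  reps <- lapply(seq_len(N_REPS), function(r) {
    reads <- load_reads(f, r)
    co <- count_overlaps(reads, ann)
    rnap2_mapped <- sum(co$table$count[co$table$class_label %in%
                                         RNAP2_CLASSES])
    normalize_track(mask_track(coverage_from_reads(reads, g$chrom_len),
                               rnap2),
                    total_mapped = rnap2_mapped, state = "rpm_total")
  })
  tracks[[f]] <- average_tracks(reps)
  pk <- call_peaks(tracks[[f]], min_run = 15, height_thresh = 50)
  peaks[[f]] <- if (nrow(pk)) data.frame(factor = f, pk) else NULL
  message(f, ": ", nrow(pk), " peaks")
}
write_tsv(do.call(rbind, peaks), file.path(dir, "peaks.tsv"))

## Air1 peaks as reference; top-bound gene set = union of top 25 mRNAs
## by Air1 and Trf5 RPKM
rpkm_df <- utils::read.delim("results/quantification/rpkm_by_factor.tsv")
mr <- rpkm_df[rpkm_df$class_label == "mRNA", ]
top_ids <- select_top_union(list(Air1 = stats::setNames(mr$Air1, mr$id),
                                 Trf5 = stats::setNames(mr$Trf5, mr$id)),
                            n = 25)
gene_set <- ann[ann$id %in% top_ids, ]
ref <- peaks[["Air1"]]
aligned <- list()
for (f in factor_names()) {
  pr <- align_to_reference_peaks(ref, tracks[[f]], gene_set, flank = 100)
  aligned[[f]] <- data.frame(factor = f, pr)
  message(f, " vs Air1 peaks: argmax offset ",
          pr$offset[which.max(pr$value)])
}
write_tsv(do.call(rbind, aligned),
          file.path(dir, "air1_anchored_profiles.tsv"))
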