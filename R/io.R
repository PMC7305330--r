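# Readers/writers for the standard formats the pipeline touches.
# Internal convention everywhere: 0-based half-open coordinates (BED native;
# GFF3 converted on read/write).

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return A [genome_ref()] object.
#' @export
read_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  genome_ref(stats::setNames(as.character(dna), names(dna)))
}

#' Write a genome to FASTA
#'
#' @param genome A `GenomeRef`.
#' @param path Output file.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seq), path)
  invisible(path)
}

#' Read transcript annotation from GFF3
#'
#' GFF3 1-based closed coordinates are converted to 0-based half-open and
#' TSS/pA positions derived per strand. The transcript class is taken from
#' an attribute key (default `gene_biotype`); biotypes outside the closed
#' vocabulary are mapped to `"other_ncRNA"`.
#'
#' @param path GFF3 file.
#' @param class_attr Attribute key carrying the class label.
#' @return A `transcript_table`.
#' @export
read_annotation <- function(path, class_attr = "gene_biotype") {
  gr <- rtracklayer::import(path, format = "GFF3")
  if (length(gr) == 0)
    return(transcript_table(character(), character(), character(),
                            integer(), integer(), character()))
  md <- S4Vectors::mcols(gr)
  cls <- if (class_attr %in% names(md)) as.character(md[[class_attr]])
         else rep(NA_character_, length(gr))
  cls[is.na(cls) | !cls %in% TRANSCRIPT_CLASSES] <- "other_ncRNA"
  ids <- if ("ID" %in% names(md)) as.character(md$ID)
         else paste0("feat", seq_along(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop("unstranded feature(s) in annotation: ",
         paste(ids[strand == "*"], collapse = ", "))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  keep <- start0 < end0
  if (!all(keep)) {
    message("rejected ", sum(!keep), " record(s) with end <= start")
  }
  transcript_table(ids[keep], as.character(GenomicRanges::seqnames(gr))[keep],
                   strand[keep], start0[keep], end0[keep], cls[keep])
}

#' Write transcript annotation to GFF3
#'
#' @param tx A `transcript_table`.
#' @param path Output file.
#' @param class_attr Attribute key for the class label.
#' @export
write_annotation <- function(tx, path, class_attr = "gene_biotype") {
  gr <- as_granges(tx)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- tx$id
  S4Vectors::mcols(gr)[[class_attr]] <- tx$class_label
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read aligned reads from BED6
#'
#' The BED name field optionally encodes `barcode|tail`; the score column is
#' interpreted as read weight. BED 0-based half-open coordinates are kept
#' as-is.
#'
#' @param path BED6 file.
#' @return A `read_table`.
#' @export
read_reads <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 1L && !nzchar(first)) first <- character()
  if (length(first) && length(strsplit(first, "\t")[[1]]) < 6)
    stop("BED file has fewer than 6 columns: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0)
    return(read_table(character(), character(), integer(), integer()))
  nm <- as.character(S4Vectors::mcols(gr)$name)
  nm[is.na(nm)] <- ""
  parts <- strsplit(nm, "|", fixed = TRUE)
  barcode <- vapply(parts, function(p) if (length(p) >= 1) p[[1]] else "", "")
  tail <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "", "")
  score <- S4Vectors::mcols(gr)$score
  if (is.null(score)) score <- rep(1, length(gr))
  score[is.na(score)] <- 1
  read_table(as.character(GenomicRanges::seqnames(gr)),
             as.character(GenomicRanges::strand(gr)),
             GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
             barcode = barcode, tail = tail, weight = score)
}

#' Write aligned reads to BED6
#'
#' @param reads A `read_table`.
#' @param path Output file.
#' @export
write_reads <- function(reads, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                   reads$chrom, reads$start, reads$end,
                   paste0(reads$barcode, "|", reads$tail),
                   reads$weight, reads$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write a coverage track to bedGraph
#'
#' One bedGraph file per strand (suffixes `.plus.bedgraph` /
#' `.minus.bedgraph` appended to `prefix`). Runs of equal value are merged;
#' zero runs are omitted, so an all-zero track produces an empty interval
#' list.
#'
#' @param track A `CoverageTrack` (see [coverage_track()]).
#' @param prefix Output path prefix.
#' @return Named character vector of the two file paths.
#' @export
write_bedgraph <- function(track, prefix) {
  paths <- c("+" = paste0(prefix, ".plus.bedgraph"),
             "-" = paste0(prefix, ".minus.bedgraph"))
  for (s in c("+", "-")) {
    con <- file(paths[[s]], "w")
    for (chrom in names(track$values)) {
      v <- track$values[[chrom]][[s]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values != 0
      if (any(keep))
        writeLines(sprintf("%s\t%d\t%d\t%.10g", chrom,
                           starts[keep], ends[keep], r$values[keep]), con)
    }
    close(con)
  }
  invisible(paths)
}

#' Read a coverage track from a bedGraph pair
#'
#' @param prefix Path prefix used by [write_bedgraph()].
#' @param chrom_len Named integer vector of chromosome lengths.
#' @param norm_state,total_mapped Normalisation metadata to attach.
#' @return A `CoverageTrack`.
#' @export
read_bedgraph <- function(prefix, chrom_len, norm_state = "raw",
                          total_mapped = NA_real_) {
  track <- coverage_track(chrom_len, norm_state = norm_state,
                          total_mapped = total_mapped)
  paths <- c("+" = paste0(prefix, ".plus.bedgraph"),
             "-" = paste0(prefix, ".minus.bedgraph"))
  for (s in c("+", "-")) {
    lines <- readLines(paths[[s]])
    if (!length(lines)) next
    f <- strsplit(lines, "\t")
    for (x in f) {
      i0 <- as.integer(x[2]); i1 <- as.integer(x[3])
      track$values[[x[1]]][[s]][(i0 + 1L):i1] <- as.numeric(x[4])
    }
  }
  track
}

#' Write reads to FASTQ
#'
#' Sequences are written with uniform placeholder qualities (the pipeline
#' is quality-agnostic).
#'
#' @param seqs Named character vector of read sequences.
#' @param path Output file.
#' @export
write_fastq <- function(seqs, path) {
  dna <- Biostrings::DNAStringSet(seqs)
  qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), ""))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read sequences from FASTQ
#'
#' @param path FASTQ file.
#' @return Named character vector of sequences.
#' @export
read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(dna), names(dna))
}
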