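#' Transcript class vocabulary
#'
#' Closed vocabulary of RNA substrate classes used throughout the pipeline.
#' Unknown biotypes encountered on import are mapped to `"other_ncRNA"`.
#'
#' @format Character vector.
#' @export
TRANSCRIPT_CLASSES <- c(
  "mRNA", "CUT", "SUT", "XUT", "snoRNA", "snRNA", "tRNA",
  "rRNA_spacer", "intron", "antisense", "intergenic", "other_ncRNA"
)

#' Default class priority for hierarchical read counting
#'
#' When a read overlaps several same-strand features the class earliest in
#' this list wins. Small structured RNAs nested in mRNAs take precedence so
#' their reads are not absorbed by the host gene.
#'
#' @format Character vector, highest priority first.
#' @export
DEFAULT_CLASS_PRIORITY <- c(
  "rRNA_spacer", "tRNA", "snRNA", "snoRNA", "CUT", "SUT", "XUT",
  "intron", "other_ncRNA", "mRNA"
)

#' RNA polymerase II transcript classes
#'
#' Classes treated as RNAPII transcription units when an analysis restricts
#' to the Pol II transcriptome (peak calling, RNAPII correlation universe).
#' Pol I (rRNA spacers) and Pol III (tRNA) products are excluded.
#'
#' @format Character vector.
#' @export
RNAP2_CLASSES <- c("mRNA", "CUT", "SUT", "XUT", "snoRNA", "snRNA",
                   "other_ncRNA")

#' Construct a genome reference
#'
#' A genome reference is the set of chromosome sequences against which
#' "non-encoded" (non-templated) tails are defined: any read 3' sequence
#' absent from the reference at the mapped position is a candidate tail.
#'
#' @param sequences Named character vector of uppercase DNA sequences
#'   (alphabet A/C/G/T/N), one element per chromosome.
#' @return An object of class `GenomeRef` with fields `seq` (named character
#'   vector) and `chrom_len` (named integer vector).
#' @export
genome_ref <- function(sequences) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("chromosome names must be present and unique")
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("non-ACGTN characters in sequence(s): ",
         paste(names(sequences)[bad], collapse = ", "))
  structure(
    list(seq = sequences,
         chrom_len = stats::setNames(nchar(sequences), names(sequences))),
    class = "GenomeRef")
}

#' @export
print.GenomeRef <- function(x, ...) {
  cat("GenomeRef:", length(x$seq), "chromosome(s),",
      sum(x$chrom_len), "bp total\n")
  invisible(x)
}

#' Construct a transcript table
#'
#' Transcripts are the unit of counting, binning and metagene anchoring.
#' Coordinates are 0-based half-open. The TSS and pA site are derived from
#' the strand: on `+` the TSS is `start` and the pA is `end - 1`; on `-`
#' the TSS is `end - 1` and the pA is `start`.
#'
#' @param id,chrom,strand,start,end,class_label Parallel vectors describing
#'   each transcript; `strand` in `+`/`-`, `class_label` from
#'   [TRANSCRIPT_CLASSES].
#' @return A `data.frame` with class `transcript_table` and columns
#'   `id, chrom, strand, start, end, tss, pa, class_label, length`.
#' @export
transcript_table <- function(id, chrom, strand, start, end, class_label) {
  stopifnot(all(strand %in% c("+", "-")))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("transcript with start >= end")
  if (anyDuplicated(id)) stop("transcript ids must be unique")
  bad <- !class_label %in% TRANSCRIPT_CLASSES
  if (any(bad)) stop("unknown class label(s): ",
                     paste(unique(class_label[bad]), collapse = ", "))
  tx <- data.frame(
    id = as.character(id), chrom = as.character(chrom), strand = strand,
    start = start, end = end,
    tss = ifelse(strand == "+", start, end - 1L),
    pa  = ifelse(strand == "+", end - 1L, start),
    class_label = class_label,
    length = end - start,
    stringsAsFactors = FALSE)
  class(tx) <- c("transcript_table", "data.frame")
  tx
}

#' Construct an aligned-read table
#'
#' Mapped single-end reads with 0-based half-open spans. The 5' random
#' barcode (3 nt by default in CRAC libraries) and any non-templated 3'
#' tail string travel with the read; `tail` is empty until oligo(A)
#' analysis has run.
#'
#' @param chrom,strand,start,end Parallel vectors of mapped spans.
#' @param barcode Random-nucleotide barcode strings ("" if absent).
#' @param tail Non-templated 3' tail strings ("" if none / not yet called).
#' @param weight Positive read counts (default 1).
#' @return A `data.frame` with class `read_table`.
#' @export
read_table <- function(chrom, strand, start, end,
                       barcode = "", tail = "", weight = 1) {
  n <- length(chrom)
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("read with start >= end")
  stopifnot(all(strand %in% c("+", "-")))
  barcode <- rep_len(as.character(barcode), n)
  if (any(grepl("[^ACGTN]", barcode[barcode != ""])))
    stop("barcode alphabet must be ACGTN")
  rd <- data.frame(
    chrom = as.character(chrom), strand = as.character(strand),
    start = start, end = end,
    barcode = barcode, tail = rep_len(as.character(tail), n),
    weight = rep_len(as.numeric(weight), n),
    stringsAsFactors = FALSE)
  class(rd) <- c("read_table", "data.frame")
  rd
}

# GRanges view of a read or transcript table (1-based closed, as GRanges).
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
}
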