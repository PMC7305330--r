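# Pre-processing computations: barcode-aware PCR-duplicate collapsing,
# low-complexity filtering, a toy exact aligner (plumbing; production
# pipelines delegate to a real aligner), and non-encoded oligo(A)-tail
# identification against the reference.

#' Collapse PCR duplicates
#'
#' Reads having identical ends — identical (chrom, strand, start, end) —
#' and identical random nucleotides in the 5' barcode are counted as one
#' molecule (weight 1, not summed). Output is sorted genomically so the
#' operation is deterministic and permutation-invariant.
#'
#' @param reads A `read_table`; every read must carry a barcode.
#' @return List with `reads` (one representative per molecule) and
#'   `report` (`reads_in`, `unique_molecules`, `duplicates_removed`).
#' @export
collapse_duplicates <- function(reads) {
  miss <- which(reads$barcode == "" | is.na(reads$barcode))
  if (length(miss))
    stop("read(s) without barcode at row(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  key <- paste(reads$chrom, reads$strand, reads$start, reads$end,
               reads$barcode, sep = "\r")
  first <- !duplicated(key)
  out <- reads[first, , drop = FALSE]
  out$weight <- 1
  ord <- order(out$chrom, out$start, out$end, out$strand, out$barcode)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_table", "data.frame")
  report <- list(reads_in = nrow(reads),
                 unique_molecules = nrow(out),
                 duplicates_removed = nrow(reads) - nrow(out))
  list(reads = out, report = report)
}

#' Low-complexity filter
#'
#' Discards sequences in which more than `threshold` of the content is a
#' single nucleotide (strict inequality: exactly 70% is kept). Such reads
#' are prone to misalignment and are removed before alignment in the
#' RNAseq and correlation analyses.
#'
#' @param seqs Character vector of non-empty sequences.
#' @param threshold Maximum tolerated single-nucleotide fraction.
#' @return Logical vector: `TRUE` = keep, `FALSE` = discard.
#' @export
low_complexity_filter <- function(seqs, threshold = 0.7) {
  if (any(!nzchar(seqs))) stop("empty sequence")
  maxfrac <- vapply(seqs, function(s) {
    counts <- table(strsplit(s, "")[[1]])
    max(counts) / nchar(s)
  }, numeric(1), USE.NAMES = FALSE)
  maxfrac <= threshold
}

#' Toy exact 3'-anchored aligner
#'
#' Finds, for each read, the longest prefix with an exact match in the
#' genome on either strand, seeded by the first 18 nt (reads with no exact
#' 18-nt seed match are unmapped). The unmatched suffix is returned for
#' tail analysis. Ties between equally long matches are broken by lowest
#' (chromosome index, genomic position, `+` before `-`). This is plumbing
#' for the synthetic pipeline, not a general-purpose aligner: no
#' mismatches, no indels.
#'
#' @param seqs Character vector of read sequences (barcodes already
#'   stripped), length >= 18 each.
#' @param genome A `GenomeRef`.
#' @param min_match Minimum exact prefix length to report a mapping.
#' @return A `data.frame` with one row per read: `mapped, chrom, strand,
#'   start, end` (0-based half-open span of the matched prefix),
#'   `match_len`, `suffix` (unmatched 3' remainder in read orientation).
#' @export
toy_align <- function(seqs, genome, min_match = 18L) {
  n <- length(seqs)
  out <- data.frame(mapped = rep(FALSE, n), chrom = NA_character_,
                    strand = NA_character_, start = NA_integer_,
                    end = NA_integer_, match_len = 0L,
                    suffix = NA_character_, stringsAsFactors = FALSE)
  long <- which(nchar(seqs) >= min_match)
  if (!length(long)) return(out)
  seeds <- substr(seqs[long], 1L, min_match)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
  chroms <- names(genome$seq)
  # subjects: forward chromosomes and their reverse complements
  rc <- revcomp(genome$seq)
  nread <- nchar(seqs[long])

  # candidate seed hits across all subjects, extended in bulk
  cand <- list()
  for (ci in seq_along(chroms)) {
    clen <- genome$chrom_len[[ci]]
    for (s in c("+", "-")) {
      subj <- if (s == "+") genome$seq[[ci]] else rc[[ci]]
      hits <- Biostrings::matchPDict(pd, Biostrings::DNAString(subj))
      starts <- Biostrings::startIndex(hits)
      starts[vapply(starts, is.null, TRUE)] <- list(integer())
      np <- lengths(starts)
      if (!sum(np)) next
      pat <- rep.int(seq_along(starts), np)
      pos <- unlist(starts, use.names = FALSE)
      avail <- pmin(nread[pat], clen - pos + 1L)
      gsub <- substring(subj, pos, pos + avail - 1L)
      rsub <- substring(seqs[long[pat]], 1L, avail)
      L <- integer(length(pat))
      full <- rsub == gsub
      L[full] <- avail[full]
      for (j in which(!full)) {
        mism <- which(charToRaw(rsub[j]) != charToRaw(gsub[j]))
        L[j] <- mism[1] - 1L
      }
      keep <- L >= min_match
      if (!any(keep)) next
      pat <- pat[keep]; pos <- pos[keep]; L <- L[keep]
      if (s == "+") {
        gstart <- pos - 1L
        gend <- gstart + L
      } else {
        gstart <- clen - (pos - 1L) - L
        gend <- clen - (pos - 1L)
      }
      cand[[length(cand) + 1L]] <- data.frame(
        pat = pat, L = L, ci = ci, minus = (s == "-"),
        gstart = gstart, gend = gend)
    }
  }
  if (!length(cand)) return(out)
  cd <- do.call(rbind, cand)
  # best per read: longest match; ties by lowest (chrom index, genomic
  # position, + before -)
  ord <- order(cd$pat, -cd$L, cd$ci, cd$gstart, cd$minus)
  cd <- cd[ord[!duplicated(cd$pat[ord])], , drop = FALSE]

  i <- long[cd$pat]
  out$mapped[i] <- TRUE
  out$chrom[i] <- chroms[cd$ci]
  out$strand[i] <- ifelse(cd$minus, "-", "+")
  out$start[i] <- cd$gstart
  out$end[i] <- cd$gend
  out$match_len[i] <- cd$L
  out$suffix[i] <- substr(seqs[i], cd$L + 1L, nchar(seqs[i]))
  out
}

#' Identify non-encoded oligo(A) tails
#'
#' Given mapped reads with their unmatched 3' suffixes (from
#' [toy_align()], which is maximal-prefix so genomically templated A-runs
#' at the junction are always consumed by the alignment and never counted
#' as tail), records the suffix as the non-templated tail and calls it
#' oligo(A) when it consists only of A and is at least `min_tail` long.
#'
#' @param aln Alignment `data.frame` from [toy_align()].
#' @param min_tail Minimum non-templated A count to call oligo(A).
#' @return `aln` with added columns `templated_3p` (genomic coordinate of
#'   the last genome-matching base), `tail_seq`, `tail_len`, `is_oligoA`.
#' @export
call_oligoA <- function(aln, min_tail = 2L) {
  aln$tail_seq <- ifelse(aln$mapped, aln$suffix, NA_character_)
  aln$tail_len <- ifelse(aln$mapped, nchar(aln$suffix), NA_integer_)
  aln$is_oligoA <- aln$mapped & aln$tail_len >= min_tail &
    grepl("^A+$", aln$tail_seq)
  aln$is_oligoA[is.na(aln$is_oligoA)] <- FALSE
  aln$templated_3p <- ifelse(!aln$mapped, NA_integer_,
                             ifelse(aln$strand == "+", aln$end - 1L,
                                    aln$start))
  aln
}

#' Pre-process a CRAC FASTQ end to end
#'
#' Strips the 5' random barcode, aligns reads with the toy aligner, calls
#' non-templated oligo(A) tails, and optionally collapses PCR duplicates.
#'
#' @param seqs Named character vector of raw read sequences (as from
#'   [read_fastq()]), barcode first.
#' @param genome A `GenomeRef`.
#' @param barcode_len Barcode length in nt.
#' @param min_tail Minimum tail length for an oligo(A) call.
#' @param collapse Collapse PCR duplicates after alignment?
#' @return List with `reads` (a `read_table` with barcode and called tail),
#'   `aln` (per-read alignment + tail calls, unmapped included),
#'   `report` (collapse report or NULL), `n_unmapped`.
#' @export
preprocess_fastq <- function(seqs, genome, barcode_len = 3L, min_tail = 2L,
                             collapse = TRUE) {
  barcode <- substr(seqs, 1L, barcode_len)
  insert <- substr(seqs, barcode_len + 1L, nchar(seqs))
  aln <- call_oligoA(toy_align(insert, genome), min_tail = min_tail)
  aln$barcode <- barcode
  ok <- aln$mapped
  reads <- read_table(aln$chrom[ok], aln$strand[ok], aln$start[ok],
                      aln$end[ok], barcode = barcode[ok],
                      tail = ifelse(aln$is_oligoA[ok], aln$tail_seq[ok], ""))
  report <- NULL
  if (collapse) {
    cc <- collapse_duplicates(reads)
    reads <- cc$reads
    report <- cc$report
  }
  list(reads = reads, aln = aln, report = report,
       n_unmapped = sum(!ok))
}
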