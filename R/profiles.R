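# Per-transcript pileups, TSS/pA-anchored metagene profiles, the
# run-length peak caller, and peak-anchored cross-factor alignment.

#' Per-transcript pileup
#'
#' Counts hits at each position of one transcript: every same-strand read
#' adds its weight to every transcript position it covers. The vector is
#' indexed 5' to 3' in transcript orientation (reversed relative to the
#' genome for minus-strand transcripts).
#'
#' @param reads A `read_table`.
#' @param tx_row Single-row `transcript_table` (or a row subset of one).
#' @return Numeric vector of length `tx_row$length`.
#' @export
pileup <- function(reads, tx_row) {
  stopifnot(nrow(tx_row) == 1)
  L <- tx_row$length
  v <- numeric(L)
  i <- which(reads$chrom == tx_row$chrom & reads$strand == tx_row$strand &
               reads$start < tx_row$end & reads$end > tx_row$start)
  for (j in i) {
    a <- max(reads$start[j], tx_row$start) - tx_row$start + 1L
    b <- min(reads$end[j], tx_row$end) - tx_row$start
    v[a:b] <- v[a:b] + reads$weight[j]
  }
  if (tx_row$strand == "-") v <- rev(v)
  v
}

#' Pileups for many transcripts at once
#'
#' @param reads A `read_table`.
#' @param tx A `transcript_table`.
#' @return Named list of pileup vectors (5'->3'), one per transcript.
#' @export
pileup_all <- function(reads, tx) {
  track <- coverage_from_reads(reads, chrom_len_from_tx(reads, tx))
  out <- vector("list", nrow(tx))
  names(out) <- tx$id
  for (i in seq_len(nrow(tx))) {
    v <- track$values[[tx$chrom[i]]][[tx$strand[i]]][
      (tx$start[i] + 1L):tx$end[i]]
    if (tx$strand[i] == "-") v <- rev(v)
    out[[i]] <- v
  }
  out
}

# smallest chromosome lengths covering both reads and transcripts
chrom_len_from_tx <- function(reads, tx) {
  chroms <- union(unique(tx$chrom), unique(reads$chrom))
  vapply(chroms, function(cn)
    max(tx$end[tx$chrom == cn], reads$end[reads$chrom == cn], 0L),
    numeric(1))
}

#' Metagene profile anchored at the TSS or pA site
#'
#' Per-gene pileups are aligned at the anchor (offset 0 = TSS or pA site)
#' and summed position-wise across genes; offsets beyond a gene's length
#' are simply not supported by that gene (ragged alignment). By default
#' only genes of at least 500 nt enter; density can be scaled to reads per
#' million mapped to mRNAs via `per_million`.
#'
#' @param pileups Named list of 5'->3' pileup vectors (e.g. from
#'   [pileup_all()], replicate-averaged upstream if desired).
#' @param anchor `"tss"` (offsets 0, 1, ...) or `"pa"` (offsets ..., -1, 0).
#' @param min_len Minimum gene length in nt for inclusion.
#' @param per_million If given, the profile is multiplied by
#'   `1e6 / per_million` (e.g. the number of reads mapped to mRNAs).
#' @return `data.frame` with columns `offset`, `value`, `n_genes` (genes
#'   supporting that offset).
#' @export
metagene <- function(pileups, anchor = c("tss", "pa"), min_len = 500,
                     per_million = NULL) {
  anchor <- match.arg(anchor)
  lens <- lengths(pileups)
  keep <- lens >= min_len
  if (!any(keep)) stop("no gene passes min_len = ", min_len)
  pileups <- pileups[keep]
  lens <- lens[keep]
  W <- max(lens)
  value <- numeric(W)
  n_genes <- integer(W)
  for (v in pileups) {
    L <- length(v)
    if (anchor == "pa") v <- rev(v)  # index 1 = anchor, growing away
    value[seq_len(L)] <- value[seq_len(L)] + v
    n_genes[seq_len(L)] <- n_genes[seq_len(L)] + 1L
  }
  offset <- if (anchor == "tss") 0:(W - 1L) else -(0:(W - 1L))
  if (!is.null(per_million)) value <- value * 1e6 / per_million
  out <- data.frame(offset = offset, value = value, n_genes = n_genes)
  if (anchor == "pa") out <- out[order(out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call peaks on a normalized coverage track
#'
#' Detects maximal runs of contiguous positions whose value strictly
#' exceeds `height_thresh`; every run of at least `min_run` positions
#' yields one peak at the position of the run maximum (plateau ties broken
#' 5'-most, i.e. lowest genomic coordinate on `+`, highest on `-`). The
#' track is expected to be restricted to RNAPII transcripts and RPM-
#' normalized to RNAPII-mapped reads before calling (see [mask_track()]
#' and [normalize_track()]).
#'
#' @param track A `CoverageTrack`.
#' @param min_run Minimum run length in nt.
#' @param height_thresh Strict height threshold.
#' @return `data.frame` with columns `chrom, strand, pos` (0-based peak
#'   position), `height, span_start, span_end` (0-based half-open cluster
#'   span), sorted by (chrom, strand, span_start).
#' @export
call_peaks <- function(track, min_run = 15L, height_thresh = 50) {
  res <- list()
  for (chrom in names(track$values)) {
    for (s in c("+", "-")) {
      v <- track$values[[chrom]][[s]]
      r <- rle(v > height_thresh)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      qual <- which(r$values & r$lengths >= min_run)
      if (!length(qual)) next
      pos <- height <- numeric(length(qual))
      for (q in seq_along(qual)) {
        i0 <- starts[qual[q]]; i1 <- ends[qual[q]]
        seg <- v[i0:i1]
        mx <- max(seg)
        at <- which(seg == mx)
        p <- if (s == "+") at[1] else at[length(at)]
        pos[q] <- i0 + p - 2L    # to 0-based
        height[q] <- mx
      }
      res[[paste0(chrom, s)]] <- data.frame(
        chrom = chrom, strand = s, pos = as.integer(pos), height = height,
        span_start = starts[qual] - 1L, span_end = ends[qual],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), strand = character(),
                      pos = integer(), height = numeric(),
                      span_start = integer(), span_end = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$strand, out$span_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sum another factor's coverage around reference peaks
#'
#' For every reference peak lying inside the gene set (same strand), the
#' other factor's track is extracted over `[pos - flank, pos + flank]`,
#' oriented 5' to 3' of the peak's strand, and summed across peaks.
#' Positions falling off a chromosome contribute 0.
#'
#' @param ref_peaks Peak `data.frame` from [call_peaks()] (the reference
#'   factor, e.g. Air1).
#' @param track The other factor's `CoverageTrack` (replicates combined
#'   upstream).
#' @param gene_set A `transcript_table` restricting which peaks are used
#'   (e.g. union of top-bound RNAPII transcripts).
#' @param flank Half-window in nt.
#' @return `data.frame` with columns `offset` (-flank..flank), `value`,
#'   plus attribute `n_peaks`.
#' @export
align_to_reference_peaks <- function(ref_peaks, track, gene_set,
                                     flank = 100L) {
  inside <- logical(nrow(ref_peaks))
  for (i in seq_len(nrow(ref_peaks))) {
    inside[i] <- any(gene_set$chrom == ref_peaks$chrom[i] &
                       gene_set$strand == ref_peaks$strand[i] &
                       gene_set$start <= ref_peaks$pos[i] &
                       gene_set$end > ref_peaks$pos[i])
  }
  if (!any(inside)) stop("no reference peak inside the gene set")
  pk <- ref_peaks[inside, , drop = FALSE]
  value <- numeric(2L * flank + 1L)
  for (i in seq_len(nrow(pk))) {
    n <- track$chrom_len[[pk$chrom[i]]]
    idx <- (pk$pos[i] - flank):(pk$pos[i] + flank)   # 0-based
    ok <- idx >= 0 & idx < n
    w <- numeric(2L * flank + 1L)
    w[ok] <- track$values[[pk$chrom[i]]][[pk$strand[i]]][idx[ok] + 1L]
    if (pk$strand[i] == "-") w <- rev(w)
    value <- value + w
  }
  out <- data.frame(offset = -flank:flank, value = value)
  attr(out, "n_peaks") <- nrow(pk)
  out
}
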