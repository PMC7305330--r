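# Overlap counting per transcript and per genome window, RPM/RPKM
# normalization, class distributions, and the two correlation-matrix
# modes (co-targeting of RNAs / co-localization of sites).

#' Count read overlaps with transcripts
#'
#' Each read is assigned to exactly one feature: among same-strand
#' overlapping features (>= 1 nt overlap) the one whose class comes first
#' in `priority` wins (ties: largest overlap, then lowest id). A read
#' whose only overlap is with the opposite strand of an mRNA is counted as
#' `antisense`; a read overlapping nothing is `intergenic`.
#'
#' @param reads A `read_table`.
#' @param tx A `transcript_table`.
#' @param priority Ordered character vector of class labels, highest
#'   priority first (classes missing from the list rank last, in
#'   vocabulary order).
#' @return List with `table` (per-transcript `data.frame`: id, class_label,
#'   length, count), `antisense`, `intergenic` (weighted counts),
#'   `assignment` (per-read feature id or `"antisense"`/`"intergenic"`),
#'   and `total` (summed read weight).
#' @export
count_overlaps <- function(reads, tx, priority = DEFAULT_CLASS_PRIORITY) {
  prio_rank <- stats::setNames(seq_along(priority), priority)
  extra <- setdiff(TRANSCRIPT_CLASSES, priority)
  prio_rank <- c(prio_rank, stats::setNames(
    length(priority) + seq_along(extra), extra))

  assignment <- rep("intergenic", nrow(reads))
  if (nrow(reads) && nrow(tx)) {
    rgr <- as_granges(reads)
    tgr <- as_granges(tx)
    ov <- GenomicRanges::findOverlaps(rgr, tgr, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    same <- reads$strand[qh] == tx$strand[sh]
    # sense assignment by (priority, overlap width, id)
    if (any(same)) {
      qs <- qh[same]; ss <- sh[same]
      width <- pmin(reads$end[qs], tx$end[ss]) -
        pmax(reads$start[qs], tx$start[ss])
      ord <- order(qs, prio_rank[tx$class_label[ss]], -width, tx$id[ss])
      keep <- ord[!duplicated(qs[ord])]
      assignment[qs[keep]] <- tx$id[ss[keep]]
    }
    # remaining reads overlapping an mRNA on the opposite strand
    anti <- !same & tx$class_label[sh] == "mRNA"
    if (any(anti)) {
      cand <- unique(qh[anti])
      cand <- cand[assignment[cand] == "intergenic"]
      assignment[cand] <- "antisense"
    }
  }
  counts <- stats::setNames(numeric(nrow(tx)), tx$id)
  feat <- assignment %in% tx$id
  if (any(feat)) {
    agg <- rowsum(reads$weight[feat], assignment[feat])
    counts[rownames(agg)] <- agg[, 1]
  }
  list(table = data.frame(id = tx$id, class_label = tx$class_label,
                          length = tx$length, count = as.numeric(counts),
                          stringsAsFactors = FALSE),
       antisense = sum(reads$weight[assignment == "antisense"]),
       intergenic = sum(reads$weight[assignment == "intergenic"]),
       assignment = assignment,
       total = sum(reads$weight))
}

#' Reads-per-million and RPKM normalization
#'
#' @param count Raw counts.
#' @param total_mapped Total mapped reads of the sample.
#' @param length Feature lengths in nt (RPKM only).
#' @return Normalized values.
#' @export
rpm <- function(count, total_mapped) 1e6 * count / total_mapped

#' @rdname rpm
#' @export
rpkm <- function(count, total_mapped, length)
  1e9 * count / (total_mapped * length)

#' Class distribution of assigned reads
#'
#' Fraction of mapped reads per transcript class (including `antisense`
#' and `intergenic` pseudo-classes).
#'
#' @param counts Output of [count_overlaps()].
#' @return Named numeric vector of fractions summing to 1.
#' @export
class_distribution <- function(counts) {
  per_class <- rowsum(counts$table$count, counts$table$class_label)[, 1]
  per_class <- c(per_class,
                 antisense = counts$antisense,
                 intergenic = counts$intergenic)
  per_class <- per_class[per_class > 0 | names(per_class) %in%
                           unique(counts$table$class_label)]
  tot <- sum(per_class)
  if (tot == 0) stop("no assigned reads")
  per_class / tot
}

#' Average class distributions across biological replicates
#'
#' Each replicate is normalized to fractions first, then the fractions are
#' averaged (arithmetic mean), so replicates of different depths weigh
#' equally.
#'
#' @param dists List of named fraction vectors from [class_distribution()].
#' @return Named fraction vector.
#' @export
average_distributions <- function(dists) {
  classes <- unique(unlist(lapply(dists, names)))
  m <- vapply(dists, function(d) {
    v <- stats::setNames(numeric(length(classes)), classes)
    v[names(d)] <- d
    v
  }, numeric(length(classes)))
  rowMeans(m)
}

#' Count reads in fixed genome windows
#'
#' The genome is tiled with `window_len`-nt windows from position 0 on
#' every chromosome and strand, independently of transcripts; the final
#' short window is kept. By default a read increments every window it
#' overlaps; `mode = "five_prime"` counts only the window holding the
#' read's 5' end.
#'
#' @param reads A `read_table`.
#' @param chrom_len Named integer vector of chromosome lengths.
#' @param window_len Window size in nt.
#' @param mode `"overlap"` or `"five_prime"`.
#' @return Named numeric vector over all (chrom, strand, window) in fixed
#'   order; names are `chrom:strand:windowstart`.
#' @export
window_counts <- function(reads, chrom_len, window_len = 50L,
                          mode = c("overlap", "five_prime")) {
  mode <- match.arg(mode)
  stopifnot(window_len >= 1)
  nwin <- ceiling(chrom_len / window_len)
  out <- list()
  for (chrom in names(chrom_len)) {
    for (s in c("+", "-")) {
      v <- numeric(nwin[[chrom]])
      i <- which(reads$chrom == chrom & reads$strand == s)
      if (length(i)) {
        if (mode == "overlap") {
          w1 <- reads$start[i] %/% window_len
          w2 <- (reads$end[i] - 1L) %/% window_len
          idx <- sequence(nvec = w2 - w1 + 1L, from = w1 + 1L)
          wt <- rep(reads$weight[i], times = w2 - w1 + 1L)
        } else {
          p5 <- if (s == "+") reads$start[i] else reads$end[i] - 1L
          idx <- p5 %/% window_len + 1L
          wt <- reads$weight[i]
        }
        agg <- rowsum(wt, idx)
        v[as.integer(rownames(agg))] <- agg[, 1]
      }
      out[[paste0(chrom, ":", s)]] <- stats::setNames(
        v, paste0(chrom, ":", s, ":",
                  (seq_len(nwin[[chrom]]) - 1L) * window_len))
    }
  }
  unlist(unname(out))
}

#' Pairwise Pearson correlation between factors
#'
#' Replicate vectors (per-transcript counts for co-targeting; fixed 50-nt
#' window counts for co-localization) are averaged per factor first, then
#' Pearson's r is computed between every pair of averaged vectors. A
#' zero-variance vector yields `NA` (undefined, not 0).
#'
#' @param samples Named list: factor -> list of replicate numeric vectors
#'   of equal length.
#' @param mode Label recorded on the result: `"co_targeting"` or
#'   `"co_localization"`.
#' @return A symmetric factor x factor matrix with unit diagonal and
#'   attribute `mode`.
#' @export
correlation_matrix <- function(samples,
                               mode = c("co_targeting", "co_localization")) {
  mode <- match.arg(mode)
  if (length(samples) < 2) stop("need at least two factors")
  avg <- lapply(samples, function(reps) {
    m <- do.call(cbind, reps)
    rowMeans(m)
  })
  len <- unique(vapply(avg, length, 0L))
  if (length(len) != 1) stop("sample vectors have unequal lengths")
  m <- do.call(cbind, avg)
  sds <- apply(m, 2, stats::sd)
  r <- suppressWarnings(stats::cor(m, method = "pearson"))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  attr(r, "mode") <- mode
  r
}
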