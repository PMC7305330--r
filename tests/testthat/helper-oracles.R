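# Independent oracles and small fixture builders shared across test files.
# Oracles are deliberately naive (per-element loops, direct formulas) so
# they stay independent of the vectorized implementation paths.

# exhaustive run-enumeration peak oracle on one strand vector
oracle_peaks <- function(v, min_run = 15, thr = 50, strand = "+") {
  idx <- which(v > thr)
  if (!length(idx)) return(NULL)
  grp <- cumsum(c(1L, diff(idx) != 1L))
  rows <- lapply(split(idx, grp), function(run) {
    if (length(run) < min_run) return(NULL)
    seg <- v[run]
    at <- run[seg == max(seg)]
    p <- if (strand == "+") at[1] else at[length(at)]
    c(pos = p - 1L, height = max(seg),
      span_start = run[1] - 1L, span_end = run[length(run)])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) NULL else out[order(out[, "span_start"]), , drop = FALSE]
}

# adjusted Rand index from a contingency table
ari <- function(tab) {
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  e <- b * cc / choose(sum(tab), 2)
  (a - e) / ((b + cc) / 2 - e)
}

# per-read brute-force class/feature assignment mirroring the counting rule
oracle_assign <- function(reads, tx, priority = DEFAULT_CLASS_PRIORITY) {
  rank_of <- function(cl) {
    r <- match(cl, priority)
    ifelse(is.na(r), length(priority) + match(cl, TRANSCRIPT_CLASSES), r)
  }
  out <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    ov <- which(tx$chrom == reads$chrom[i] &
                  tx$start < reads$end[i] & tx$end > reads$start[i])
    sense <- ov[tx$strand[ov] == reads$strand[i]]
    if (length(sense)) {
      width <- pmin(reads$end[i], tx$end[sense]) -
        pmax(reads$start[i], tx$start[sense])
      o <- order(rank_of(tx$class_label[sense]), -width, tx$id[sense])
      out[i] <- tx$id[sense[o[1]]]
    } else if (any(tx$class_label[ov] == "mRNA")) {
      out[i] <- "antisense"
    } else out[i] <- "intergenic"
  }
  out
}

# position-wise replicate-averaged pileups over an annotation
avg_pileups <- function(sims, ann) {
  pls <- lapply(sims, function(s) pileup_all(s$reads, ann))
  out <- pls[[1]]
  for (gid in names(out))
    out[[gid]] <- Reduce(`+`, lapply(pls, `[[`, gid)) / length(pls)
  out
}

# a small shared genome + mRNA annotation for simulation tests
fixture_genome <- function() make_genome(2, 20000, seed = 401)
fixture_annotation <- function(g = fixture_genome())
  make_annotation(g, c(mRNA = 25, snoRNA = 5, CUT = 5),
                  min_len = 300, max_len = 1500, seed = 402)
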