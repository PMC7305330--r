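# Genotype comparisons: rank-stratified fold changes, per-position
# pseudocount log2 enrichment, and pA-aligned RNAseq distributions per
# gene group.

#' Stratified per-bin log2 fold change
#'
#' Genes are sorted descending by a ranking metric (e.g. Trf5 binding
#' RPKM, so bin 1 = most bound), split into consecutive bins of
#' `bin_size` genes (the last bin may be smaller), and each gene's
#' `log2((mut + c) / (wt + c))` computed on normalized (RPKM) values with
#' pseudocount `c`. The per-bin summary is the mean of per-gene log2
#' ratios by default; `summary = "ratio_of_sums"` uses
#' `log2(sum(mut + c) / sum(wt + c))` instead.
#'
#' @param rank_metric Named numeric vector: gene -> ranking value.
#' @param wt,mut Named numeric vectors of replicate-averaged RPKM per
#'   condition. Genes present in `rank_metric` but absent here count as 0.
#' @param bin_size Genes per bin.
#' @param pseudocount Pseudocount added to both numerator and denominator.
#' @param summary `"mean_of_logs"` or `"ratio_of_sums"`.
#' @return `data.frame` with columns `bin, n_genes, value`; attribute
#'   `per_gene` holds the per-gene log2 ratios in rank order.
#' @export
stratified_foldchange <- function(rank_metric, wt, mut, bin_size = 200L,
                                  pseudocount = 5,
                                  summary = c("mean_of_logs",
                                              "ratio_of_sums")) {
  summary <- match.arg(summary)
  genes <- names(rank_metric)[order(-rank_metric, names(rank_metric))]
  w <- wt[genes]; m <- mut[genes]
  n_missing <- sum(is.na(w)) + sum(is.na(m))
  if (n_missing)
    message(n_missing, " gene-condition value(s) missing; treated as 0")
  w[is.na(w)] <- 0; m[is.na(m)] <- 0
  lfc <- log2((m + pseudocount) / (w + pseudocount))
  bin <- (seq_along(genes) - 1L) %/% bin_size + 1L
  value <- if (summary == "mean_of_logs")
    as.numeric(tapply(lfc, bin, mean))
  else as.numeric(tapply(seq_along(genes), bin, function(i)
    log2(sum(m[i] + pseudocount) / sum(w[i] + pseudocount))))
  out <- data.frame(bin = sort(unique(bin)),
                    n_genes = as.integer(table(bin)),
                    value = value)
  attr(out, "per_gene") <- stats::setNames(lfc, genes)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Per-position log2 enrichment between conditions
#'
#' RPM-normalized replicate tracks are averaged per condition, then
#' `log2((wt + c) / (mut + c))` is computed at every position with
#' pseudocount `c` added to both numerator and denominator (so positions
#' empty in both conditions are exactly 0). Set
#' `orientation = "mut_over_wt"` to flip the ratio.
#'
#' @param wt_tracks,mut_tracks Lists of replicate `CoverageTrack`s
#'   (RPM-normalized, same genome).
#' @param pseudocount Pseudocount (default 5).
#' @param orientation Which condition is the numerator.
#' @return A `CoverageTrack`-shaped object whose values are log2 ratios
#'   (`norm_state = "log2_enrichment"`).
#' @export
positional_log2_enrichment <- function(wt_tracks, mut_tracks,
                                       pseudocount = 5,
                                       orientation = c("wt_over_mut",
                                                       "mut_over_wt")) {
  orientation <- match.arg(orientation)
  if (inherits(wt_tracks, "CoverageTrack")) wt_tracks <- list(wt_tracks)
  if (inherits(mut_tracks, "CoverageTrack")) mut_tracks <- list(mut_tracks)
  wt <- average_tracks(wt_tracks)
  mut <- average_tracks(mut_tracks)
  if (!identical(lapply(wt$values, function(x) lengths(x)),
                 lapply(mut$values, function(x) lengths(x))))
    stop("wt and mut tracks have mismatched chromosome lengths")
  for (chrom in names(wt$values))
    for (s in c("+", "-")) {
      a <- wt$values[[chrom]][[s]] + pseudocount
      b <- mut$values[[chrom]][[s]] + pseudocount
      wt$values[[chrom]][[s]] <- if (orientation == "wt_over_mut")
        log2(a / b) else log2(b / a)
    }
  wt$norm_state <- "log2_enrichment"
  wt$total_mapped <- NA_real_
  wt
}

#' pA-aligned, self-normalized group profile
#'
#' Metagene of RNAseq pileups over one gene group, aligned at the pA site
#' and divided by its own total so the profile integrates to 1 — making
#' shapes comparable between genotypes sequenced at different depths and
#' replicate counts.
#'
#' @param pileups Named list of 5'->3' pileup vectors (replicate-averaged
#'   for the genotype).
#' @param group Character vector of gene ids forming the group.
#' @param min_len Minimum gene length (0 disables the filter).
#' @return `data.frame` with columns `offset` (<= 0), `value` (sums to 1),
#'   `n_genes`.
#' @export
pa_aligned_group_profile <- function(pileups, group, min_len = 0) {
  group <- intersect(group, names(pileups))
  if (!length(group)) stop("empty gene group")
  mg <- metagene(pileups[group], anchor = "pa", min_len = min_len)
  tot <- sum(mg$value)
  if (tot == 0) stop("group has no signal")
  mg$value <- mg$value / tot
  mg
}
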