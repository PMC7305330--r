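# Label-free pull-down quantification (iBAQ -> riBAQ -> enrichment),
# bait-relative recovery, TRAMP complex stoichiometry, and
# efficiency-corrected qPCR fold change.

#' Relative iBAQ (riBAQ)
#'
#' Divides each protein's iBAQ value by the sum of all non-contaminant
#' iBAQ values in the sample, giving relative molar abundances.
#' Contaminants receive a riBAQ relative to the same denominator but are
#' excluded from it.
#'
#' @param ibaq Numeric vector of iBAQ values for one sample.
#' @param contaminant Logical vector flagging contaminant proteins.
#' @return Numeric vector of riBAQ values; non-contaminant entries sum
#'   to 1.
#' @export
compute_ribaq <- function(ibaq, contaminant = rep(FALSE, length(ibaq))) {
  stopifnot(length(ibaq) == length(contaminant), all(ibaq >= 0))
  denom <- sum(ibaq[!contaminant])
  if (denom <= 0) stop("sample has no non-contaminant signal")
  ibaq / denom
}

#' Pull-down enrichment over the mock control
#'
#' Enrichment is the riBAQ ratio between the bait pull-down and the mock
#' sample; proteins with a ratio below `threshold` are considered not
#' enriched (strict: exactly `threshold` is enriched). A protein detected
#' in the pull-down but absent from the mock gets an infinite ratio and is
#' flagged.
#'
#' @param bait_ribaq,mock_ribaq Named numeric vectors over a matched
#'   protein universe.
#' @param threshold Enrichment cutoff (default 2).
#' @return `data.frame` with columns `protein, ribaq_bait, ribaq_mock,
#'   ratio, enriched, infinite_ratio`.
#' @export
enrichment <- function(bait_ribaq, mock_ribaq, threshold = 2) {
  stopifnot(length(bait_ribaq) == length(mock_ribaq))
  prot <- names(bait_ribaq)
  if (!is.null(names(mock_ribaq)) && !identical(prot, names(mock_ribaq)))
    mock_ribaq <- mock_ribaq[prot]
  ratio <- bait_ribaq / mock_ribaq
  inf <- mock_ribaq == 0 & bait_ribaq > 0
  ratio[inf] <- Inf
  ratio[mock_ribaq == 0 & bait_ribaq == 0] <- NaN
  enriched <- !is.nan(ratio) & ratio >= threshold
  data.frame(protein = if (is.null(prot)) seq_along(ratio) else prot,
             ribaq_bait = as.numeric(bait_ribaq),
             ribaq_mock = as.numeric(mock_ribaq),
             ratio = as.numeric(ratio), enriched = enriched,
             infinite_ratio = inf, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Bait-relative recovery with replicate mean and SD
#'
#' Per replicate, every protein's iBAQ is divided by the bait protein's
#' iBAQ (bait set to 1); the mean and sample standard deviation (n-1)
#' across replicates are reported.
#'
#' @param ibaq_mat Numeric matrix, proteins x replicates, rownames =
#'   protein names.
#' @param bait Bait protein name (must have iBAQ > 0 in every replicate).
#' @return `data.frame` with columns `protein, mean, sd`.
#' @export
bait_relative_recovery <- function(ibaq_mat, bait) {
  if (!bait %in% rownames(ibaq_mat)) stop("bait absent: ", bait)
  b <- ibaq_mat[bait, ]
  if (any(b <= 0)) stop("bait iBAQ must be > 0 in every replicate")
  rel <- sweep(ibaq_mat, 2, b, "/")
  data.frame(protein = rownames(ibaq_mat),
             mean = rowMeans(rel),
             sd = if (ncol(rel) > 1) apply(rel, 1, stats::sd) else NA_real_,
             stringsAsFactors = FALSE, row.names = NULL)
}

round_to_hundred <- function(x) sign(x) * floor(abs(x) / 100 + 0.5) * 100

#' Infer TRAMP complex abundances from protein copy numbers
#'
#' Water-filling stoichiometry under the observed interaction pattern:
#' Trf5 partners only Air1, Trf4 partners both Air proteins. TRAMP5-1
#' takes `min(Trf5, Air1)`; the remaining Air1 pairs with Trf4 as
#' TRAMP4-1 (capped by available Trf4); remaining Trf4 pairs with Air2 as
#' TRAMP4-2. Outputs are reported raw and rounded to the nearest hundred
#' (half away from zero), with unpaired surpluses.
#'
#' @param copies Named numeric vector with entries `Air1, Air2, Trf4,
#'   Trf5` (copies per cell).
#' @return List with `complexes` (named: TRAMP4_1, TRAMP4_2, TRAMP5_1),
#'   `rounded` (same, nearest 100), and `residuals` (unpaired Air1, Air2,
#'   Trf4, Trf5).
#' @export
infer_complex_abundance <- function(copies) {
  need <- c("Air1", "Air2", "Trf4", "Trf5")
  stopifnot(all(need %in% names(copies)), all(copies >= 0))
  air1 <- copies[["Air1"]]; air2 <- copies[["Air2"]]
  trf4 <- copies[["Trf4"]]; trf5 <- copies[["Trf5"]]
  t51 <- min(trf5, air1)
  t41 <- min(max(air1 - t51, 0), trf4)
  t42 <- min(air2, max(trf4 - t41, 0))
  complexes <- c(TRAMP4_1 = t41, TRAMP4_2 = t42, TRAMP5_1 = t51)
  residuals <- c(Air1 = air1 - t51 - t41, Air2 = air2 - t42,
                 Trf4 = trf4 - t41 - t42, Trf5 = trf5 - t51)
  list(complexes = complexes,
       rounded = round_to_hundred(complexes),
       residuals = residuals)
}

#' Efficiency-corrected qPCR fold change
#'
#' Triplicate Ct values are averaged per gene and condition; the fold
#' change of each target between conditions, relative to the reference
#' gene (SCR1 by default), is the standard efficiency-corrected ratio
#' `E_target^(Ct_a - Ct_b) / E_ref^(Ct_ref,a - Ct_ref,b)`.
#'
#' @param ct Long-format `data.frame` with columns `gene, condition, ct`
#'   (three rows per gene x condition).
#' @param efficiency Named numeric vector of per-gene amplification
#'   efficiencies in fold per cycle (1 < E <= 2).
#' @param condition_a,condition_b Condition labels; the fold change is
#'   expression in `a` relative to `b`.
#' @param reference Reference gene id.
#' @return Named numeric vector of fold changes for every non-reference
#'   gene.
#' @export
qpcr_foldchange <- function(ct, efficiency, condition_a, condition_b,
                            reference = "SCR1") {
  if (!reference %in% ct$gene) stop("reference gene missing: ", reference)
  stopifnot(all(efficiency > 1), all(efficiency <= 2))
  mean_ct <- tapply(ct$ct, list(ct$gene, ct$condition), mean)
  dct <- mean_ct[, condition_a] - mean_ct[, condition_b]
  e <- efficiency[rownames(mean_ct)]
  if (anyNA(e)) stop("missing efficiency for: ",
                     paste(rownames(mean_ct)[is.na(e)], collapse = ", "))
  targets <- setdiff(rownames(mean_ct), reference)
  fc <- e[targets]^(dct[targets]) / e[[reference]]^dct[[reference]]
  stats::setNames(as.numeric(fc), targets)
}
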