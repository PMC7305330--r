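# Seed-deterministic generators for toy genomes, annotations, CRAC/RNAseq
# reads and iBAQ tables, each with a complete truth table. The generators
# emulate the statistical structure the downstream analyses assume: factor-
# specific positional binding archetypes along transcripts, shared per-gene
# affinities within an archetype, 5' random barcodes, PCR duplication, and
# planted non-templated oligo(A) tails that are unambiguous by construction.

# Run code under a temporary RNG state so generators do not disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Describe a factor's positional binding archetype
#'
#' An archetype summarizes where along a transcript a factor crosslinks:
#' the expected fraction of binding in each fifth of the transcript
#' (`bin_weights`), optional TSS- or pA-anchored Gaussian peak components,
#' a per-gene affinity profile shared by all factors of the same archetype,
#' and the oligo(A) tailing behaviour of the bound RNAs.
#'
#' @param name Factor name.
#' @param bin_weights Five non-negative numbers summing to 1: expected
#'   binding fraction per fifth of the transcript.
#' @param tss_peak_frac,pa_peak_frac Mixture weight of the TSS / pA
#'   anchored Gaussian components (default 0: positions are drawn from
#'   `bin_weights` alone).
#' @param tss_peak_offset,pa_peak_offset Peak centre in nt downstream of
#'   the TSS / upstream of the pA site.
#' @param tss_peak_sd,pa_peak_sd Gaussian spread of the anchored peaks, nt.
#' @param oligoA_frac Probability that a bound molecule carries a
#'   non-templated oligo(A) tail.
#' @param tail_len_dist Probabilities over tail lengths 1..10.
#' @param affinity_seed Integer seeding the per-gene affinity profile;
#'   factors sharing `affinity_seed` prefer the same genes. `NULL` means
#'   uniform affinity.
#' @param affinity_sdlog Log-sd of the lognormal per-gene affinities.
#' @return An object of class `FactorArchetype`.
#' @export
factor_archetype <- function(name,
                             bin_weights = rep(0.2, 5),
                             tss_peak_frac = 0, pa_peak_frac = 0,
                             tss_peak_offset = 50, pa_peak_offset = 50,
                             tss_peak_sd = 20, pa_peak_sd = 20,
                             oligoA_frac = 0,
                             tail_len_dist = c(0.25, 0.25, 0.2, 0.1, 0.08,
                                               0.05, 0.03, 0.02, 0.01, 0.01),
                             affinity_seed = NULL,
                             affinity_sdlog = 1) {
  stopifnot(length(bin_weights) == 5, all(bin_weights >= 0))
  if (abs(sum(bin_weights) - 1) > 1e-9) stop("bin_weights must sum to 1")
  stopifnot(oligoA_frac >= 0, oligoA_frac <= 1,
            tss_peak_frac >= 0, pa_peak_frac >= 0,
            tss_peak_frac + pa_peak_frac <= 1,
            length(tail_len_dist) == 10, all(tail_len_dist >= 0))
  structure(list(name = name, bin_weights = bin_weights,
                 tss_peak_frac = tss_peak_frac, pa_peak_frac = pa_peak_frac,
                 tss_peak_offset = tss_peak_offset,
                 pa_peak_offset = pa_peak_offset,
                 tss_peak_sd = tss_peak_sd, pa_peak_sd = pa_peak_sd,
                 oligoA_frac = oligoA_frac,
                 tail_len_dist = tail_len_dist / sum(tail_len_dist),
                 affinity_seed = affinity_seed,
                 affinity_sdlog = affinity_sdlog),
            class = "FactorArchetype")
}

#' Preset archetypes
#'
#' Convenience constructors for the four positional archetypes the
#' analyses distinguish: a TSS-proximal peak, a pA-proximal peak, uniform
#' binding, and a smooth 3'-bias.
#'
#' @param name Factor name.
#' @param ... Passed on to [factor_archetype()] to override defaults.
#' @return A `FactorArchetype`.
#' @export
archetype_tss_peaked <- function(name, ...) {
  args <- list(name = name, bin_weights = c(0.6, 0.1, 0.1, 0.1, 0.1),
               tss_peak_frac = 0.6, ...)
  do.call(factor_archetype, args[!duplicated(names(args), fromLast = TRUE)])
}

#' @rdname archetype_tss_peaked
#' @export
archetype_pa_peaked <- function(name, ...) {
  args <- list(name = name, bin_weights = c(0.1, 0.1, 0.1, 0.1, 0.6),
               pa_peak_frac = 0.6, ...)
  do.call(factor_archetype, args[!duplicated(names(args), fromLast = TRUE)])
}

#' @rdname archetype_tss_peaked
#' @export
archetype_uniform <- function(name, ...) {
  args <- list(name = name, bin_weights = rep(0.2, 5), ...)
  do.call(factor_archetype, args[!duplicated(names(args), fromLast = TRUE)])
}

#' @rdname archetype_tss_peaked
#' @export
archetype_3p_biased <- function(name, ...) {
  args <- list(name = name, bin_weights = c(0.05, 0.1, 0.15, 0.25, 0.45), ...)
  do.call(factor_archetype, args[!duplicated(names(args), fromLast = TRUE)])
}

#' Generate a random toy genome
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome in nt (>= 1000).
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A `GenomeRef` with chromosomes named `chrI`, `chrII`, ...
#' @export
make_genome <- function(n_chrom = 2, chrom_len = 50000, seed = 1) {
  stopifnot(chrom_len >= 1000)
  roman <- as.character(utils::as.roman(seq_len(n_chrom)))
  with_seed(seed, {
    seqs <- stats::setNames(random_dna(n_chrom, chrom_len),
                            paste0("chr", roman))
    genome_ref(seqs)
  })
}

#' Generate a random annotation on a genome
#'
#' Places the requested number of transcripts per class at random,
#' non-overlapping on the same strand. mRNAs get a configurable fraction
#' of genes longer than 500 nt so they are eligible for metagene analysis;
#' other classes draw lengths uniformly from `[min_len, max_len]`.
#'
#' @param genome A `GenomeRef`.
#' @param n_per_class Named integer vector, e.g. `c(mRNA = 50, snoRNA = 10)`.
#' @param min_len,max_len Transcript length range, nt.
#' @param frac_long Fraction of mRNAs drawn longer than 500 nt.
#' @param seed Integer seed.
#' @return A `transcript_table` with ids `<class><k>`.
#' @export
make_annotation <- function(genome, n_per_class = c(mRNA = 50),
                            min_len = 200, max_len = 2000,
                            frac_long = 0.8, seed = 1) {
  stopifnot(all(names(n_per_class) %in% TRANSCRIPT_CLASSES))
  chroms <- names(genome$seq)
  with_seed(seed, {
    occupied <- list()  # per chrom:strand, matrix of placed intervals
    res <- list()
    for (cls in names(n_per_class)) {
      for (k in seq_len(n_per_class[[cls]])) {
        if (cls == "mRNA") {
          len <- if (stats::runif(1) < frac_long)
            sample(max(501, min_len):max_len, 1)
          else sample(min_len:500, 1)
        } else len <- sample(min_len:max_len, 1)
        placed <- FALSE
        for (try in 1:1000) {
          chrom <- sample(chroms, 1)
          n <- genome$chrom_len[[chrom]]
          if (n < len) next
          strand <- sample(c("+", "-"), 1)
          start <- sample.int(n - len + 1L, 1) - 1L
          end <- start + len
          key <- paste0(chrom, strand)
          ivs <- occupied[[key]]
          if (is.null(ivs) || !any(start < ivs[, 2] & end > ivs[, 1])) {
            occupied[[key]] <- rbind(ivs, c(start, end))
            res[[length(res) + 1]] <- data.frame(
              id = paste0(cls, k), chrom = chrom, strand = strand,
              start = start, end = end, class_label = cls,
              stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("genome too small to place all requested features (",
               cls, " #", k, ")")
      }
    }
    df <- do.call(rbind, res)
    transcript_table(df$id, df$chrom, df$strand, df$start, df$end,
                     df$class_label)
  })
}

# Default sampling weight of transcript classes in a CRAC library; classes
# absent from the annotation are dropped and the rest renormalized.
DEFAULT_CLASS_WEIGHTS <- c(mRNA = 0.55, snoRNA = 0.10, CUT = 0.10,
                           SUT = 0.08, XUT = 0.07, rRNA_spacer = 0.05,
                           tRNA = 0.03, snRNA = 0.02)

# Per-transcript affinity profile for an archetype: lognormal weights drawn
# from the archetype's own seed so factors sharing the archetype share gene
# preferences across independent read simulations.
archetype_affinity <- function(archetype, tx_ids) {
  if (is.null(archetype$affinity_seed)) return(rep(1, length(tx_ids)))
  with_seed(archetype$affinity_seed,
            stats::setNames(stats::rlnorm(length(tx_ids), 0,
                                          archetype$affinity_sdlog), tx_ids))
}

#' Simulate a CRAC (or RNAseq) read library with truth
#'
#' Each molecule picks a transcript (class weights x per-gene affinity),
#' a position along it by mixing the archetype's bin weights with the
#' TSS/pA Gaussian anchor components (the sampled position is the read
#' midpoint), optionally gains a non-templated oligo(A) tail, and gets a
#' random 5' barcode. PCR duplicates re-emit molecules with identical span
#' AND barcode. Planted tails are unambiguous by construction: if the
#' genomic base just 3' of a tailed molecule's end is an A the mapped span
#' is extended instead, so templated A-runs never masquerade as tails.
#'
#' @param genome A `GenomeRef`.
#' @param annotation A `transcript_table`.
#' @param archetype A `FactorArchetype`.
#' @param n_reads Number of molecules (before PCR duplication).
#' @param read_len Mapped read length, nt.
#' @param pcr_dup_rate Duplicates emitted as a fraction of molecules.
#' @param seed Integer seed.
#' @param class_weights Named sampling weights over transcript classes;
#'   defaults to a yeast-CRAC-like mix restricted to annotated classes.
#' @param barcode_len 5' random barcode length (0 disables barcodes, as in
#'   RNAseq libraries).
#' @param truncate_3p Optional named numeric vector (gene id -> fraction in
#'   [0,1)): reads for those genes are placed only in the 5' `1 - fraction`
#'   of the transcript, emulating loss of 3' signal.
#' @param fastq Optional path; if given the reads are also written as FASTQ.
#' @return List with `seqs` (named read sequences, barcode + insert +
#'   tail), `reads` (`read_table` of all emitted reads incl. duplicates,
#'   genomic spans with barcode and tail strings), and `truth` (one row per
#'   molecule: id, transcript, span, barcode, tail_len, sampled bin).
#' @export
simulate_crac_reads <- function(genome, annotation, archetype,
                                n_reads = 10000, read_len = 40,
                                pcr_dup_rate = 0, seed = 1,
                                class_weights = NULL, barcode_len = 3,
                                truncate_3p = NULL, fastq = NULL) {
  stopifnot(n_reads >= 1)
  tx <- annotation[annotation$length >= read_len, , drop = FALSE]
  if (nrow(tx) < nrow(annotation))
    warning(nrow(annotation) - nrow(tx),
            " transcript(s) shorter than read_len skipped")
  if (!nrow(tx)) stop("no transcript long enough for read_len")
  if (is.null(class_weights)) class_weights <- DEFAULT_CLASS_WEIGHTS
  class_weights <- class_weights[names(class_weights) %in% tx$class_label]
  if (!length(class_weights))
    stop("no annotated transcript matches class_weights")
  affinity <- archetype_affinity(archetype, tx$id)

  # per-transcript sampling weight: class weight split by affinity
  w <- numeric(nrow(tx))
  for (cls in names(class_weights)) {
    i <- which(tx$class_label == cls)
    if (!length(i)) next
    wi <- affinity[i]
    w[i] <- class_weights[[cls]] * wi / sum(wi)
  }

  with_seed(seed, {
    ti <- sample.int(nrow(tx), n_reads, replace = TRUE, prob = w)
    L <- tx$length[ti]
    eff_L <- L
    if (!is.null(truncate_3p)) {
      tf <- truncate_3p[tx$id[ti]]
      tf[is.na(tf)] <- 0
      eff_L <- pmax(read_len, as.integer(round(L * (1 - tf))))
    }
    # positional component: 0 = bins, 1 = TSS anchor, 2 = pA anchor
    comp <- sample(0:2, n_reads, replace = TRUE,
                   prob = c(1 - archetype$tss_peak_frac -
                              archetype$pa_peak_frac,
                            archetype$tss_peak_frac, archetype$pa_peak_frac))
    bin <- sample.int(5, n_reads, replace = TRUE,
                      prob = archetype$bin_weights)
    centre <- numeric(n_reads)
    b0 <- comp == 0
    centre[b0] <- (bin[b0] - 1 + stats::runif(sum(b0))) / 5 * eff_L[b0]
    # anchored components draw from a truncated Gaussian (rejection), so
    # reads near short-transcript edges do not pile up at a clamp boundary
    draw_truncated <- function(mu, sd, lo, hi) {
      v <- stats::rnorm(length(lo), mu, sd)
      for (t in 1:50) {
        bad <- v < lo | v > hi
        if (!any(bad)) break
        v[bad] <- stats::rnorm(sum(bad), mu, sd)
      }
      pmin(pmax(v, lo), hi)
    }
    half <- read_len / 2
    b1 <- comp == 1
    centre[b1] <- draw_truncated(archetype$tss_peak_offset,
                                 archetype$tss_peak_sd,
                                 rep(half, sum(b1)), eff_L[b1] - half)
    b2 <- comp == 2
    centre[b2] <- eff_L[b2] - 1 -
      draw_truncated(archetype$pa_peak_offset, archetype$pa_peak_sd,
                     rep(half - 1, sum(b2)), eff_L[b2] - half - 1)
    s <- pmin(pmax(as.integer(round(centre - read_len / 2)), 0L),
              eff_L - read_len)  # read start in transcript coords
    # genomic span in read orientation
    plus <- tx$strand[ti] == "+"
    gstart <- ifelse(plus, tx$start[ti] + s, tx$end[ti] - s - read_len)
    gend <- gstart + read_len
    chrom <- tx$chrom[ti]
    strand <- tx$strand[ti]

    tailed <- stats::runif(n_reads) < archetype$oligoA_frac
    tail_len <- integer(n_reads)
    tail_len[tailed] <- sample.int(10, sum(tailed), replace = TRUE,
                                   prob = archetype$tail_len_dist)
    # extend tailed spans over genomic A-runs so the planted tail is
    # unambiguously non-templated
    for (j in which(tailed)) {
      sq <- genome$seq[[chrom[j]]]
      n <- genome$chrom_len[[chrom[j]]]
      if (strand[j] == "+") {
        while (gend[j] < n &&
               substr(sq, gend[j] + 1L, gend[j] + 1L) == "A")
          gend[j] <- gend[j] + 1L
      } else {
        while (gstart[j] > 0 &&
               substr(sq, gstart[j], gstart[j]) == "T")
          gstart[j] <- gstart[j] - 1L
      }
    }

    barcode <- if (barcode_len > 0) random_dna(n_reads, barcode_len)
               else rep("", n_reads)
    if (barcode_len > 0) {
      # biological molecules that coincide on the same span must carry
      # distinct barcodes, so that (span, barcode) identity holds exactly
      # for PCR duplicates and nothing else
      span_key <- paste(chrom, strand, gstart, gend)
      for (attempt in 1:100) {
        clash <- duplicated(paste(span_key, barcode))
        if (!any(clash)) break
        barcode[clash] <- random_dna(sum(clash), barcode_len)
      }
      if (any(duplicated(paste(span_key, barcode))))
        warning("coincident molecules exhausted the barcode space")
    }
    tail_str <- strrep("A", tail_len)

    truth <- data.frame(
      id = sprintf("mol%06d", seq_len(n_reads)),
      transcript = tx$id[ti], class_label = tx$class_label[ti],
      chrom = chrom, strand = strand, start = gstart, end = gend,
      barcode = barcode, tail_len = tail_len, bin = bin, comp = comp,
      stringsAsFactors = FALSE)

    # PCR duplicates: identical span AND barcode
    n_dup <- round(pcr_dup_rate * n_reads)
    dup_of <- if (n_dup > 0) sample.int(n_reads, n_dup, replace = TRUE)
              else integer()
    emit <- c(seq_len(n_reads), dup_of)

    reads <- read_table(chrom[emit], strand[emit], gstart[emit], gend[emit],
                        barcode = barcode[emit], tail = tail_str[emit])

    # sequences: barcode + oriented genomic insert + planted tail
    insert <- character(n_reads)
    for (cn in unique(chrom)) {
      i <- which(chrom == cn)
      insert[i] <- substring(genome$seq[[cn]], gstart[i] + 1L, gend[i])
    }
    neg <- strand == "-"
    if (any(neg)) insert[neg] <- revcomp(insert[neg])
    seqs <- stats::setNames(paste0(barcode, insert, tail_str)[emit],
                            sprintf("read%06d", seq_along(emit)))
    if (!is.null(fastq)) write_fastq(seqs, fastq)
    list(seqs = seqs, reads = reads, truth = truth)
  })
}

#' Simulate an RNAseq library
#'
#' Thin wrapper over [simulate_crac_reads()] with a uniform positional
#' archetype, no barcodes and no tails; an optional per-gene 3' truncation
#' emulates transcripts whose 3' region is under-represented in one
#' genotype.
#'
#' @inheritParams simulate_crac_reads
#' @return As [simulate_crac_reads()].
#' @export
simulate_rnaseq <- function(genome, annotation, n_reads = 10000,
                            read_len = 40, seed = 1, class_weights = NULL,
                            truncate_3p = NULL, fastq = NULL) {
  simulate_crac_reads(genome, annotation,
                      archetype_uniform("rnaseq"),
                      n_reads = n_reads, read_len = read_len,
                      pcr_dup_rate = 0, seed = seed,
                      class_weights = class_weights, barcode_len = 0,
                      truncate_3p = truncate_3p, fastq = fastq)
}

#' Simulate a bait pull-down / mock iBAQ table pair
#'
#' Background proteins share a lognormal abundance in bait and mock
#' samples; true partners are `enrich_factor`-fold more abundant in the
#' bait pull-down; the bait itself is present only in the pull-down; a
#' fraction of proteins are flagged contaminants.
#'
#' @param n_proteins Number of background proteins (excluding the bait).
#' @param bait Bait protein name.
#' @param true_partners Character vector of partner protein names (subset
#'   of the generated background names or new names, which are appended).
#' @param enrich_factor Fold enrichment of partners in the bait sample
#'   (> 1).
#' @param contaminant_frac Fraction of background proteins flagged as
#'   contaminants.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   noise on every measured iBAQ (0 = noiseless).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `protein, contaminant, is_bait,
#'   truth_partner, ibaq_mock, ibaq_bait`.
#' @export
simulate_ibaq <- function(n_proteins = 100, bait = "BAIT",
                          true_partners = c("P1", "P2", "P3"),
                          enrich_factor = 4, contaminant_frac = 0.1,
                          noise_cv = 0.2, seed = 1) {
  stopifnot(enrich_factor > 1)
  with_seed(seed, {
    prot <- c(paste0("prot", seq_len(n_proteins)), true_partners, bait)
    n <- length(prot)
    is_bait <- prot == bait
    partner <- prot %in% true_partners
    contaminant <- rep(FALSE, n)
    bg <- which(!is_bait & !partner)
    contaminant[sample(bg, round(contaminant_frac * length(bg)))] <- TRUE
    sdlog <- sqrt(log(1 + noise_cv^2))
    # heavier abundance spread for the background; partners and bait stay
    # near the typical abundance so riBAQ denominator inflation in the
    # pull-down cannot on its own push a noiseless 4-fold partner below
    # the 2-fold enrichment cutoff
    base <- stats::rlnorm(n, meanlog = log(1e6), sdlog = 1.5)
    base[partner] <- stats::rlnorm(sum(partner), meanlog = log(1e6),
                                   sdlog = 1)
    noise <- function() if (noise_cv > 0) stats::rlnorm(n, 0, sdlog) else 1
    ibaq_mock <- base * noise()
    ibaq_bait <- base * ifelse(partner, enrich_factor, 1) * noise()
    ibaq_mock[is_bait] <- 0
    ibaq_bait[is_bait] <- 1e6 * enrich_factor
    data.frame(protein = prot, contaminant = contaminant,
               is_bait = is_bait, truth_partner = partner,
               ibaq_mock = ibaq_mock, ibaq_bait = ibaq_bait,
               stringsAsFactors = FALSE)
  })
}
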