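test_that("make_genome is seed-deterministic with the right shape and composition", {
  g1 <- make_genome(2, 1000, seed = 1)
  g2 <- make_genome(2, 1000, seed = 1)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g1, f1); write_fasta(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(length(g1$seq), 2L)
  expect_false(identical(g1$seq, make_genome(2, 1000, seed = 2)$seq))

  big <- make_genome(1, 100000, seed = 3)
  comp <- table(strsplit(big$seq[[1]], "")[[1]]) / 100000
  expect_true(all(abs(comp - 0.25) < 0.02))
})

test_that("make_annotation honours class counts, avoids same-strand overlap, errors at capacity", {
  g <- fixture_genome()
  tx <- make_annotation(g, c(mRNA = 30, snoRNA = 8), seed = 5)
  expect_equal(sum(tx$class_label == "mRNA"), 30L)
  expect_equal(sum(tx$class_label == "snoRNA"), 8L)
  # same-strand overlap count = 0
  for (key in split(seq_len(nrow(tx)), paste(tx$chrom, tx$strand))) {
    iv <- tx[key, ]
    iv <- iv[order(iv$start), ]
    if (nrow(iv) > 1)
      expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))
  }
  expect_identical(make_annotation(g, c(mRNA = 10), seed = 9),
                   make_annotation(g, c(mRNA = 10), seed = 9))
  tiny <- make_genome(1, 1000, seed = 1)
  expect_error(make_annotation(tiny, c(mRNA = 100), min_len = 400,
                               max_len = 500, seed = 1),
               "too small")
})

test_that("simulated molecules have unique (span, barcode) keys when pcr_dup_rate is 0", {
  g <- fixture_genome(); ann <- fixture_annotation(g)
  sim <- simulate_crac_reads(g, ann, archetype_uniform("u"),
                             n_reads = 1500, pcr_dup_rate = 0, seed = 7)
  key <- paste(sim$reads$chrom, sim$reads$strand, sim$reads$start,
               sim$reads$end, sim$reads$barcode)
  expect_equal(length(unique(key)), 1500L)
  expect_equal(nrow(sim$truth), 1500L)
})

test_that("oligoA_frac controls planted tails (0 = none; 0.3 recovered within binomial CI)", {
  g <- fixture_genome(); ann <- fixture_annotation(g)
  none <- simulate_crac_reads(g, ann, archetype_uniform("u", oligoA_frac = 0),
                              n_reads = 800, seed = 8)
  expect_true(all(none$truth$tail_len == 0))
  some <- simulate_crac_reads(g, ann,
                              archetype_uniform("u", oligoA_frac = 0.3),
                              n_reads = 10000, seed = 9)
  expect_lt(abs(mean(some$truth$tail_len > 0) - 0.3), 0.02)
})

test_that("untailed molecule spans lie inside their source transcript", {
  g <- fixture_genome(); ann <- fixture_annotation(g)
  sim <- simulate_crac_reads(g, ann,
                             archetype_tss_peaked("t", oligoA_frac = 0.2),
                             n_reads = 2000, seed = 10)
  tr <- sim$truth[sim$truth$tail_len == 0, ]
  m <- match(tr$transcript, ann$id)
  expect_true(all(tr$start >= ann$start[m]))
  expect_true(all(tr$end <= ann$end[m]))
  # tailed spans may extend past the 3' end only over the genomic A-run
  tl <- sim$truth[sim$truth$tail_len > 0, ]
  m <- match(tl$transcript, ann$id)
  over <- ifelse(tl$strand == "+", tl$end - ann$end[m],
                 ann$start[m] - tl$start)
  expect_true(all(over <= 15))
})

test_that("per-bin read fractions converge to bin_weights when anchors are disabled", {
  g <- make_genome(2, 50000, seed = 11)
  ann <- make_annotation(g, c(mRNA = 30), min_len = 600, max_len = 1500,
                         seed = 12)
  w <- c(0.4, 0.25, 0.15, 0.1, 0.1)
  sim <- simulate_crac_reads(g, ann, factor_archetype("f", bin_weights = w),
                             n_reads = 50000, seed = 13,
                             class_weights = c(mRNA = 1), barcode_len = 0)
  emp <- as.numeric(table(factor(sim$truth$bin, levels = 1:5))) / 50000
  expect_lt(sum(abs(emp - w)), 0.05)
})

test_that("regeneration with identical config and seed is byte-identical", {
  g <- fixture_genome(); ann <- fixture_annotation(g)
  arch <- archetype_pa_peaked("p", oligoA_frac = 0.25, affinity_seed = 44)
  s1 <- simulate_crac_reads(g, ann, arch, n_reads = 600, pcr_dup_rate = 0.3,
                            seed = 21)
  s2 <- simulate_crac_reads(g, ann, arch, n_reads = 600, pcr_dup_rate = 0.3,
                            seed = 21)
  expect_identical(s1, s2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fastq(s1$seqs, f1); write_fastq(s2$seqs, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("noiseless iBAQ simulation gives partners a riBAQ ratio of at least 2", {
  tab <- simulate_ibaq(n_proteins = 60, enrich_factor = 4, noise_cv = 0,
                       seed = 31)
  expect_true(tab$ibaq_mock[tab$is_bait] == 0)
  expect_gt(tab$ibaq_bait[tab$is_bait], 0)
  rb <- compute_ribaq(tab$ibaq_bait, tab$contaminant)
  rm_ <- compute_ribaq(tab$ibaq_mock, tab$contaminant)
  ratio <- rb / rm_
  expect_true(all(ratio[tab$truth_partner] >= 2))
  expect_identical(tab, simulate_ibaq(n_proteins = 60, enrich_factor = 4,
                                      noise_cv = 0, seed = 31))
})
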