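test_that("stratified fold change has closed-form values and bin-order invariance", {
  genes <- sprintf("g%03d", 1:400)
  metric <- setNames(400:1, genes)
  wt <- setNames(runif(400, 10, 100), genes)

  same <- stratified_foldchange(metric, wt, wt, bin_size = 100)
  expect_true(all(same$value == 0))

  dbl <- stratified_foldchange(metric, wt, 2 * wt, bin_size = 100,
                               pseudocount = 0)
  expect_true(all(abs(dbl$value - 1) < 1e-12))
  expect_equal(dbl$n_genes, rep(100L, 4))

  # permuting metric values WITHIN a bin leaves per-bin means unchanged
  metric2 <- metric
  metric2[1:100] <- rev(metric2[1:100])
  mut <- wt * runif(400, 0.2, 1)
  a <- stratified_foldchange(metric, wt, mut, bin_size = 100)
  b <- stratified_foldchange(metric2, wt, mut, bin_size = 100)
  expect_equal(a$value, b$value)

  # genes absent from a count table count as zero
  wt_miss <- wt[-(1:5)]
  expect_message(
    fc <- stratified_foldchange(metric, wt_miss, mut, bin_size = 100),
    "missing")
  expect_equal(fc$value[1],
               mean(log2((mut[names(metric)[1:100]] + 5) /
                           (c(rep(0, 5), wt[names(metric)[6:100]]) + 5))))
})

test_that("rank-proportional depletion yields monotone per-bin fold changes", {
  set.seed(91)
  ng <- 1000
  metric <- setNames(sort(rlnorm(ng, 3, 1), decreasing = TRUE),
                     sprintf("g%04d", 1:ng))
  wt <- metric * rlnorm(ng, 0, 0.1)
  mut <- wt / (1 + metric / median(metric)) * rlnorm(ng, 0, 0.1)
  names(wt) <- names(mut) <- names(metric)
  fc <- stratified_foldchange(metric, wt, mut, bin_size = 200)
  expect_gt(abs(cor(fc$bin, fc$value, method = "spearman")), 0.9)
})

test_that("positional enrichment follows log2((a+5)/(b+5)) and is antisymmetric", {
  cl <- c(c1 = 50L)
  mk <- function(vals) {
    tr <- coverage_track(cl)
    tr$values$c1[["+"]] <- vals
    tr$norm_state <- "rpm_total"
    tr
  }
  a <- mk(rep(5, 50)); b <- mk(numeric(50))
  e <- positional_log2_enrichment(list(a), list(b))
  expect_true(all(e$values$c1[["+"]] == 1))      # log2(10/5)
  z <- positional_log2_enrichment(list(b), list(b))
  expect_true(all(z$values$c1[["+"]] == 0))      # pseudocounts cancel
  same <- positional_log2_enrichment(list(a), list(a))
  expect_true(all(same$values$c1[["+"]] == 0))

  set.seed(92)
  x <- mk(rpois(50, 8)); y <- mk(rpois(50, 3))
  fwd <- positional_log2_enrichment(list(x), list(y))
  rev_ <- positional_log2_enrichment(list(y), list(x))
  expect_equal(fwd$values$c1[["+"]], -rev_$values$c1[["+"]])
  flip <- positional_log2_enrichment(list(x), list(y),
                                     orientation = "mut_over_wt")
  expect_equal(flip$values$c1[["+"]], -fwd$values$c1[["+"]])

  short <- coverage_track(c(c1 = 10L), norm_state = "raw")
  short$norm_state <- "rpm_total"
  expect_error(positional_log2_enrichment(list(a), list(short)),
               "mismatch")
})

test_that("replicate tracks are averaged per condition before the ratio", {
  cl <- c(c1 = 20L)
  mk <- function(v) {
    tr <- coverage_track(cl)
    tr$values$c1[["+"]] <- v
    tr$norm_state <- "rpm_total"
    tr
  }
  e <- positional_log2_enrichment(list(mk(rep(10, 20)), mk(rep(20, 20))),
                                  list(mk(rep(5, 20))))
  expect_true(all(e$values$c1[["+"]] == 1))      # log2((15+5)/(5+5))
})

test_that("pA-aligned group profiles integrate to one and detect a planted 3' deficit", {
  flat <- list(g1 = rep(3, 400))
  pr <- pa_aligned_group_profile(flat, "g1")
  expect_equal(sum(pr$value), 1)
  expect_true(all(abs(pr$value - 1 / 400) < 1e-12))
  expect_error(pa_aligned_group_profile(flat, "nope"), "empty")

  g <- make_genome(2, 40000, seed = 93)
  ann <- make_annotation(g, c(mRNA = 30), min_len = 800, max_len = 1500,
                         seed = 94)
  grp <- list(t = ann$id[1:10], c = ann$id[11:30])
  trunc <- setNames(rep(0.15, 10), grp$t)
  wt <- lapply(1:2, function(r)
    simulate_rnaseq(g, ann, n_reads = 15000, seed = 100 + r,
                    class_weights = c(mRNA = 1)))
  mu <- lapply(1:2, function(r)
    simulate_rnaseq(g, ann, n_reads = 15000, seed = 200 + r,
                    class_weights = c(mRNA = 1), truncate_3p = trunc))
  pw <- avg_pileups(wt, ann); pm <- avg_pileups(mu, ann)
  ratio3p <- function(gs) {
    w <- pa_aligned_group_profile(pw, gs)
    m <- pa_aligned_group_profile(pm, gs)
    win <- floor(0.1 * min(ann$length[ann$id %in% gs]))
    sum(m$value[m$offset >= -(win - 1)]) /
      sum(w$value[w$offset >= -(win - 1)])
  }
  expect_lt(ratio3p(grp$t), 0.8)
  expect_gt(ratio3p(grp$c), 0.95)
  # identical data across genotypes -> identical profiles
  expect_equal(pa_aligned_group_profile(pw, grp$c),
               pa_aligned_group_profile(pw, grp$c))
})
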