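test_that("pileup counts hits per transcript position, 5' to 3'", {
  tx <- transcript_table(c("p", "m"), c("c1", "c1"), c("+", "-"),
                         c(100L, 300L), c(200L, 400L), c("mRNA", "mRNA"))
  rd <- read_table(c("c1", "c1"), c("+", "-"), c(110L, 360L),
                   c(140L, 390L), barcode = "AAA")
  vp <- pileup(rd, tx[1, ])
  expect_equal(sum(vp), 30)
  expect_equal(which(vp == 1), 11:40)
  # minus-strand transcript: genomic [360,390) is transcript offsets 10..39
  vm <- pileup(rd, tx[2, ])
  expect_equal(which(vm == 1), 11:40)
  expect_equal(pileup_all(rd, tx), list(p = vp, m = vm))
})

test_that("pileup totals equal summed per-read overlap lengths (brute force)", {
  g <- fixture_genome(); ann <- fixture_annotation(g)
  sim <- simulate_crac_reads(g, ann, archetype_uniform("u"),
                             n_reads = 500, seed = 71)
  pl <- pileup_all(sim$reads, ann)
  for (i in sample(nrow(ann), 5)) {
    txr <- ann[i, ]
    ov <- pmin(sim$reads$end, txr$end) - pmax(sim$reads$start, txr$start)
    ov[sim$reads$chrom != txr$chrom | sim$reads$strand != txr$strand] <- 0
    expect_equal(sum(pl[[txr$id]]), sum(pmax(ov, 0)))
  }
})

test_that("metagene on a single uniform gene is flat; ragged genes taper support", {
  one <- list(gene1 = rep(1, 700))
  mg <- metagene(one, anchor = "tss")
  expect_true(all(mg$value == 1))
  expect_equal(nrow(mg), 700L)

  two <- list(a = rep(2, 600), b = rep(3, 800))
  mg <- metagene(two, anchor = "tss")
  expect_equal(mg$value[mg$offset == 100], 5)
  expect_equal(mg$value[mg$offset == 700], 3)   # only gene b reaches there
  expect_equal(mg$n_genes[mg$offset == 700], 1L)
  expect_error(metagene(list(short = rep(1, 100)), "tss"), "min_len")
})

test_that("metagene at pA on mirrored pileups equals metagene at TSS", {
  g <- fixture_genome(); ann <- fixture_annotation(g)
  sim <- simulate_crac_reads(g, ann, archetype_3p_biased("b"),
                             n_reads = 3000, seed = 72)
  pl <- pileup_all(sim$reads, ann)
  tss <- metagene(pl, anchor = "tss")
  pa <- metagene(lapply(pl, rev), anchor = "pa")
  expect_equal(rev(pa$value), tss$value)
})

test_that("a planted TSS-proximal peak is recovered at its offset", {
  g <- make_genome(2, 50000, seed = 73)
  ann <- make_annotation(g, c(mRNA = 40), min_len = 600, max_len = 1500,
                         seed = 74)
  arch <- factor_archetype("f", tss_peak_frac = 1, tss_peak_sd = 20,
                           tss_peak_offset = 50)
  sim <- simulate_crac_reads(g, ann, arch, n_reads = 20000, seed = 75,
                             class_weights = c(mRNA = 1), barcode_len = 0)
  mg <- metagene(pileup_all(sim$reads, ann), anchor = "tss")
  expect_lt(abs(mg$offset[which.max(mg$value)] - 50), 5.5)
})

test_that("region sums add flanks and summarize replicates with n-1 SD", {
  tr <- coverage_track(c(c1 = 1000L))
  tr$values$c1[["+"]][] <- 1
  expect_equal(region_sum(tr, "c1", 100, 200, flank = 10)$mean, 120)
  expect_equal(region_sum(tr, "c1", 100, 200, flank = 0)$mean, 100)
  tr2 <- tr; tr2$values$c1[["+"]][] <- 1.4
  rs <- region_sum(list(tr, tr2), "c1", 100, 200, flank = 0)
  expect_equal(rs$mean, 120)
  expect_equal(rs$sd, sd(c(100, 140)))
  expect_error(region_sum(tr, "c1", -20, 100, flank = 0), "outside")
})

test_that("peak calling applies run-length and strict height rules with 5'-most ties", {
  mk <- function(v, strand = "+") {
    tr <- coverage_track(c(c1 = 200L))
    tr$values$c1[[strand]] <- v
    tr
  }
  base <- numeric(200)
  v <- base; v[21:35] <- 51                 # 15 positions above
  expect_equal(nrow(call_peaks(mk(v))), 1L)
  v <- base; v[21:34] <- 1000               # 14 positions: too short
  expect_equal(nrow(call_peaks(mk(v))), 0L)
  v <- base; v[21:40] <- 50                 # exactly 50: strict >
  expect_equal(nrow(call_peaks(mk(v))), 0L)
  # plateau tie: 5'-most, strand aware
  v <- base; v[21:40] <- 60; v[25:30] <- 80
  expect_equal(call_peaks(mk(v))$pos, 24L)
  expect_equal(call_peaks(mk(v, "-"))$pos, 29L)
  # run boundaries recorded as the cluster span
  pk <- call_peaks(mk(v))
  expect_equal(pk$span_start, 20L)
  expect_equal(pk$span_end, 40L)
})

test_that("peak calls equal the exhaustive run-enumeration oracle on random tracks", {
  set.seed(76)
  for (i in 1:20) {
    v <- rep(rexp(500, 1 / 30), each = 20)   # 10k positions, blocky
    tr <- coverage_track(c(cZ = 10000L))
    s <- if (i %% 2) "+" else "-"
    tr$values$cZ[[s]] <- v
    pk <- call_peaks(tr)
    o <- oracle_peaks(v, strand = s)
    if (is.null(o)) {
      expect_equal(nrow(pk), 0L)
    } else {
      expect_equal(pk$pos, unname(o[, "pos"]))
      expect_equal(pk$height, unname(o[, "height"]))
      expect_equal(pk$span_start, unname(o[, "span_start"]))
      expect_equal(pk$span_end, unname(o[, "span_end"]))
    }
  }
})

test_that("peak-anchored alignment is maximal at offset 0 for the factor itself and recovers planted shifts", {
  cl <- c(c1 = 5000L)
  tx <- transcript_table("g1", "c1", "+", 0L, 5000L, "mRNA")
  ref <- coverage_track(cl)
  set.seed(77)
  centres <- c(500, 1500, 2500, 3500, 4400)
  for (cc in centres)
    ref$values$c1[["+"]][(cc - 30):(cc + 30)] <-
      60 + 40 * exp(-((-30:30) / 10)^2)
  pk <- call_peaks(ref)
  expect_equal(nrow(pk), length(centres))
  self <- align_to_reference_peaks(pk, ref, tx, flank = 100)
  expect_equal(self$offset[which.max(self$value)], 0L)

  flat <- coverage_track(cl); flat$values$c1[["+"]][] <- 2
  fp <- align_to_reference_peaks(pk, flat, tx, flank = 100)
  expect_true(all(fp$value == 2 * length(centres)))

  shifted <- coverage_track(cl)
  shifted$values$c1[["+"]] <- c(numeric(25), ref$values$c1[["+"]])[1:5000]
  sp <- align_to_reference_peaks(pk, shifted, tx, flank = 100)
  expect_lt(abs(sp$offset[which.max(sp$value)] - 25), 3.5)

  away <- transcript_table("far", "c1", "+", 4900L, 4990L, "mRNA")
  expect_error(align_to_reference_peaks(pk, ref, away), "no reference peak")
})
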