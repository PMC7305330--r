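test_that("riBAQ divides by the non-contaminant sum and contaminants are excluded from it", {
  r <- compute_ribaq(c(3, 1))
  expect_equal(r, c(0.75, 0.25))
  r2 <- compute_ribaq(c(3, 1, 100), contaminant = c(FALSE, FALSE, TRUE))
  expect_equal(r2[1:2], c(0.75, 0.25))   # denominator unchanged
  expect_equal(r2[3], 25)
  expect_equal(sum(r2[1:2]), 1)          # non-contaminant riBAQ sums to 1
  expect_error(compute_ribaq(c(0, 0)), "no non-contaminant")
})

test_that("enrichment threshold is strict-below-2 exclusion with infinite-ratio flagging", {
  b <- c(p1 = 1.99e-3, p2 = 2e-3, p3 = 5e-4, p4 = 0)
  m <- c(p1 = 1e-3, p2 = 1e-3, p3 = 0, p4 = 0)
  e <- enrichment(b, m)
  expect_equal(e$enriched, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(e$ratio[1], 1.99)
  expect_true(is.infinite(e$ratio[3]) && e$infinite_ratio[3])
  expect_true(is.nan(e$ratio[4]))
})

test_that("enrichment is invariant to rescaling one sample's iBAQ values", {
  tab <- simulate_ibaq(n_proteins = 40, noise_cv = 0.3, seed = 101)
  rb <- compute_ribaq(tab$ibaq_bait, tab$contaminant)
  rm_ <- compute_ribaq(tab$ibaq_mock, tab$contaminant)
  e1 <- enrichment(setNames(rb, tab$protein), setNames(rm_, tab$protein))
  rb2 <- compute_ribaq(tab$ibaq_bait * 57, tab$contaminant)
  e2 <- enrichment(setNames(rb2, tab$protein), setNames(rm_, tab$protein))
  expect_equal(e1$ratio, e2$ratio, tolerance = 1e-12)
})

test_that("a noiseless 4-fold simulation is classified perfectly", {
  tab <- simulate_ibaq(n_proteins = 80, enrich_factor = 4, noise_cv = 0,
                       seed = 102)
  non_bait <- !tab$is_bait
  rb <- compute_ribaq(tab$ibaq_bait, tab$contaminant)
  rm_ <- compute_ribaq(tab$ibaq_mock, tab$contaminant)
  e <- enrichment(setNames(rb, tab$protein), setNames(rm_, tab$protein))
  expect_equal(e$enriched[non_bait], tab$truth_partner[non_bait])
  expect_true(e$enriched[tab$is_bait])   # bait only in pull-down
})

test_that("bait-relative recovery normalizes to the bait and reports n-1 SD", {
  mat <- rbind(bait = c(10, 10), partner = c(4, 6))
  br <- bait_relative_recovery(mat, "bait")
  expect_equal(br$mean[br$protein == "bait"], 1)
  expect_equal(br$sd[br$protein == "bait"], 0)
  expect_equal(br$mean[br$protein == "partner"], 0.5)
  expect_equal(br$sd[br$protein == "partner"], sd(c(0.4, 0.6)))
  expect_equal(bait_relative_recovery(rbind(b = 10, p = 5), "b")$mean,
               c(1, 0.5))
  expect_error(bait_relative_recovery(mat, "nope"), "absent")
})

test_that("TRAMP stoichiometry reproduces the worked copy-number example", {
  copies <- c(Air1 = 1851, Air2 = 1750, Trf4 = 2659, Trf5 = 1329)
  ca <- infer_complex_abundance(copies)
  expect_equal(unname(ca$rounded["TRAMP5_1"]), 1300)
  expect_equal(unname(ca$complexes["TRAMP5_1"]), 1329)
  # material conservation
  expect_lte(ca$complexes["TRAMP4_1"] + ca$complexes["TRAMP5_1"],
             copies["Air1"])
  expect_lte(ca$complexes["TRAMP4_2"], copies["Air2"])
  expect_true(all(ca$complexes >= 0))
})

test_that("stoichiometry degenerate cases and conservation on random inputs", {
  no5 <- infer_complex_abundance(c(Air1 = 500, Air2 = 300, Trf4 = 400,
                                   Trf5 = 0))
  expect_equal(unname(no5$complexes["TRAMP5_1"]), 0)
  expect_equal(unname(no5$complexes["TRAMP4_1"]), 400)  # min(Air1, Trf4)
  eq <- infer_complex_abundance(c(Air1 = 700, Air2 = 300, Trf4 = 900,
                                  Trf5 = 700))
  expect_equal(unname(eq$complexes["TRAMP4_1"]), 0)
  set.seed(103)
  for (i in 1:50) {
    cp <- setNames(runif(4, 0, 3000), c("Air1", "Air2", "Trf4", "Trf5"))
    ca <- infer_complex_abundance(cp)
    expect_true(all(ca$complexes >= 0))
    expect_lte(ca$complexes["TRAMP4_1"] + ca$complexes["TRAMP5_1"],
               cp["Air1"] + 1e-9)
    expect_lte(ca$complexes["TRAMP4_2"], cp["Air2"] + 1e-9)
    expect_lte(ca$complexes["TRAMP5_1"], min(cp["Trf5"], cp["Air1"]) + 1e-9)
  }
})

test_that("qPCR fold change is the efficiency-corrected ratio over the reference gene", {
  ct <- expand.grid(gene = c("SCR1", "t1"), condition = c("a", "b"),
                    rep = 1:3, stringsAsFactors = FALSE)
  ct$ct <- 20
  expect_equal(unname(qpcr_foldchange(ct, c(SCR1 = 2, t1 = 2), "a", "b")), 1)

  ct2 <- ct
  ct2$ct[ct2$gene == "t1" & ct2$condition == "a"] <- 21   # dCt_target = 1
  expect_equal(unname(qpcr_foldchange(ct2, c(SCR1 = 2, t1 = 2), "a", "b")), 2)

  ct3 <- ct
  ct3$ct[ct3$gene == "t1" & ct3$condition == "a"] <- 22    # dCt_target = 2
  ct3$ct[ct3$gene == "SCR1" & ct3$condition == "a"] <- 21  # dCt_ref = 1
  expect_equal(unname(qpcr_foldchange(ct3, c(SCR1 = 2, t1 = 1.9), "a", "b")),
               1.9^2 / 2)

  # triplicates are averaged before the ratio
  ct4 <- ct
  ct4$ct[ct4$gene == "t1" & ct4$condition == "a"] <- c(20, 21, 22)
  expect_equal(unname(qpcr_foldchange(ct4, c(SCR1 = 2, t1 = 2), "a", "b")), 2)

  expect_error(qpcr_foldchange(ct[ct$gene != "SCR1", ],
                               c(t1 = 2), "a", "b"), "reference")
})
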