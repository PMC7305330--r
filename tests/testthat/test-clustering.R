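test_that("top-gene union behaves for identical, disjoint and random rankings", {
  v <- setNames(100:1, sprintf("g%03d", 1:100))
  same <- select_top_union(list(a = v, b = v), n = 10)
  expect_equal(length(same), 10L)
  expect_equal(same, sort(names(v)[1:10]))

  d1 <- setNames(c(rep(10, 5), rep(0, 5)), paste0("x", 1:10))
  d2 <- setNames(c(rep(0, 5), rep(10, 5)), paste0("x", 1:10))
  expect_equal(length(select_top_union(list(a = d1, b = d2), n = 5)), 10L)

  set.seed(81)
  tabs <- lapply(1:3, function(i) setNames(runif(200), sprintf("g%03d", 1:200)))
  got <- select_top_union(tabs, n = 50)
  brute <- sort(unique(unlist(lapply(tabs, function(v) {
    o <- order(-v, names(v))
    names(v)[o][1:50]
  }))))
  expect_equal(got, brute)
  expect_warning(select_top_union(list(a = v), n = 1000), "fewer")
})

test_that("bin occupancy divides genes into five bins normalized to a per-gene total of 1", {
  pl <- list(f1 = list(u = rep(2, 500), front = c(rep(5, 100), rep(0, 400)),
                       z = numeric(503)))
  m <- bin_occupancy(pl)
  expect_equal(unname(m["u", ]), rep(0.2, 5))
  expect_equal(unname(m["front", ]), c(1, 0, 0, 0, 0))
  expect_equal(unname(m["z", ]), rep(0, 5))   # zero coverage -> zero block
  # remainder nucleotides go to the last bin
  m2 <- bin_occupancy(list(f = list(g = rep(1, 503))))
  expect_equal(sum(m2["g", ]), 1)
  expect_equal(unname(m2["g", 5]), 103 / 503)
})

test_that("simulated archetype bin weights are recovered from binned pileups", {
  g <- make_genome(2, 50000, seed = 82)
  ann <- make_annotation(g, c(mRNA = 30), min_len = 600, max_len = 1500,
                         seed = 83)
  w <- c(0.6, 0.1, 0.1, 0.1, 0.1)
  sim <- simulate_crac_reads(g, ann, factor_archetype("f", bin_weights = w),
                             n_reads = 20000, seed = 84,
                             class_weights = c(mRNA = 1), barcode_len = 0)
  m <- bin_occupancy(list(f = pileup_all(sim$reads, ann)))
  # read-weighted mean occupancy across genes approximates the weights
  cov <- setNames(table(sim$truth$transcript)[rownames(m)], rownames(m))
  est <- colSums(m * as.numeric(cov)) / sum(as.numeric(cov))
  expect_lt(sum(abs(est - w)), 0.05)
})

test_that("k = 1 medians is the coordinate-wise median and separated blobs split perfectly", {
  set.seed(85)
  x <- matrix(rnorm(100 * 4), 100)
  rownames(x) <- paste0("r", 1:100)
  km1 <- kmedians(x, k = 1, seed = 1, n_restarts = 2)
  expect_equal(unname(km1$medians[1, ]), unname(apply(x, 2, median)))

  blob <- rbind(matrix(rnorm(60 * 2, 0, 0.1), 60),
                matrix(rnorm(40 * 2, 5, 0.1), 40))
  rownames(blob) <- paste0("b", 1:100)
  km2 <- kmedians(blob, k = 2, seed = 2)
  expect_equal(unname(km2$assignment), rep(c(1L, 2L), c(60, 40)))
  expect_error(kmedians(blob, k = 200, seed = 1), "distinct rows")
})

test_that("planted archetypes are recovered and the objective never increases", {
  protos <- rbind(c(1, 0, 0, 0, 0), c(0, 0, 0, 0, 1), c(.5, .5, 0, 0, 0),
                  c(0, 0, .5, .5, 0), c(.2, .2, .2, .2, .2),
                  c(0, .5, 0, .5, 0))
  set.seed(86)
  lab <- sample(1:6, 600, replace = TRUE)
  x <- protos[lab, ] + matrix(rnorm(600 * 5, 0, 0.05), 600)
  rownames(x) <- paste0("g", 1:600)
  km <- kmedians(x, k = 6, seed = 3)
  expect_gte(ari(table(km$assignment, lab)), 0.95)
  for (tr in km$all_traces) expect_true(all(diff(tr) <= 1e-9))
  # row-permutation invariance up to cluster relabeling
  perm <- sample.int(nrow(x))
  km2 <- kmedians(x[perm, ], k = 6, seed = 3)
  expect_equal(ari(table(km$assignment[rownames(x)[perm]],
                         km2$assignment)), 1)
  # noise -> 0 gives perfect recovery
  x0 <- protos[lab, ] + matrix(rnorm(600 * 5, 0, 0.005), 600)
  rownames(x0) <- paste0("g", 1:600)
  expect_equal(ari(table(kmedians(x0, k = 6, seed = 4)$assignment, lab)), 1)
})

test_that("heat-map ordering groups by cluster and re-indexes held-out tables identically", {
  set.seed(87)
  x <- rbind(matrix(rnorm(30 * 3, 0, 0.1), 30),
             matrix(rnorm(30 * 3, 4, 0.1), 30))
  rownames(x) <- paste0("g", 1:60)
  km <- kmedians(x, k = 2, seed = 5)
  extra <- matrix(seq_len(60), 60, 1, dimnames = list(rownames(x), "rpm"))
  oh <- order_heatmap(km, x, list(side = extra))
  expect_setequal(oh$order, rownames(x))           # bijection on gene ids
  expect_true(all(diff(as.integer(oh$cluster)) >= 0))
  expect_equal(rownames(oh$extras$side), oh$order)
  # extra table equal to the clustering input keeps the same row order
  oh2 <- order_heatmap(km, x, list(self = x))
  expect_equal(rownames(oh2$extras$self), oh2$order)
  # missing genes become NA rows
  oh3 <- suppressMessages(
    order_heatmap(km, x, list(part = extra[1:50, , drop = FALSE])))
  expect_true(anyNA(oh3$extras$part))
})
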