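# Five-bin occupancy vectors, top-gene union selection, seeded k-medians,
# and heat-map row ordering with pass-through sorting of held-out data.

#' Select the union of top-bound genes across factors
#'
#' Ranks mRNAs per factor by replicate-averaged RPKM (descending; ties at
#' the cutoff broken by gene id) and returns the union of the per-factor
#' top-`n` sets.
#'
#' @param rpkm_per_factor Named list: factor -> named numeric vector of
#'   per-gene RPKM (mRNAs only, replicate-averaged).
#' @param n Number of genes per factor.
#' @return Sorted character vector of gene ids.
#' @export
select_top_union <- function(rpkm_per_factor, n = 1000) {
  tops <- lapply(rpkm_per_factor, function(v) {
    if (length(v) < n) {
      warning("fewer than ", n, " genes available; using all ", length(v))
      return(names(v))
    }
    ord <- order(-v, names(v))
    names(v)[ord][seq_len(n)]
  })
  sort(unique(unlist(tops)))
}

#' Five-bin occupancy matrix
#'
#' Each gene is divided into `n_bins` equal-length bins from TSS to pA
#' site (remainder nucleotides go to the last bin); the value of a bin is
#' the fraction of that gene's total binding for that factor falling in
#' the bin (per-gene total set to 1). Genes with zero coverage for a
#' factor contribute an all-zero block; genes shorter than `n_bins` are
#' excluded. Replicates should be averaged before calling.
#'
#' @param pileups_per_factor Named list: factor -> named list of 5'->3'
#'   pileup vectors (replicate-averaged).
#' @param genes Gene ids to include (rows).
#' @param n_bins Number of bins.
#' @return Matrix genes x (factor x bin), columns named `factor.bin1..5`,
#'   rows in `genes` order.
#' @export
bin_occupancy <- function(pileups_per_factor, genes = NULL, n_bins = 5L) {
  factors <- names(pileups_per_factor)
  if (is.null(genes)) genes <- names(pileups_per_factor[[1]])
  lens <- lengths(pileups_per_factor[[1]][genes])
  short <- lens < n_bins
  if (any(short)) {
    message("excluded ", sum(short), " gene(s) shorter than ", n_bins, " nt")
    genes <- genes[!short]
  }
  m <- matrix(0, nrow = length(genes), ncol = n_bins * length(factors),
              dimnames = list(genes, paste0(
                rep(factors, each = n_bins), ".bin", seq_len(n_bins))))
  for (fi in seq_along(factors)) {
    pl <- pileups_per_factor[[fi]]
    for (gi in seq_along(genes)) {
      v <- pl[[genes[gi]]]
      L <- length(v)
      edge <- floor(L / n_bins) * (0:(n_bins - 1L))
      edge <- c(edge, L)  # last bin takes the remainder
      b <- diff(c(0, cumsum(v)[edge[-1]]))
      tot <- sum(b)
      if (tot > 0)
        m[gi, (fi - 1L) * n_bins + seq_len(n_bins)] <- b / tot
    }
  }
  m
}

# Euclidean distances from rows of x to one centre
dist_to <- function(x, centre) sqrt(rowSums(sweep(x, 2, centre)^2))

# ++-style seeding: first centre uniform, then rows sampled with
# probability proportional to squared distance from the nearest chosen
# centre. Far more reliable than uniform row sampling at recovering
# well-separated archetypes.
init_centres <- function(x, k) {
  n <- nrow(x)
  idx <- sample.int(n, 1)
  dmin <- dist_to(x, x[idx, ])^2
  for (j in 2:k) {
    p <- if (sum(dmin) > 0) dmin / sum(dmin) else rep(1 / n, n)
    idx <- c(idx, sample.int(n, 1, prob = p))
    dmin <- pmin(dmin, dist_to(x, x[idx[j], ])^2)
  }
  x[idx, , drop = FALSE]
}

kmedians_once <- function(x, k, max_iter) {
  n <- nrow(x)
  centres <- init_centres(x, k)
  assign_prev <- rep(0L, n)
  trace <- numeric(0)
  obj_prev <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d <- vapply(seq_len(k), function(j) dist_to(x, centres[j, ]),
                numeric(n))
    assign <- max.col(-d, ties.method = "first")
    # re-seed empty clusters with the row farthest from its centre
    for (j in which(tabulate(assign, k) == 0)) {
      far <- which.max(d[cbind(seq_len(n), assign)])
      assign[far] <- j
      d[far, ] <- 0
    }
    obj <- sum(d[cbind(seq_len(n), assign)])
    if (obj > obj_prev + 1e-12) {
      # median update increased the Euclidean objective (possible since
      # per-dimension medians minimize L1, not L2): keep the previous
      # state and stop
      assign <- assign_keep
      centres <- centres_keep
      break
    }
    trace <- c(trace, obj)
    if (identical(assign, assign_prev) || iter >= max_iter) break
    assign_keep <- assign; centres_keep <- centres
    obj_prev <- obj
    assign_prev <- assign
    for (j in seq_len(k))
      centres[j, ] <- apply(x[assign == j, , drop = FALSE], 2,
                            stats::median)
  }
  list(assignment = assign, medians = centres, n_iter = iter,
       objective = trace[length(trace)], trace = trace)
}

#' k-medians clustering
#'
#' Lloyd-style iteration: assign each row to the nearest centre by
#' Euclidean distance, then update each centre to the per-dimension median
#' of its members; stop when assignments are stable. Empty clusters are
#' re-seeded with the row farthest from its centre. The best of
#' `n_restarts` runs (lowest within-cluster sum of Euclidean distances) is
#' returned; results are fully determined by `seed`. Cluster ids are
#' canonicalized by descending cluster size.
#'
#' @param x Numeric matrix (rows = genes, e.g. an occupancy matrix from
#'   [bin_occupancy()]).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param max_iter Iteration cap per restart.
#' @param n_restarts Independent random initializations.
#' @return List with `assignment` (named integer vector, 1..k),
#'   `medians` (k x ncol matrix), `n_iter`, `objective`, `trace`
#'   (objective per iteration of the winning run, non-increasing),
#'   `all_traces` (per-restart objective traces), `seed`.
#' @export
kmedians <- function(x, k = 6L, seed = 1L, max_iter = 100L,
                     n_restarts = 10L) {
  if (k > nrow(unique(as.data.frame(x))))
    stop("k exceeds the number of distinct rows")
  with_seed(seed, {
    best <- NULL
    all_traces <- vector("list", n_restarts)
    for (r in seq_len(n_restarts)) {
      run <- kmedians_once(x, k, max_iter)
      all_traces[[r]] <- run$trace
      if (is.null(best) || run$objective < best$objective) best <- run
    }
    best$all_traces <- all_traces
    # canonical labels: descending cluster size, ties by first occurrence
    sizes <- tabulate(best$assignment, k)
    relabel <- order(-sizes)
    map <- integer(k); map[relabel] <- seq_len(k)
    best$assignment <- stats::setNames(map[best$assignment], rownames(x))
    best$medians <- best$medians[relabel, , drop = FALSE]
    rownames(best$medians) <- paste0("cluster", seq_len(k))
    best$seed <- seed
    best
  })
}

#' Order heat-map rows by cluster, carrying held-out datasets along
#'
#' Rows are grouped by cluster id (ascending) and ordered within a cluster
#' by distance to the cluster median; every extra table is re-indexed to
#' the same row order (genes missing from an extra table become NA rows).
#'
#' @param result A [kmedians()] result.
#' @param x The clustered matrix (rows named by gene).
#' @param extra_tables Optional named list of matrices / data.frames
#'   indexed by gene id, not part of the clustering (e.g. per-gene RPM
#'   side panels), to be sorted identically.
#' @return List with `order` (gene ids), `cluster` (per ordered gene),
#'   `matrix` (reordered `x`), `extras` (reordered tables).
#' @export
order_heatmap <- function(result, x, extra_tables = NULL) {
  genes <- rownames(x)
  cl <- result$assignment[genes]
  d <- numeric(length(genes))
  for (j in sort(unique(cl))) {
    i <- which(cl == j)
    d[i] <- dist_to(x[i, , drop = FALSE], result$medians[j, ])
  }
  ord <- order(cl, d, genes)
  out_genes <- genes[ord]
  extras <- NULL
  if (!is.null(extra_tables)) {
    extras <- lapply(extra_tables, function(tab) {
      tab <- as.matrix(tab)
      missing <- setdiff(out_genes, rownames(tab))
      if (length(missing)) {
        message(length(missing), " gene(s) missing from extra table; NA")
        fill <- matrix(NA_real_, length(missing), ncol(tab),
                       dimnames = list(missing, colnames(tab)))
        tab <- rbind(tab, fill)
      }
      tab[out_genes, , drop = FALSE]
    })
  }
  list(order = out_genes, cluster = cl[ord],
       matrix = x[out_genes, , drop = FALSE], extras = extras)
}
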