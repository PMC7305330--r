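# Per-position, per-strand coverage with a declared normalization state.

#' Construct an empty coverage track
#'
#' A coverage track holds one numeric vector per chromosome per strand plus
#' the normalization state: `raw` (integer hit counts), `rpm_total`
#' (per million total mapped reads) or `rpm_mrna` (per million reads mapped
#' to mRNAs) — the latter two mirror the two normalizations used for
#' genome-wide profiles and for RNAPII-restricted peak calling.
#'
#' @param chrom_len Named integer vector of chromosome lengths.
#' @param norm_state One of `"raw"`, `"rpm_total"`, `"rpm_mrna"`.
#' @param total_mapped Read count the normalization divides by (NA for raw).
#' @return An object of class `CoverageTrack`.
#' @export
coverage_track <- function(chrom_len, norm_state = "raw",
                           total_mapped = NA_real_) {
  norm_state <- match.arg(norm_state, c("raw", "rpm_total", "rpm_mrna"))
  values <- lapply(chrom_len, function(n)
    list("+" = numeric(n), "-" = numeric(n)))
  structure(list(values = values,
                 chrom_len = chrom_len,
                 norm_state = norm_state,
                 total_mapped = total_mapped),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack:", length(x$values), "chromosome(s),",
      x$norm_state,
      if (!is.na(x$total_mapped)) paste0("(total_mapped=", x$total_mapped, ")")
      else "", "\n")
  invisible(x)
}

#' Pile reads into a raw coverage track
#'
#' Each read adds its weight to every position it covers, on its own
#' strand.
#'
#' @param reads A `read_table`.
#' @param chrom_len Named integer vector of chromosome lengths.
#' @return A raw `CoverageTrack` with `total_mapped` set to the summed read
#'   weights.
#' @export
coverage_from_reads <- function(reads, chrom_len) {
  track <- coverage_track(chrom_len, norm_state = "raw",
                          total_mapped = sum(reads$weight))
  if (!nrow(reads)) return(track)
  key <- split(seq_len(nrow(reads)),
               list(chrom = reads$chrom, strand = reads$strand), drop = TRUE)
  for (k in names(key)) {
    i <- key[[k]]
    chrom <- reads$chrom[i[1]]; s <- reads$strand[i[1]]
    n <- chrom_len[[chrom]]
    # difference-array accumulation: O(reads + chrom_len)
    d <- numeric(n + 1L)
    st <- pmax(reads$start[i], 0L) + 1L
    en <- pmin(reads$end[i], n) + 1L
    ok <- st < en
    for (j in which(ok)) {
      d[st[j]] <- d[st[j]] + reads$weight[i[j]]
      d[en[j]] <- d[en[j]] - reads$weight[i[j]]
    }
    track$values[[chrom]][[s]] <- track$values[[chrom]][[s]] +
      cumsum(d)[seq_len(n)]
  }
  track
}

#' Normalize a coverage track to reads per million
#'
#' @param track A raw `CoverageTrack`.
#' @param total_mapped Read count to normalize by. Defaults to the track's
#'   own `total_mapped` (RPM over all mapped reads); pass the mRNA-mapped
#'   count with `state = "rpm_mrna"` for mRNA-relative density.
#' @param state Normalization label to record.
#' @return A normalized `CoverageTrack`.
#' @export
normalize_track <- function(track, total_mapped = track$total_mapped,
                            state = "rpm_total") {
  stopifnot(is.finite(total_mapped), total_mapped > 0)
  state <- match.arg(state, c("rpm_total", "rpm_mrna"))
  f <- 1e6 / total_mapped
  track$values <- lapply(track$values, function(ch) lapply(ch, `*`, f))
  track$norm_state <- state
  track$total_mapped <- total_mapped
  track
}

#' Mask a coverage track to a set of transcripts
#'
#' Positions outside the given transcripts (on each transcript's own
#' strand) are zeroed. Used to restrict peak calling to RNAPII
#' transcription units before RPM normalization.
#'
#' @param track A `CoverageTrack`.
#' @param tx A `transcript_table` defining the kept regions.
#' @return The masked `CoverageTrack`.
#' @export
mask_track <- function(track, tx) {
  keep <- lapply(track$chrom_len, function(n)
    list("+" = logical(n), "-" = logical(n)))
  for (i in seq_len(nrow(tx))) {
    chrom <- tx$chrom[i]; s <- tx$strand[i]
    n <- track$chrom_len[[chrom]]
    i0 <- max(tx$start[i], 0L) + 1L; i1 <- min(tx$end[i], n)
    if (i0 <= i1) keep[[chrom]][[s]][i0:i1] <- TRUE
  }
  for (chrom in names(track$values))
    for (s in c("+", "-"))
      track$values[[chrom]][[s]][!keep[[chrom]][[s]]] <- 0
  track
}

#' Total signal in a track
#'
#' @param track A `CoverageTrack`.
#' @return Sum over all positions and strands.
#' @export
track_sum <- function(track) {
  sum(vapply(track$values, function(ch) sum(ch[["+"]]) + sum(ch[["-"]]),
             numeric(1)))
}

#' Average replicate coverage tracks position-wise
#'
#' @param tracks List of `CoverageTrack`s on the same genome, same
#'   normalization state.
#' @return The position-wise mean track.
#' @export
average_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  states <- unique(vapply(tracks, `[[`, "", "norm_state"))
  if (length(states) != 1)
    stop("tracks have mixed normalization states: ",
         paste(states, collapse = ", "))
  out <- tracks[[1]]
  if (length(tracks) == 1) return(out)
  for (chrom in names(out$values))
    for (s in c("+", "-")) {
      acc <- out$values[[chrom]][[s]]
      for (t in tracks[-1]) acc <- acc + t$values[[chrom]][[s]]
      out$values[[chrom]][[s]] <- acc / length(tracks)
    }
  out$total_mapped <- mean(vapply(tracks, `[[`, 1, "total_mapped"))
  out
}

#' Sum normalized hits over a region with flanks
#'
#' Sums track values over `[start - flank, end + flank)` on the given
#' strand; with several replicate tracks the per-replicate sums are
#' averaged and the sample standard deviation (n-1) reported, matching how
#' region-level signal (for example over the A2-A3 segment of ITS1) is
#' summarized with error bars.
#'
#' @param tracks A `CoverageTrack` or list of replicate tracks.
#' @param chrom,start,end Region (0-based half-open).
#' @param strand Strand of the signal.
#' @param flank Extension in nt on each side (default 10).
#' @return List with `mean`, `sd` (NA for a single track) and `values`
#'   (per-replicate sums).
#' @export
region_sum <- function(tracks, chrom, start, end, strand = "+", flank = 10L) {
  if (inherits(tracks, "CoverageTrack")) tracks <- list(tracks)
  n <- tracks[[1]]$chrom_len[[chrom]]
  if (is.null(n)) stop("unknown chromosome: ", chrom)
  i0 <- start - flank; i1 <- end + flank
  if (i0 < 0 || i1 > n)
    stop("region (with flank) outside chromosome ", chrom)
  vals <- vapply(tracks, function(t)
    sum(t$values[[chrom]][[strand]][(i0 + 1L):i1]), numeric(1))
  list(mean = mean(vals),
       sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
       values = vals)
}
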