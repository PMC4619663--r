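# Empirical permutation test for overlap between called regions and a
# peak track (e.g. transcription-factor binding sites). The null is
# built from "DMR-like" regions: runs of consecutive manifest probes
# with inter-probe gaps below 1 kb and an average of five CpGs per
# region, sampled uniformly from the array's probe space.

# Precomputed sampling structure. Chromosomes are laid out on a single
# linear axis (cumulative offsets with a wide spacer) so span-vs-peak
# overlap reduces to two findInterval() calls on sorted boundary
# vectors.
dmr_like_prep <- function(manifest, peaks, max_gap = 1000L) {
  manifest <- manifest[order(manifest$chrom, manifest$pos), , drop = FALSE]
  chroms <- unique(manifest$chrom)
  span <- vapply(chroms, function(ch) {
    max(manifest$pos[manifest$chrom == ch])
  }, 0)
  offset <- setNames(c(0, cumsum(span + 1e7))[seq_along(chroms)], chroms)
  abs_pos <- manifest$pos + offset[manifest$chrom]
  n <- nrow(manifest)
  # run[i]: number of consecutive probes starting at i with all
  # inter-probe gaps strictly below max_gap (same chromosome)
  ok <- c(diff(abs_pos) < max_gap, FALSE) &
    c(manifest$chrom[-1] == manifest$chrom[-n], FALSE)
  run <- integer(n)
  run[n] <- 1L
  for (i in (n - 1L):1L) run[i] <- if (ok[i]) run[i + 1L] + 1L else 1L
  ord <- order(run, decreasing = TRUE)
  max_run <- run[ord[1L]]
  cnt <- vapply(seq_len(max_run), function(k) sum(run >= k), 0L)
  pk <- GenomicRanges::reduce(GenomicRanges::sort(peaks))
  pk_chrom <- as.character(GenomicRanges::seqnames(pk))
  keep <- pk_chrom %in% chroms
  pk <- pk[keep]; pk_chrom <- pk_chrom[keep]
  pk_start <- sort(GenomicRanges::start(pk) + offset[pk_chrom])
  pk_end <- sort(GenomicRanges::end(pk) + offset[pk_chrom])
  list(manifest = manifest, abs_pos = abs_pos, run = run, ord = ord,
       cnt = cnt, max_run = max_run, pk_start = pk_start,
       pk_end = pk_end)
}

# Draw n non-overlapping (in probe space) DMR-like regions; returns
# start index and probe count per region.
draw_dmr_like <- function(prep, n, mean_cpgs = 5, min_cpgs = 3L,
                          max_tries = 100L) {
  if (prep$max_run < min_cpgs) {
    stop("manifest has no run of ", min_cpgs, " closely spaced probes")
  }
  k <- pmin(min_cpgs + stats::rpois(n, mean_cpgs - min_cpgs),
            prep$max_run)
  start <- rep(NA_integer_, n)
  need <- seq_len(n)
  for (try in seq_len(max_tries)) {
    u <- floor(stats::runif(length(need)) * prep$cnt[k[need]]) + 1
    start[need] <- prep$ord[u]
    o <- order(start)
    ends <- start + k - 1L
    prev_end <- cummax(c(-1L, ends[o][-n]))
    clash <- o[start[o] <= prev_end]
    if (length(clash) == 0) return(cbind(start = start, k = k))
    need <- clash
  }
  stop("could not place ", n, " non-overlapping DMR-like regions; ",
       "try fewer regions or a denser manifest")
}

#' Sample DMR-like regions from the probe manifest
#'
#' A DMR-like region starts at a uniformly chosen eligible probe and
#' spans `k` consecutive manifest probes with all inter-probe gaps below
#' `max_gap`, where `k = 3 + Poisson(mean_cpgs - 3)` so the expected
#' length is `mean_cpgs` CpGs with a minimum of 3 (matching the region
#' caller's minimum). Regions within one draw do not share probes.
#'
#' @param manifest probe manifest.
#' @param n_regions number of regions to draw.
#' @param mean_cpgs expected CpGs per region.
#' @param max_gap maximum inter-probe gap (exclusive), bp.
#' @return data.frame `chrom`, `start`, `end`, `n_probes`.
#' @export
sample_dmr_like <- function(manifest, n_regions, mean_cpgs = 5,
                            max_gap = 1000L) {
  prep <- dmr_like_prep(manifest, GenomicRanges::GRanges(), max_gap)
  d <- draw_dmr_like(prep, n_regions, mean_cpgs)
  idx_end <- d[, "start"] + d[, "k"] - 1L
  data.frame(
    chrom = prep$manifest$chrom[d[, "start"]],
    start = prep$manifest$pos[d[, "start"]],
    end = prep$manifest$pos[idx_end],
    n_probes = d[, "k"],
    stringsAsFactors = FALSE
  )
}

#' Permutation test for region-peak overlap
#'
#' The statistic is the number of regions whose genomic span intersects
#' at least one peak by >= 1 bp. The null distribution is built by
#' redrawing `n_regions` DMR-like regions from the manifest `n_perm`
#' times. The two-sided p-value doubles the smaller add-one-corrected
#' tail, capped at 1 (so it is never exactly 0: the smallest attainable
#' value is `2 / (n_perm + 1)`).
#'
#' @param observed_regions data.frame of called regions (`chrom`,
#'   `start`, `end`).
#' @param peaks `GRanges` of peaks.
#' @param manifest probe manifest the null regions are drawn from.
#' @param n_perm number of permutations.
#' @param seed optional integer seed set before drawing the null.
#' @param mean_cpgs,max_gap null-region geometry, see
#'   [sample_dmr_like()].
#' @return object of class `permutation_result`: `observed_overlap`,
#'   `null_overlaps`, `p_two_sided`, `n_perm`, `n_regions`, `seed`.
#' @export
permutation_overlap_test <- function(observed_regions, peaks, manifest,
                                     n_perm = 20000L, seed = NULL,
                                     mean_cpgs = 5, max_gap = 1000L) {
  if (nrow(observed_regions) == 0) stop("no observed regions")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  obs_gr <- GenomicRanges::GRanges(
    observed_regions$chrom,
    IRanges::IRanges(observed_regions$start, observed_regions$end))
  observed <- sum(IRanges::overlapsAny(obs_gr, peaks))
  prep <- dmr_like_prep(manifest, peaks, max_gap)
  n_regions <- nrow(observed_regions)
  null <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    d <- draw_dmr_like(prep, n_regions, mean_cpgs)
    a <- prep$abs_pos[d[, "start"]]
    z <- prep$abs_pos[d[, "start"] + d[, "k"] - 1L]
    hit <- findInterval(z, prep$pk_start) >
      findInterval(a - 1, prep$pk_end)
    null[b] <- sum(hit)
  }
  p_up <- (sum(null >= observed) + 1) / (n_perm + 1)
  p_lo <- (sum(null <= observed) + 1) / (n_perm + 1)
  structure(list(
    observed_overlap = observed,
    null_overlaps = null,
    p_two_sided = min(1, 2 * min(p_up, p_lo)),
    n_perm = n_perm,
    n_regions = n_regions,
    seed = seed
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed=%d/%d null mean=%.2f p=%.3g (n_perm=%d)\n",
    x$observed_overlap, x$n_regions, mean(x$null_overlaps),
    x$p_two_sided, x$n_perm))
  invisible(x)
}
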