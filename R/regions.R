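# Consecutive-CpG region calling (tHRs and dDMRs).
#
# A region is a run of array probes, bounded by criterion-matching CpGs,
# containing at least `min_matching` matching CpGs and at most
# `max_nonmatching` non-matching CpGs in total, with every pair of
# adjacent member probes at most `max_gap` bp apart. The normative
# semantics is the maximal-interval one: among all probe intervals
# satisfying those constraints, intervals contained in another valid
# interval are discarded; remaining overlapping candidates are resolved
# deterministically by keeping the leftmost-starting (then, on an equal
# start, the longer) and skipping candidates that share probes with an
# already kept region.

#' Call regions of consecutive matching CpGs
#'
#' @param manifest probe manifest (`probe_id`, `chrom`, `pos`), sorted by
#'   (chromosome, position); unsorted input is an error.
#' @param match logical vector, one flag per manifest probe: does the
#'   probe match the calling criterion? Probes discarded upstream (e.g.
#'   by an SD filter) are treated as non-matching by default; set
#'   `drop_na = TRUE` to remove `NA`-flagged probes from the manifest
#'   before calling instead.
#' @param max_gap maximum distance (bp) between adjacent member probes.
#' @param min_matching minimum number of matching CpGs per region.
#' @param max_nonmatching maximum number of non-matching CpGs per region
#'   (a total budget, not a per-run one).
#' @param kind label stored on the emitted regions (e.g. `"tHR"`,
#'   `"dDMR_gom"`).
#' @param tissue tissue label stored on the emitted regions.
#' @param drop_na see `match`.
#' @return data.frame with one row per region: `chrom`, `start`, `end`
#'   (1-based positions of the first and last matching CpG), `kind`,
#'   `tissue`, `n_matching`, `n_nonmatching`, `n_probes`, and a list
#'   column `probes` of member probe ids in positional order.
#' @export
call_regions <- function(manifest, match, max_gap = 1000L,
                         min_matching = 3L, max_nonmatching = 3L,
                         kind = "region", tissue = NA_character_,
                         drop_na = FALSE) {
  if (length(match) != nrow(manifest)) {
    stop("match must have one flag per manifest probe")
  }
  if (drop_na) {
    keep <- !is.na(match)
    manifest <- manifest[keep, , drop = FALSE]
    match <- match[keep]
  } else {
    match[is.na(match)] <- FALSE
  }
  ord <- order(manifest$chrom, manifest$pos)
  if (!identical(ord, seq_len(nrow(manifest)))) {
    stop("manifest must be sorted by (chrom, pos)")
  }
  out <- list()
  for (chr in unique(manifest$chrom)) {
    idx <- which(manifest$chrom == chr)
    pos <- manifest$pos[idx]
    flg <- match[idx]
    # split where adjacent probes are farther apart than max_gap
    brk <- c(0L, which(diff(pos) > max_gap), length(pos))
    for (s in seq_len(length(brk) - 1L)) {
      seg <- (brk[s] + 1L):brk[s + 1L]
      regs <- scan_segment(pos[seg], flg[seg], min_matching,
                           max_nonmatching)
      if (is.null(regs)) next
      for (r in seq_len(nrow(regs))) {
        mem <- seg[regs$from[r]:regs$to[r]]
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr,
          start = pos[seg][regs$from[r]],
          end = pos[seg][regs$to[r]],
          kind = kind, tissue = tissue,
          n_matching = regs$n_match[r],
          n_nonmatching = regs$n_nonmatch[r],
          n_probes = length(mem),
          probes = I(list(manifest$probe_id[idx][mem])),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) return(empty_regions())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_regions <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             kind = character(), tissue = character(),
             n_matching = integer(), n_nonmatching = integer(),
             n_probes = integer(), probes = I(list()),
             stringsAsFactors = FALSE)
}

# One gap-free segment. For each matching start the farthest matching
# end within the mismatch budget is found through the non-matching
# prefix count (two-pointer equivalent); intervals sharing an end are
# containment-duplicates of the leftmost one, and survivors are selected
# greedily left to right.
scan_segment <- function(pos, flg, min_matching, max_nonmatching) {
  mi <- which(flg)
  if (length(mi) < min_matching) return(NULL)
  nm <- cumsum(!flg)
  nm_at_m <- nm[mi]
  # q[p]: index (into mi) of the last matching probe reachable from the
  # p-th matching probe without exceeding the budget
  q <- findInterval(nm_at_m + max_nonmatching, nm_at_m)
  n_match <- q - seq_along(mi) + 1L
  first <- c(TRUE, q[-1L] > q[-length(q)])  # containment-maximal only
  cand <- which(first & n_match >= min_matching)
  if (length(cand) == 0) return(NULL)
  # greedy non-overlap selection in start order
  res <- list()
  last_end <- -Inf
  for (p in cand) {
    if (mi[p] <= last_end) next
    res[[length(res) + 1L]] <- c(from = mi[p], to = mi[q[p]],
                                 n_match = n_match[p],
                                 n_nonmatch = nm[mi[q[p]]] - nm[mi[p]])
    last_end <- mi[q[p]]
  }
  as.data.frame(do.call(rbind, res))
}

#' Convert called regions to a BED-convention interval track
#'
#' A region spanning 1-based positions `[start, end]` becomes the
#' half-open interval `(start - 1, end]`, so [read_bed()] on the written
#' file covers exactly the same 1-based positions.
#'
#' @param regions data.frame from [call_regions()].
#' @return `GRanges` labelled by region kind.
#' @export
regions_to_bed <- function(regions) {
  if (nrow(regions) == 0) return(GenomicRanges::GRanges())
  granges_from_bed0(regions$chrom, regions$start - 1L, regions$end,
                    label = regions$kind)
}
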