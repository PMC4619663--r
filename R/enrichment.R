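# 2x2 odds-ratio enrichment of called probe sets against categorical
# annotations, nearest-gene mapping, and signal metaprofiles around
# called regions.

#' 2x2 odds ratio with Haldane-Anscombe correction
#'
#' `OR = (a*d)/(b*c)`; when any cell is zero, 0.5 is added to all four
#' cells first.
#'
#' @param a,b,c,d cell counts of the 2x2 table (rows: called /
#'   background; columns: in category / not).
#' @return the odds ratio, a positive number.
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}

#' Odds-ratio enrichment of a called set against categories
#'
#' For every category the 2x2 table is: `a` called probes in the
#' category, `b` called probes outside it, `c` background probes in the
#' category, `d` background probes outside it (the background includes
#' the called probes). The odds ratio is `(a*d)/(b*c)`; when any cell is
#' zero the Haldane-Anscombe correction adds 0.5 to all four cells
#' before forming the ratio. The p-value is the Pearson chi-squared test
#' (1 df, no continuity correction) on the uncorrected table.
#'
#' @param called character vector of called probe ids; must be a subset
#'   of `background`.
#' @param background character vector of background probe ids (all
#'   QC-passing probes on the array).
#' @param labels category per background probe: a named character/factor
#'   vector covering `background`.
#' @return data.frame with one row per category: `category`, `a`, `b`,
#'   `c`, `d`, `odds_ratio`, `chi2_p`.
#' @export
enrichment_or <- function(called, background, labels) {
  if (!all(called %in% background)) {
    stop("called set is not a subset of the background")
  }
  if (!all(background %in% names(labels))) {
    stop("labels do not cover the background set")
  }
  lab_bg <- as.character(labels[background])
  lab_called <- as.character(labels[called])
  cats <- sort(unique(lab_bg))
  res <- lapply(cats, function(cat) {
    a <- sum(lab_called == cat)
    b <- length(called) - a
    c_ <- sum(lab_bg == cat)
    d <- length(background) - c_
    or <- odds_ratio_2x2(a, b, c_, d)
    p <- tryCatch(
      suppressWarnings(stats::chisq.test(
        matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE),
        correct = FALSE)$p.value),
      error = function(e) NA_real_)
    data.frame(category = cat, a = a, b = b, c = c_, d = d,
               odds_ratio = or, chi2_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Label probes by the chromatin state covering them
#'
#' @param manifest probe manifest.
#' @param segmentation `GRanges` of chromatin states with a `name`
#'   metadata column of state labels; states are expected to partition
#'   the covered bases. A probe covered by several intervals (only
#'   possible for a malformed segmentation) takes the first overlapping
#'   interval in sorted order; a probe outside every state is labelled
#'   `"unsegmented"`.
#' @return named character vector of state labels per probe.
#' @export
probe_states <- function(manifest, segmentation) {
  probes <- probe_granges(manifest)
  lab <- rep("unsegmented", length(probes))
  if (length(segmentation) > 0) {
    seg <- GenomicRanges::sort(segmentation)
    hits <- GenomicRanges::findOverlaps(probes, seg, select = "first")
    got <- !is.na(hits)
    lab[got] <- as.character(S4Vectors::mcols(seg)$name)[hits[got]]
  }
  setNames(lab, manifest$probe_id)
}

#' Enrichment of a called set across chromatin states
#'
#' Induces a per-probe state label from the segmentation track and runs
#' [enrichment_or()] on it.
#'
#' @inheritParams enrichment_or
#' @inheritParams probe_states
#' @return data.frame as in [enrichment_or()], one row per state.
#' @export
chromatin_state_enrichment <- function(called, background, manifest,
                                       segmentation) {
  labels <- probe_states(manifest, segmentation)
  enrichment_or(called, background, labels)
}

#' Map probes or regions to their nearest gene
#'
#' The nearest gene minimises the distance from the query position (a
#' probe's coordinate, or a region's midpoint) to the nearer of the
#' gene's TSS and TES; positions between the gene's span endpoints have
#' distance 0. Ties are broken by the smaller TSS distance, then by
#' lexicographic gene id. The signed distance is the strand-aware offset
#' from the nearer endpoint: negative upstream of the TSS, positive
#' downstream of the TES, 0 inside the span.
#'
#' @param items data.frame of queries: probes (`probe_id`, `chrom`,
#'   `pos`) or regions (`chrom`, `start`, `end`; midpoint is used).
#' @param genes gene-model data.frame.
#' @return data.frame with `chrom`, `pos`, `gene_id`, `distance`
#'   (non-negative), `signed_distance`; `NA` gene when the query's
#'   chromosome has no genes.
#' @export
nearest_gene <- function(items, genes) {
  if (nrow(genes) == 0) stop("gene set is empty")
  pos <- if ("pos" %in% colnames(items)) items$pos else
    (items$start + items$end) %/% 2L
  chrom <- items$chrom
  n <- length(pos)
  out <- data.frame(chrom = chrom, pos = pos,
                    gene_id = NA_character_, distance = NA_real_,
                    signed_distance = NA_real_,
                    stringsAsFactors = FALSE)
  for (chr in unique(chrom)) {
    gi <- which(genes$chrom == chr)
    qi <- which(chrom == chr)
    if (length(gi) == 0) next
    g <- genes[gi, , drop = FALSE]
    tss <- ifelse(g$strand == "+", g$tx_start, g$tx_end)
    tes <- ifelse(g$strand == "+", g$tx_end, g$tx_start)
    lo <- pmin(g$tx_start, g$tx_end)
    hi <- pmax(g$tx_start, g$tx_end)
    for (q in qi) {
      p <- pos[q]
      d_tss <- abs(p - tss)
      d_tes <- abs(p - tes)
      d <- pmin(d_tss, d_tes)
      d[p >= lo & p <= hi] <- 0
      best <- order(d, d_tss, g$gene_id)[1L]
      out$gene_id[q] <- g$gene_id[best]
      out$distance[q] <- d[best]
      dir <- if (g$strand[best] == "+") 1L else -1L
      out$signed_distance[q] <- if (d[best] == 0) 0 else {
        if (d_tss[best] <= d_tes[best]) (p - tss[best]) * dir
        else (p - tes[best]) * dir
      }
    }
  }
  out
}

#' Mean signal profile around regions
#'
#' Each region plus `flank` bp on either side is mapped onto a common
#' axis: the first quarter of the bins covers the upstream flank, the
#' middle half the (length-scaled) region body, the last quarter the
#' downstream flank. Signal intervals are reduced to their midpoints,
#' weighted by a `score` metadata column when present (tag count 1
#' otherwise); per bin, weights are summed within each region and then
#' averaged across regions.
#'
#' @param signal `GRanges` of tags or scored intervals.
#' @param regions data.frame from [call_regions()] (or any data.frame
#'   with `chrom`, `start`, `end`).
#' @param flank flank size in bp on each side.
#' @param n_bins total number of bins across flank + body + flank.
#' @return numeric vector of per-bin mean signal, length `n_bins`.
#' @export
region_metaprofile <- function(signal, regions, flank = 5000L,
                               n_bins = 20L) {
  stopifnot(n_bins >= 1)
  prof <- matrix(0, nrow = nrow(regions), ncol = n_bins)
  if (nrow(regions) == 0) return(rep(0, n_bins))
  tag_chrom <- as.character(GenomicRanges::seqnames(signal))
  tag_pos <- (GenomicRanges::start(signal) +
                GenomicRanges::end(signal)) %/% 2L
  w <- S4Vectors::mcols(signal)$score
  if (is.null(w)) w <- rep(1, length(signal))
  for (r in seq_len(nrow(regions))) {
    s <- regions$start[r]; e <- regions$end[r]
    sel <- tag_chrom == regions$chrom[r] &
      tag_pos >= s - flank & tag_pos <= e + flank
    if (!any(sel)) next
    p <- tag_pos[sel]
    x <- numeric(length(p))
    up <- p < s; dn <- p > e; body <- !up & !dn
    x[up] <- 0.25 * (p[up] - (s - flank)) / flank
    x[body] <- if (e > s) 0.25 + 0.5 * (p[body] - s) / (e - s) else 0.5
    x[dn] <- 0.75 + 0.25 * (p[dn] - e) / flank
    bin <- pmin(pmax(ceiling(x * n_bins), 1L), n_bins)
    for (k in seq_along(bin)) prof[r, bin[k]] <- prof[r, bin[k]] + w[sel][k]
  }
  colMeans(prof)
}
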