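# CpG annotation on two independent axes:
#   CGI-centric: CGI / shore (SHO) / shelf (SHE) / non-CGI (NC)
#   genic:       distal promoter (DP) / proximal promoter (PP) /
#                gene body (GB) / downstream (DS) / intergenic (IG)

CGI_CLASSES <- c("CGI", "SHO", "SHE", "NC")
GENIC_CLASSES <- c("PP", "DP", "GB", "DS", "IG")

#' Classify probes relative to CpG islands
#'
#' A probe inside a (merged) CpG island is `CGI`; within 2 kb of an
#' island edge, `SHO` (shore); within 2-4 kb, `SHE` (shelf); beyond 4 kb
#' (or on a chromosome without islands), `NC`. Boundaries are inclusive
#' toward the class nearer the island: a probe at exactly 2,000 bp is a
#' shore, at exactly 4,000 bp a shelf.
#'
#' @param manifest probe manifest (`probe_id`, `chrom`, `pos`).
#' @param cgi_track `GRanges` of CpG islands (overlapping islands are
#'   merged before distance computation).
#' @param shore_bp,shelf_bp shore and shelf half-widths in bp.
#' @return factor of classes (`CGI`, `SHO`, `SHE`, `NC`), one per
#'   manifest probe, named by probe id.
#' @export
classify_cgi <- function(manifest, cgi_track, shore_bp = 2000L,
                         shelf_bp = 2000L) {
  probes <- probe_granges(manifest)
  cls <- rep("NC", length(probes))
  if (length(cgi_track) > 0) {
    merged <- GenomicRanges::reduce(cgi_track)
    inside <- IRanges::overlapsAny(probes, merged)
    hits <- GenomicRanges::distanceToNearest(probes, merged)
    # GRanges gap distance counts positions strictly between the ranges;
    # edge distance for a non-overlapping probe is gap + 1.
    d <- rep(Inf, length(probes))
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance + 1
    cls[d <= shore_bp + shelf_bp] <- "SHE"
    cls[d <= shore_bp] <- "SHO"
    cls[inside] <- "CGI"
  }
  setNames(factor(cls, levels = CGI_CLASSES), manifest$probe_id)
}

# Strand-aware genic windows as genomic intervals; offsets are relative
# to the TSS in the direction of transcription.
genic_windows <- function(genes, promoter_distal = c(-10000L, -1501L),
                          promoter_proximal = c(-1500L, 500L),
                          body_offset = 501L, downstream_bp = 5000L) {
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$tx_start, genes$tx_end)
  tes <- ifelse(plus, genes$tx_end, genes$tx_start)
  dir <- ifelse(plus, 1L, -1L)
  win <- function(off1, off2) {
    a <- tss + dir * off1
    b <- tss + dir * off2
    data.frame(chrom = genes$chrom, start = pmin(a, b), end = pmax(a, b))
  }
  gene_len <- abs(genes$tx_end - genes$tx_start)
  list(
    PP = win(promoter_proximal[1], promoter_proximal[2]),
    DP = win(promoter_distal[1], promoter_distal[2]),
    GB = {
      w <- win(body_offset, gene_len)
      w[gene_len >= body_offset, , drop = FALSE]
    },
    DS = {
      a <- tes + dir * 1L
      b <- tes + dir * downstream_bp
      data.frame(chrom = genes$chrom, start = pmin(a, b), end = pmax(a, b))
    }
  )
}

#' Classify probes relative to gene models
#'
#' Windows are strand-aware around the transcription start (TSS) and end
#' (TES): distal promoter `DP` (-10 kb to -1.5 kb of the TSS), proximal
#' promoter `PP` (-1.5 kb to +0.5 kb), gene body `GB` (+0.5 kb to the
#' TES), downstream `DS` (TES to +5 kb past it); anything else is
#' intergenic `IG`. A probe falling in windows of several genes or
#' window types takes the highest-precedence class.
#'
#' @param manifest probe manifest.
#' @param genes gene models (`gene_id`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`).
#' @param precedence order in which competing window classes win;
#'   default `PP > DP > GB > DS`.
#' @return factor of classes (`PP`, `DP`, `GB`, `DS`, `IG`), one per
#'   probe, named by probe id.
#' @export
classify_genic <- function(manifest, genes,
                           precedence = c("PP", "DP", "GB", "DS")) {
  stopifnot(setequal(precedence, c("PP", "DP", "GB", "DS")))
  probes <- probe_granges(manifest)
  wins <- genic_windows(genes)
  cls <- rep("IG", nrow(manifest))
  for (k in rev(precedence)) {
    w <- wins[[k]]
    w <- w[w$start <= w$end, , drop = FALSE]
    if (nrow(w) == 0) next
    w$start <- pmax(w$start, 1L)
    gr <- GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$start, w$end))
    cls[IRanges::overlapsAny(probes, gr)] <- k
  }
  setNames(factor(cls, levels = GENIC_CLASSES), manifest$probe_id)
}

#' Annotate all probes on both axes
#'
#' @inheritParams classify_cgi
#' @inheritParams classify_genic
#' @return data.frame `probe_id`, `cgi_class`, `genic_class`.
#' @export
annotate_probes <- function(manifest, cgi_track, genes) {
  data.frame(
    probe_id = manifest$probe_id,
    cgi_class = classify_cgi(manifest, cgi_track),
    genic_class = classify_genic(manifest, genes),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Median methylation per combined feature
#'
#' For every (tissue, week) cell, probe-level replicate means are
#' computed; the median over probes is then reported for each combined
#' CGI x genic feature. Empty feature cells are reported as `NA`.
#'
#' @param beta probes x samples beta matrix.
#' @param meta sample sheet.
#' @param labels annotation data.frame from [annotate_probes()].
#' @return data.frame `cgi_class`, `genic_class`, `tissue`, `week`,
#'   `median_beta`, `n_probes`.
#' @export
median_by_feature <- function(beta, meta, labels) {
  if (!all(rownames(beta) %in% labels$probe_id)) {
    stop("labels do not cover all probes in the beta matrix")
  }
  gs <- group_stats(beta, meta)
  lab <- labels[match(rownames(beta), labels$probe_id), ]
  feat <- interaction(lab$cgi_class, lab$genic_class, drop = FALSE)
  out <- expand.grid(feature = levels(feat),
                     gi = seq_len(nrow(gs$groups)))
  res <- lapply(seq_len(nrow(out)), function(i) {
    sel <- feat == out$feature[i]
    x <- gs$mean[sel, out$gi[i]]
    x <- x[!is.na(x)]
    c(median = if (length(x)) stats::median(x) else NA_real_,
      n = length(x))
  })
  res <- do.call(rbind, res)
  parts <- strsplit(as.character(out$feature), ".", fixed = TRUE)
  data.frame(
    cgi_class = vapply(parts, `[`, "", 1L),
    genic_class = vapply(parts, `[`, "", 2L),
    tissue = gs$groups$tissue[out$gi],
    week = gs$groups$week[out$gi],
    median_beta = res[, "median"],
    n_probes = as.integer(res[, "n"]),
    stringsAsFactors = FALSE
  )
}

#' Fractions of probes in low / intermediate / high methylation classes
#'
#' Per (tissue, week) cell, probe replicate means are binned into three
#' classes split at the given thresholds (default 0.25 and 0.75), using
#' left-closed intervals `[0, t1)`, `[t1, t2)`, `[t2, 1]`.
#'
#' @param beta probes x samples beta matrix.
#' @param meta sample sheet.
#' @param thresholds two strictly increasing values in (0, 1).
#' @return data.frame `tissue`, `week`, `hypo`, `intermediate`, `hyper`;
#'   the three fractions sum to 1 per row.
#' @export
methylation_class_fractions <- function(beta, meta,
                                        thresholds = c(0.25, 0.75)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2],
            thresholds[1] > 0, thresholds[2] < 1)
  gs <- group_stats(beta, meta)
  out <- gs$groups
  frac <- t(apply(gs$mean, 2, function(m) {
    m <- m[!is.na(m)]
    cls <- findInterval(m, thresholds)
    tabulate(cls + 1L, nbins = 3L) / length(m)
  }))
  out$hypo <- frac[, 1]
  out$intermediate <- frac[, 2]
  out$hyper <- frac[, 3]
  out
}
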