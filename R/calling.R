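# Threshold-based probe callers. All comparisons are made on replicate
# means per (tissue, week) cell, with inclusive (>=) thresholds; sample
# SDs use the n-1 denominator.

new_call_set <- function(kind, tissue, probes, stats) {
  structure(list(kind = kind, tissue = tissue, probes = probes,
                 stats = stats),
            class = "call_set")
}

#' @export
print.call_set <- function(x, ...) {
  cat(sprintf("<call_set> kind=%s tissue=%s n_probes=%d\n",
              x$kind, x$tissue, length(x$probes)))
  invisible(x)
}

#' Probe quality-control filtering
#'
#' An observation (probe x sample) fails QC if its bead count is below
#' `bead_min` or its detection p-value exceeds `detp_max`. A probe is
#' retained only if its fraction of passing observations is at least
#' `success_min` (the boundary is inclusive: exactly 95% passes) and it
#' is not on the ambiguous-mapping exclusion list.
#'
#' @param detection_p probe x sample matrix of detection p-values.
#' @param bead_count probe x sample integer matrix of bead counts.
#' @param bead_min minimum bead count for a passing observation.
#' @param detp_max maximum detection p-value for a passing observation.
#' @param success_min minimum fraction of passing observations per probe.
#' @param exclude character vector of probe ids to drop regardless
#'   (e.g. ambiguously mapped probes).
#' @return character vector of retained probe ids.
#' @export
filter_probes <- function(detection_p, bead_count, bead_min = 3L,
                          detp_max = 0.01, success_min = 0.95,
                          exclude = character()) {
  if (!identical(dim(detection_p), dim(bead_count)) ||
      !identical(rownames(detection_p), rownames(bead_count))) {
    stop("detection_p and bead_count matrices are not aligned")
  }
  fail <- bead_count < bead_min | detection_p > detp_max
  success <- 1 - rowMeans(fail)
  keep <- success >= success_min & !(rownames(detection_p) %in% exclude)
  rownames(detection_p)[keep]
}

#' Call tissue-specific hypomethylated CpGs
#'
#' A probe is first discarded if the standard deviation of its beta
#' values across all samples of the target tissue (replicates pooled
#' over weeks) is `>= sd_max`, indicating an unstable estimate. It is
#' then called hypomethylated in the target tissue iff, at every week
#' and against every other tissue, the other tissue's replicate mean
#' exceeds the target's by at least `delta` (inclusive).
#'
#' @param beta probes x samples beta matrix.
#' @param meta sample sheet; every (tissue, week) cell must be nonempty.
#' @param target_tissue tissue label to test.
#' @param sd_max discard threshold on the within-target-tissue SD.
#' @param delta minimum beta difference, applied per week per other
#'   tissue.
#' @param compare `"every"` (default) requires the difference against
#'   each other tissue at each week; `"max"` requires it only against
#'   the most methylated other tissue at each week (a weaker reading).
#' @return a `call_set` with kind `"tissue_hypo"`; `$stats` carries
#'   per-week means, the pooled SD and the minimum per-week difference
#'   for every probe that survived the SD filter.
#' @export
call_tissue_hypomethylation <- function(beta, meta, target_tissue,
                                        sd_max = 0.1, delta = 0.20,
                                        compare = c("every", "max")) {
  compare <- match.arg(compare)
  tissues <- unique(meta$tissue)
  if (length(tissues) < 2) stop("need at least 2 tissues")
  if (!target_tissue %in% tissues) {
    stop("unknown target tissue: ", target_tissue)
  }
  weeks <- sort(unique(meta$week))
  check_cells(meta, tissues, weeks)

  gs <- group_stats(beta, meta)
  tcols <- which(colnames(beta) %in%
                   meta$sample_id[meta$tissue == target_tissue])
  x <- beta[, tcols, drop = FALSE]
  pooled_sd <- sqrt(rowSums((x - rowMeans(x))^2) / (ncol(x) - 1))

  other <- setdiff(tissues, target_tissue)
  # per week: difference against every other tissue ("every", the strict
  # reading) or against the most methylated one ("max"); min_diff is the
  # binding difference over weeks
  min_diff <- rep(Inf, nrow(beta))
  for (w in weeks) {
    tg <- gs$mean[, group_key(target_tissue, w)]
    dw <- if (compare == "every") rep(Inf, nrow(beta)) else
      rep(-Inf, nrow(beta))
    for (ot in other) {
      d <- gs$mean[, group_key(ot, w)] - tg
      dw <- if (compare == "every") pmin(dw, d) else pmax(dw, d)
    }
    min_diff <- pmin(min_diff, dw)
  }
  eligible <- !is.na(pooled_sd) & pooled_sd < sd_max &
    !is.na(min_diff) & is.finite(min_diff)
  called <- eligible & min_diff >= delta

  stats <- data.frame(
    probe_id = rownames(beta),
    gs$mean[, group_key(target_tissue, weeks), drop = FALSE],
    sd_target = pooled_sd,
    min_diff = min_diff,
    called = called,
    row.names = NULL, check.names = FALSE, stringsAsFactors = FALSE
  )
  colnames(stats)[2:(1 + length(weeks))] <- paste0("mean_W", weeks)
  new_call_set("tissue_hypo", target_tissue, rownames(beta)[called],
               stats[eligible, , drop = FALSE])
}

check_cells <- function(meta, tissues, weeks) {
  for (t in tissues) for (w in weeks) {
    if (!any(meta$tissue == t & meta$week == w)) {
      stop(sprintf("design cell (%s, week %d) has no samples", t, w))
    }
  }
  invisible(TRUE)
}

#' Call gain and loss of methylation over gestation
#'
#' Within one tissue, a probe is discarded if the replicate SD within
#' any (tissue, week) cell is `>= sd_max` (or if a cell has fewer than
#' two replicates, leaving the SD undefined). Gain of methylation (GOM)
#' requires `mean(W22) - mean(W9) >= delta` with the mid week allowed to
#' undershoot W9 or overshoot W22 by at most `w18_tol`; loss of
#' methylation (LOM) is the mirror image.
#'
#' @param beta probes x samples beta matrix.
#' @param meta sample sheet; the tissue must have all three weeks.
#' @param tissue tissue to analyse.
#' @param delta minimum absolute beta change between the first and last
#'   week.
#' @param w18_tol tolerance on the mid-week mean relative to the
#'   bracketing weeks.
#' @param sd_max discard threshold on the within-cell replicate SD.
#' @param weeks the three gestational weeks, in increasing order.
#' @return list with `call_set`s `gom` and `lom`; each `$stats` has
#'   per-week means and SDs for the probes surviving the SD filter.
#' @export
call_dynamic <- function(beta, meta, tissue, delta = 0.20,
                         w18_tol = 0.05, sd_max = 0.10,
                         weeks = c(9L, 18L, 22L)) {
  stopifnot(length(weeks) == 3)
  sub <- meta[meta$tissue == tissue, , drop = FALSE]
  if (!all(weeks %in% sub$week)) {
    stop(sprintf("tissue %s lacks week(s) %s", tissue,
                 paste(setdiff(weeks, sub$week), collapse = ", ")))
  }
  cols <- colnames(beta) %in% sub$sample_id
  gs <- group_stats(beta[, cols, drop = FALSE], sub)
  keys <- group_key(tissue, weeks)
  m <- gs$mean[, keys, drop = FALSE]
  s <- gs$sd[, keys, drop = FALSE]
  if (any(gs$n[match(keys, group_key(gs$groups$tissue, gs$groups$week))] < 2)) {
    warning(sprintf(
      "tissue %s: some (tissue, week) cells have < 2 replicates; %s",
      tissue, "their probes are excluded (SD undefined)"))
  }
  sd_ok <- rowSums(is.na(s) | s >= sd_max) == 0
  complete <- rowSums(is.na(m)) == 0
  eligible <- sd_ok & complete

  m9 <- m[, 1]; m18 <- m[, 2]; m22 <- m[, 3]
  gom <- eligible & (m22 - m9 >= delta) &
    (m18 >= m9 - w18_tol) & (m18 <= m22 + w18_tol)
  lom <- eligible & (m9 - m22 >= delta) &
    (m18 <= m9 + w18_tol) & (m18 >= m22 - w18_tol)

  stats <- data.frame(
    probe_id = rownames(beta), m, s,
    delta_obs = m22 - m9,
    row.names = NULL, check.names = FALSE, stringsAsFactors = FALSE
  )
  colnames(stats)[2:7] <- c(paste0("mean_W", weeks), paste0("sd_W", weeks))
  list(
    gom = new_call_set("gom", tissue, rownames(beta)[gom],
                       cbind(stats, called = gom)[eligible, ]),
    lom = new_call_set("lom", tissue, rownames(beta)[lom],
                       cbind(stats, called = lom)[eligible, ])
  )
}
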