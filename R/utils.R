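# Replicate-group summaries shared by the annotation summaries and the
# probe callers. A "group" is one (tissue, week) cell of the design.

#' Per-probe replicate-group means and standard deviations
#'
#' Computes, for every probe, the mean and (n-1 denominator) standard
#' deviation of beta across the replicates of each (tissue, week) cell.
#' A probe with a missing beta in a cell gets `NA` for that cell's mean
#' and SD: missing observations exclude the probe from that group's
#' statistics rather than being silently dropped.
#'
#' @param beta numeric matrix, probes x samples.
#' @param meta sample sheet; `sample_id` must cover `colnames(beta)`.
#' @return list with `groups` (data.frame `tissue`, `week`), `mean` and
#'   `sd` (probe x group matrices, columns named `tissue.week`), and `n`
#'   (replicates per group).
#' @export
group_stats <- function(beta, meta) {
  if (!all(colnames(beta) %in% meta$sample_id)) {
    stop("beta columns missing from sample sheet: ",
         paste(setdiff(colnames(beta), meta$sample_id), collapse = ", "))
  }
  meta <- meta[match(colnames(beta), meta$sample_id), , drop = FALSE]
  key <- paste(meta$tissue, meta$week, sep = ".")
  groups <- unique(data.frame(tissue = meta$tissue, week = meta$week,
                              key = key, stringsAsFactors = FALSE))
  groups <- groups[order(groups$tissue, groups$week), , drop = FALSE]
  gmean <- matrix(NA_real_, nrow(beta), nrow(groups),
                  dimnames = list(rownames(beta), groups$key))
  gsd <- gmean
  gn <- integer(nrow(groups))
  for (i in seq_len(nrow(groups))) {
    cols <- which(key == groups$key[i])
    gn[i] <- length(cols)
    x <- beta[, cols, drop = FALSE]
    m <- rowMeans(x)
    gmean[, i] <- m
    if (length(cols) >= 2) {
      gsd[, i] <- sqrt(rowSums((x - m)^2) / (length(cols) - 1))
    }
  }
  list(groups = groups[, c("tissue", "week")], mean = gmean, sd = gsd,
       n = gn)
}

group_key <- function(tissue, week) paste(tissue, week, sep = ".")
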