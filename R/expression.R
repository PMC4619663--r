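# Counts-per-million expression and gene-set temporal trend summaries.

#' Counts per million
#'
#' `cpm = count / library_size * 1e6`, so every column sums to one
#' million. No further normalization is applied.
#'
#' @param counts genes x samples matrix of non-negative integer counts.
#' @return numeric matrix of the same shape.
#' @export
cpm_matrix <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  sweep(counts, 2, lib, "/") * 1e6
}

#' Temporal trend summary for a gene set
#'
#' Within one tissue, per gene and week the arithmetic mean CPM over
#' biological replicates is taken; per week, the median and
#' interquartile range over the genes of the set are reported. The
#' per-gene direction is the sign of `mean(last week) - mean(first
#' week)`; genes with equal endpoint means (including all-zero genes)
#' are ties. The direction p-value comes from [direction_test()].
#'
#' @param cpm CPM matrix from [cpm_matrix()].
#' @param meta sample sheet covering the CPM columns.
#' @param gene_set character vector of gene ids; its intersection with
#'   the matrix rows must be nonempty.
#' @param tissue tissue to summarise.
#' @param weeks weeks in increasing order.
#' @return object of class `trend_summary` with per-week `median_cpm`
#'   and `iqr_cpm`, direction counts `n_up` / `n_down` / `n_tied`,
#'   `direction_p`, and the per-gene week means in `$per_gene`.
#' @export
geneset_trend <- function(cpm, meta, gene_set, tissue,
                          weeks = c(9L, 18L, 22L)) {
  genes <- intersect(gene_set, rownames(cpm))
  if (length(genes) == 0) {
    stop("gene set has no genes in the expression matrix")
  }
  sub <- meta[meta$tissue == tissue & meta$week %in% weeks, , drop = FALSE]
  wk_means <- vapply(weeks, function(w) {
    cols <- sub$sample_id[sub$week == w]
    cols <- intersect(cols, colnames(cpm))
    if (length(cols) == 0) {
      stop(sprintf("no samples for tissue %s week %d", tissue, w))
    }
    rowMeans(cpm[genes, cols, drop = FALSE])
  }, numeric(length(genes)))
  if (is.null(dim(wk_means))) {
    wk_means <- matrix(wk_means, nrow = 1)
  }
  colnames(wk_means) <- paste0("W", weeks)
  med <- apply(wk_means, 2, stats::median)
  iqr <- apply(wk_means, 2, stats::IQR)
  d <- wk_means[, ncol(wk_means)] - wk_means[, 1]
  n_up <- sum(d > 0); n_down <- sum(d < 0); n_tied <- sum(d == 0)
  structure(list(
    tissue = tissue, weeks = weeks, genes = genes,
    median_cpm = med, iqr_cpm = iqr,
    n_up = n_up, n_down = n_down, n_tied = n_tied,
    direction_p = direction_test(n_up, n_down),
    per_gene = data.frame(gene_id = genes, wk_means, row.names = NULL)
  ), class = "trend_summary")
}

#' @export
print.trend_summary <- function(x, ...) {
  cat(sprintf("<trend_summary> tissue=%s genes=%d up=%d down=%d tied=%d p=%.3g\n",
              x$tissue, length(x$genes), x$n_up, x$n_down, x$n_tied,
              if (is.na(x$direction_p)) NA else x$direction_p))
  invisible(x)
}

#' Direction test for up/down regulation
#'
#' Two-sided exact binomial (sign) test of the number of upregulated
#' genes among the non-tied genes, with success probability 0.5. Ties
#' are excluded; if every gene is tied the test is undefined and `NA` is
#' returned.
#'
#' @param n_up,n_down counts of up- and downregulated genes.
#' @return two-sided p-value, or `NA` when `n_up + n_down == 0`.
#' @export
direction_test <- function(n_up, n_down) {
  n <- n_up + n_down
  if (n == 0) return(NA_real_)
  stats::binom.test(n_up, n, p = 0.5,
                    alternative = "two.sided")$p.value
}
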