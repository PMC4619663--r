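#' @importFrom utils read.table write.table
#' @importFrom stats setNames
NULL

# Single place where the two coordinate conventions meet:
# probe manifests carry 1-based positions (Illumina convention), interval
# tracks are BED-style 0-based half-open on disk and GRanges (1-based
# closed) in memory.

#' Convert 0-based half-open intervals to a GRanges
#'
#' Interval tracks (CpG islands, chromatin states, binding peaks, region
#' calls) are stored on disk as BED: 0-based, half-open. In memory the
#' package uses `GRanges`, which is 1-based and closed. This is the single
#' conversion point: BED interval `[start0, end0)` becomes GRanges
#' `[start0 + 1, end0]`. A 1-based probe position `p` therefore overlaps a
#' BED interval `(s, e)` iff `s < p <= e`.
#'
#' @param chrom character vector of chromosome names.
#' @param start0 integer vector, 0-based starts.
#' @param end0 integer vector, exclusive ends; must satisfy `start0 < end0`.
#' @param label optional character vector stored as the `name` metadata
#'   column.
#' @return A `GRanges`, sorted by (chromosome, start).
#' @export
granges_from_bed0 <- function(chrom, start0, end0, label = NULL) {
  if (any(start0 >= end0)) {
    bad <- which(start0 >= end0)[1L]
    stop(sprintf("interval %d has start >= end (%d >= %d)",
                 bad, start0[bad], end0[bad]))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0)
  )
  if (!is.null(label)) S4Vectors::mcols(gr)$name <- label
  GenomicRanges::sort(gr)
}

#' Convert a GRanges back to 0-based half-open coordinates
#'
#' Inverse of [granges_from_bed0()].
#'
#' @param gr a `GRanges`.
#' @return data.frame with columns `chrom`, `start0`, `end0` and, when a
#'   `name` metadata column is present, `label`.
#' @export
granges_to_bed0 <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(S4Vectors::mcols(gr)$name)) {
    df$label <- as.character(S4Vectors::mcols(gr)$name)
  }
  df
}

#' Represent manifest probes as width-1 GRanges
#'
#' @param manifest probe manifest data.frame (`probe_id`, `chrom`, `pos`).
#' @return width-1 `GRanges` named by probe id, in manifest order.
#' @export
probe_granges <- function(manifest) {
  gr <- GenomicRanges::GRanges(
    seqnames = manifest$chrom,
    ranges = IRanges::IRanges(start = manifest$pos, width = 1L)
  )
  names(gr) <- manifest$probe_id
  gr
}

read_tsv_strict <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(required_cols, colnames(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
  df
}

write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a probe manifest
#'
#' Tab-separated with header columns `probe_id`, `chrom`, `pos` (1-based).
#' Probes are returned sorted by (chromosome, position).
#'
#' @param path TSV path.
#' @return data.frame with columns `probe_id`, `chrom`, `pos`.
#' @export
read_manifest <- function(path) {
  df <- read_tsv_strict(path, c("probe_id", "chrom", "pos"))
  df$pos <- as.integer(df$pos)
  validate_manifest(df)
  df[order(df$chrom, df$pos), , drop = FALSE]
}

validate_manifest <- function(manifest) {
  if (anyDuplicated(manifest$probe_id)) {
    dup <- manifest$probe_id[duplicated(manifest$probe_id)][1L]
    stop("duplicate probe_id in manifest: ", dup)
  }
  if (any(is.na(manifest$pos)) || any(manifest$pos < 1L)) {
    stop("manifest positions must be integers >= 1")
  }
  invisible(manifest)
}

#' @rdname read_manifest
#' @param manifest manifest data.frame to write.
#' @export
write_manifest <- function(manifest, path) {
  write_tsv_plain(manifest[, c("probe_id", "chrom", "pos")], path)
}

#' Read a beta-value matrix
#'
#' Rows are probes (first column `probe_id`), remaining columns are
#' samples. All non-missing values must lie in \[0, 1\]; anything else is
#' rejected with the offending probe and sample named. Rows are returned in
#' manifest (chromosome, position) order.
#'
#' @param path TSV path.
#' @param manifest probe manifest; every row id must appear in it.
#' @return numeric matrix, probes x samples.
#' @export
read_beta_matrix <- function(path, manifest) {
  df <- read_tsv_strict(path, "probe_id")
  ids <- df$probe_id
  unknown <- setdiff(ids, manifest$probe_id)
  if (length(unknown) > 0) {
    stop("probes absent from manifest: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  m <- as.matrix(df[, setdiff(colnames(df), "probe_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0,1]: probe %s, sample %s (%.4g)",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
                 m[bad[1, , drop = FALSE]]))
  }
  keep <- manifest$probe_id[manifest$probe_id %in% ids]
  ord <- order(manifest$chrom[match(keep, manifest$probe_id)],
               manifest$pos[match(keep, manifest$probe_id)])
  m[keep[ord], , drop = FALSE]
}

#' @rdname read_beta_matrix
#' @param beta matrix to write (row names are probe ids).
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta), beta,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}

#' Read a sample sheet
#'
#' Columns: `sample_id`, `tissue`, `week` (integer gestational week),
#' `replicate`, `sex` (`F`, `M` or `unknown`).
#'
#' @param path TSV path.
#' @return data.frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_strict(path, c("sample_id", "tissue", "week", "replicate"))
  df$week <- as.integer(df$week)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sheet")
  if (any(is.na(df$week))) stop("non-integer week in sample sheet")
  if (is.null(df$sex)) df$sex <- "unknown"
  df
}

#' @rdname read_sample_sheet
#' @param meta sample sheet data.frame.
#' @export
write_sample_sheet <- function(meta, path) {
  write_tsv_plain(meta, path)
}

#' Read gene models
#'
#' Columns: `gene_id`, `chrom`, `strand` (`+` or `-`; `.` is rejected
#' because promoter windows require orientation), `tx_start`, `tx_end`
#' (1-based inclusive, `tx_start <= tx_end`). The TSS is `tx_start` on the
#' plus strand and `tx_end` on the minus strand; the TES is the opposite
#' end.
#'
#' @param path TSV path.
#' @return data.frame of gene models.
#' @export
read_gene_models <- function(path) {
  df <- read_tsv_strict(path, c("gene_id", "chrom", "strand",
                                "tx_start", "tx_end"))
  df$tx_start <- as.integer(df$tx_start)
  df$tx_end <- as.integer(df$tx_end)
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad) > 0) {
    stop(sprintf("gene %s: strand must be '+' or '-', got '%s'",
                 df$gene_id[bad[1]], df$strand[bad[1]]))
  }
  bad <- which(df$tx_start > df$tx_end)
  if (length(bad) > 0) {
    stop(sprintf("gene %s: tx_start > tx_end", df$gene_id[bad[1]]))
  }
  df
}

#' @rdname read_gene_models
#' @param genes gene-model data.frame.
#' @export
write_gene_models <- function(genes, path) {
  write_tsv_plain(genes[, c("gene_id", "chrom", "strand",
                            "tx_start", "tx_end")], path)
}

#' Read a count matrix
#'
#' Genes in rows (first column `gene_id`), samples in columns. Counts must
#' be non-negative integers.
#'
#' @param path TSV path.
#' @return integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  df <- read_tsv_strict(path, "gene_id")
  m <- as.matrix(df[, setdiff(colnames(df), "gene_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene_id
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)[1, ]
    stop(sprintf("count is not a non-negative integer: gene %s, sample %s",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @param counts matrix to write (row names are gene ids).
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}

#' Read / write BED interval tracks
#'
#' BED3 or BED4 (chrom, start, end, optional name), tab-separated,
#' 0-based half-open. Malformed rows (non-numeric coordinates,
#' `start >= end`) are rejected with the line number. Returns a `GRanges`
#' via [granges_from_bed0()].
#'
#' @param path BED path.
#' @return `GRanges` (1-based closed), sorted.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(GenomicRanges::GRanges())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 3)) {
    stop("BED line ", which(ncol < 3)[1], ": fewer than 3 columns")
  }
  chrom <- vapply(parts, `[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  if (any(is.na(start0)) || any(is.na(end0))) {
    stop("BED line ", which(is.na(start0) | is.na(end0))[1],
         ": non-integer coordinate")
  }
  if (any(start0 >= end0)) {
    stop("BED line ", which(start0 >= end0)[1], ": start >= end")
  }
  label <- if (any(ncol >= 4)) {
    vapply(parts, function(p) if (length(p) >= 4) p[4] else ".", "")
  } else NULL
  granges_from_bed0(chrom, start0, end0, label)
}

#' @rdname read_bed
#' @param track `GRanges` to write.
#' @export
write_bed <- function(track, path) {
  df <- granges_to_bed0(track)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
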