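# Independent brute-force oracles and small fixture builders. The
# oracles deliberately use naive enumeration so they share no code with
# the implementations they check.

make_manifest <- function(pos, chrom = "chr1") {
  data.frame(probe_id = sprintf("p%05d", seq_along(pos)),
             chrom = chrom, pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

# Exhaustive maximal-interval oracle for the region caller (single
# chromosome): enumerate all probe intervals, filter by the four
# constraints, drop intervals contained in another survivor, then apply
# the deterministic leftmost-start (equal start: longer) non-overlap
# selection.
oracle_regions <- function(pos, flg, max_gap = 1000, min_matching = 3,
                           max_nonmatching = 3) {
  n <- length(pos)
  cand <- list()
  for (i in seq_len(n)) {
    if (!flg[i]) next
    n_match <- 0L; n_non <- 0L
    for (j in i:n) {
      if (j > i && pos[j] - pos[j - 1] > max_gap) break
      if (flg[j]) n_match <- n_match + 1L else n_non <- n_non + 1L
      if (n_non > max_nonmatching) break
      if (flg[j] && n_match >= min_matching) {
        cand[[length(cand) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(cand) == 0) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, cand)
  keep <- vapply(seq_len(nrow(m)), function(r) {
    !any(m[, 1] <= m[r, 1] & m[, 2] >= m[r, 2] &
           (m[, 1] != m[r, 1] | m[, 2] != m[r, 2]))
  }, TRUE)
  m <- m[keep, , drop = FALSE]
  m <- m[order(m[, 1], -m[, 2]), , drop = FALSE]
  sel <- matrix(integer(0), ncol = 2)
  last_end <- -Inf
  for (r in seq_len(nrow(m))) {
    if (m[r, 1] > last_end) {
      sel <- rbind(sel, m[r, , drop = FALSE])
      last_end <- m[r, 2]
    }
  }
  sel
}

# Brute-force CGI classification by direct distance to every island.
oracle_cgi <- function(pos, islands_1based) {
  vapply(pos, function(p) {
    if (nrow(islands_1based) == 0) return("NC")
    s <- islands_1based$start; e <- islands_1based$end
    if (any(p >= s & p <= e)) return("CGI")
    d <- min(ifelse(p < s, s - p, p - e))
    if (d <= 2000) "SHO" else if (d <= 4000) "SHE" else "NC"
  }, "")
}

# Brute-force genic classification: per gene, strand-aware offset from
# the TSS; precedence PP > DP > GB > DS.
oracle_genic <- function(pos, genes) {
  vapply(pos, function(p) {
    has <- c(PP = FALSE, DP = FALSE, GB = FALSE, DS = FALSE)
    for (g in seq_len(nrow(genes))) {
      dir <- if (genes$strand[g] == "+") 1 else -1
      tss <- if (dir == 1) genes$tx_start[g] else genes$tx_end[g]
      len <- genes$tx_end[g] - genes$tx_start[g]
      off <- (p - tss) * dir
      if (off >= -1500 && off <= 500) has["PP"] <- TRUE
      if (off >= -10000 && off <= -1501) has["DP"] <- TRUE
      if (off >= 501 && off <= len) has["GB"] <- TRUE
      if (off >= len + 1 && off <= len + 5000) has["DS"] <- TRUE
    }
    if (has["PP"]) "PP" else if (has["DP"]) "DP"
    else if (has["GB"]) "GB" else if (has["DS"]) "DS" else "IG"
  }, "")
}

# Small complete design: a beta matrix built directly from a matrix of
# per-(tissue, week) means, with exact replicate values.
make_design <- function(tissues = c("A", "B"), weeks = c(9, 18, 22),
                        reps = 3) {
  grid <- expand.grid(replicate = seq_len(reps), week = weeks,
                      tissue = tissues, stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_W%d_r%d", grid$tissue, grid$week,
                                 grid$replicate),
             tissue = grid$tissue, week = grid$week,
             replicate = grid$replicate, sex = "unknown",
             stringsAsFactors = FALSE)
}

# beta matrix in which probe p has mean `means[p, (tissue, week)]` and
# replicates are offset symmetrically by +/- spread (keeping the mean
# exact and the SD = spread for 2 of 3 replicates; spread small).
beta_from_means <- function(means_by_group, meta, spread = 0.01) {
  groups <- colnames(means_by_group)
  beta <- matrix(NA_real_, nrow(means_by_group), nrow(meta),
                 dimnames = list(rownames(means_by_group),
                                 meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    key <- paste(meta$tissue[j], meta$week[j], sep = ".")
    off <- c(-spread, 0, spread)[(meta$replicate[j] - 1) %% 3 + 1]
    beta[, j] <- pmin(pmax(means_by_group[, key] + off, 0), 1)
  }
  beta
}
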