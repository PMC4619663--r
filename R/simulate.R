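# Synthetic 450k-style data with planted truth. The generator emulates
# a fetal multi-tissue design: beta values in [0,1] with replicate-level
# Beta-distributed noise, CpGs clustered with CGI-like geometry, planted
# tissue-specific hypomethylated blocks, planted gain/loss-of-
# methylation (GOM/LOM) trajectories across gestational weeks, binding
# peaks enriched at planted LOM blocks, and negative-binomial expression
# counts with per-gene-set temporal trends.

#' Planted signal specification
#'
#' One contiguous block of CpGs carrying an effect. `tissue_hypo` blocks
#' are hypomethylated in the target tissue at every week;
#' `gom`/`lom` blocks follow the mean trajectory across weeks in the
#' target tissue; `neutral` blocks sit at the background mean.
#'
#' @param kind one of `"tissue_hypo"`, `"gom"`, `"lom"`, `"neutral"`.
#' @param target_tissue tissue carrying the effect (`NA` for neutral).
#' @param n_cpgs_in_block CpGs in the block.
#' @param mean_trajectory per-week mean beta in the target tissue, all
#'   in \[0, 1\].
#' @param background_mean mean beta outside the target tissue; for
#'   `tissue_hypo` it must be >= the target mean at every week.
#' @return a `planted_signal` list.
#' @export
planted_signal <- function(kind, target_tissue = NA_character_,
                           n_cpgs_in_block = 5L,
                           mean_trajectory = c(0.5, 0.5, 0.5),
                           background_mean = 0.5) {
  kind <- match.arg(kind, c("tissue_hypo", "gom", "lom", "neutral"))
  if (any(mean_trajectory < 0 | mean_trajectory > 1)) {
    stop("mean_trajectory: values must lie in [0, 1]")
  }
  if (background_mean < 0 || background_mean > 1) {
    stop("background_mean: must lie in [0, 1]")
  }
  if (kind == "tissue_hypo" &&
      any(background_mean - mean_trajectory < 0)) {
    stop("tissue_hypo: background_mean must be >= target mean at every week")
  }
  if (n_cpgs_in_block < 1) stop("n_cpgs_in_block: must be >= 1")
  structure(list(kind = kind, target_tissue = target_tissue,
                 n_cpgs_in_block = as.integer(n_cpgs_in_block),
                 mean_trajectory = mean_trajectory,
                 background_mean = background_mean),
            class = "planted_signal")
}

#' Default planted-signal set
#'
#' Blocks cycle over every (tissue, effect kind) combination:
#' tissue-specific hypomethylation at beta 0.20 against a 0.50
#' background, GOM trajectories (0.20, 0.35, 0.50) and LOM trajectories
#' (0.50, 0.35, 0.20) — a planted effect of 0.30, comfortably above the
#' 0.20 calling threshold.
#'
#' @param tissues tissue labels.
#' @param n_blocks total number of planted blocks.
#' @param block_size CpGs per block.
#' @export
default_planted_signals <- function(tissues, n_blocks = 400L,
                                    block_size = 5L) {
  kinds <- c("tissue_hypo", "gom", "lom")
  combos <- expand.grid(tissue = tissues, kind = kinds,
                        stringsAsFactors = FALSE)
  lapply(seq_len(n_blocks), function(i) {
    cb <- combos[(i - 1L) %% nrow(combos) + 1L, ]
    traj <- switch(cb$kind,
                   tissue_hypo = c(0.2, 0.2, 0.2),
                   gom = c(0.2, 0.35, 0.5),
                   lom = c(0.5, 0.35, 0.2))
    planted_signal(cb$kind, cb$tissue, block_size, traj,
                   background_mean = 0.5)
  })
}

#' Simulation configuration
#'
#' Defaults mirror the fetal study design: four tissues (amnion, muscle,
#' adrenal, pancreas) at gestational weeks 9, 18 and 22 with three
#' biological replicates per cell; 20,000 CpGs of which 2,000 sit in
#' planted blocks; Beta-distributed noise with concentration 200 (SD
#' about 0.035 at a mean of 0.5).
#'
#' @param n_chromosomes,n_cpgs,n_genes,n_cgis counts (all >= 1).
#' @param tissues tissue labels.
#' @param weeks strictly increasing integer gestational weeks.
#' @param replicates_per_cell replicates per (tissue, week) cell.
#' @param noise_concentration Beta-distribution concentration kappa; an
#'   observed beta is drawn from `Beta(mu*kappa, (1-mu)*kappa)`.
#' @param background_mean mean beta of unplanted probes.
#' @param planted list of [planted_signal()] objects.
#' @param seed integer seed; all randomness of [simulate_dataset()]
#'   flows from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 2L, n_cpgs = 20000L,
                       n_genes = 200L, n_cgis = 100L,
                       tissues = c("amnion", "muscle", "adrenal",
                                   "pancreas"),
                       weeks = c(9L, 18L, 22L),
                       replicates_per_cell = 3L,
                       noise_concentration = 200,
                       background_mean = 0.5,
                       planted = default_planted_signals(tissues),
                       seed = 1L) {
  cfg <- structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    n_cpgs = as.integer(n_cpgs), n_genes = as.integer(n_genes),
    n_cgis = as.integer(n_cgis), tissues = tissues,
    weeks = as.integer(weeks),
    replicates_per_cell = as.integer(replicates_per_cell),
    noise_concentration = noise_concentration,
    background_mean = background_mean,
    planted = planted, seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  for (f in c("n_chromosomes", "n_cpgs", "n_genes", "n_cgis",
              "replicates_per_cell")) {
    if (cfg[[f]] < 1L) stop(sprintf("%s: must be >= 1", f))
  }
  if (length(cfg$weeks) < 2 || any(diff(cfg$weeks) <= 0)) {
    stop("weeks: must be strictly increasing")
  }
  if (cfg$noise_concentration <= 0) {
    stop("noise_concentration: must be > 0")
  }
  for (sig in cfg$planted) {
    if (!inherits(sig, "planted_signal")) {
      stop("planted: entries must be planted_signal objects")
    }
    if (length(sig$mean_trajectory) != length(cfg$weeks)) {
      stop("planted: mean_trajectory length must match weeks")
    }
    if (!is.na(sig$target_tissue) &&
        !sig$target_tissue %in% cfg$tissues) {
      stop("planted: unknown target_tissue ", sig$target_tissue)
    }
  }
  n_planted <- sum(vapply(cfg$planted, `[[`, 1L, "n_cpgs_in_block"))
  if (n_planted > cfg$n_cpgs) {
    stop("n_cpgs: smaller than the number of planted CpGs")
  }
  cfg
}

#' Simulate the probe manifest, gene models and CpG-island track
#'
#' CpGs are laid out in clusters: intra-cluster gaps of 50-900 bp (under
#' the 1 kb region-calling limit) and inter-cluster gaps of 5-20 kb
#' (over 4 kb, so clusters cannot bridge). Every planted block occupies
#' one dedicated cluster. CpG islands cover the first >= 3 probes of
#' randomly chosen clusters; genes are anchored near cluster starts with
#' random strand and 2-20 kb length. Uses the current RNG state;
#' [simulate_dataset()] seeds it.
#'
#' @param config a [sim_config()].
#' @return list with `manifest` (data.frame), `genes` (data.frame),
#'   `cgis` (`GRanges`), `truth` (list of per-probe `probes` and
#'   per-block `blocks` data.frames).
#' @export
simulate_manifest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  planted_sizes <- vapply(config$planted, `[[`, 1L, "n_cpgs_in_block")
  n_background <- config$n_cpgs - sum(planted_sizes)
  # background cluster sizes
  bg_sizes <- integer(0)
  while (sum(bg_sizes) < n_background) {
    bg_sizes <- c(bg_sizes, sample(4:12, 64, replace = TRUE))
  }
  bg_sizes <- bg_sizes[cumsum(bg_sizes) <= n_background]
  short <- n_background - sum(bg_sizes)
  if (short > 0) bg_sizes <- c(bg_sizes, short)
  clusters <- data.frame(
    size = c(planted_sizes, bg_sizes),
    signal = c(seq_along(planted_sizes), rep(NA_integer_,
                                             length(bg_sizes)))
  )
  clusters <- clusters[sample(nrow(clusters)), , drop = FALSE]
  # chromosomes get near-equal numbers of clusters
  chrom_of <- sort(rep_len(seq_len(config$n_chromosomes),
                           nrow(clusters)))
  n_cl <- nrow(clusters)
  pos_list <- vector("list", n_cl)
  cl_chrom <- character(n_cl)
  for (chr in seq_len(config$n_chromosomes)) {
    at <- 10000L
    for (ci in which(chrom_of == chr)) {
      sz <- clusters$size[ci]
      gaps <- if (sz > 1) sample(50:900, sz - 1L, replace = TRUE)
              else integer(0)
      pos <- at + cumsum(c(0L, gaps))
      pos_list[[ci]] <- pos
      cl_chrom[ci] <- paste0("chr", chr)
      at <- pos[sz] + sample(5000:20000, 1L)
    }
  }
  sizes <- clusters$size
  probes <- data.frame(
    chrom = rep(cl_chrom, sizes),
    pos = unlist(pos_list),
    signal = rep(clusters$signal, sizes),
    block_id = rep(ifelse(is.na(clusters$signal), NA_integer_,
                          seq_len(n_cl)), sizes),
    stringsAsFactors = FALSE
  )
  planted_cl <- which(!is.na(clusters$signal))
  block_rows <- lapply(planted_cl, function(ci) {
    sig <- config$planted[[clusters$signal[ci]]]
    pos <- pos_list[[ci]]
    data.frame(block_id = ci, signal_id = clusters$signal[ci],
               chrom = cl_chrom[ci], start = pos[1],
               end = pos[length(pos)], kind = sig$kind,
               target_tissue = sig$target_tissue,
               stringsAsFactors = FALSE)
  })
  probes <- probes[order(probes$chrom, probes$pos), , drop = FALSE]
  probes$probe_id <- sprintf("cg%07d", seq_len(nrow(probes)))
  manifest <- data.frame(probe_id = probes$probe_id,
                         chrom = probes$chrom, pos = probes$pos,
                         stringsAsFactors = FALSE)
  blocks <- if (length(block_rows) > 0) {
    do.call(rbind, block_rows)
  } else {
    data.frame(block_id = integer(), signal_id = integer(),
               chrom = character(), start = integer(), end = integer(),
               kind = character(), target_tissue = character(),
               stringsAsFactors = FALSE)
  }
  blocks <- blocks[order(blocks$chrom, blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL
  kind <- rep("neutral", nrow(probes))
  tt <- rep(NA_character_, nrow(probes))
  pl <- !is.na(probes$signal)
  kind[pl] <- vapply(config$planted[probes$signal[pl]], `[[`, "",
                     "kind")
  tt[pl] <- vapply(config$planted[probes$signal[pl]], `[[`,
                   NA_character_, "target_tissue")
  truth_probes <- data.frame(
    probe_id = probes$probe_id, kind = kind, target_tissue = tt,
    block_id = probes$block_id, stringsAsFactors = FALSE
  )

  # CGIs: first >= 3 probes of randomly chosen clusters
  csize_ok <- which(clusters$size >= 3L)
  if (length(csize_ok) < config$n_cgis) {
    stop("n_cgis: not enough clusters with >= 3 probes")
  }
  cgi_cl <- sample(csize_ok, config$n_cgis)
  cgi_rows <- lapply(cgi_cl, function(ci) {
    pos <- pos_list[[ci]]
    m <- sample(3:length(pos), 1L)
    data.frame(chrom = cl_chrom[ci], start0 = pos[1] - 51L,
               end0 = pos[m] + 50L)
  })
  cgi <- do.call(rbind, cgi_rows)
  cgis <- granges_from_bed0(cgi$chrom, cgi$start0, cgi$end0,
                            label = sprintf("CGI_%03d",
                                            seq_len(nrow(cgi))))

  # genes anchored near cluster starts
  anchor <- sample(nrow(clusters), config$n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  len <- sample(2000:20000, config$n_genes, replace = TRUE)
  tss <- vapply(anchor, function(ci) pos_list[[ci]][1], 0L) +
    sample(-500:500, config$n_genes, replace = TRUE)
  tx_start <- ifelse(strand == "+", tss, tss - len)
  tx_end <- ifelse(strand == "+", tss + len, tss)
  tx_start <- pmax(tx_start, 1L)
  genes <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(config$n_genes)),
    chrom = cl_chrom[anchor],
    strand = strand, tx_start = as.integer(tx_start),
    tx_end = as.integer(tx_end), stringsAsFactors = FALSE
  )
  list(manifest = manifest, genes = genes, cgis = cgis,
       truth = list(probes = truth_probes, blocks = blocks))
}

make_sample_sheet <- function(config) {
  grid <- expand.grid(replicate = seq_len(config$replicates_per_cell),
                      week = config$weeks, tissue = config$tissues,
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s_W%d_r%d", grid$tissue, grid$week,
                        grid$replicate),
    tissue = grid$tissue, week = grid$week, replicate = grid$replicate,
    sex = rep_len(c("F", "M"), nrow(grid)),
    stringsAsFactors = FALSE
  )
}

#' Simulate the beta-value matrix
#'
#' Every observation is drawn from `Beta(mu*kappa, (1-mu)*kappa)` where
#' `mu` is the planted mean (trajectory value for the block's target
#' tissue at the sample's week, the block's background mean for other
#' tissues) or the global background mean for neutral probes, and
#' `kappa` is `noise_concentration`. Uses the current RNG state.
#'
#' @param sim result of [simulate_manifest()].
#' @param config the same [sim_config()].
#' @return list with `beta` (probes x samples matrix), `meta` (sample
#'   sheet) and `truth` (passed through).
#' @export
simulate_beta <- function(sim, config) {
  meta <- make_sample_sheet(config)
  n_p <- nrow(sim$manifest)
  mu <- matrix(config$background_mean, n_p, nrow(meta),
               dimnames = list(sim$manifest$probe_id, meta$sample_id))
  tp <- sim$truth$probes
  stopifnot(identical(tp$probe_id, sim$manifest$probe_id))
  planted_rows <- which(tp$kind != "neutral")
  if (length(planted_rows) > 0) {
    for (bid in unique(tp$block_id[planted_rows])) {
      rows <- which(tp$block_id %in% bid)
      blk <- sim$truth$blocks[sim$truth$blocks$block_id == bid, ]
      sig_target <- blk$target_tissue
      sig <- config$planted[[blk$signal_id]]
      for (wi in seq_along(config$weeks)) {
        w <- config$weeks[wi]
        if (is.na(sig_target)) {
          cols <- which(meta$week == w)
        } else {
          cols <- which(meta$week == w & meta$tissue == sig_target)
          bg_cols <- which(meta$week == w & meta$tissue != sig_target)
          mu[rows, bg_cols] <- sig$background_mean
        }
        mu[rows, cols] <- sig$mean_trajectory[wi]
      }
    }
  }
  kappa <- config$noise_concentration
  mu_c <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
  beta <- matrix(stats::rbeta(length(mu), mu_c * kappa,
                              (1 - mu_c) * kappa),
                 nrow = n_p, dimnames = dimnames(mu))
  list(beta = beta, meta = meta, truth = sim$truth)
}

#' Simulate binding peaks enriched at planted LOM blocks
#'
#' Exactly `round(frac_overlap_lom * n_lom_blocks)` peaks are centred
#' inside randomly chosen LOM blocks; `n_decoys` decoy peaks are placed
#' away from every planted block. Uses the current RNG state.
#'
#' @param sim result of [simulate_manifest()].
#' @param frac_overlap_lom fraction of LOM blocks to cover, in \[0, 1\].
#' @param n_decoys number of decoy peaks.
#' @param peak_width peak width in bp.
#' @return `GRanges` of peaks.
#' @export
simulate_peaks <- function(sim, frac_overlap_lom, n_decoys = 100L,
                           peak_width = 400L) {
  if (frac_overlap_lom < 0 || frac_overlap_lom > 1) {
    stop("frac_overlap_lom: must lie in [0, 1]")
  }
  blocks <- sim$truth$blocks
  lom <- blocks[blocks$kind == "lom", , drop = FALSE]
  if (nrow(lom) == 0) stop("truth contains no lom blocks")
  n_hit <- round(frac_overlap_lom * nrow(lom))
  hit <- if (n_hit > 0) lom[sample(nrow(lom), n_hit), , drop = FALSE]
         else lom[0, ]
  half <- peak_width %/% 2L
  peak_rows <- list()
  for (i in seq_len(nrow(hit))) {
    mid <- (hit$start[i] + hit$end[i]) %/% 2L
    peak_rows[[length(peak_rows) + 1L]] <- data.frame(
      chrom = hit$chrom[i], start0 = max(0L, mid - half),
      end0 = mid + half)
  }
  # decoys: uniform over each chromosome's extent, rejected if within
  # peak_width of any planted block
  ext <- tapply(sim$manifest$pos, sim$manifest$chrom, max)
  chroms <- names(ext)
  blk_gr <- GenomicRanges::GRanges(
    blocks$chrom,
    IRanges::IRanges(blocks$start - peak_width, blocks$end + peak_width))
  placed <- 0L
  rounds <- 0L
  while (placed < n_decoys && rounds < 100L) {
    rounds <- rounds + 1L
    m <- 2L * (n_decoys - placed) + 10L
    ch <- sample(chroms, m, replace = TRUE)
    mid <- floor(stats::runif(m) * as.integer(ext[ch])) + 1L
    cand <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(pmax(1L, mid - half), mid + half))
    ok <- which(!IRanges::overlapsAny(cand, blk_gr))
    ok <- utils::head(ok, n_decoys - placed)
    if (length(ok) > 0) {
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        chrom = ch[ok], start0 = pmax(0L, mid[ok] - half - 1L),
        end0 = mid[ok] + half)
      placed <- placed + length(ok)
    }
  }
  if (placed < n_decoys) stop("could not place all decoy peaks")
  pk <- do.call(rbind, peak_rows)
  granges_from_bed0(pk$chrom, pk$start0, pk$end0,
                    label = sprintf("peak_%04d", seq_len(nrow(pk))))
}

#' Simulate negative-binomial expression counts with temporal trends
#'
#' A fraction of the genes is linked to GOM blocks (expression halves
#' from the first to the last week), an equal fraction to LOM blocks
#' (expression doubles), and the rest is stable; trend multipliers are
#' geometric across weeks. The linked fractions are kept small so the
#' trend genes do not shift the library composition appreciably (CPM
#' ratios then reflect the per-gene fold change). Library-size factors
#' span a 2.5-fold range. Counts are `NB(mu = baseline * trend *
#' libfactor, size = 1/dispersion)`. Uses the current RNG state.
#'
#' @param sim result of [simulate_manifest()].
#' @param config the [sim_config()].
#' @param dispersion NB dispersion (size = 1/dispersion).
#' @param fold_change endpoint fold change for linked gene sets.
#' @param linked_fraction fraction of genes linked to each of the GOM
#'   and LOM block sets.
#' @param base_meanlog,base_sdlog lognormal baseline expression.
#' @return list with `counts` (genes x samples integer matrix),
#'   `gene_sets` (data.frame `gene_id`, `set`, `block_id`) and `meta`.
#' @export
simulate_expression <- function(sim, config, dispersion = 0.05,
                                fold_change = 2,
                                linked_fraction = 0.05,
                                base_meanlog = log(100),
                                base_sdlog = 1) {
  genes <- sim$genes
  if (nrow(genes) == 0) stop("no genes to simulate")
  meta <- make_sample_sheet(config)
  blocks <- sim$truth$blocks
  gomb <- blocks$block_id[blocks$kind == "gom"]
  lomb <- blocks$block_id[blocks$kind == "lom"]
  n <- nrow(genes)
  n_link <- min(max(1L, round(linked_fraction * n)), n %/% 2L)
  set <- rep("stable", n)
  block_id <- rep(NA_integer_, n)
  if (length(gomb) > 0 && n_link > 0) {
    set[seq_len(n_link)] <- "gom_linked"
    block_id[seq_len(n_link)] <- rep_len(gomb, n_link)
  }
  if (length(lomb) > 0 && n_link > 0) {
    idx <- n_link + seq_len(n_link)
    set[idx] <- "lom_linked"
    block_id[idx] <- rep_len(lomb, n_link)
  }
  gene_sets <- data.frame(gene_id = genes$gene_id, set = set,
                          block_id = block_id,
                          stringsAsFactors = FALSE)
  nw <- length(config$weeks)
  mult <- function(fold) fold^((seq_len(nw) - 1) / (nw - 1))
  trend <- rbind(gom_linked = mult(1 / fold_change),
                 lom_linked = mult(fold_change),
                 stable = rep(1, nw))
  base <- stats::rlnorm(n, base_meanlog, base_sdlog)
  libf <- sample(seq(0.5, 1.25, length.out = nrow(meta)))
  mu <- matrix(0, n, nrow(meta),
               dimnames = list(genes$gene_id, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    wi <- match(meta$week[j], config$weeks)
    mu[, j] <- base * trend[set, wi] * libf[j]
  }
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / dispersion),
                   nrow = n, dimnames = dimnames(mu))
  storage.mode(counts) <- "integer"
  list(counts = counts, gene_sets = gene_sets, meta = meta)
}

#' Simulate a complete dataset
#'
#' Seeds the RNG once from `config$seed` and draws, in this order:
#' manifest geometry, beta values, expression counts, peaks. Two calls
#' with the same config are therefore identical. When `outdir` is
#' given, all tables are written as TSV/BED.
#'
#' @param config a [sim_config()].
#' @param frac_overlap_lom fraction of LOM blocks covered by a peak.
#' @param n_decoys decoy peaks.
#' @param outdir optional output directory.
#' @return list with `manifest`, `genes`, `cgis`, `truth`, `beta`,
#'   `meta`, `counts`, `gene_sets`, `peaks`, `config`.
#' @export
simulate_dataset <- function(config, frac_overlap_lom = 0.5,
                             n_decoys = 100L, outdir = NULL) {
  set.seed(config$seed)
  sim <- simulate_manifest(config)
  bt <- simulate_beta(sim, config)
  ex <- simulate_expression(sim, config)
  pk <- simulate_peaks(sim, frac_overlap_lom, n_decoys)
  out <- list(manifest = sim$manifest, genes = sim$genes,
              cgis = sim$cgis, truth = sim$truth, beta = bt$beta,
              meta = bt$meta, counts = ex$counts,
              gene_sets = ex$gene_sets, peaks = pk, config = config)
  if (!is.null(outdir)) write_dataset(out, outdir)
  out
}

#' @rdname simulate_dataset
#' @param dataset result of [simulate_dataset()].
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_manifest(dataset$manifest, p("manifest.tsv"))
  write_beta_matrix(dataset$beta, p("beta.tsv"))
  write_sample_sheet(dataset$meta, p("samples.tsv"))
  write_gene_models(dataset$genes, p("genes.tsv"))
  write_bed(dataset$cgis, p("cgis.bed"))
  blk <- dataset$truth$blocks
  write_bed(granges_from_bed0(blk$chrom, blk$start - 1L, blk$end,
                              label = blk$kind), p("blocks.bed"))
  write_bed(dataset$peaks, p("peaks.bed"))
  write_counts(dataset$counts, p("counts.tsv"))
  write_tsv_plain(dataset$truth$probes, p("truth.tsv"))
  write_tsv_plain(dataset$gene_sets, p("gene_sets.tsv"))
  invisible(outdir)
}
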