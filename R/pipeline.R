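# End-to-end orchestration: simulate (optional) -> annotate -> call ->
# regions -> enrichment -> permutation overlap -> expression trends.

#' Pipeline configuration
#'
#' Collects input paths, output directory, calling thresholds and the
#' seed. All thresholds default to the published values: SD filter 0.1,
#' beta difference 0.20, mid-week tolerance 0.05, 1 kb maximum gap,
#' >= 3 matching and <= 3 non-matching CpGs per region, 20,000
#' permutations.
#'
#' @param input_dir directory holding `manifest.tsv`, `beta.tsv`,
#'   `samples.tsv`, `genes.tsv`, `cgis.bed` and optionally `peaks.bed`,
#'   `segmentation.bed`, `counts.tsv`, `gene_sets.tsv` (the layout
#'   written by [write_dataset()]).
#' @param output_dir directory for stage outputs.
#' @param sd_max,delta,w18_tol,max_gap,min_matching,max_nonmatching,n_perm
#'   thresholds, see the calling and region functions.
#' @param seed integer seed used for the permutation stage.
#' @param stages character vector of stages to run, a subset of
#'   `c("annotate", "call", "regions", "enrich", "permute", "trends")`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            sd_max = 0.1, delta = 0.20, w18_tol = 0.05,
                            max_gap = 1000L, min_matching = 3L,
                            max_nonmatching = 3L, n_perm = 20000L,
                            seed = 1L,
                            stages = c("annotate", "call", "regions",
                                       "enrich", "permute", "trends")) {
  stopifnot(sd_max > 0, delta > 0, w18_tol >= 0, max_gap >= 1,
            min_matching >= 1, max_nonmatching >= 0, n_perm >= 1)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 sd_max = sd_max, delta = delta, w18_tol = w18_tol,
                 max_gap = as.integer(max_gap),
                 min_matching = as.integer(min_matching),
                 max_nonmatching = as.integer(max_nonmatching),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 stages = stages),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order; every output file is recorded with
#' its MD5 checksum in the returned run manifest (also written as
#' `run_manifest.json`). The summary table counts called
#' hypomethylated / GOM / LOM probes and regions per tissue.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the run manifest list (`outputs` with checksums,
#'   `summary` counts, `seed`, `thresholds`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ind <- config$input_dir
  outd <- config$output_dir
  dir.create(outd, recursive = TRUE, showWarnings = FALSE)
  req <- function(f) {
    p <- file.path(ind, f)
    if (!file.exists(p)) stop("pipeline input missing: ", p)
    p
  }
  opt <- function(f) {
    p <- file.path(ind, f)
    if (file.exists(p)) p else NULL
  }
  manifest <- read_manifest(req("manifest.tsv"))
  beta <- read_beta_matrix(req("beta.tsv"), manifest)
  meta <- read_sample_sheet(req("samples.tsv"))
  genes <- read_gene_models(req("genes.tsv"))
  cgis <- read_bed(req("cgis.bed"))
  tissues <- sort(unique(meta$tissue))
  outputs <- character(0)
  summary_rows <- list()
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(NULL)
    t0 <- Sys.time()
    res <- fun()
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  labels <- run_stage("annotate", function() {
    lab <- annotate_probes(manifest, cgis, genes)
    f <- file.path(outd, "labels.tsv")
    write_tsv_plain(lab, f)
    outputs <<- c(outputs, f)
    lab
  })

  calls <- run_stage("call", function() {
    per_tissue <- lapply(tissues, function(tt) {
      hypo <- call_tissue_hypomethylation(beta, meta, tt,
                                          sd_max = config$sd_max,
                                          delta = config$delta)
      dyn <- call_dynamic(beta, meta, tt, delta = config$delta,
                          w18_tol = config$w18_tol,
                          sd_max = config$sd_max,
                          weeks = sort(unique(meta$week)))
      list(hypo = hypo, gom = dyn$gom, lom = dyn$lom)
    })
    names(per_tissue) <- tissues
    rows <- do.call(rbind, lapply(tissues, function(tt) {
      cs <- per_tissue[[tt]]
      do.call(rbind, lapply(cs, function(s) {
        if (length(s$probes) == 0) return(NULL)
        data.frame(probe_id = s$probes, tissue = tt, kind = s$kind,
                   stringsAsFactors = FALSE)
      }))
    }))
    if (is.null(rows)) rows <- data.frame(probe_id = character(),
                                          tissue = character(),
                                          kind = character())
    f <- file.path(outd, "calls.tsv")
    write_tsv_plain(rows, f)
    outputs <<- c(outputs, f)
    per_tissue
  })

  regions <- run_stage("regions", function() {
    if (is.null(calls)) stop("stage 'regions' requires stage 'call'")
    all_regs <- list()
    for (tt in tissues) {
      for (kd in c("hypo", "gom", "lom")) {
        cs <- calls[[tt]][[kd]]
        match <- manifest$probe_id %in% cs$probes
        kind <- c(hypo = "tHR", gom = "dDMR_gom", lom = "dDMR_lom")[kd]
        regs <- call_regions(manifest, match,
                             max_gap = config$max_gap,
                             min_matching = config$min_matching,
                             max_nonmatching = config$max_nonmatching,
                             kind = kind, tissue = tt)
        all_regs[[paste(tt, kd, sep = ".")]] <- regs
        summary_rows[[length(summary_rows) + 1L]] <<- data.frame(
          tissue = tt, kind = kind, n_probes = length(cs$probes),
          n_regions = nrow(regs), stringsAsFactors = FALSE)
      }
    }
    combined <- do.call(rbind, all_regs)
    f <- file.path(outd, "regions.tsv")
    flat <- combined[, setdiff(colnames(combined), "probes")]
    flat$probes <- vapply(combined$probes, paste, "", collapse = ",")
    write_tsv_plain(flat, f)
    fb <- file.path(outd, "regions.bed")
    write_bed(regions_to_bed(combined), fb)
    outputs <<- c(outputs, f, fb)
    all_regs
  })

  run_stage("enrich", function() {
    if (is.null(calls) || is.null(labels)) {
      stop("stage 'enrich' requires stages 'annotate' and 'call'")
    }
    background <- manifest$probe_id
    cgi_lab <- setNames(as.character(labels$cgi_class), labels$probe_id)
    gen_lab <- setNames(as.character(labels$genic_class),
                        labels$probe_id)
    seg_path <- opt("segmentation.bed")
    res <- list()
    for (tt in tissues) {
      for (kd in c("hypo", "gom", "lom")) {
        called <- calls[[tt]][[kd]]$probes
        if (length(called) == 0) next
        for (axis in c("cgi", "genic", "state")) {
          lab <- switch(axis, cgi = cgi_lab, genic = gen_lab,
                        state = NULL)
          if (axis == "state") {
            if (is.null(seg_path)) next
            er <- chromatin_state_enrichment(called, background,
                                             manifest,
                                             read_bed(seg_path))
          } else {
            er <- enrichment_or(called, background, lab)
          }
          er$tissue <- tt; er$kind <- kd; er$axis <- axis
          res[[length(res) + 1L]] <- er
        }
      }
    }
    if (length(res) > 0) {
      f <- file.path(outd, "enrichment.tsv")
      write_tsv_plain(do.call(rbind, res), f)
      outputs <<- c(outputs, f)
    }
    # nearest-gene lists for downstream GO submission
    if (!is.null(calls)) {
      ng <- list()
      for (tt in tissues) for (kd in c("hypo", "gom", "lom")) {
        ids <- calls[[tt]][[kd]]$probes
        if (length(ids) == 0) next
        items <- manifest[manifest$probe_id %in% ids, ]
        x <- nearest_gene(items, genes)
        x$tissue <- tt; x$kind <- kd
        ng[[length(ng) + 1L]] <- x
      }
      if (length(ng) > 0) {
        f <- file.path(outd, "nearest_genes.tsv")
        write_tsv_plain(do.call(rbind, ng), f)
        outputs <<- c(outputs, f)
      }
    }
    invisible(NULL)
  })

  run_stage("permute", function() {
    pk_path <- opt("peaks.bed")
    if (is.null(pk_path) || is.null(regions)) return(NULL)
    peaks <- read_bed(pk_path)
    res <- list()
    for (nm in names(regions)) {
      regs <- regions[[nm]]
      if (nrow(regs) == 0) next
      pr <- permutation_overlap_test(regs, peaks, manifest,
                                     n_perm = config$n_perm,
                                     seed = config$seed)
      res[[nm]] <- list(observed_overlap = pr$observed_overlap,
                        n_regions = pr$n_regions,
                        p_two_sided = pr$p_two_sided,
                        n_perm = pr$n_perm)
    }
    if (length(res) > 0) {
      f <- file.path(outd, "perm_overlap.json")
      jsonlite::write_json(res, f, auto_unbox = TRUE, digits = NA)
      outputs <<- c(outputs, f)
    }
    invisible(NULL)
  })

  run_stage("trends", function() {
    ct_path <- opt("counts.tsv")
    gs_path <- opt("gene_sets.tsv")
    if (is.null(ct_path) || is.null(gs_path)) return(NULL)
    counts <- read_counts(ct_path)
    gsets <- read_tsv_strict(gs_path, c("gene_id", "set"))
    cpm <- cpm_matrix(counts)
    weeks <- sort(unique(meta$week))
    res <- list()
    for (s in unique(gsets$set)) {
      ids <- gsets$gene_id[gsets$set == s]
      for (tt in tissues) {
        tr <- tryCatch(geneset_trend(cpm, meta, ids, tt, weeks),
                       error = function(e) NULL)
        if (is.null(tr)) next
        res[[length(res) + 1L]] <- data.frame(
          gene_set = s, tissue = tt,
          t(setNames(tr$median_cpm, paste0("median_", names(tr$median_cpm)))),
          n_up = tr$n_up, n_down = tr$n_down, n_tied = tr$n_tied,
          direction_p = tr$direction_p, stringsAsFactors = FALSE)
      }
    }
    if (length(res) > 0) {
      f <- file.path(outd, "trends.tsv")
      write_tsv_plain(do.call(rbind, res), f)
      outputs <<- c(outputs, f)
    }
    invisible(NULL)
  })

  summary_df <- if (length(summary_rows) > 0) {
    do.call(rbind, summary_rows)
  } else data.frame()
  if (nrow(summary_df) > 0) {
    f <- file.path(outd, "summary.tsv")
    write_tsv_plain(summary_df, f)
    outputs <- c(outputs, f)
  }
  manifest_out <- list(
    seed = config$seed,
    thresholds = config[c("sd_max", "delta", "w18_tol", "max_gap",
                          "min_matching", "max_nonmatching", "n_perm")],
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs))),
    summary = summary_df
  )
  jsonlite::write_json(manifest_out, file.path(outd, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest_out)
}
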