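test_that("probe QC applies the 95% success boundary inclusively", {
  n_samp <- 100
  detp <- matrix(0.001, 3, n_samp,
                 dimnames = list(c("ok", "borderline", "fail"), NULL))
  beads <- matrix(10L, 3, n_samp, dimnames = dimnames(detp))
  detp["fail", 1:6] <- 0.5       # 6/100 failing -> success 94% -> removed
  beads["borderline", 1:5] <- 2L # 5/100 failing -> success 95% -> kept
  kept <- filter_probes(detp, beads)
  expect_setequal(kept, c("ok", "borderline"))

  kept2 <- filter_probes(detp, beads, exclude = "ok")
  expect_equal(kept2, "borderline")
  expect_error(filter_probes(detp, beads[1:2, ]), "not aligned")
})

test_that("tissue hypomethylation requires the delta at every week and tissue", {
  meta <- make_design(tissues = c("A", "B", "C"))
  man <- make_manifest(c(100, 200, 300, 400))
  keys <- paste(rep(c("A", "B", "C"), each = 3), c(9, 18, 22), sep = ".")
  means <- matrix(0.5, 4, 9, dimnames = list(man$probe_id, keys))
  # p1: target 0.20 everywhere, others >= 0.45 -> called
  means[1, startsWith(keys, "A")] <- 0.20
  # p2: one other tissue at one week with difference 0.19 -> not called
  means[2, startsWith(keys, "A")] <- 0.20
  means[2, "B.18"] <- 0.39
  # p3: difference exactly 0.20 everywhere -> called (inclusive)
  means[3, startsWith(keys, "A")] <- 0.30
  beta <- beta_from_means(means, meta, spread = 0.01)
  cs <- call_tissue_hypomethylation(beta, meta, "A")
  expect_setequal(cs$probes, c("p00001", "p00003"))

  # SD filter: a probe with high variance in the target tissue is discarded
  beta2 <- beta
  acols <- meta$sample_id[meta$tissue == "A"]
  beta2["p00001", acols] <- rep(c(0.05, 0.35), length.out = 9)
  cs2 <- call_tissue_hypomethylation(beta2, meta, "A")
  expect_false("p00001" %in% cs2$probes)

  # missing design cell is an error naming the cell
  meta_bad <- meta[!(meta$tissue == "B" & meta$week == 18), ]
  expect_error(
    call_tissue_hypomethylation(beta[, meta_bad$sample_id], meta_bad, "A"),
    "\\(B, week 18\\)")
})

test_that("dynamic calling implements the mid-week tolerance rule", {
  meta <- make_design(tissues = "A")
  man <- make_manifest(100 * (1:5))
  keys <- paste("A", c(9, 18, 22), sep = ".")
  tr <- rbind(
    c(0.10, 0.30, 0.40),  # GOM
    c(0.10, 0.06, 0.35),  # GOM: 0.06 >= 0.10 - 0.05
    c(0.10, 0.04, 0.35),  # not called: mid week below tolerance
    c(0.50, 0.50, 0.50),  # neither
    c(0.45, 0.30, 0.20))  # LOM (0.25 drop, mid between)
  means <- matrix(tr, 5, 3, dimnames = list(man$probe_id, keys))
  beta <- beta_from_means(means, meta, spread = 0.01)
  dyn <- call_dynamic(beta, meta, "A")
  expect_setequal(dyn$gom$probes, c("p00001", "p00002"))
  expect_equal(dyn$lom$probes, "p00005")
  expect_length(intersect(dyn$gom$probes, dyn$lom$probes), 0)

  # unstable replicate group (SD >= 0.1) discards the probe
  beta2 <- beta
  w9 <- meta$sample_id[meta$week == 9]
  beta2["p00001", w9] <- c(0.0, 0.1, 0.3)
  dyn2 <- call_dynamic(beta2, meta, "A")
  expect_false("p00001" %in% dyn2$gom$probes)

  expect_error(call_dynamic(beta, meta[meta$week != 18, ], "A"),
               "lacks week")
})

test_that("a single replicate leaves the SD undefined and excludes probes", {
  meta <- make_design(tissues = "A", reps = 1)
  man <- make_manifest(100 * (1:2))
  beta <- matrix(c(0.1, 0.5, 0.3, 0.5, 0.5, 0.5), 2, 3, byrow = TRUE,
                 dimnames = list(man$probe_id, meta$sample_id))
  expect_warning(dyn <- call_dynamic(beta, meta, "A"), "< 2 replicates")
  expect_length(dyn$gom$probes, 0)
})

test_that("calling is equivariant under tissue relabeling and monotone in delta", {
  set.seed(31)
  cfg <- sim_config(n_cpgs = 1500, n_genes = 20, n_cgis = 20,
                    planted = default_planted_signals(
                      c("amnion", "muscle", "adrenal", "pancreas"),
                      n_blocks = 30),
                    seed = 31)
  ds <- simulate_dataset(cfg, n_decoys = 10)
  cs <- call_tissue_hypomethylation(ds$beta, ds$meta, "muscle")

  # relabel: swap tissue names muscle <-> adrenal in the metadata only
  meta_sw <- ds$meta
  meta_sw$tissue <- ifelse(ds$meta$tissue == "muscle", "adrenal",
                           ifelse(ds$meta$tissue == "adrenal", "muscle",
                                  ds$meta$tissue))
  cs_sw <- call_tissue_hypomethylation(ds$beta, meta_sw, "adrenal")
  expect_setequal(cs_sw$probes, cs$probes)

  # raising delta never adds probes
  for (d in c(0.25, 0.30, 0.40)) {
    expect_true(all(
      call_tissue_hypomethylation(ds$beta, ds$meta, "muscle",
                                  delta = d)$probes %in% cs$probes))
  }
  dyn20 <- call_dynamic(ds$beta, ds$meta, "muscle", delta = 0.20)
  dyn30 <- call_dynamic(ds$beta, ds$meta, "muscle", delta = 0.30)
  expect_true(all(dyn30$gom$probes %in% dyn20$gom$probes))
  expect_true(all(dyn30$lom$probes %in% dyn20$lom$probes))
})
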