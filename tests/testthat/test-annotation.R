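test_that("CGI classes follow island distance with inclusive boundaries", {
  # island covering 1-based 10001..12000 (BED 10000..12000)
  cgi <- granges_from_bed0("chr1", 10000, 12000)
  pos <- c(11000,              # inside -> CGI
           12000 + 2000,       # exactly 2 kb beyond the edge -> SHO
           12000 + 1,          # 1 bp beyond -> SHO
           12000 + 2500,       # 2.5 kb -> SHE
           12000 + 4000,       # exactly 4 kb -> SHE
           12000 + 4500,       # beyond shelves -> NC
           10001 - 2000)       # exactly 2 kb upstream of start -> SHO
  cls <- classify_cgi(make_manifest(pos), cgi)
  expect_equal(as.character(cls),
               c("CGI", "SHO", "SHO", "SHE", "SHE", "NC", "SHO"))
  # empty track: everything NC
  expect_true(all(classify_cgi(make_manifest(pos),
                               GenomicRanges::GRanges()) == "NC"))
})

test_that("genic classes are strand-aware with PP>DP>GB>DS precedence", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tx_start = 100000L, tx_end = 120000L,
                      stringsAsFactors = FALSE)
  man <- make_manifest(c(99000, 95000, 100300, 110000, 121000, 126000,
                         50000))
  cls <- classify_genic(man, genes)
  expect_equal(as.character(cls),
               c("PP", "DP", "PP", "GB", "DS", "IG", "IG"))

  # minus-strand gene: TSS = tx_end; upstream is genomically rightward
  genes_m <- data.frame(gene_id = "g2", chrom = "chr1", strand = "-",
                        tx_start = 50000L, tx_end = 60000L,
                        stringsAsFactors = FALSE)
  cls_m <- classify_genic(make_manifest(c(60800, 63000, 55000, 49000)),
                          genes_m)
  expect_equal(as.character(cls_m), c("PP", "DP", "GB", "DS"))
})

test_that("annotation agrees with brute-force scans and partitions probes", {
  set.seed(11)
  for (rep in 1:3) {
    pos <- sort(sample(1:500000, 400))
    isl <- sort(sample(1:480000, 20))
    islands <- data.frame(start = isl, end = isl + sample(500:3000, 20))
    cgi <- granges_from_bed0("chr1", islands$start - 1L, islands$end)
    man <- make_manifest(pos)
    got <- classify_cgi(man, cgi)
    expect_equal(as.character(got), oracle_cgi(pos, islands))
    expect_equal(sum(table(got)), length(pos))

    gstart <- sample(1:480000, 15)
    genes <- data.frame(gene_id = sprintf("g%02d", 1:15), chrom = "chr1",
                        strand = sample(c("+", "-"), 15, replace = TRUE),
                        tx_start = gstart,
                        tx_end = gstart + sample(1000:20000, 15),
                        stringsAsFactors = FALSE)
    gotg <- classify_genic(man, genes)
    expect_equal(as.character(gotg), oracle_genic(pos, genes))
    expect_equal(sum(table(gotg)), length(pos))
  }
})

test_that("genic classification is invariant under translation and reflection", {
  set.seed(12)
  pos <- sort(sample(10000:200000, 100))
  gstart <- sample(10000:190000, 8)
  genes <- data.frame(gene_id = sprintf("g%d", 1:8), chrom = "chr1",
                      strand = sample(c("+", "-"), 8, replace = TRUE),
                      tx_start = gstart, tx_end = gstart + 5000L,
                      stringsAsFactors = FALSE)
  base <- classify_genic(make_manifest(pos), genes)

  shift <- 1000000L
  genes_t <- transform(genes, tx_start = tx_start + shift,
                       tx_end = tx_end + shift)
  expect_equal(as.character(classify_genic(make_manifest(pos + shift),
                                           genes_t)),
               as.character(base))

  # reflect coordinates and flip strands: classes unchanged
  M <- 1000000L
  genes_r <- data.frame(gene_id = genes$gene_id, chrom = "chr1",
                        strand = ifelse(genes$strand == "+", "-", "+"),
                        tx_start = M - genes$tx_end,
                        tx_end = M - genes$tx_start,
                        stringsAsFactors = FALSE)
  man_r <- make_manifest(rev(M - pos))
  refl <- classify_genic(man_r, genes_r)
  expect_equal(as.character(rev(refl)), as.character(base))
})

test_that("median per combined feature matches planted means", {
  meta <- make_design(tissues = c("A", "B"))
  man <- make_manifest(seq(1000, 40000, by = 1000))
  keys <- paste(rep(c("A", "B"), each = 3), c(9, 18, 22), sep = ".")
  means <- matrix(0.5, nrow(man), 6,
                  dimnames = list(man$probe_id, keys))
  beta <- beta_from_means(means, meta, spread = 0)
  labels <- data.frame(probe_id = man$probe_id,
                       cgi_class = rep(c("CGI", "NC"), each = 20),
                       genic_class = "IG")
  med <- median_by_feature(beta, meta, labels)
  expect_true(all(med$median_beta[!is.na(med$median_beta)] == 0.5))
  # empty feature cells are missing, not zero
  expect_true(all(is.na(med$median_beta[med$cgi_class == "SHO"])))

  # single feature with betas 0.1/0.2/0.9 in one group -> median 0.2
  man3 <- make_manifest(c(100, 200, 300))
  m3 <- matrix(c(0.1, 0.2, 0.9), 3, 6,
               dimnames = list(man3$probe_id, keys))
  b3 <- beta_from_means(m3, meta, spread = 0)
  lab3 <- data.frame(probe_id = man3$probe_id, cgi_class = "CGI",
                     genic_class = "PP")
  med3 <- median_by_feature(b3, meta, lab3)
  expect_equal(unique(med3$median_beta[med3$cgi_class == "CGI"]), 0.2)
})

test_that("methylation class fractions split at 0.25/0.75", {
  meta <- make_design(tissues = "A", weeks = 9, reps = 3)
  man <- make_manifest(c(100, 200, 300))
  means <- matrix(c(0.1, 0.5, 0.9), 3, 1,
                  dimnames = list(man$probe_id, "A.9"))
  fr <- methylation_class_fractions(beta_from_means(means, meta, 0), meta)
  expect_equal(unlist(fr[1, c("hypo", "intermediate", "hyper")]),
               c(hypo = 1, intermediate = 1, hyper = 1) / 3)

  means[] <- 0
  fr0 <- methylation_class_fractions(beta_from_means(means, meta, 0), meta)
  expect_equal(unlist(fr0[1, c("hypo", "intermediate", "hyper")]),
               c(hypo = 1, intermediate = 0, hyper = 0))

  # uniform betas: fractions approach (0.25, 0.50, 0.25)
  set.seed(21)
  n <- 100000
  manu <- make_manifest(seq_len(n) * 10)
  betau <- matrix(runif(n * 3), n,
                  dimnames = list(manu$probe_id, meta$sample_id))
  fru <- methylation_class_fractions(betau, meta)
  # replicate means of 3 uniforms concentrate toward 0.5; widen check to
  # the single-sample case for the distributional claim
  meta1 <- meta[1, , drop = FALSE]
  fr1 <- methylation_class_fractions(betau[, 1, drop = FALSE], meta1)
  expect_equal(fr1$hypo, 0.25, tolerance = 0.05)
  expect_equal(fr1$intermediate, 0.50, tolerance = 0.03)
  expect_equal(fr1$hyper, 0.25, tolerance = 0.05)
  expect_equal(fru$hypo + fru$intermediate + fru$hyper, 1)
})
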