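test_that("simulate_dataset emits the 3 x 5 design and parseable files", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(seed = 21, n_transcripts = 120, n_snps = 300,
                           n_enriched_snps = 20, n_de_lnc = 10,
                           n_cis_pairs = 5, n_module_blocks = 1,
                           module_block_size = 8)
  sim <- simulate_dataset(cfg, dir)
  design <- read.delim(sim$paths$design)
  expect_equal(nrow(design), 15)
  expect_equal(as.vector(table(design$individual)), c(5, 5, 5))
  expect_equal(length(unique(design$stage)), 5)

  tx <- read_gtf(sim$paths$gtf)
  expect_length(tx, 120)
  seqs <- read_fasta(sim$paths$fasta)
  tx <- attach_sequences(tx, seqs)  # strict: lengths must match
  expr <- read_expression_matrix(sim$paths$counts, sim$paths$fpkm,
                                 sim$paths$design)
  expect_equal(nrow(expr$counts), 120)
  snps <- read_snp_effects(sim$paths$snps)
  expect_equal(nrow(snps), 300)

  # truth ids all exist in the dataset
  all_ids <- names(tx)
  expect_true(all(sim$truth$lncrna_ids %in% all_ids))
  expect_true(all(sim$truth$de_ids %in% all_ids))
  expect_true(all(unlist(sim$truth$module_blocks) %in% all_ids))
  expect_true(all(sim$truth$enriched_snp_ids %in% snps$id))
  # planted sets are disjoint
  expect_length(intersect(sim$truth$de_ids, sim$truth$cis_pairs$lncrna_id), 0)
})

test_that("same config and seed give byte-identical outputs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- simulation_config(seed = 9, n_transcripts = 80, n_snps = 200,
                           n_enriched_snps = 10, n_de_lnc = 8,
                           n_cis_pairs = 4, n_module_blocks = 1,
                           module_block_size = 6)
  s1 <- simulate_dataset(cfg, d1)
  s2 <- simulate_dataset(cfg, d2)
  for (nm in names(s1$paths)) {
    expect_identical(readLines(s1$paths[[nm]]), readLines(s2$paths[[nm]]),
                     label = nm)
  }
})

test_that("planted fold change is realized in FPKM (generator self-check)", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(seed = 31, n_transcripts = 300, n_de_lnc = 30,
                           de_log2fc = 2, n_snps = 100, n_enriched_snps = 10)
  sim <- simulate_dataset(cfg, dir)
  expr <- read_expression_matrix(sim$paths$counts, sim$paths$fpkm,
                                 sim$paths$design)
  stage <- as.character(expr$design$stage)
  ratio <- vapply(sim$truth$de_ids, function(id) {
    mean(expr$fpkm[id, stage == "+1"]) / mean(expr$fpkm[id, stage == "-14"])
  }, 0.0)
  # planted log2fc = 2 -> ratio ~ 4; within 2x of 4.0 for >= 90% of features
  expect_gte(mean(ratio > 2 & ratio < 8), 0.9)
})

test_that("cis pairs are placed within the window and correlated", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(seed = 13, n_transcripts = 200, n_cis_pairs = 10,
                           n_snps = 100, n_enriched_snps = 10, n_de_lnc = 10)
  sim <- simulate_dataset(cfg, dir)
  loci <- transcript_loci(read_gtf(sim$paths$gtf))
  expr <- read_expression_matrix(sim$paths$counts, sim$paths$fpkm,
                                 sim$paths$design)
  pairs <- sim$truth$cis_pairs
  for (r in seq_len(nrow(pairs))) {
    l <- loci[loci$feature_id == pairs$lncrna_id[r], ]
    g <- loci[loci$feature_id == pairs$gene_id[r], ]
    expect_identical(l$chrom, g$chrom)
    gap <- max(0, max(l$start, g$start) - min(l$end, g$end))
    expect_lte(gap, 100000)
  }
  rhos <- vapply(seq_len(nrow(pairs)), function(r) {
    cor(expr$fpkm[pairs$lncrna_id[r], ], expr$fpkm[pairs$gene_id[r], ],
        method = "spearman")
  }, 0.0)
  expect_gt(median(rhos), 0.5)
})

test_that("infeasible configurations error before writing", {
  expect_error(simulation_config(frac_known = 0.9, frac_novel_u = 0.3,
                                 frac_novel_i = 0.2),
               "sum to 1")
  expect_error(simulation_config(n_snps = 10, n_enriched_snps = 20),
               "n_enriched_snps")
  cfg <- simulation_config(n_transcripts = 40, n_cis_pairs = 30)
  d <- withr::local_tempdir()
  expect_error(simulate_dataset(cfg, file.path(d, "x")), "infeasible")
  expect_false(file.exists(file.path(d, "x", "transcripts.gtf")))
})

test_that("simulate_null_gwas yields an exchangeable universe", {
  cfg <- simulation_config(seed = 5, n_snps = 400, n_enriched_snps = 40)
  fs <- feature_set("set", data.frame(feature_id = "f1", chrom = "chr1",
                                      start = 1e6, end = 2e6), flank = 0L)
  nul <- simulate_null_gwas(cfg, fs)
  expect_true(nul$truth$exchangeable)
  expect_equal(nrow(nul$snps), 400)
  expect_length(nul$truth$in_set_ids, 40)
  # in-set ids really fall inside the interval
  inset <- nul$snps[nul$snps$id %in% nul$truth$in_set_ids, ]
  expect_true(all(inset$pos >= 1e6 & inset$pos <= 2e6))
  # determinism
  nul2 <- simulate_null_gwas(cfg, fs)
  expect_identical(nul, nul2)
  # effect scale identical in and out of the set (exchangeability, loosely)
  out <- nul$snps[!(nul$snps$id %in% nul$truth$in_set_ids), ]
  expect_lt(abs(sd(inset$beta) - sd(out$beta)), 0.05)
})
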