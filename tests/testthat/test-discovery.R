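test_that("find_max_orf handles minimal and degenerate cases", {
  expect_equal(find_max_orf("ATGTAA"), 6L)
  expect_equal(find_max_orf("CCCCCC"), 0L)
  expect_equal(find_max_orf(""), 0L)
  expect_equal(find_max_orf("atgtaa"), 6L)          # case-insensitive
  expect_equal(find_max_orf("ATGAAATAA"), 9L)       # 1 codon + stop
  expect_equal(find_max_orf("ATGAAA"), 0L)          # no stop -> no ORF
  expect_equal(find_max_orf("AATGTAAC"), 6L)        # frame 2
  expect_equal(find_max_orf("ATNTAA"), 0L)          # N never matches start
  expect_equal(find_max_orf("ATGNNNTAA"), 9L)       # N inside the ORF is fine
  expect_error(find_max_orf("ATGXTAA"), "outside")
})

test_that("find_max_orf matches the brute-force oracle on random sequences", {
  set.seed(17)
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    expect_identical(find_max_orf(s), orf_oracle(s), label = paste("seq", i))
  }
  # sprinkle Ns
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 300, TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    expect_identical(find_max_orf(s), orf_oracle(s))
  }
})

make_toy_transcript <- function(id, class_code = "u", len = 500L,
                                n_exons = 2L, occ = 3L, asm = 2L,
                                seq = NULL) {
  per <- len %/% n_exons
  lens <- c(rep(per, n_exons - 1L), len - per * (n_exons - 1L))
  starts <- cumsum(c(1L, head(lens, -1) + 1000L))
  if (is.null(seq)) seq <- strrep("C", len)
  transcript_model(id, paste0("g_", id), "chr1", "+",
                   exons = data.frame(start = starts,
                                      end = starts + lens - 1L),
                   class_code = class_code, assembler_support = asm,
                   sample_occurrence = occ, sequence = seq)
}

toy_inputs <- function(tx) {
  ids <- names(tx)
  fpkm <- matrix(5, length(ids), 15,
                 dimnames = list(ids, paste0("s", 1:15)))
  scores <- data.frame(transcript_id = ids, cpc_score = -1,
                       plek_score = -1, cnci_score = -1)
  list(fpkm = fpkm, scores = scores)
}

test_that("cascade applies filters in order and records first failure", {
  tx <- list(
    known = make_toy_transcript("known", class_code = "="),
    ok = make_toy_transcript("ok"),
    short = make_toy_transcript("short", len = 199L),
    mono = make_toy_transcript("mono", n_exons = 1L, len = 1000L),
    unsup = make_toy_transcript("unsup", occ = 1L, asm = 1L),
    other = make_toy_transcript("other", class_code = "j"),
    orfy = make_toy_transcript("orfy", len = 600L,
                               seq = paste0(strrep("C", 99),
                                            "ATG", strrep("A", 393), "TAA",
                                            strrep("C", 102))))
  names(tx) <- vapply(tx, `[[`, "", "transcript_id")
  inp <- toy_inputs(tx)
  inp$fpkm["ok", ] <- c(rep(0, 14), 0.3)  # boundary: max FPKM == 0.3 passes
  res <- run_discovery_cascade(tx, inp$fpkm, inp$scores)
  rep <- res$report
  get <- function(id, col) rep[[col]][rep$transcript_id == id]
  expect_equal(get("known", "status"), "known")
  expect_equal(get("ok", "status"), "retained_lncRNA")
  expect_equal(get("short", "removal_reason"), "length")
  expect_equal(get("mono", "removal_reason"), "exon_count")
  expect_equal(get("unsup", "removal_reason"), "support")
  expect_equal(get("other", "removal_reason"), "class_code")
  expect_equal(get("orfy", "removal_reason"), "orf")
  # report reconciles: statuses partition the input
  reasons <- c("support", "class_code", "length", "exon_count", "expression",
               "orf", "coding_potential")
  expect_equal(sum(res$counts[c("known", "retained_lncRNA", reasons)]),
               res$counts[["input"]])

  # expression boundary: just below the threshold is removed
  inp$fpkm["ok", ] <- c(rep(0, 14), 0.299)
  res2 <- run_discovery_cascade(tx, inp$fpkm, inp$scores)
  expect_equal(res2$report$removal_reason[res2$report$transcript_id == "ok"],
               "expression")
})

test_that("coding-potential modes any/all differ as documented", {
  tx <- list(x = make_toy_transcript("x"))
  inp <- toy_inputs(tx)
  inp$scores$cpc_score <- 2  # one positive score out of three
  res_any <- run_discovery_cascade(tx, inp$fpkm, inp$scores,
                                   discovery_params(coding_mode = "any"))
  res_all <- run_discovery_cascade(tx, inp$fpkm, inp$scores,
                                   discovery_params(coding_mode = "all"))
  expect_equal(res_any$report$removal_reason, "coding_potential")
  expect_equal(res_all$report$status, "retained_lncRNA")
})

test_that("cascade errors on missing scores or sequence", {
  tx <- list(x = make_toy_transcript("x"))
  inp <- toy_inputs(tx)
  expect_error(run_discovery_cascade(tx, inp$fpkm, inp$scores[0, ]),
               "lacking coding-potential scores")
  tx$x$sequence <- NULL
  expect_error(run_discovery_cascade(tx, inp$fpkm, inp$scores),
               "lack a sequence")
})

test_that("cascade is order-stable and monotone in the FPKM threshold", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(seed = 19, n_transcripts = 150, n_snps = 100,
                           n_enriched_snps = 10, n_de_lnc = 10)
  sim <- simulate_dataset(cfg, dir)
  tx <- attach_sequences(read_gtf(sim$paths$gtf), read_fasta(sim$paths$fasta))
  expr <- read_expression_matrix(sim$paths$counts, sim$paths$fpkm,
                                 sim$paths$design)
  scores <- read.delim(sim$paths$scores)
  res <- run_discovery_cascade(tx, expr, scores)
  set.seed(1)
  perm <- sample(names(tx))
  res_perm <- run_discovery_cascade(tx[perm], expr, scores)
  expect_setequal(unname(res$lncrna_ids), unname(res_perm$lncrna_ids))

  res_hi <- run_discovery_cascade(tx, expr, scores,
                                  discovery_params(min_fpkm = 50))
  expect_true(all(res_hi$lncrna_ids %in% res$lncrna_ids))
})
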