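test_that("read_gtf aggregates exons and validates input", {
  path <- withr::local_tempfile(fileext = ".gtf")
  attr1 <- 'transcript_id "t1"; gene_id "g1"; class_code "u"; assembler_support "2"; sample_occurrence "3";'
  writeLines(c(
    paste("chr1\tsrc\texon\t100\t200\t.\t+\t.", attr1, sep = "\t"),
    paste("chr1\tsrc\texon\t300\t450\t.\t+\t.", attr1, sep = "\t")), path)
  tx <- read_gtf(path)
  expect_length(tx, 1)
  expect_equal(nrow(tx$t1$exons), 2)
  expect_equal(transcript_length(tx$t1), 101L + 151L)
  expect_equal(tx$t1$class_code, "u")
  expect_equal(tx$t1$sample_occurrence, 3L)

  # wrong column count -> parse error naming the line
  writeLines(c("chr1\tsrc\texon\t100\t200\t.\t+",
               paste("chr1\tsrc\texon\t1\t5\t.\t+\t.", attr1, sep = "\t")),
             path)
  expect_error(read_gtf(path), "line 1.*expected 9")

  # end < start -> validation error
  writeLines(paste("chr1\tsrc\texon\t200\t100\t.\t+\t.", attr1, sep = "\t"),
             path)
  expect_error(read_gtf(path), "end.*<.*start")

  # missing class_code defaults to "=" with a warning
  writeLines(paste("chr1\tsrc\texon\t10\t90\t.\t+\t.",
                   'transcript_id "t2"; gene_id "g2";', sep = "\t"), path)
  expect_warning(tx2 <- read_gtf(path), "class_code")
  expect_equal(tx2$t2$class_code, "=")
})

test_that("GTF write/read round trip is lossless on synthetic transcripts", {
  set.seed(11)
  tx <- lapply(1:50, function(i) {
    n_ex <- sample(1:4, 1)
    lens <- sample(50:400, n_ex, replace = TRUE)
    gaps <- sample(100:2000, n_ex, replace = TRUE)
    starts <- i * 10000L + cumsum(gaps) + c(0L, cumsum(head(lens, -1)))
    ends <- starts + lens - 1L
    transcript_model(sprintf("t%02d", i), sprintf("g%02d", i),
                     chrom = sample(c("chr1", "chr2"), 1),
                     strand = sample(c("+", "-"), 1),
                     exons = data.frame(start = starts, end = ends),
                     class_code = sample(c("=", "u", "i", "j"), 1),
                     assembler_support = sample(1:2, 1),
                     sample_occurrence = sample(1:15, 1))
  })
  names(tx) <- vapply(tx, `[[`, "", "transcript_id")
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(tx, path)
  back <- read_gtf(path)
  expect_identical(names(back), names(tx))
  for (id in names(tx)) {
    expect_equal(back[[id]][names(back[[id]]) != "sequence"],
                 tx[[id]][names(tx[[id]]) != "sequence"])
  }
})

test_that("expression matrix reading aligns columns to the design", {
  set.seed(3)
  dir <- withr::local_tempdir()
  design <- data.frame(sample_id = paste0("I", rep(1:3, each = 5), "_",
                                          rep(c("-14", "-10", "-6", "-2", "+1"), 3)),
                       individual = rep(paste0("I", 1:3), each = 5),
                       stage = rep(c("-14", "-10", "-6", "-2", "+1"), 3))
  counts <- matrix(rpois(150, 50), 10, 15,
                   dimnames = list(paste0("f", 1:10), design$sample_id))
  fpkm <- counts / 2
  expr <- expression_matrix(counts, fpkm, design)
  p <- file.path(dir, c("c.tsv", "f.tsv", "d.tsv"))
  write_expression_matrix(expr, p[1], p[2], p[3])
  back <- read_expression_matrix(p[1], p[2], p[3])
  expect_equal(dim(back$counts), c(10L, 15L))
  expect_equal(unname(back$counts), unname(counts))

  # shuffled fpkm columns on disk are realigned
  ftab <- read.delim(p[2], check.names = FALSE)
  ftab <- ftab[, c("feature_id", sample(design$sample_id))]
  write.table(ftab, p[2], sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_expression_matrix(p[1], p[2], p[3])
  expect_equal(back2$fpkm, back$fpkm)
  expect_identical(colnames(back2$counts), colnames(back2$fpkm))

  # missing sample in the matrix is an error naming the id
  ctab <- read.delim(p[1], check.names = FALSE)
  write.table(ctab[, -2], p[1], sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_matrix(p[1], p[2], p[3]),
               colnames(ctab)[2], fixed = TRUE)
})

test_that("SNP table IO validates and round trips", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "snps.tsv")
  writeLines(c("id\tchrom\tpos\tbeta", "s2\tchr1\t500\t0.1",
               "s1\tchr1\t100\t-0.2", "s3\tchr2\t50\t0.05"), p)
  snps <- read_snp_effects(p)
  expect_equal(snps$id, c("s1", "s2", "s3"))  # coordinate order

  writeLines(c("id\tchrom\tpos\tbeta", "s1\tchr1\t100\tNA"), p)
  expect_error(read_snp_effects(p), "non-numeric beta at row 1")
  writeLines(c("id\tchrom\tpos\tbeta", "s1\tchr1\t100\t0.1",
               "s1\tchr1\t200\t0.2"), p)
  expect_error(read_snp_effects(p), "duplicate")

  set.seed(5)
  big <- data.frame(id = sprintf("r%04d", 1:1000),
                    chrom = sample(c("chr1", "chr2", "chr3"), 1000, TRUE),
                    pos = sample.int(1e6, 1000), beta = rnorm(1000),
                    n_AA = rpois(1000, 200), n_Aa = rpois(1000, 400),
                    n_aa = rpois(1000, 200))
  big <- big[order(big$chrom, big$pos), ]; rownames(big) <- NULL
  write_snp_effects(big, p)
  expect_equal(read_snp_effects(p), big)
})

test_that("BED output is 0-based half-open and round trips", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "x.bed")
  feats <- data.frame(feature_id = c("b", "a"), chrom = c("chr1", "chr1"),
                      start = c(300L, 100L), end = c(400L, 200L),
                      strand = c("-", "+"))
  write_bed(feats, p)
  lines <- readLines(p)
  expect_equal(lines[1], "chr1\t99\t200\ta\t0\t+")
  back <- read_bed(p)
  expect_equal(back$start, c(100L, 300L))
  expect_equal(back$end, c(200L, 400L))

  write_bed(feats[0, ], p)
  expect_length(readLines(p), 0)
})

test_that("interval and transcript invariants are enforced", {
  expect_error(genomic_interval("chr1", 0, 10), "start")
  expect_error(genomic_interval("chr1", 10, 5), "end")
  expect_error(transcript_model("t", "g", "chr1", "+",
                                exons = data.frame(start = c(1, 50),
                                                   end = c(60, 100))),
               "overlapping")
  expect_error(transcript_model("t", "g", "chr1", "+",
                                exons = data.frame(start = 1, end = 90),
                                sequence = "ACGT"),
               "sequence length")
})
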