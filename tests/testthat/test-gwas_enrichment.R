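test_that("milk-ability phenotype follows the weight-balance formula", {
  expect_equal(milk_ability_phenotype(60, 15, 5, 2, 3), 45)
  expect_equal(milk_ability_phenotype(0, 0, 0, 0, 0), 0)
  expect_equal(milk_ability_phenotype(10, 15, 0, 0, 0), -5)
  expect_error(milk_ability_phenotype(10, -1, 0, 0, 0), "non-negative")
})

test_that("snp_qc computes MAF and HWE as in the printed cases", {
  snps <- data.frame(id = c("a", "b", "c"), chrom = "chr1", pos = 1:3,
                     beta = 0.1,
                     n_AA = c(25, 99, 50), n_Aa = c(50, 1, 0),
                     n_aa = c(25, 0, 50))
  qc <- snp_qc(snps)
  rep <- qc$report
  # (25,50,25): perfect HWE at MAF 0.5
  expect_equal(rep$maf[1], 0.5)
  expect_equal(rep$hwe_chisq[1], 0)
  expect_equal(rep$hwe_p[1], 1)
  expect_true(rep$kept[1])
  # (99,1,0): minor allele frequency 0.005 < 0.01
  expect_equal(rep$maf[2], 0.005)
  expect_false(rep$kept[2])
  expect_equal(rep$reason[2], "maf")
  # (50,0,50): chi-square = 100, p << 0.001
  expect_equal(rep$hwe_chisq[3], 100)
  expect_lt(rep$hwe_p[3], 0.001)
  expect_equal(rep$reason[3], "hwe")
  expect_equal(qc$snps$id, "a")
  expect_error(snp_qc(data.frame(id = "x", chrom = "1", pos = 1, beta = 0,
                                 n_AA = 0, n_Aa = 0, n_aa = 0)),
               "zero total")
})

test_that("SNP-to-feature assignment respects the flank and deduplicates", {
  fs <- feature_set("s", data.frame(feature_id = c("f1", "f2"),
                                    chrom = "chr1",
                                    start = c(20000L, 25000L),
                                    end = c(30000L, 35000L)),
                    flank = 10000L)
  snps <- data.frame(id = c("in", "edge", "out", "far_chrom", "overlap2"),
                     chrom = c("chr1", "chr1", "chr1", "chr9", "chr1"),
                     pos = c(15000L, 10000L, 9999L, 25000L, 27000L),
                     beta = 1)
  hit <- map_snps_to_features(snps, fs)
  expect_setequal(hit$id, c("in", "edge", "overlap2"))
  # a SNP inside two overlapping intervals counts once
  expect_equal(sum(hit$id == "overlap2"), 1)
})

test_that("sum statistic and its contract", {
  expect_equal(sum_statistic(c(0.5, -0.5)), 0.5)
  expect_equal(sum_statistic(rep(0, 10)), 0)
  expect_error(sum_statistic(numeric(0)), "zero")
  set.seed(1)
  b <- rnorm(100)
  acc <- 0
  for (x in b) acc <- acc + x * x
  expect_equal(sum_statistic(b), acc)
})

test_that("permutation enrichment: determinism, p floor, scale equivariance", {
  set.seed(31)
  u <- null_universe(500, 20)
  e1 <- permutation_enrichment(u$snps, u$fs, n_perm = 500, seed = 9)
  e2 <- permutation_enrichment(u$snps, u$fs, n_perm = 500, seed = 9)
  expect_identical(e1, e2)
  expect_equal(e1$m_g, 20L)
  expect_gte(e1$p_emp, 1 / 501)
  expect_lte(e1$p_emp, 1)

  scaled <- u$snps; scaled$beta <- scaled$beta * 3
  e3 <- permutation_enrichment(scaled, u$fs, n_perm = 500, seed = 9)
  expect_equal(e3$t_obs, 9 * e1$t_obs)
  expect_equal(e3$null_sums, 9 * e1$null_sums)
  expect_equal(e3$p_emp, e1$p_emp)
  expect_equal(e3$fold, e1$fold)

  # plain p-mode uses the strict proportion
  ep <- permutation_enrichment(u$snps, u$fs, n_perm = 500, seed = 9,
                               p_mode = "plain")
  expect_equal(ep$p_emp, sum(e1$null_sums > e1$t_obs) / 500)
})

test_that("exhaustive enumeration on the 4-SNP universe matches", {
  snps <- data.frame(id = paste0("s", 1:4), chrom = "chr1", pos = 1:4,
                     beta = c(2, 1.5, 0.3, 0.1))
  fs <- feature_set("top", data.frame(feature_id = "f", chrom = "chr1",
                                      start = 1L, end = 2L), flank = 0L)
  combos <- combn(4, 2)
  sums <- apply(combos, 2, function(ix) sum(snps$beta[ix]^2))
  t_obs <- sum(snps$beta[1:2]^2)
  p_exact <- mean(sums >= t_obs)  # = 1/6: only the observed pair reaches it
  e <- permutation_enrichment(snps, fs, n_perm = 20000, seed = 2)
  expect_equal(e$m_g, 2L)
  expect_equal(e$t_obs, t_obs)
  expect_lt(abs(e$p_emp - p_exact), 0.012)       # MC error at 20k perms
  expect_lt(abs(e$fold - t_obs / mean(sums)), 0.05)
})

test_that("monotonicity: inflating in-feature effects never increases p", {
  set.seed(77)
  u <- null_universe(300, 15)
  inflate <- function(fac) {
    s <- u$snps
    s$beta[1:15] <- s$beta[1:15] * fac
    permutation_enrichment(s, u$fs, n_perm = 1000, seed = 4)$p_emp
  }
  ps <- vapply(c(1, 2, 4, 8), inflate, 0.0)
  expect_true(all(diff(ps) <= 0))
})
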