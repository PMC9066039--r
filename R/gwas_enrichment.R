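# Permutation-based enrichment of GWAS SNP effects in genomic feature sets.
#
# The statistic is the sum of squared marker effects over the SNPs assigned
# to a feature set (feature bodies +/- a flank); the null is built by
# repeatedly drawing the same number of SNPs uniformly without replacement
# from the whole QC-passed SNP universe.

#' Milk-ability phenotype from litter weights
#'
#' Computed as litter weight at weaning minus litter weight at birth minus
#' litter weight fostered in, plus litter weight at death plus litter weight
#' fostered out. All inputs are in kg and must be non-negative; the result
#' may be negative.
#'
#' @param at_weaning,at_born,foster_in,at_death,foster_out litter weights
#'   (kg); vectorized.
#' @return Numeric milk-ability phenotype (kg).
#' @export
milk_ability_phenotype <- function(at_weaning, at_born, foster_in = 0,
                                   at_death = 0, foster_out = 0) {
  w <- cbind(at_weaning, at_born, foster_in, at_death, foster_out)
  if (any(w < 0, na.rm = TRUE)) stopf("litter weights must be non-negative")
  at_weaning - at_born - foster_in + at_death + foster_out
}

#' SNP quality control: MAF and Hardy-Weinberg filters
#'
#' Allele frequencies are computed from the genotype counts
#' (`n_AA`, `n_Aa`, `n_aa`); the Hardy-Weinberg test is a 1-df chi-square
#' goodness of fit of observed genotype counts against expectations under
#' the estimated allele frequencies. SNPs with minor allele frequency below
#' `maf_min` or HWE p below `hwe_p_min` are removed.
#'
#' @param snps `data.frame` of SNP records with genotype-count columns.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min minimum HWE p-value (default 0.001).
#' @return A list with `snps` (kept records) and `report` (per-SNP `maf`,
#'   `hwe_chisq`, `hwe_p`, `kept`, `reason`).
#' @export
snp_qc <- function(snps, maf_min = 0.01, hwe_p_min = 0.001) {
  need <- c("n_AA", "n_Aa", "n_aa")
  if (!all(need %in% names(snps))) {
    stopf("snp_qc requires genotype count columns: %s",
          paste(need, collapse = ", "))
  }
  nAA <- snps$n_AA; nAa <- snps$n_Aa; naa <- snps$n_aa
  n <- nAA + nAa + naa
  if (any(n == 0)) stopf("SNP(s) with zero total genotype count")
  p <- (2 * nAA + nAa) / (2 * n)
  maf <- pmin(p, 1 - p)
  exp_counts <- cbind(n * p^2, n * 2 * p * (1 - p), n * (1 - p)^2)
  obs <- cbind(nAA, nAa, naa)
  terms <- (obs - exp_counts)^2 / exp_counts
  terms[exp_counts == 0 & obs == 0] <- 0
  chisq <- rowSums(terms)
  hwe_p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  hwe_p[!is.finite(chisq)] <- 0
  kept <- maf >= maf_min & hwe_p >= hwe_p_min
  reason <- rep(NA_character_, nrow(snps))
  reason[maf < maf_min] <- "maf"
  reason[maf >= maf_min & hwe_p < hwe_p_min] <- "hwe"
  report <- data.frame(id = snps$id, maf = maf, hwe_chisq = chisq,
                       hwe_p = hwe_p, kept = kept, reason = reason,
                       stringsAsFactors = FALSE)
  list(snps = snps[kept, , drop = FALSE], report = report)
}

#' Construct a feature set for enrichment testing
#'
#' @param name set name.
#' @param intervals `data.frame` with `feature_id`, `chrom`, `start`, `end`.
#' @param flank flank in nt added on both sides of every interval when
#'   assigning SNPs (default 10000).
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(name, intervals, flank = 10000L) {
  if (flank < 0) stopf("flank must be >= 0")
  validate_intervals(data.frame(chrom = intervals$chrom,
                                start = intervals$start,
                                end = intervals$end, strand = "."))
  structure(list(name = name,
                 intervals = intervals[, c("feature_id", "chrom", "start",
                                           "end")],
                 flank = as.integer(flank)),
            class = "feature_set")
}

#' Assign SNPs to a feature set
#'
#' A SNP is assigned if its position lies within `[start - flank,
#' end + flank]` of at least one interval of the set (strand ignored). Each
#' SNP counts once toward `m_g` no matter how many intervals contain it.
#'
#' @param snps `data.frame` of SNP records (`id`, `chrom`, `pos`, `beta`).
#' @param fs a [feature_set()].
#' @return The subset of `snps` assigned to the set (distinct SNPs).
#' @export
map_snps_to_features <- function(snps, fs) {
  iv <- fs$intervals
  hit <- logical(nrow(snps))
  for (ch in unique(iv$chrom)) {
    rows <- iv$chrom == ch
    srows <- which(snps$chrom == ch)
    if (length(srows) == 0) next
    windows <- IRanges::IRanges(start = pmax(1L, iv$start[rows] - fs$flank),
                                end = iv$end[rows] + fs$flank)
    pts <- IRanges::IRanges(start = snps$pos[srows], width = 1L)
    ov <- IRanges::findOverlaps(pts, windows)
    hit[srows[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  snps[hit, , drop = FALSE]
}

#' Sum-of-squared-effects statistic
#'
#' @param betas non-empty numeric vector of marker effects.
#' @return `sum(betas^2)`.
#' @export
sum_statistic <- function(betas) {
  if (length(betas) == 0) {
    stopf("feature set with zero assigned SNPs cannot be tested")
  }
  sum(betas^2)
}

#' Permutation enrichment of GWAS effects in a feature set
#'
#' Computes the observed sum of squared effects over the `m_g` SNPs assigned
#' to the feature set, then builds a null distribution by drawing `m_g` SNPs
#' uniformly without replacement from the full QC-passed universe `n_perm`
#' times. The empirical p is one-tailed (null at least as large as observed);
#' by default it carries the +1/(N+1) correction, the plain proportion
#' `#\{T_null > T_obs\}/N` is available via `p_mode = "plain"`. Enrichment
#' fold is `T_obs / mean(T_null)`.
#'
#' @param snps_all QC-passed SNP universe (`data.frame` with `id`, `chrom`,
#'   `pos`, `beta`).
#' @param fs a [feature_set()].
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @param p_mode `"corrected"` (default) or `"plain"`.
#' @return An object of class `enrichment_result`: `feature_set`, `m_g`,
#'   `t_obs`, `null_sums`, `p_emp`, `fold`, `seed`, `p_mode`.
#' @export
permutation_enrichment <- function(snps_all, fs, n_perm = 10000L, seed = 1L,
                                   p_mode = c("corrected", "plain")) {
  p_mode <- match.arg(p_mode)
  assigned <- map_snps_to_features(snps_all, fs)
  m_g <- nrow(assigned)
  if (m_g < 1L) stopf("feature set '%s' has no assigned SNPs", fs$name)
  if (m_g > nrow(snps_all)) stopf("m_g exceeds the SNP universe size")
  t_obs <- sum_statistic(assigned$beta)
  beta2 <- snps_all$beta^2
  n <- length(beta2)
  null_sums <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) sum(beta2[sample.int(n, m_g)]), 0.0)
  })
  p_emp <- switch(p_mode,
                  corrected = (sum(null_sums >= t_obs) + 1) / (n_perm + 1),
                  plain = sum(null_sums > t_obs) / n_perm)
  structure(list(feature_set = fs$name, m_g = m_g, t_obs = t_obs,
                 null_sums = null_sums, p_emp = p_emp,
                 fold = t_obs / mean(null_sums), seed = as.integer(seed),
                 p_mode = p_mode),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> set '%s': m_g = %d, T_sum = %.4f, fold = %.4f, p = %.4g (%s, %d perms)\n",
              x$feature_set, x$m_g, x$t_obs, x$fold, x$p_emp, x$p_mode,
              length(x$null_sums)))
  invisible(x)
}
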