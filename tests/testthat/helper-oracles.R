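# Independent oracles used by the unit and acceptance tests. Each one is a
# deliberately naive re-implementation (loops, enumeration) kept independent
# of the package's own code paths.

# Brute-force longest-ORF scan: for every ATG in every frame, walk codon by
# codon to the first stop.
orf_oracle <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (f in 0:2) {
    i <- f + 1L
    while (i + 2L <= n) {
      if (substr(s, i, i + 2L) == "ATG") {
        j <- i
        while (j + 2L <= n) {
          cod <- substr(s, j, j + 2L)
          if (j > i && cod %in% stops) {
            best <- max(best, j + 2L - i + 1L)
            break
          }
          j <- j + 3L
        }
      }
      i <- i + 3L
    }
  }
  as.integer(best)
}

# Rule-by-rule discovery oracle working on raw per-transcript tables.
discovery_oracle <- function(tx_tab, fpkm, scores,
                             min_len = 200, min_exons = 2, min_fpkm = 0.3,
                             max_orf = 360, min_support = 2,
                             coding_mode = "any") {
  retained <- character(0)
  for (r in seq_len(nrow(tx_tab))) {
    id <- tx_tab$transcript_id[r]
    if (tx_tab$sample_occurrence[r] < min_support &&
        tx_tab$assembler_support[r] < min_support) next
    if (tx_tab$class_code[r] == "=") next
    if (!(tx_tab$class_code[r] %in% c("u", "i"))) next
    if (tx_tab$length[r] < min_len) next
    if (tx_tab$n_exons[r] < min_exons) next
    if (max(fpkm[id, ]) < min_fpkm) next
    if (orf_oracle(tx_tab$sequence[r]) >= max_orf) next
    sc <- scores[scores$transcript_id == id, ]
    pos <- c(sc$cpc_score > 0, sc$plek_score > 0, sc$cnci_score > 0)
    coding <- if (coding_mode == "any") any(pos) else all(pos)
    if (coding) next
    retained <- c(retained, id)
  }
  retained
}

# Adjusted Rand index.
ari <- function(a, b) {
  tab <- table(a, b)
  s2 <- function(x) sum(choose(x, 2))
  A <- s2(tab)
  B <- s2(rowSums(tab))
  C <- s2(colSums(tab))
  N <- choose(length(a), 2)
  E <- B * C / N
  (A - E) / ((B + C) / 2 - E)
}

# Step-by-step TMM oracle following the documented trim rule with explicit
# sorting instead of rank arithmetic.
tmm_oracle <- function(counts) {
  totals <- colSums(counts)
  ref <- which.min(abs(totals - median(totals)))
  f <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    if (s == ref) { f[s] <- 1; next }
    keep <- counts[, s] > 0 & counts[, ref] > 0
    ys <- counts[keep, s]; yr <- counts[keep, ref]
    M <- log2((ys / totals[s]) / (yr / totals[ref]))
    A <- 0.5 * log2((ys / totals[s]) * (yr / totals[ref]))
    w <- (totals[s] - ys) / (totals[s] * ys) +
      (totals[ref] - yr) / (totals[ref] * yr)
    n <- length(M)
    loM <- floor(n * 0.30) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    sel <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f[s] <- 2^(sum((M / w)[sel]) / sum((1 / w)[sel]))
  }
  f / exp(mean(log(f)))
}

# Hand-looped TOM formula evaluation.
tom_oracle <- function(expr, power) {
  a <- abs(cor(t(expr)))^power
  diag(a) <- 0
  m <- nrow(a)
  tom <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) { tom[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(m)) l <- l + a[i, u] * a[u, j]
      ki <- sum(a[i, ]); kj <- sum(a[j, ])
      tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  tom
}

# Exact Spearman permutation null for n = 5: distribution of rho over all
# 120 permutations; two-sided exact p of an observed rho.
spearman_exact_p_n5 <- function(rho_obs) {
  perms <- do.call(rbind, combinat_perms(1:5))
  rhos <- apply(perms, 1, function(y) cor(1:5, y))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# NB count matrix for the 3 x 5 design with optional planted stage effects.
# stage_l2fc: named list contrast-stage -> log2 fold change applied to the
# features in `planted`.
make_nb_dataset <- function(n_features, mu_range = c(20, 200), phi = 0.1,
                            planted = integer(0), planted_stage = "+1",
                            planted_l2fc = 0, mu_planted = NULL,
                            indiv_sd = 0.1) {
  stages <- c("-14", "-10", "-6", "-2", "+1")
  design <- data.frame(sample_id = paste0("s", 1:15),
                       individual = rep(c("I1", "I2", "I3"), each = 5),
                       stage = rep(stages, 3), stringsAsFactors = FALSE)
  mu <- exp(stats::runif(n_features, log(mu_range[1]), log(mu_range[2])))
  if (!is.null(mu_planted)) mu[planted] <- mu_planted
  ind_eff <- stats::rnorm(3, 0, indiv_sd)
  lmu <- outer(log(mu), ind_eff[match(design$individual,
                                      c("I1", "I2", "I3"))], `+`)
  if (length(planted) > 0 && planted_l2fc != 0) {
    hit <- design$stage == planted_stage
    lmu[planted, hit] <- lmu[planted, hit] + planted_l2fc * log(2)
  }
  counts <- matrix(stats::rnbinom(n_features * 15, mu = exp(lmu),
                                  size = 1 / phi), n_features, 15,
                   dimnames = list(paste0("g", seq_len(n_features)),
                                   design$sample_id))
  fpkm <- counts / outer(rep(1, n_features), colSums(counts) / 1e6)
  expression_matrix(counts, fpkm, design)
}

# Correlated feature block: nf features sharing a latent profile with
# pairwise correlation cor_w across ns samples.
make_block <- function(nf, cor_w, ns = 15) {
  lat <- stats::rnorm(ns)
  t(vapply(seq_len(nf), function(i) {
    sqrt(cor_w) * lat + sqrt(1 - cor_w) * stats::rnorm(ns)
  }, numeric(ns)))
}

# Exchangeable-null SNP universe on one chromosome with a fixed in-set
# block of m_g SNPs at positions 1..m_g (flank 0 feature set).
null_universe <- function(n_univ, m_g, beta_sd = 1) {
  snps <- data.frame(id = sprintf("S%05d", seq_len(n_univ)),
                     chrom = "chr1", pos = seq_len(n_univ),
                     beta = stats::rnorm(n_univ, 0, beta_sd),
                     stringsAsFactors = FALSE)
  fs <- feature_set("null_set",
                    data.frame(feature_id = "blk", chrom = "chr1",
                               start = 1L, end = m_g),
                    flank = 0L)
  list(snps = snps, fs = fs)
}
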