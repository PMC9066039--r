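# Cis-target prediction: protein-coding genes within a genomic window of a
# lncRNA whose expression correlates (Spearman) across samples.

#' Candidate cis lncRNA-gene pairs by genomic proximity
#'
#' A pair is a candidate if both features are on the same chromosome and the
#' gap between their interval boundaries is at most `window` nt (overlapping
#' intervals have distance 0). Strand is ignored, and the relation is
#' symmetric in the two roles.
#'
#' @param lncs `data.frame` with `feature_id`, `chrom`, `start`, `end`.
#' @param genes `data.frame` of the same shape.
#' @param window maximum gap in nt (default 100000).
#' @return `data.frame` with `lncrna_id`, `gene_id`, `distance`.
#' @export
cis_candidates <- function(lncs, genes, window = 100000L) {
  if (window < 0) stopf("window must be >= 0")
  out <- list()
  for (ch in intersect(unique(lncs$chrom), unique(genes$chrom))) {
    l <- lncs[lncs$chrom == ch, , drop = FALSE]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    ij <- expand.grid(i = seq_len(nrow(l)), j = seq_len(nrow(g)))
    d <- pmax(0L, pmax(l$start[ij$i], g$start[ij$j]) -
                pmin(l$end[ij$i], g$end[ij$j]))
    keep <- d <= window
    if (any(keep)) {
      out[[ch]] <- data.frame(lncrna_id = l$feature_id[ij$i[keep]],
                              gene_id = g$feature_id[ij$j[keep]],
                              distance = as.integer(d[keep]),
                              stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      distance = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$lncrna_id, res$gene_id), , drop = FALSE]
}

#' Spearman correlation with t-approximation p-value
#'
#' The coefficient is the Pearson correlation of mid-ranks (ties averaged);
#' the two-sided p-value comes from `t = rho * sqrt((n-2)/(1-rho^2))` on
#' `n - 2` df. `|rho| = 1` returns the smallest representable positive p.
#'
#' @param x,y numeric vectors of equal length `n >= 4`.
#' @return A list with `rho` and `p` (both `NA` with a warning if either
#'   vector has zero variance).
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 4L) stopf("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warnf("zero variance in one of the vectors; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-12) {
    return(list(rho = sign(rho), p = .Machine$double.xmin))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Predict cis targets of lncRNAs
#'
#' Correlates the expression (FPKM) of each candidate pair across samples by
#' [spearman_correlation()] and flags pairs with `p < alpha` (unadjusted by
#' default; `adjust = TRUE` applies a BH correction before flagging).
#'
#' @param candidates output of [cis_candidates()].
#' @param expr an [expression_matrix()].
#' @param alpha significance threshold (default 0.05).
#' @param adjust apply BH to the pair p-values before flagging.
#' @return `data.frame` with one row per scored pair: `lncrna_id`,
#'   `gene_id`, `distance`, `rho`, `p`, `significant`. Candidates missing
#'   from the matrix are skipped with a warning.
#' @export
predict_targets <- function(candidates, expr, alpha = 0.05, adjust = FALSE) {
  fpkm <- expr$fpkm
  present <- candidates$lncrna_id %in% rownames(fpkm) &
    candidates$gene_id %in% rownames(fpkm)
  if (any(!present)) {
    warnf("%d candidate pair(s) skipped: member(s) missing from the expression matrix",
          sum(!present))
  }
  cand <- candidates[present, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      distance = integer(0), rho = numeric(0), p = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  rp <- lapply(seq_len(nrow(cand)), function(i) {
    suppressWarnings(spearman_correlation(fpkm[cand$lncrna_id[i], ],
                                          fpkm[cand$gene_id[i], ]))
  })
  cand$rho <- vapply(rp, `[[`, 0.0, "rho")
  cand$p <- vapply(rp, `[[`, 0.0, "p")
  pflag <- if (adjust) bh_adjust(cand$p) else cand$p
  cand$significant <- !is.na(pflag) & pflag < alpha
  rownames(cand) <- NULL
  cand
}
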