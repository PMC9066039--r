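# Weighted co-expression module detection: soft-threshold power selection,
# topological overlap matrix, average-linkage module detection and
# module-stage association via module eigengenes. Unsigned network.

scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < 3L || diff(range(k)) < 1e-12) {
    return(list(r2 = 0, slope = NA_real_))
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(keep) < 3L) return(list(r2 = 0, slope = NA_real_))
  x <- log10(kmean[keep])
  y <- log10(freq[keep] / sum(freq[keep]))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r2 = 0, slope = NA_real_))
  }
  slope <- stats::cov(x, y) / stats::var(x)
  r2 <- stats::cor(x, y)^2
  # a scale-free degree distribution decays: only a negative slope counts
  list(r2 = if (slope < 0) r2 else 0, slope = slope)
}

#' Pick the soft-threshold power for an unsigned network
#'
#' For each candidate power the unsigned adjacency `|cor|^power` is formed
#' and the scale-free topology fit is measured as the squared correlation of
#' `log10(freq(k))` against `log10(k)` over a connectivity histogram
#' (counted only when the log-log slope is negative, i.e. the degree
#' distribution decays). Returns the smallest power whose fit reaches
#' `r2_min`, or 6 with a warning if none does.
#'
#' A power only qualifies while the mean connectivity stays at or above
#' `k_min` (default 1): at extreme powers the adjacency of a pure-noise
#' matrix collapses to near-zero connectivity whose histogram mimics a
#' power law, so an unguarded fit would accept noise.
#'
#' @param expr numeric matrix, features x samples.
#' @param powers candidate powers (default `1:20`).
#' @param r2_min scale-free fit threshold (default 0.8).
#' @param k_min minimum mean connectivity for a power to qualify.
#' @param n_bins connectivity histogram bins.
#' @return Integer power, with attribute `fits` (a `data.frame` of `power`,
#'   `r2`, `slope`, `k_mean`).
#' @export
pick_soft_power <- function(expr, powers = 1:20, r2_min = 0.8, k_min = 1,
                            n_bins = 10L) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 3L) stopf("need at least 3 features")
  cmat <- abs(stats::cor(t(expr)))
  diag(cmat) <- 0
  fits <- do.call(rbind, lapply(powers, function(p) {
    a <- cmat^p
    k <- rowSums(a)
    f <- scale_free_fit(k, n_bins)
    data.frame(power = p, r2 = f$r2, slope = f$slope, k_mean = mean(k))
  }))
  ok <- which(fits$r2 >= r2_min & fits$k_mean >= k_min)
  if (length(ok) == 0) {
    warnf("no power reaches scale-free fit R^2 >= %.2f; falling back to 6",
          r2_min)
    out <- 6L
  } else {
    out <- as.integer(fits$power[ok[1]])
  }
  attr(out, "fits") <- fits
  out
}

#' Topological overlap matrix from expression
#'
#' Unsigned adjacency `a_ij = |cor(x_i, x_j)|^power`, then
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `TOM_ii = 1`. Constant features are excluded with a warning before the
#' computation.
#'
#' @param expr numeric matrix, features x samples.
#' @param power soft-threshold power (`>= 1`).
#' @return Symmetric TOM similarity matrix with entries in `[0, 1]`.
#' @export
tom_from_expression <- function(expr, power) {
  if (power < 1) stopf("power must be >= 1")
  expr <- as.matrix(expr)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warnf("%d constant feature(s) excluded from the network", sum(sds == 0))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  a <- abs(stats::cor(t(expr)))^power
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  dimnames(tom) <- list(rownames(expr), rownames(expr))
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' `1 - TOM` with a static cut at a fixed absolute height: branches below
#' `cut_height` become modules if they hold at least `min_module_size`
#' features, everything else is labeled 0 (unassigned). A fixed cut keeps
#' incoherent (noise) features unassigned — their pairwise TOM
#' dissimilarity sits near 1, above any reasonable cut — while coherent
#' blocks merge far below it; a data-adaptive cut that chases the maximal
#' number of branches systematically over-splits coherent modules. Module
#' labels are ordered by decreasing size.
#'
#' @param tom TOM similarity matrix.
#' @param min_module_size minimum features per module (default 5).
#' @param cut_height static cut height on the `1 - TOM` dendrogram
#'   (default 0.95).
#' @return Named integer vector of module labels (0 = unassigned).
#' @export
detect_modules <- function(tom, min_module_size = 5L, cut_height = 0.95) {
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  best <- stats::cutree(hc, h = cut_height)
  sizes <- table(best)
  big <- names(sizes)[sizes >= min_module_size]
  if (length(big) == 0) {
    warnf("no module reaches the minimum size; all features unassigned")
    return(stats::setNames(rep(0L, nrow(tom)), rownames(tom)))
  }
  ord <- big[order(sizes[big], decreasing = TRUE)]
  out <- rep(0L, length(best))
  for (i in seq_along(ord)) out[best == as.integer(ord[i])] <- i
  stats::setNames(out, rownames(tom))
}

#' Module eigengene
#'
#' First principal component across samples of the module's per-feature
#' standardized expression, unit-norm and sign-oriented so the mean
#' correlation with member profiles is positive.
#'
#' @param expr numeric matrix, features x samples.
#' @param members feature ids of the module.
#' @return Numeric eigengene of length `ncol(expr)` (`NA` if the module
#'   expression is constant).
#' @export
module_eigengene <- function(expr, members) {
  sub <- expr[members, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (all(sds == 0)) return(rep(NA_real_, ncol(expr)))
  sub <- sub[sds > 0, , drop = FALSE]
  z <- (sub - rowMeans(sub)) / apply(sub, 1, stats::sd)
  sv <- svd(z, nu = 0, nv = 1)
  eg <- sv$v[, 1]
  cors <- apply(z, 1, function(r) stats::cor(r, eg))
  if (mean(cors, na.rm = TRUE) < 0) eg <- -eg
  stats::setNames(eg, colnames(expr))
}

#' Module-stage association
#'
#' Correlates each module eigengene with each stage's 0/1 sample indicator
#' (Pearson), with p-values from the Student t distribution on `n - 2` df.
#' With `stage_coding = "numeric"` the single quantitative day covariate is
#' used instead of the five indicators.
#'
#' @param labels named module labels from [detect_modules()].
#' @param expr numeric matrix, features x samples (columns = design rows).
#' @param design `data.frame` with `stage` per sample.
#' @param stage_coding `"indicator"` (default) or `"numeric"`.
#' @return A list with `eigengenes` (modules x samples), `r` and `p`
#'   (modules x traits matrices).
#' @export
module_trait_association <- function(labels, expr, design,
                                     stage_coding = c("indicator", "numeric")) {
  stage_coding <- match.arg(stage_coding)
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) stopf("no modules to test")
  stage <- as_stage(design$stage)
  traits <- if (stage_coding == "indicator") {
    m <- vapply(STAGE_LEVELS, function(s) as.numeric(stage == s),
                numeric(length(stage)))
    colnames(m) <- STAGE_LEVELS
    m
  } else {
    matrix(as.numeric(as.character(stage)), ncol = 1,
           dimnames = list(NULL, "day"))
  }
  n <- nrow(traits)
  eg <- t(vapply(mods, function(m) {
    module_eigengene(expr, names(labels)[labels == m])
  }, numeric(ncol(expr))))
  rownames(eg) <- paste0("ME", mods)
  r <- matrix(NA_real_, length(mods), ncol(traits),
              dimnames = list(rownames(eg), colnames(traits)))
  p <- r
  for (i in seq_along(mods)) {
    if (anyNA(eg[i, ])) next
    for (j in seq_len(ncol(traits))) {
      rij <- stats::cor(eg[i, ], traits[, j])
      r[i, j] <- rij
      if (abs(rij) >= 1 - 1e-12) {
        p[i, j] <- .Machine$double.xmin
      } else {
        tstat <- rij * sqrt((n - 2) / (1 - rij^2))
        p[i, j] <- 2 * stats::pt(-abs(tstat), df = n - 2)
      }
    }
  }
  list(eigengenes = eg, r = r, p = p)
}
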