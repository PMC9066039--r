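# Expression-pattern clustering: per-feature stage profiles, k-means (Lloyd)
# and gap-statistic selection of the cluster number.

#' Per-feature stage profiles
#'
#' Mean FPKM per stage, z-standardized per feature (shape, not level, defines
#' an expression pattern). Features with a constant profile are excluded with
#' a warning.
#'
#' @param expr an [expression_matrix()].
#' @param feature_ids features to profile (default: all).
#' @return Matrix features x stages of standardized stage means.
#' @export
stage_profiles <- function(expr, feature_ids = rownames(expr$fpkm)) {
  missing <- setdiff(feature_ids, rownames(expr$fpkm))
  if (length(missing) > 0) {
    stopf("feature(s) missing from the FPKM matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  stage <- as_stage(expr$design$stage)
  prof <- t(apply(expr$fpkm[feature_ids, , drop = FALSE], 1, function(v) {
    tapply(v, stage, mean)
  }))
  colnames(prof) <- levels(stage)
  sds <- apply(prof, 1, stats::sd)
  if (any(sds == 0)) {
    warnf("%d feature(s) with constant stage profile excluded", sum(sds == 0))
    prof <- prof[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (prof - rowMeans(prof)) / sds
}

# Total within-cluster sum of squares of a labeled point set.
wss_of <- function(x, labels) {
  sum(vapply(split(seq_len(nrow(x)), labels), function(rows) {
    xc <- x[rows, , drop = FALSE]
    sum(sweep(xc, 2, colMeans(xc))^2)
  }, 0.0))
}

kmeans_best <- function(x, k, n_init, iter_max = 100L) {
  if (k == 1L) {
    return(list(cluster = rep(1L, nrow(x)), tot.withinss = wss_of(x, rep(1L, nrow(x)))))
  }
  best <- NULL
  for (i in seq_len(n_init)) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = k, iter.max = iter_max,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stopf("k-means failed for k = %d", k)
  best
}

#' Cluster expression patterns by k-means
#'
#' Lloyd's algorithm with `n_init` random restarts (best within-cluster sum
#' of squares kept). Cluster labels are renumbered by descending cluster size
#' so that the labeling is deterministic up to the data and seed.
#'
#' @param profiles numeric matrix, features x dimensions.
#' @param k number of clusters (`1 <= k <= nrow(profiles)`).
#' @param seed RNG seed.
#' @param n_init random restarts.
#' @return A list with `labels` (named integer vector), `k`, `wss`.
#' @export
cluster_patterns <- function(profiles, k, seed = 1L, n_init = 25L) {
  profiles <- as.matrix(profiles)
  if (k < 1L) stopf("k must be >= 1")
  if (k > nrow(profiles)) stopf("k (%d) exceeds number of features (%d)",
                                k, nrow(profiles))
  km <- local_seed(seed, kmeans_best(profiles, k, n_init))
  sizes <- table(km$cluster)
  new_lab <- stats::setNames(seq_along(sizes),
                             names(sort(sizes, decreasing = TRUE)))
  labels <- unname(new_lab[as.character(km$cluster)])
  list(labels = stats::setNames(as.integer(labels), rownames(profiles)),
       k = as.integer(k), wss = km$tot.withinss)
}

#' Select the cluster number by the gap statistic
#'
#' Tibshirani's gap statistic with `B` uniform reference datasets drawn
#' independently per dimension over the observed data range. For each k the
#' gap is `mean(log W*_k) - log W_k` and `s(k)` is the reference
#' standard deviation scaled by `sqrt(1 + 1/B)`; the selected `k*` is the
#' smallest k with `gap(k) >= gap(k+1) - s(k+1)` (1-SE rule), falling back to
#' the largest k in the range if no k satisfies it.
#'
#' @param profiles numeric matrix, features x dimensions.
#' @param k_range candidate cluster numbers (default `1:8`).
#' @param B number of reference datasets (default 50).
#' @param seed RNG seed.
#' @param n_init k-means restarts per fit.
#' @return A list with `k` (selected), `curve` (`data.frame` with `k`,
#'   `gap`, `s`, `log_w`) .
#' @export
gap_statistic_select_k <- function(profiles, k_range = 1:8, B = 50L,
                                   seed = 1L, n_init = 10L) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 2L) stopf("need at least 2 features")
  if (B < 10L) stopf("B must be >= 10")
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > n) stopf("k_range exceeds the number of features")
  tot_ss <- sum(sweep(profiles, 2, colMeans(profiles))^2)
  if (tot_ss < 1e-12) {
    warnf("all profiles identical; k* = 1")
    return(list(k = 1L,
                curve = data.frame(k = 1L, gap = 0, s = 0, log_w = -Inf)))
  }
  lo <- apply(profiles, 2, min)
  hi <- apply(profiles, 2, max)
  local_seed(seed, {
    log_w <- vapply(k_range, function(k) {
      log(kmeans_best(profiles, k, n_init)$tot.withinss + 1e-300)
    }, 0.0)
    log_wb <- matrix(0.0, nrow = B, ncol = length(k_range))
    for (b in seq_len(B)) {
      ref <- vapply(seq_along(lo), function(j) stats::runif(n, lo[j], hi[j]),
                    numeric(n))
      log_wb[b, ] <- vapply(k_range, function(k) {
        log(kmeans_best(ref, k, n_init)$tot.withinss + 1e-300)
      }, 0.0)
    }
    gap <- colMeans(log_wb) - log_w
    s <- apply(log_wb, 2, stats::sd) * sqrt(1 + 1 / B)
    kstar <- k_range[length(k_range)]
    for (i in seq_len(length(k_range) - 1L)) {
      if (gap[i] >= gap[i + 1L] - s[i + 1L]) {
        kstar <- k_range[i]
        break
      }
    }
    list(k = as.integer(kstar),
         curve = data.frame(k = k_range, gap = gap, s = s, log_w = log_w))
  })
}
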