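#' Principal component analysis of an autoscaled matrix
#'
#' Thin SVD-based PCA. The input is assumed centered (autoscaled); scores are
#' the projections onto orthonormal loadings ordered by decreasing variance.
#'
#' @param x numeric matrix (samples x features), already centered.
#' @param n_components number of components; defaults to full rank
#'   `min(n_samples - 1, n_features)`.
#' @return List with `scores`, `loadings` (columns orthonormal),
#'   `var_explained` (per-component fractions of total variance; sums to 1
#'   at full rank), `sdev`.
#' @export
pca <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  max_rank <- min(nrow(x) - 1L, ncol(x))
  n_components <- n_components %||% max_rank
  if (!is_count(n_components) || n_components > max_rank) {
    stop_config("n_components must be in 1..%d", max_rank)
  }
  sv <- svd(x, nu = n_components, nv = n_components)
  tot <- sum(sv$d^2)
  list(scores = sv$u %*% diag(sv$d[seq_len(n_components)], n_components),
       loadings = sv$v,
       var_explained = sv$d[seq_len(n_components)]^2 / tot,
       sdev = sv$d / sqrt(max(nrow(x) - 1, 1)))
}

#' Cross-validated PCA scree analysis
#'
#' Repeated k-fold cross-validation of PCA: in each repetition samples are
#' shuffled into `n_folds` folds; for each fold, PCA is fitted on the
#' training folds (autoscaled with training parameters) and the cumulative
#' total explained variance (TEV) per component count is recorded, along
#' with the held-out reconstruction error. Per repetition:
#' * `q2[r, c]` = 1 - PRESS_c / TSS over the pooled test folds (test rows
#'   scaled with training parameters and projected onto training loadings);
#' * `min_components[r]` = smallest component count whose across-folds mean
#'   cumulative TEV reaches `threshold`.
#'
#' @param table a complete [feature_table] or numeric matrix (QC samples,
#'   if present, are excluded).
#' @param n_folds folds (default 10).
#' @param n_repeats repetitions with fresh random fold splits (default 100).
#' @param threshold cumulative-TEV criterion in (0, 1] (default 0.8).
#' @param max_components cap on the number of components examined; defaults
#'   to the feature count (bounded by training-fold rank).
#' @param seed integer seed.
#' @return An object of class `scree_result`: `tev_curves` (repeats x folds
#'   x components cumulative TEV), `q2` (repeats x components),
#'   `min_components` (per repeat, from the mean curve),
#'   `min_components_fold` (repeats x folds), `threshold`.
#' @export
cv_scree <- function(table, n_folds = 10, n_repeats = 100, threshold = 0.8,
                     max_components = NULL, seed = 1) {
  vals <- if (inherits(table, "feature_table")) bio_samples(table)$values else as.matrix(table)
  if (anyNA(vals)) stop_config("cv_scree requires a complete (imputed) table")
  if (threshold <= 0 || threshold > 1) stop_config("threshold must be in (0, 1]")
  n <- nrow(vals); p <- ncol(vals)
  if (n < n_folds) stop_config("need at least n_folds samples")
  n_comp <- min(max_components %||% p, p, n - ceiling(n / n_folds) - 1L)
  if (n_comp < 1) stop_config("too few samples for even one component")

  tev <- array(NA_real_, c(n_repeats, n_folds, n_comp))
  press <- array(0, c(n_repeats, n_comp))
  tss <- numeric(n_repeats)
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      fold <- sample(rep_len(seq_len(n_folds), n))
      for (f in seq_len(n_folds)) {
        tr <- vals[fold != f, , drop = FALSE]
        te <- vals[fold == f, , drop = FALSE]
        sc <- scale_train(tr)
        sv <- svd(sc$scaled, nu = 0, nv = n_comp)
        ev <- sv$d^2 / sum(sv$d^2)
        tev[r, f, ] <- cumsum(ev)[seq_len(n_comp)]
        te_s <- sweep(sweep(te, 2, sc$center), 2, sc$scale, `/`)
        tss[r] <- tss[r] + sum(te_s^2)
        t_sc <- te_s %*% sv$v
        # cumulative reconstruction: residual sum of squares after c components
        resid <- te_s
        for (cc in seq_len(n_comp)) {
          resid <- resid - t_sc[, cc, drop = FALSE] %*% t(sv$v[, cc, drop = FALSE])
          press[r, cc] <- press[r, cc] + sum(resid^2)
        }
      }
    }
  })
  q2 <- 1 - press / tss
  mean_curves <- apply(tev, c(1, 3), mean)            # repeats x components
  first_reach <- function(curve) {
    i <- which(curve >= threshold)
    if (length(i)) min(i) else NA_integer_
  }
  structure(list(
    tev_curves = tev,
    q2 = q2,
    min_components = apply(mean_curves, 1, first_reach),
    min_components_fold = apply(tev, c(1, 2), first_reach),
    threshold = threshold), class = "scree_result")
}

#' @export
print.scree_result <- function(x, ...) {
  mc <- x$min_components
  cat(sprintf("<scree_result> %d repeats x %d folds | threshold %.2f | min components: median %s (range %s-%s)\n",
              dim(x$tev_curves)[1], dim(x$tev_curves)[2], x$threshold,
              stats::median(mc, na.rm = TRUE), min(mc, na.rm = TRUE), max(mc, na.rm = TRUE)))
  invisible(x)
}

#' Ward-linkage hierarchical clustering
#'
#' Agglomerative clustering of samples under Ward's minimum-variance
#' criterion on Euclidean distances (the squared-Euclidean "ward.D2"
#' update). Input must be complete (imputed, typically autoscaled).
#'
#' @param x numeric matrix (samples x features) or complete [feature_table].
#' @return An `hclust` object.
#' @export
ward_hca <- function(x) {
  vals <- if (inherits(x, "feature_table")) x$values else as.matrix(x)
  if (anyNA(vals)) stop_config("ward_hca requires a complete (imputed) table")
  if (nrow(vals) < 2) stop_config("need at least 2 samples")
  stats::hclust(stats::dist(vals, method = "euclidean"), method = "ward.D2")
}

#' Cluster purity of a dendrogram cut
#'
#' Cuts the tree into `k` clusters and scores how well clusters coincide
#' with known class labels: per-cluster purity is the fraction of samples
#' from the cluster's majority class, and the overall purity the
#' size-weighted mean.
#'
#' @param dendrogram an `hclust` object (from [ward_hca()]).
#' @param class_labels one label per sample.
#' @param k number of clusters (default: number of distinct labels).
#' @return An object of class `purity_result`: `assignments`,
#'   `per_cluster_purity`, `overall_purity`, `k`.
#' @export
cluster_purity <- function(dendrogram, class_labels, k = NULL) {
  stopifnot(inherits(dendrogram, "hclust"))
  labels <- as.factor(class_labels)
  n <- length(dendrogram$order)
  if (length(labels) != n) stop_config("need one class label per clustered sample")
  k <- k %||% nlevels(droplevels(labels))
  if (!is_count(k) || k > n) stop_config("k must be in 1..%d", n)
  assign <- stats::cutree(dendrogram, k = k)
  per <- vapply(seq_len(k), function(cl) {
    tab <- table(labels[assign == cl])
    max(tab) / sum(tab)
  }, numeric(1))
  sizes <- tabulate(assign, k)
  structure(list(assignments = assign,
                 per_cluster_purity = per,
                 overall_purity = sum(per * sizes) / n,
                 k = k), class = "purity_result")
}

#' @export
print.purity_result <- function(x, ...) {
  cat(sprintf("<purity_result> k=%d | overall purity %.3f\n", x$k, x$overall_purity))
  invisible(x)
}
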