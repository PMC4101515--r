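#' Imputation configuration
#'
#' @param method one of `"zero"`, `"mean"`, `"median"`, `"knn"`, `"rf"`.
#' @param k neighbours for kNN (default 10, the convention of the classical
#'   expression-data implementation; the value used in the original
#'   metabolomics comparison is not reported).
#' @param n_trees trees per random forest (default 100).
#' @param max_iter cap on random-forest imputation sweeps (default 10).
#' @param min_node minimum node size of the regression trees (default 5).
#' @param mtry features tried per split; default `floor(sqrt(p - 1))`, the
#'   convention of the iterative-forest imputation package the comparison
#'   is based on.
#' @param weighted if `TRUE`, kNN averages neighbours with inverse-distance
#'   weights (classical variant); default `FALSE` = unweighted mean.
#' @param orientation kNN neighbour entities: `"features"` (default;
#'   metabolites are matched by partial distances, the expression-data
#'   tradition) or `"samples"` (the same algorithm on the transposed
#'   matrix, falling back to the sample's observed mean).
#' @param seed integer seed (random forest only).
#' @return An object of class `imputation_config`.
#' @export
imputation_config <- function(method = c("zero", "mean", "median", "knn", "rf"),
                              k = 10, n_trees = 100, max_iter = 10,
                              min_node = 5, mtry = NULL, weighted = FALSE,
                              orientation = c("features", "samples"),
                              seed = 1) {
  method <- match.arg(method)
  orientation <- match.arg(orientation)
  if (!is_count(k) || !is_count(n_trees) || !is_count(max_iter) || !is_count(min_node)) {
    stop_config("k, n_trees, max_iter and min_node must be positive integers")
  }
  if (!is.null(mtry) && !is_count(mtry)) stop_config("mtry must be a positive integer")
  structure(list(method = method, k = k, n_trees = n_trees, max_iter = max_iter,
                 min_node = min_node, mtry = mtry, weighted = weighted,
                 orientation = orientation, seed = seed),
            class = "imputation_config")
}

new_imputation_result <- function(table, completed_vals, method,
                                  convergence = numeric(0), fallback_count = 0L) {
  structure(list(
    completed = feature_table(completed_vals, class_labels = table$class_labels,
                              is_qc = table$is_qc),
    method = method,
    n_imputed = sum(is.na(table$values)),
    convergence = convergence,
    fallback_count = fallback_count), class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> method=%s | %d cells imputed", x$method, x$n_imputed))
  if (x$method == "knn") cat(sprintf(" | %d fallbacks", x$fallback_count))
  if (x$method == "rf" && length(x$convergence)) {
    cat(sprintf(" | delta: %s", paste(signif(x$convergence, 3), collapse = " ")))
  }
  cat("\n")
  invisible(x)
}

#' Impute missing values
#'
#' Dispatcher over the five substitutes compared in the package:
#' [impute_zero()], [impute_mean()], [impute_median()], [impute_knn()],
#' [impute_rf()].
#'
#' @param table a [feature_table] with missing cells (`NA`).
#' @param config an [imputation_config()] (or a method name).
#' @return An `imputation_result`: `completed` table (no missing cells; all
#'   observed cells bit-identical to the input), `method`, `n_imputed`, plus
#'   `convergence` (rf) and `fallback_count` (knn).
#' @export
impute <- function(table, config = imputation_config("zero")) {
  if (is.character(config)) config <- imputation_config(config)
  stopifnot(inherits(config, "imputation_config"))
  switch(config$method,
         zero = impute_zero(table),
         mean = impute_mean(table),
         median = impute_median(table),
         knn = impute_knn(table, config),
         rf = impute_rf(table, config))
}

#' Zero imputation
#' @rdname impute
#' @export
impute_zero <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  vals <- table$values
  vals[is.na(vals)] <- 0
  new_imputation_result(table, vals, "zero")
}

check_all_observed <- function(vals) {
  empty <- which(colSums(!is.na(vals)) == 0)
  if (length(empty)) {
    stop_config("feature(s) with no observed values: %s",
                paste(colnames(vals)[empty], collapse = ", "))
  }
}

impute_column_stat <- function(table, stat, method) {
  stopifnot(inherits(table, "feature_table"))
  vals <- table$values
  check_all_observed(vals)
  for (j in which(colSums(is.na(vals)) > 0)) {
    obs <- vals[, j][!is.na(vals[, j])]
    vals[is.na(vals[, j]), j] <- stat(obs)
  }
  new_imputation_result(table, vals, method)
}

#' Mean imputation
#' @rdname impute
#' @export
impute_mean <- function(table) impute_column_stat(table, mean, "mean")

#' Median imputation
#' @rdname impute
#' @export
impute_median <- function(table) impute_column_stat(table, stats::median, "median")

# Feature-to-feature partial Euclidean distances: d(f,g) = sqrt(mean over
# co-observed samples of (f-g)^2); NA when no sample observes both.
knn_feature_distances <- function(vals) {
  p <- ncol(vals)
  d <- matrix(NA_real_, p, p)
  for (f in seq_len(p - 1)) {
    for (g in (f + 1):p) {
      co <- !is.na(vals[, f]) & !is.na(vals[, g])
      if (any(co)) {
        d[f, g] <- d[g, f] <- sqrt(mean((vals[co, f] - vals[co, g])^2))
      }
    }
  }
  d
}

#' k-nearest-neighbour imputation
#'
#' Neighbours are features (metabolites), following the expression-data
#' tradition: the distance between two features is the Euclidean distance
#' averaged over the samples where both are observed, so candidates with
#' missing coordinates still get a distance. The k nearest features of a
#' feature with a hole are averaged (unweighted by default) at that sample;
#' if none of the k neighbours is observed there, the feature's own observed
#' mean is used and `fallback_count` incremented. Equidistant neighbours are
#' broken by lowest feature index.
#'
#' @rdname impute
#' @export
knn_impute_matrix <- function(vals, k, weighted) {
  out <- vals
  fallback <- 0L
  need <- which(colSums(is.na(vals)) > 0)
  if (length(need)) {
    d <- knn_feature_distances(vals)
    col_means <- colMeans(vals, na.rm = TRUE)
    for (f in need) {
      df <- d[f, ]
      cand <- which(!is.na(df))
      # ties broken by lowest feature index (order() is stable on the index)
      nb <- cand[order(df[cand])][seq_len(min(k, length(cand)))]
      for (s in which(is.na(vals[, f]))) {
        avail <- nb[!is.na(vals[s, nb])]
        if (length(avail)) {
          if (isTRUE(weighted)) {
            w <- 1 / pmax(d[f, avail], .Machine$double.eps)
            out[s, f] <- sum(w * vals[s, avail]) / sum(w)
          } else {
            out[s, f] <- mean(vals[s, avail])
          }
        } else {
          out[s, f] <- col_means[f]
          fallback <- fallback + 1L
        }
      }
    }
  }
  list(out = out, fallback = fallback)
}

impute_knn <- function(table, config = imputation_config("knn")) {
  stopifnot(inherits(table, "feature_table"))
  vals <- table$values
  n_units <- if (config$orientation == "features") ncol(vals) else nrow(vals)
  if (config$k >= n_units) {
    stop_config("k (%d) must be smaller than the number of %s (%d)",
                config$k, config$orientation, n_units)
  }
  check_all_observed(vals)
  if (config$orientation == "samples" && any(rowSums(!is.na(vals)) == 0)) {
    stop_config("sample(s) with no observed values cannot be imputed by sample-wise kNN")
  }
  res <- if (config$orientation == "features") {
    knn_impute_matrix(vals, config$k, config$weighted)
  } else {
    tr <- knn_impute_matrix(t(vals), config$k, config$weighted)
    tr$out <- t(tr$out)
    tr
  }
  new_imputation_result(table, res$out, "knn", fallback_count = res$fallback)
}

#' Iterative random-forest imputation
#'
#' missForest-style scheme: missing cells are initialized with feature means;
#' features are visited in order of increasing missingness; each feature with
#' holes is regressed on all other (currently imputed) features with a
#' regression random forest fitted on the rows where it is observed, and its
#' holes are replaced by forest predictions. After each full sweep the
#' relative change `delta = sum((X_new - X_old)^2) / sum(X_new^2)` is
#' recorded; iteration stops when delta increases (the matrix from the sweep
#' before the increase is returned) or after `max_iter` sweeps.
#'
#' @rdname impute
#' @export
impute_rf <- function(table, config = imputation_config("rf")) {
  stopifnot(inherits(table, "feature_table"))
  vals <- table$values
  p <- ncol(vals)
  if (p < 2) stop_config("random-forest imputation needs at least 2 features")
  check_all_observed(vals)
  miss <- is.na(vals)
  if (!any(miss)) return(new_imputation_result(table, vals, "rf"))

  cur <- vals
  for (j in seq_len(p)) cur[miss[, j], j] <- mean(vals[, j], na.rm = TRUE)
  visit <- order(colSums(miss))  # increasing missingness
  visit <- visit[colSums(miss)[visit] > 0]
  mtry <- config$mtry %||% max(1L, floor(sqrt(p - 1)))

  deltas <- numeric(0)
  best <- cur
  with_seed(config$seed, {
    for (it in seq_len(config$max_iter)) {
      prev <- cur
      for (j in visit) {
        obs <- !miss[, j]
        pred <- .rf_regress(cur[obs, -j, drop = FALSE], vals[obs, j],
                            cur[!obs, -j, drop = FALSE],
                            as.integer(config$n_trees), as.integer(mtry),
                            as.integer(config$min_node))
        cur[!obs, j] <- pred
      }
      deltas[it] <- sum((cur - prev)^2) / sum(cur^2)
      if (it > 1 && deltas[it] > deltas[it - 1]) break
      best <- cur
    }
  })
  new_imputation_result(table, best, "rf", convergence = deltas)
}

#' Normalized root-mean-square error of an imputation
#'
#' `sqrt(mean((imputed - true)^2) / var_pop(true))` over the masked cells
#' only, with the population variance (n denominator) of the true masked
#' values, so that imputing every hole with the mean of the true masked
#' values scores exactly 1 and a perfect imputation scores 0.
#'
#' @param result an `imputation_result` (or completed [feature_table]/matrix).
#' @param truth a [masked_dataset][apply_missingness] carrying the mask and
#'   the complete table.
#' @return Nonnegative scalar.
#' @export
nrmse <- function(result, truth) {
  stopifnot(inherits(truth, "masked_dataset"))
  vals <- if (inherits(result, "imputation_result")) result$completed$values
          else if (inherits(result, "feature_table")) result$values
          else as.matrix(result)
  if (!identical(dim(vals), dim(truth$truth$values))) {
    stop_config("imputed table and truth have different shapes")
  }
  if (!any(truth$mask)) stop_config("empty mask: NRMSE undefined")
  tv <- truth$truth$values[truth$mask]
  iv <- vals[truth$mask]
  v <- mean((tv - mean(tv))^2)
  if (v == 0) stop_config("true masked values have zero variance: NRMSE undefined")
  sqrt(mean((iv - tv)^2) / v)
}
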