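#' Sample skewness
#'
#' Third standardized moment. Default variant `g1 = m3 / m2^(3/2)` with
#' central moments on the n denominator; `"adjusted"` applies the
#' Fisher-Pearson small-sample correction
#' `b1 = g1 * sqrt(n(n-1)) / (n-2)`. A symmetric sample scores 0; the
#' log-normal-like intensity distributions of GC-MS metabolites are strongly
#' positive.
#'
#' @param values numeric vector; `NA` (missing) values are dropped.
#' @param variant `"g1"` (default) or `"adjusted"`.
#' @return Scalar skewness.
#' @export
skewness <- function(values, variant = c("g1", "adjusted")) {
  variant <- match.arg(variant)
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 3) stop_config("skewness requires at least 3 observed values")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) stop_config("skewness undefined for zero-variance values")
  g1 <- mean((v - m)^3) / m2^1.5
  if (variant == "adjusted") g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

#' Excess kurtosis
#'
#' `m4 / m2^2 - 3` (population moments); a normal sample scores near 0.
#'
#' @inheritParams skewness
#' @return Scalar excess kurtosis.
#' @export
kurtosis <- function(values) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 3) stop_config("kurtosis requires at least 3 observed values")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) stop_config("kurtosis undefined for zero-variance values")
  mean((v - m)^4) / m2^2 - 3
}

#' Per-feature, per-class distribution diagnostics
#'
#' For every (feature, class) cell: observed count, percent missing, mean,
#' median, sample sd, standard error (`sd / sqrt(n_observed)`), skewness and
#' excess kurtosis -- all over observed values only. Cells with fewer than 3
#' observed values (or zero variance) get `NA` skewness/kurtosis and are
#' flagged rather than erroring. The mean/median ratio is the recommended
#' quick check for skew before choosing an imputation method.
#'
#' @param table a [feature_table] (QC samples are excluded).
#' @param skew_variant passed to [skewness()].
#' @return A data.frame of class `summary_table`, one row per
#'   (feature, class).
#' @export
group_summary <- function(table, skew_variant = "g1") {
  stopifnot(inherits(table, "feature_table"))
  tb <- bio_samples(table)
  labels <- droplevels(tb$class_labels)
  rows <- expand.grid(feature = feature_ids(tb), class = levels(labels),
                      stringsAsFactors = FALSE)
  stats_list <- lapply(seq_len(nrow(rows)), function(i) {
    v <- tb$values[labels == rows$class[i], rows$feature[i]]
    obs <- v[!is.na(v)]
    n_obs <- length(obs)
    can_shape <- n_obs >= 3 && length(unique(obs)) > 1
    data.frame(
      n_observed = n_obs,
      pct_missing = 100 * (length(v) - n_obs) / length(v),
      mean = if (n_obs) mean(obs) else NA_real_,
      median = if (n_obs) stats::median(obs) else NA_real_,
      sd = if (n_obs >= 2) stats::sd(obs) else NA_real_,
      se = if (n_obs >= 2) stats::sd(obs) / sqrt(n_obs) else NA_real_,
      skewness = if (can_shape) skewness(obs, skew_variant) else NA_real_,
      kurtosis = if (can_shape) kurtosis(obs) else NA_real_,
      shape_flagged = !can_shape)
  })
  out <- cbind(rows, do.call(rbind, stats_list))
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Compare imputation methods end to end
#'
#' Runs the full evaluation grid for a set of imputation methods on one
#' masked dataset: imputation error (NRMSE against the retained ground
#' truth), cross-validated PCA component demand at the TEV threshold, Ward
#' HCA purity, and bootstrap-validated PC-LDA and PLS-DA classification
#' rates with their selected component counts.
#'
#' @param dataset a [masked_dataset][apply_missingness] (or a
#'   [feature_table] with missing cells, in which case NRMSE is `NA`).
#' @param methods character vector of imputation method names.
#' @param eval_config list of evaluation knobs: `n_folds`, `n_repeats`,
#'   `threshold`, `max_components`, `n_boot`, `k`, `n_trees`, `seed`.
#'   Defaults are desk-scale (repeats/boot counts reduced from the
#'   full-study 100).
#' @return A data.frame of class `method_comparison`, one row per method:
#'   `method`, `nrmse`, `scree_components` (mean over repetitions of the
#'   per-repetition minimum component count), `purity`, `pc_lda_rate`,
#'   `pc_lda_components`, `pls_da_rate`, `pls_da_components`.
#' @export
compare_methods <- function(dataset,
                            methods = c("zero", "mean", "median", "knn", "rf"),
                            eval_config = list()) {
  known <- c("zero", "mean", "median", "knn", "rf")
  if (!all(methods %in% known)) {
    stop_config("unknown method(s): %s", paste(setdiff(methods, known), collapse = ", "))
  }
  cfg <- utils::modifyList(list(n_folds = 10, n_repeats = 20, threshold = 0.8,
                                max_components = 10, n_boot = 50, k = 10,
                                n_trees = 100, seed = 1), eval_config)
  if (inherits(dataset, "masked_dataset")) {
    tab <- dataset$table
    truth <- if (any(dataset$mask)) dataset else NULL
  } else if (inherits(dataset, "feature_table")) {
    tab <- dataset
    truth <- NULL
  } else stop_config("dataset must be a masked_dataset or feature_table")

  rows <- lapply(methods, function(m) {
    icfg <- imputation_config(m, k = cfg$k, n_trees = cfg$n_trees,
                              seed = derive_seed(cfg$seed, paste0("impute_", m)))
    res <- impute(tab, icfg)
    completed <- bio_samples(res$completed)
    sc <- autoscale(completed)
    scree <- cv_scree(completed, n_folds = cfg$n_folds, n_repeats = cfg$n_repeats,
                      threshold = cfg$threshold,
                      seed = derive_seed(cfg$seed, "scree"))
    pur <- cluster_purity(ward_hca(sc$scaled), droplevels(completed$class_labels))
    boot_lda <- bootstrap_evaluate(completed, classifier = "pc_lda",
                                   max_components = cfg$max_components,
                                   n_boot = cfg$n_boot,
                                   seed = derive_seed(cfg$seed, "boot_lda"))
    boot_pls <- bootstrap_evaluate(completed, classifier = "pls_da",
                                   max_components = cfg$max_components,
                                   n_boot = cfg$n_boot,
                                   seed = derive_seed(cfg$seed, "boot_pls"))
    data.frame(method = m,
               nrmse = if (is.null(truth)) NA_real_ else nrmse(res, truth),
               scree_components = mean(scree$min_components, na.rm = TRUE),
               purity = pur$overall_purity,
               pc_lda_rate = boot_lda$headline_rate,
               pc_lda_components = boot_lda$selected_components,
               pls_da_rate = boot_pls$headline_rate,
               pls_da_components = boot_pls$selected_components)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("method_comparison", "data.frame")
  out
}
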