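#' Normalize to an internal standard
#'
#' Divides every sample (row) by its intensity of a spiked internal-standard
#' feature (e.g. succinic d4 acid), correcting per-sample technical
#' variability from derivatisation and injection volume. The internal-standard
#' column is removed from the output; missing cells stay missing.
#'
#' @param table a [feature_table].
#' @param is_feature feature id of the internal standard.
#' @return A [feature_table] without the internal-standard column.
#' @export
normalize_internal_standard <- function(table, is_feature) {
  stopifnot(inherits(table, "feature_table"))
  j <- match(is_feature, feature_ids(table))
  if (is.na(j)) stop_config("internal standard '%s' not found", is_feature)
  is_vals <- table$values[, j]
  bad <- which(is.na(is_vals) | is_vals <= 0)
  if (length(bad)) {
    stop_config("internal standard missing or nonpositive in sample(s): %s",
                paste(sample_ids(table)[bad], collapse = ", "))
  }
  out <- table$values[, -j, drop = FALSE] / is_vals
  feature_table(out, class_labels = table$class_labels, is_qc = table$is_qc)
}

#' QC-based feature filtering
#'
#' Two sequential filters computed on the pooled-QC injections: (1) features
#' detected (non-missing) in fewer than `detection_min` of QC samples are
#' removed; (2) among survivors, features whose QC coefficient of variation
#' (sample sd / mean x 100, observed QC values only) exceeds `cv_max` percent
#' are removed as poorly reproducible.
#'
#' @param table a [feature_table] containing at least one QC sample.
#' @param detection_min minimum detected fraction in QC (default 0.5).
#' @param cv_max maximum QC coefficient of variation in percent (default 30).
#' @return A list with `table` (filtered [feature_table]) and `report`
#'   (class `filter_report`: `removed_by_detection`, `removed_by_cv`,
#'   `cv_values`).
#' @export
qc_filter <- function(table, detection_min = 0.5, cv_max = 30) {
  stopifnot(inherits(table, "feature_table"))
  qc_rows <- which(table$is_qc)
  if (!length(qc_rows)) stop_config("qc_filter requires at least one QC sample")
  qc <- table$values[qc_rows, , drop = FALSE]
  det_frac <- colMeans(!is.na(qc))
  cv_values <- apply(qc, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    m <- mean(v)
    if (m == 0) return(NA_real_)
    100 * stats::sd(v) / m
  })
  removed_det <- feature_ids(table)[det_frac < detection_min]
  survivors <- setdiff(feature_ids(table), removed_det)
  removed_cv <- survivors[!is.na(cv_values[survivors]) & cv_values[survivors] > cv_max]
  keep <- setdiff(survivors, removed_cv)
  report <- structure(list(removed_by_detection = removed_det,
                           removed_by_cv = removed_cv,
                           cv_values = cv_values),
                      class = "filter_report")
  list(table = subset_table(table, cols = match(keep, feature_ids(table))),
       report = report)
}

#' Autoscale a completed table
#'
#' Per-feature standardization: subtract the column mean, divide by the
#' column standard deviation (sample sd, n-1 denominator). Applied strictly
#' after imputation -- the input must be complete. Returns the transform
#' parameters so held-out data can be scaled with training-set parameters.
#'
#' @param x a complete [feature_table] or numeric matrix.
#' @return A list of class `autoscale`: `scaled` (matrix with columns of mean
#'   0 and sd 1), `center`, `scale`.
#' @export
autoscale <- function(x) {
  vals <- if (inherits(x, "feature_table")) x$values else as.matrix(x)
  if (anyNA(vals)) {
    stop_config("autoscaling requires a complete table: impute missing values first")
  }
  ctr <- colMeans(vals)
  scl <- apply(vals, 2, stats::sd)
  zero <- which(scl == 0)
  if (length(zero)) {
    stop_config("zero-variance feature(s): %s",
                paste((colnames(vals) %||% as.character(zero))[zero], collapse = ", "))
  }
  scaled <- sweep(sweep(vals, 2, ctr), 2, scl, `/`)
  structure(list(scaled = scaled, center = ctr, scale = scl), class = "autoscale")
}

#' Scale new data with previously fitted autoscale parameters
#'
#' Applies a training-set [autoscale()] transform (its per-feature means and
#' sds) to held-out data, as honest cross-validation and bootstrap loops
#' require.
#'
#' @param fit an [autoscale()] result.
#' @param x matrix or [feature_table] with the same features.
#' @return Scaled numeric matrix.
#' @export
apply_autoscale <- function(fit, x) {
  vals <- if (inherits(x, "feature_table")) x$values else as.matrix(x)
  sweep(sweep(vals, 2, fit$center), 2, fit$scale, `/`)
}

# Tolerant variant for resampling loops: a bootstrap draw can produce a
# constant column; such columns are centered and left at 0 instead of
# erroring, since they carry no information for the classifier.
scale_train <- function(vals) {
  ctr <- colMeans(vals)
  scl <- apply(vals, 2, stats::sd)
  scl[scl == 0] <- 1
  list(scaled = sweep(sweep(vals, 2, ctr), 2, scl, `/`), center = ctr, scale = scl)
}
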