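#' Samples-by-features metabolite intensity table
#'
#' The central container of the package: a numeric matrix of (relative)
#' intensities with samples in rows and metabolite features in columns.
#' Missing cells are encoded as `NA` and are strictly distinct from `0`
#' (a zero is a real measured zero, not a missing value). Each sample
#' carries a class label (e.g. normoxia / hypoxia / anoxia) and a flag
#' marking pooled quality-control (QC) injections; QC samples typically
#' have no class label.
#'
#' @param values numeric matrix, samples x features; `NA` = missing; no
#'   negative intensities.
#' @param sample_ids unique character vector, one per row. Defaults to
#'   rownames or `S1..Sn`.
#' @param feature_ids unique character vector, one per column. Defaults to
#'   colnames or `F1..Fp`.
#' @param class_labels factor or character, one per sample (`NA` allowed for
#'   QC samples).
#' @param is_qc logical, one per sample (recycled if length 1).
#'
#' @return An object of class `feature_table`: a list with elements
#'   `values`, `class_labels`, `is_qc`. Ids live in the dimnames of `values`.
#' @export
feature_table <- function(values, sample_ids = NULL, feature_ids = NULL,
                          class_labels = NULL, is_qc = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_config("`values` must be a numeric matrix (samples x features)")
  }
  n <- nrow(values); p <- ncol(values)
  sample_ids <- as.character(sample_ids %||% rownames(values) %||% paste0("S", seq_len(n)))
  feature_ids <- as.character(feature_ids %||% colnames(values) %||% paste0("F", seq_len(p)))
  if (length(sample_ids) != n) stop_config("sample_ids length != number of rows")
  if (length(feature_ids) != p) stop_config("feature_ids length != number of columns")
  if (anyDuplicated(sample_ids)) stop_config("duplicate sample ids: %s",
    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids)) stop_config("duplicate feature ids: %s",
    paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (any(values < 0, na.rm = TRUE)) stop_config("negative intensities are not allowed")
  dimnames(values) <- list(sample_ids, feature_ids)
  is_qc <- rep_len(as.logical(is_qc), n)
  if (is.null(class_labels)) {
    class_labels <- factor(rep(NA_character_, n))
  } else {
    if (length(class_labels) != n) stop_config("class_labels length != number of samples")
    class_labels <- as.factor(class_labels)
  }
  if (anyNA(class_labels[!is_qc])) {
    stop_config("class label missing for non-QC sample(s): %s",
      paste(sample_ids[!is_qc & is.na(class_labels)], collapse = ", "))
  }
  structure(list(values = values, class_labels = class_labels, is_qc = is_qc),
            class = "feature_table")
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
print.feature_table <- function(x, ...) {
  n_miss <- sum(is.na(x$values))
  cat(sprintf("<feature_table> %d samples x %d features | %d missing (%.1f%%) | %d QC\n",
              nrow(x$values), ncol(x$values), n_miss,
              100 * n_miss / length(x$values), sum(x$is_qc)))
  cl <- table(droplevels(x$class_labels[!x$is_qc]))
  if (length(cl)) cat("classes:", paste(names(cl), cl, sep = "=", collapse = " "), "\n")
  invisible(x)
}

sample_ids <- function(x) rownames(x$values)
feature_ids <- function(x) colnames(x$values)

# Subset rows/columns keeping metadata aligned.
subset_table <- function(x, rows = NULL, cols = NULL) {
  rows <- rows %||% seq_len(nrow(x$values))
  cols <- cols %||% seq_len(ncol(x$values))
  feature_table(x$values[rows, cols, drop = FALSE],
                class_labels = x$class_labels[rows],
                is_qc = x$is_qc[rows])
}

# Non-QC biological samples only (classification and clustering operate on these).
bio_samples <- function(x) subset_table(x, rows = which(!x$is_qc))
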