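#' Read a feature table from CSV
#'
#' Interchange format: a header row, reserved leading columns `sample_id`,
#' `class`, `is_qc`, then one column per metabolite feature. An empty cell or
#' the string `"NA"` is a missing value; `"0"` is a true numeric zero and is
#' never treated as missing.
#'
#' @param path path to a CSV file.
#' @return A [feature_table].
#' @export
read_feature_table <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = NULL)
  required <- c("sample_id", "class", "is_qc")
  if (!all(required %in% names(raw)[1:3])) {
    stop_config("first three columns must be %s (got: %s)",
                paste(required, collapse = ", "),
                paste(utils::head(names(raw), 3), collapse = ", "))
  }
  feat_cols <- names(raw)[!(names(raw) %in% required)]
  if (!length(feat_cols)) stop_config("no feature columns found in %s", path)
  dup <- feat_cols[duplicated(feat_cols)]
  if (length(dup)) stop_config("duplicated feature id in header: %s",
                               paste(unique(dup), collapse = ", "))
  vals <- sapply(feat_cols, function(fc) {
    v <- raw[[fc]]
    v[v == "" | v == "NA"] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) stop_config("non-numeric value '%s' in feature '%s', line %d",
                                 v[bad[1]], fc, bad[1] + 1L)
    neg <- which(num < 0)
    if (length(neg)) stop_config("negative intensity in feature '%s', line %d",
                                 fc, neg[1] + 1L)
    num
  })
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(raw$sample_id, feat_cols))
  cls <- raw$class
  cls[cls == "" | cls == "NA"] <- NA_character_
  feature_table(vals, sample_ids = raw$sample_id, feature_ids = feat_cols,
                class_labels = cls,
                is_qc = tolower(raw$is_qc) %in% c("true", "1", "yes"))
}

#' Write a feature table to CSV
#'
#' Inverse of [read_feature_table()]: missing cells are written as empty
#' strings, zeros as `0`, so the missing mask round-trips losslessly.
#'
#' @param table a [feature_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  vals <- table$values
  chr <- matrix(ifelse(is.na(vals), "", formatC(vals, format = "g", digits = 15)),
                nrow = nrow(vals))
  df <- data.frame(sample_id = rownames(vals),
                   class = as.character(table$class_labels),
                   is_qc = table$is_qc, chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-(1:3)] <- colnames(vals)
  df$class[is.na(df$class)] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Write the ground-truth mask of a masked dataset
#'
#' Sidecar CSV with one row per artificially deleted cell:
#' `sample_id, feature_id, true_value`.
#'
#' @param masked a [masked_dataset][apply_missingness].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(masked, path) {
  idx <- which(masked$mask, arr.ind = TRUE)
  df <- data.frame(sample_id = rownames(masked$truth$values)[idx[, 1]],
                   feature_id = colnames(masked$truth$values)[idx[, 2]],
                   true_value = masked$truth$values[masked$mask])
  utils::write.csv(df[order(df$sample_id, df$feature_id), ], path, row.names = FALSE)
  invisible(path)
}
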