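#' Configuration of the synthetic metabolite-table generator
#'
#' Emulates the structure of a GC-MS intensity table from a three-condition
#' cell-culture study: log-normally distributed, mostly positively skewed
#' feature intensities; a minority of negatively skewed features; blocks of
#' mutually correlated metabolites (pathway co-regulation); and multiplicative
#' class effects on a subset of features.
#'
#' Per feature j, a latent Gaussian matrix Z (with correlated blocks built
#' from a shared block factor, pairwise correlation `block_rho`) is pushed
#' through `x = exp(mu_j + sigma_j * z)`, with the log-normal shape
#' `sigma_j ~ U(0.1, skew_scale)`. Features selected for a class effect get a
#' class-specific log-mean shift `class_effect * N(0,1)`. A `reflect_fraction`
#' of features is reflected (`x' = max(x) + min(x) - x`), producing the
#' negatively skewed minority seen in real tables.
#'
#' @param n_per_class samples per biological class.
#' @param n_classes number of classes (default 3: normoxia/hypoxia/anoxia
#'   analogue).
#' @param n_features number of metabolite features (default 52).
#' @param skew_scale upper end of the per-feature log-normal shape sigma,
#'   drawn from U(0.1, skew_scale). Default 1.2 spans sample skewness from
#'   near 0 to beyond 3 at realistic n.
#' @param sigma_range optional explicit range `c(lo, hi)` for the log-normal
#'   shape, overriding `U(0.1, skew_scale)`; `c(1, 1)` fixes sigma = 1 for
#'   every feature.
#' @param class_effect scale of the per-class log-mean shift applied to
#'   `class_effect_fraction` of features; 0 disables class structure.
#' @param class_effect_fraction fraction of features carrying a class effect.
#' @param n_corr_blocks number of correlated feature blocks.
#' @param block_size features per correlated block; requires
#'   `n_corr_blocks * block_size <= n_features`.
#' @param block_rho latent pairwise correlation within a block, in \[0, 1).
#' @param reflect_fraction fraction of features reflected to negative skew.
#' @param n_qc number of pooled-QC samples appended (class label `NA`); QC
#'   values are the feature-wise mean profile with small log-normal noise.
#' @param seed integer seed; identical config + seed gives identical output.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_per_class = 30, n_classes = 3, n_features = 52,
                             skew_scale = 1.2, sigma_range = NULL,
                             class_effect = 1.2, class_effect_fraction = 0.8,
                             n_corr_blocks = 5, block_size = 10, block_rho = 0.85,
                             reflect_fraction = 0.15, n_qc = 0, seed = 1) {
  if (!is_count(n_per_class) || !is_count(n_classes) || !is_count(n_features)) {
    stop_config("n_per_class, n_classes and n_features must be positive integers")
  }
  if (skew_scale < 0 || class_effect < 0) {
    stop_config("skew_scale and class_effect must be nonnegative")
  }
  if (!is.null(sigma_range) &&
      (length(sigma_range) != 2 || any(sigma_range < 0) || sigma_range[1] > sigma_range[2])) {
    stop_config("sigma_range must be c(lo, hi) with 0 <= lo <= hi")
  }
  if (n_corr_blocks < 0 || (n_corr_blocks > 0 && !is_count(block_size))) {
    stop_config("invalid correlated-block configuration")
  }
  if (n_corr_blocks * block_size > n_features) {
    stop_config("n_corr_blocks * block_size (%d) exceeds n_features (%d)",
                n_corr_blocks * block_size, n_features)
  }
  if (block_rho < 0 || block_rho >= 1) stop_config("block_rho must be in [0, 1)")
  if (class_effect_fraction < 0 || class_effect_fraction > 1 ||
      reflect_fraction < 0 || reflect_fraction > 1) {
    stop_config("fractions must be in [0, 1]")
  }
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a complete (no-missing) synthetic feature table
#'
#' @param config a [generator_config()].
#' @return A [feature_table] with `n_per_class * n_classes` biological samples
#'   (plus `n_qc` QC samples), strictly positive values and no missing cells.
#' @export
generate_complete <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n_bio <- config$n_per_class * config$n_classes
    p <- config$n_features
    classes <- factor(rep(paste0("class", seq_len(config$n_classes)),
                          each = config$n_per_class))

    # latent Gaussians with correlated blocks
    z <- matrix(stats::rnorm(n_bio * p), n_bio, p)
    if (config$n_corr_blocks > 0) {
      for (b in seq_len(config$n_corr_blocks)) {
        cols <- ((b - 1) * config$block_size + 1):(b * config$block_size)
        g <- stats::rnorm(n_bio)
        z[, cols] <- sqrt(config$block_rho) * g +
          sqrt(1 - config$block_rho) * z[, cols]
      }
    }

    sr <- config$sigma_range %||% c(0.1, max(config$skew_scale, 0.1))
    sigma <- stats::runif(p, min = sr[1], max = sr[2])
    mu <- stats::rnorm(p, mean = 2, sd = 0.4)
    # correlated block-mates emulate co-regulated / chemically related
    # metabolites: they share the block's intensity scale and shape (small
    # jitter), as e.g. isomer features quantified at similar abundance do
    if (config$n_corr_blocks > 0) {
      for (b in seq_len(config$n_corr_blocks)) {
        cols <- ((b - 1) * config$block_size + 1):(b * config$block_size)
        mu[cols] <- mu[cols[1]] + stats::rnorm(length(cols), sd = 0.05)
        sigma[cols] <- pmax(0.05, sigma[cols[1]] + stats::rnorm(length(cols), sd = 0.03))
      }
    }

    # class-specific log-mean shifts on a feature subset; a co-regulated
    # block responds as a unit (shared class shift, small per-member jitter),
    # free features respond independently
    shift <- matrix(0, config$n_classes, p)
    if (config$class_effect > 0 && config$class_effect_fraction > 0) {
      in_block <- rep(FALSE, p)
      if (config$n_corr_blocks > 0) {
        for (b in seq_len(config$n_corr_blocks)) {
          cols <- ((b - 1) * config$block_size + 1):(b * config$block_size)
          in_block[cols] <- TRUE
          if (stats::runif(1) < config$class_effect_fraction) {
            delta <- config$class_effect * stats::rnorm(config$n_classes)
            shift[, cols] <- delta + 0.1 * config$class_effect *
              stats::rnorm(config$n_classes * length(cols))
          }
        }
      }
      free <- which(!in_block)
      responsive <- free[stats::runif(length(free)) < config$class_effect_fraction]
      if (length(responsive)) {
        shift[, responsive] <- config$class_effect *
          stats::rnorm(config$n_classes * length(responsive))
      }
    }

    logx <- sweep(z, 2, sigma, `*`)
    logx <- sweep(logx, 2, mu, `+`)
    logx <- logx + shift[as.integer(classes), , drop = FALSE]
    x <- exp(logx)

    # reflect a minority of features to negative skew, keeping positivity
    n_ref <- round(config$reflect_fraction * p)
    if (n_ref > 0) {
      ref_features <- sample.int(p, n_ref)
      for (j in ref_features) x[, j] <- max(x[, j]) + min(x[, j]) - x[, j]
    }

    if (config$n_qc > 0) {
      qc_profile <- colMeans(x)
      qc <- matrix(rep(qc_profile, each = config$n_qc), config$n_qc, p) *
        exp(matrix(stats::rnorm(config$n_qc * p, sd = 0.05), config$n_qc, p))
      x <- rbind(x, qc)
      classes <- factor(c(as.character(classes), rep(NA_character_, config$n_qc)),
                        levels = levels(classes))
    }

    feature_table(x,
                  sample_ids = c(paste0("S", seq_len(n_bio)),
                                 if (config$n_qc > 0) paste0("QC", seq_len(config$n_qc))),
                  feature_ids = paste0("M", seq_len(p)),
                  class_labels = classes,
                  is_qc = c(rep(FALSE, n_bio), rep(TRUE, config$n_qc)))
  })
}

#' Missingness specification
#'
#' @param mechanism `"MCAR"` (cells deleted completely at random), `"LOD"`
#'   (limit-of-detection: deletion probability decreases with intensity rank,
#'   emulating low-signal dropout) or `"MIXED"` (a `lod_weight` share of the
#'   deleted cells from the LOD mechanism, the rest MCAR).
#' @param target_fraction fraction of cells to delete, in \[0, 1). The exact
#'   count `round(target_fraction * n_cells)` is deleted (weighted sampling
#'   without replacement), so the realized fraction is reproducible.
#' @param lod_weight share of missing cells produced by LOD censoring under
#'   `MIXED`; ignored otherwise.
#' @param lod_gamma exponent of the rank-based LOD weight
#'   `w = (1 - (rank - 0.5)/n)^lod_gamma`; larger values concentrate deletion
#'   harder on the lowest intensities.
#' @param seed integer seed.
#' @return An object of class `missingness_spec`.
#' @export
missingness_spec <- function(mechanism = c("MCAR", "LOD", "MIXED"),
                             target_fraction = 0.15, lod_weight = 0.7,
                             lod_gamma = 3, seed = 1) {
  mechanism <- match.arg(mechanism)
  if (target_fraction < 0 || target_fraction >= 1) {
    stop_config("target_fraction must be in [0, 1)")
  }
  if (lod_weight < 0 || lod_weight > 1) stop_config("lod_weight must be in [0, 1]")
  structure(list(mechanism = mechanism, target_fraction = target_fraction,
                 lod_weight = lod_weight, lod_gamma = lod_gamma, seed = seed),
            class = "missingness_spec")
}

#' Superimpose missingness with known ground truth
#'
#' Deletes exactly `round(target_fraction * n_cells)` cells from a complete
#' table by weighted sampling without replacement (uniform weights for MCAR;
#' rank-based weights favouring low intensities for LOD). A draw that would
#' leave any feature without an observed value is rejected and redrawn, so
#' every downstream imputer's preconditions hold.
#'
#' @param table a complete [feature_table] (no missing cells).
#' @param spec a [missingness_spec()].
#' @return An object of class `masked_dataset`: list with `table` (the
#'   table with `NA` holes), `truth` (the original complete table), `mask`
#'   (logical matrix, `TRUE` = deleted), `mechanism`, `target_fraction`.
#' @export
apply_missingness <- function(table, spec) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "missingness_spec"))
  if (anyNA(table$values)) {
    stop_config("input table already contains missing cells")
  }
  vals <- table$values
  n_cells <- length(vals)
  n_mask <- round(spec$target_fraction * n_cells)
  mask <- matrix(FALSE, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  if (n_mask > 0) {
    w_lod <- (1 - (rank(vals, ties.method = "first") - 0.5) / n_cells)^spec$lod_gamma
    with_seed(spec$seed, {
      for (attempt in 1:100) {
        sel <- switch(spec$mechanism,
          MCAR = sample.int(n_cells, n_mask),
          LOD = sample.int(n_cells, n_mask, prob = w_lod),
          MIXED = {
            n_lod <- round(spec$lod_weight * n_mask)
            s1 <- if (n_lod > 0) sample.int(n_cells, n_lod, prob = w_lod) else integer(0)
            rest <- setdiff(seq_len(n_cells), s1)
            c(s1, if (n_mask - n_lod > 0) sample(rest, n_mask - n_lod))
          })
        m <- mask
        m[sel] <- TRUE
        if (all(colSums(!m) >= 1L)) {
          mask <- m
          break
        }
        if (attempt == 100) stop_config(
          "could not place %d missing cells without emptying a feature", n_mask)
      }
    })
  }
  holed <- vals
  holed[mask] <- NA_real_
  structure(list(
    table = feature_table(holed, class_labels = table$class_labels,
                          is_qc = table$is_qc),
    truth = table, mask = mask,
    mechanism = spec$mechanism, target_fraction = spec$target_fraction),
    class = "masked_dataset")
}

#' @export
print.masked_dataset <- function(x, ...) {
  cat(sprintf("<masked_dataset> %s | %d/%d cells masked (%.1f%%)\n",
              x$mechanism, sum(x$mask), length(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}
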