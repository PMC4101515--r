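#' Can LDA be used without prior PCA?
#'
#' Plain LDA requires more samples than features after accounting for the
#' group structure: with `n_samples` samples, `n_groups` groups and
#' `n_features` input features the condition is
#' `(n_samples - n_groups - 1) > n_features`. Collinear, feature-rich
#' metabolomics tables typically fail it, which is why LDA is run on
#' principal-component scores (PC-LDA).
#'
#' @param n_samples,n_groups,n_features positive integers.
#' @return `TRUE` if plain LDA is admissible.
#' @export
lda_feasible <- function(n_samples, n_groups, n_features) {
  if (!is_count(n_samples) || !is_count(n_groups) || !is_count(n_features)) {
    stop_config("all arguments must be positive integers")
  }
  (n_samples - n_groups - 1) > n_features
}

#' One-hot dummy coding of class labels
#'
#' Each class becomes an indicator column (e.g. with three classes the first
#' class is coded 1,0,0, the second 0,1,0, the third 0,0,1); every row has
#' exactly one 1.
#'
#' @param labels factor or character vector.
#' @param class_order optional explicit class ordering.
#' @return List with `matrix` (n x n_classes) and `class_order`.
#' @export
dummy_code <- function(labels, class_order = NULL) {
  labels <- as.character(labels)
  class_order <- class_order %||% levels(factor(labels))
  if (!all(labels %in% class_order)) stop_config("labels outside class_order")
  m <- outer(labels, class_order, `==`) * 1
  colnames(m) <- class_order
  list(matrix = m, class_order = class_order)
}

# Fisher/Gaussian LDA with pooled within-class covariance on a (low-dim)
# score matrix. Priors proportional to training class frequencies; a small
# ridge (1e-8 x trace) keeps the pooled covariance invertible.
lda_fit <- function(scores, labels) {
  labels <- droplevels(as.factor(labels))
  classes <- levels(labels)
  d <- ncol(scores)
  means <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(scores[labels == cl, , drop = FALSE])
  }))
  pooled <- matrix(0, d, d)
  for (cl in classes) {
    xs <- scores[labels == cl, , drop = FALSE]
    xc <- sweep(xs, 2, colMeans(xs))
    pooled <- pooled + crossprod(xc)
  }
  pooled <- pooled / (nrow(scores) - length(classes))
  pooled <- pooled + diag(1e-8 * sum(diag(pooled)), d)
  list(means = means, cov_inv = solve(pooled),
       log_prior = log(as.numeric(table(labels)[classes]) / length(labels)),
       classes = classes)
}

lda_predict <- function(fit, scores) {
  # linear discriminant functions delta_c(x) = x' S^-1 mu_c - mu_c' S^-1 mu_c / 2 + log pi_c
  lin <- scores %*% fit$cov_inv %*% t(fit$means)
  const <- -0.5 * rowSums((fit$means %*% fit$cov_inv) * fit$means) + fit$log_prior
  disc <- sweep(lin, 2, const, `+`)
  colnames(disc) <- fit$classes
  list(labels = fit$classes[max.col(disc, ties.method = "first")], scores = disc)
}

#' PC-LDA: linear discriminant analysis on principal-component scores
#'
#' Training chain: autoscale the training table (training parameters),
#' PCA, keep the first `n_pcs` score dimensions, fit a multi-class LDA with
#' pooled within-class covariance. Test samples are pushed through the same
#' chain (training scaling, training loadings) and assigned to the class
#' with the largest discriminant value.
#'
#' @param train numeric matrix or [feature_table] of training samples
#'   (complete, unscaled intensities).
#' @param labels training class labels.
#' @param test matrix/table of test samples.
#' @param n_pcs number of principal components passed to LDA.
#' @return List with `labels` (predicted test classes) and `scores`
#'   (discriminant values, one column per class).
#' @export
pc_lda_train_predict <- function(train, labels, test, n_pcs) {
  tr <- if (inherits(train, "feature_table")) train$values else as.matrix(train)
  te <- if (inherits(test, "feature_table")) test$values else as.matrix(test)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop_config("need at least 2 training classes")
  if (min(table(labels)) < 2) stop_config("every training class needs >= 2 samples")
  sc <- scale_train(tr)
  max_rank <- min(nrow(tr) - 1L, ncol(tr))
  if (!is_count(n_pcs) || n_pcs > max_rank) {
    stop_config("n_pcs must be in 1..%d", max_rank)
  }
  sv <- svd(sc$scaled, nu = n_pcs, nv = n_pcs)
  tr_scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  te_scores <- sweep(sweep(te, 2, sc$center), 2, sc$scale, `/`) %*% sv$v
  fit <- lda_fit(tr_scores, labels)
  lda_predict(fit, te_scores)
}

# NIPALS PLS2: successive orthogonal latent variables maximizing X-Y
# covariance, with X- and Y-deflation each round.
pls2_fit <- function(X, Y, n_components, tol = 1e-10, max_inner = 500) {
  E <- X; F_ <- Y
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Q <- matrix(0, ncol(Y), n_components)
  Tm <- matrix(0, n, n_components)
  for (a in seq_len(n_components)) {
    u <- F_[, which.max(apply(F_, 2, stats::var))]
    t_old <- rep(Inf, n)
    for (i in seq_len(max_inner)) {
      w <- crossprod(E, u)
      w <- w / sqrt(sum(w^2))
      t_ <- E %*% w
      q <- crossprod(F_, t_) / sum(t_^2)
      u <- F_ %*% q / sum(q^2)
      if (sum((t_ - t_old)^2) < tol * sum(t_^2)) break
      t_old <- t_
    }
    p_ <- crossprod(E, t_) / sum(t_^2)
    E <- E - t_ %*% t(p_)
    F_ <- F_ - t_ %*% t(q)
    W[, a] <- w; P[, a] <- p_; Q[, a] <- q; Tm[, a] <- t_
  }
  list(W = W, P = P, Q = Q, scores = Tm)
}

# Predicted Y for 1..n_components cumulatively, pushing test X through the
# training deflation sequence. Returns an array (n_test x n_y x n_components).
pls2_predict_path <- function(fit, Xtest) {
  n_components <- ncol(fit$W)
  n <- nrow(Xtest); ny <- nrow(fit$Q)
  E <- Xtest
  yhat <- matrix(0, n, ny)
  path <- array(0, c(n, ny, n_components))
  for (a in seq_len(n_components)) {
    t_ <- E %*% fit$W[, a]
    E <- E - t_ %*% t(fit$P[, a])
    yhat <- yhat + t_ %*% t(fit$Q[, a])
    path[, , a] <- yhat
  }
  path
}

#' PLS-DA: partial least squares discriminant analysis
#'
#' PLS2 regression (classical NIPALS with X- and Y-deflation) of the
#' autoscaled training matrix on the column-centered dummy class matrix.
#' A test sample is assigned to the class with the largest predicted dummy
#' entry; exact ties go to the class earliest in `class_order`.
#'
#' @inheritParams pc_lda_train_predict
#' @param n_components number of latent variables.
#' @return List with `labels` (predicted test classes), `y_pred` (predicted
#'   dummy matrix at `n_components`), `class_order`.
#' @export
pls_da_train_predict <- function(train, labels, test, n_components) {
  tr <- if (inherits(train, "feature_table")) train$values else as.matrix(train)
  te <- if (inherits(test, "feature_table")) test$values else as.matrix(test)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop_config("need at least 2 training classes")
  max_rank <- min(nrow(tr) - 1L, ncol(tr))
  if (!is_count(n_components) || n_components > max_rank) {
    stop_config("n_components must be in 1..%d", max_rank)
  }
  sc <- scale_train(tr)
  dummy <- dummy_code(labels)
  y_center <- colMeans(dummy$matrix)
  Yc <- sweep(dummy$matrix, 2, y_center)
  fit <- pls2_fit(sc$scaled, Yc, n_components)
  te_s <- sweep(sweep(te, 2, sc$center), 2, sc$scale, `/`)
  path <- pls2_predict_path(fit, te_s)
  y_pred <- sweep(path[, , n_components, drop = FALSE][, , 1, drop = TRUE], 2,
                  y_center, `+`)
  y_pred <- matrix(y_pred, nrow = nrow(te_s),
                   dimnames = list(NULL, dummy$class_order))
  list(labels = dummy$class_order[max.col(y_pred, ties.method = "first")],
       y_pred = y_pred, class_order = dummy$class_order)
}

# First effective maximum of an accuracy curve: the smallest component count
# that no later count beats by more than `tol` (percentage points). This is
# the operational reading of "first local maximum" arrows on accuracy-vs-
# components plots: a literal strict-local-maximum rule degenerates both on
# saturation plateaus (no strict maximum exists) and on Monte-Carlo ripples
# (a 0.02-point dip in a rising curve creates a spurious early "peak").
# A flat curve selects 1; tol = 0 reduces to the first global maximum.
first_local_maximum <- function(curve, tol = 0.5) {
  m <- length(curve)
  for (i in seq_len(m)) {
    if (curve[i] >= max(curve[i:m]) - tol) return(i)
  }
  m
}

#' Bootstrap validation of PC-LDA / PLS-DA over component counts
#'
#' Draws `n_boot` bootstrap resamples (n samples with replacement) as
#' training sets; the out-of-bag (OOB) samples -- on average ~36.8% of the
#' data, while training sets contain ~63.2% distinct samples -- form the
#' test set. For every component count `1..max_components` the classifier is
#' trained and the OOB correct-classification fraction recorded. Resamples
#' whose training set misses a class (or whose OOB set is empty) are redrawn
#' and counted in `n_redraws`. The component count is then chosen as the
#' first local maximum of the mean accuracy curve.
#'
#' @param table complete [feature_table] or matrix (QC samples excluded).
#' @param labels class labels (taken from the table if omitted).
#' @param classifier `"pls_da"` or `"pc_lda"`.
#' @param max_components largest component count examined.
#' @param n_boot number of bootstrap resamples (default 100).
#' @param selection_tol tolerance (accuracy percentage points) used when
#'   locating the first effective maximum of the mean curve: the smallest
#'   component count that no larger count beats by more than this margin.
#'   Guards the selection against Monte-Carlo ripple; 0 selects the first
#'   global maximum.
#' @param seed integer seed.
#' @return An object of class `bootstrap_result`: `accuracy` (n_boot x
#'   max_components, NA where a resample's rank could not support the
#'   component count), `mean_curve` (percent), `selected_components`,
#'   `headline_rate` (percent at the selected count), `oob_fraction`,
#'   `train_distinct_fraction`, `n_redraws`.
#' @export
bootstrap_evaluate <- function(table, labels = NULL,
                               classifier = c("pls_da", "pc_lda"),
                               max_components = 10, n_boot = 100,
                               selection_tol = 0.5, seed = 1) {
  classifier <- match.arg(classifier)
  if (!is_count(n_boot)) stop_config("n_boot must be a positive integer")
  if (!is_count(max_components)) stop_config("max_components must be a positive integer")
  if (inherits(table, "feature_table")) {
    tb <- bio_samples(table)
    vals <- tb$values
    labels <- labels %||% droplevels(tb$class_labels)
  } else {
    vals <- as.matrix(table)
  }
  if (anyNA(vals)) stop_config("bootstrap_evaluate requires a complete (imputed) table")
  labels <- droplevels(as.factor(labels))
  if (min(base::table(labels)) < 3) stop_config("every class needs >= 3 samples")
  n <- nrow(vals)

  acc <- matrix(NA_real_, n_boot, max_components)
  oob_frac <- numeric(n_boot)
  train_distinct <- numeric(n_boot)
  n_redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), idx)
        ok <- length(oob) > 0 &&
          all(levels(labels) %in% labels[idx]) &&
          min(base::table(labels[idx])) >= 2
        if (ok) break
        n_redraws <- n_redraws + 1L
      }
      oob_frac[b] <- length(oob) / n
      train_distinct[b] <- length(unique(idx)) / n
      tr <- vals[idx, , drop = FALSE]
      te <- vals[oob, , drop = FALSE]
      true_lab <- as.character(labels[oob])
      rank_cap <- min(max_components, length(unique(idx)) - 1L, ncol(vals))
      if (classifier == "pls_da") {
        sc <- scale_train(tr)
        dummy <- dummy_code(labels[idx], class_order = levels(labels))
        y_center <- colMeans(dummy$matrix)
        fit <- pls2_fit(sc$scaled, sweep(dummy$matrix, 2, y_center), rank_cap)
        path <- pls2_predict_path(fit, sweep(sweep(te, 2, sc$center), 2, sc$scale, `/`))
        for (cc in seq_len(rank_cap)) {
          yh <- sweep(matrix(path[, , cc], nrow = length(oob)), 2, y_center, `+`)
          pred <- dummy$class_order[max.col(yh, ties.method = "first")]
          acc[b, cc] <- mean(pred == true_lab)
        }
      } else {
        sc <- scale_train(tr)
        sv <- svd(sc$scaled, nu = rank_cap, nv = rank_cap)
        tr_scores <- sv$u %*% diag(sv$d[seq_len(rank_cap)], rank_cap)
        te_scores <- sweep(sweep(te, 2, sc$center), 2, sc$scale, `/`) %*% sv$v
        for (cc in seq_len(rank_cap)) {
          fit <- lda_fit(tr_scores[, seq_len(cc), drop = FALSE], labels[idx])
          pred <- lda_predict(fit, te_scores[, seq_len(cc), drop = FALSE])$labels
          acc[b, cc] <- mean(pred == true_lab)
        }
      }
    }
  })
  mean_curve <- 100 * colMeans(acc, na.rm = TRUE)
  sel <- first_local_maximum(mean_curve, tol = selection_tol)
  structure(list(accuracy = acc, mean_curve = mean_curve,
                 selected_components = sel,
                 headline_rate = mean_curve[sel],
                 oob_fraction = mean(oob_frac),
                 train_distinct_fraction = mean(train_distinct),
                 n_redraws = n_redraws,
                 classifier = classifier), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %s | %d resamples | %.1f%% at %d components | mean OOB %.1f%%\n",
              x$classifier, nrow(x$accuracy), x$headline_rate,
              x$selected_components, 100 * x$oob_fraction))
  invisible(x)
}

#' Composition of bootstrap resamples
#'
#' Measures, without training any classifier, the average fraction of
#' distinct samples in bootstrap training sets and the average out-of-bag
#' fraction; for large n these approach 1 - 1/e (63.2%) and 1/e (36.8%).
#'
#' @param n number of samples.
#' @param n_boot number of resamples (default 100).
#' @param seed integer seed.
#' @return List with `train_distinct_fraction` and `oob_fraction`.
#' @export
bootstrap_composition <- function(n, n_boot = 100, seed = 1) {
  if (!is_count(n) || !is_count(n_boot)) stop_config("n and n_boot must be positive integers")
  with_seed(seed, {
    td <- numeric(n_boot); ob <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      td[b] <- length(unique(idx)) / n
      ob[b] <- 1 - td[b]
    }
    list(train_distinct_fraction = mean(td), oob_fraction = mean(ob))
  })
}
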