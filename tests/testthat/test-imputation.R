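test_that("zero, mean and median substitutes fill holes as specified", {
  col <- function(v) feature_table(cbind(f = v, g = seq_along(v)),
                                   class_labels = rep("x", length(v)))
  expect_equal(unname(impute_zero(col(c(1, NA, 3)))$completed$values[, "f"]), c(1, 0, 3))
  expect_equal(unname(impute_mean(col(c(2, 4, NA, 6)))$completed$values[3, "f"]), 4)
  expect_equal(unname(impute_mean(col(c(1, 2, NA, 9)))$completed$values[3, "f"]), 4)
  expect_equal(unname(impute_median(col(c(1, 2, NA, 9)))$completed$values[3, "f"]), 2)
  expect_equal(unname(impute_median(col(c(1, 3, NA, 7, 9, 5)))$completed$values[3, "f"]), 5)

  # symmetric column: mean and median agree
  sym <- col(c(1, 2, 3, 4, 5, NA))
  expect_equal(impute_mean(sym)$completed$values, impute_median(sym)$completed$values)

  # tables without holes pass through unchanged
  full <- col(c(1, 2, 3))
  for (m in c("zero", "mean", "median", "knn", "rf")) {
    res <- impute(full, imputation_config(m, k = 1))
    expect_identical(res$completed$values, full$values)
    expect_equal(res$n_imputed, 0L)
  }

  # all-missing feature: zero fills, statistics error
  am <- feature_table(cbind(f = c(NA_real_, NA), g = c(1, 2)),
                      class_labels = c("x", "x"))
  expect_equal(unname(impute_zero(am)$completed$values[, "f"]), c(0, 0))
  expect_error(impute_mean(am), "no observed values")
  expect_error(impute_median(am), "no observed values")
})

test_that("all imputers never alter observed cells (bit-exact)", {
  for (seed in 1:5) {
    tab <- random_masked_table(n = 12, p = 6, miss = 0.25, seed = seed)
    obs <- !is.na(tab$values)
    for (m in c("zero", "mean", "median", "knn", "rf")) {
      res <- impute(tab, imputation_config(m, k = 3, n_trees = 20, seed = seed))
      expect_identical(res$completed$values[obs], tab$values[obs])
      expect_false(anyNA(res$completed$values))
      expect_equal(res$n_imputed, sum(!obs))
    }
  }
})

test_that("kNN toy example matches the exhaustive-distance oracle", {
  vals <- cbind(f1 = c(1, 2, 3), f2 = c(1, 2, NA), f3 = c(10, 20, 30))
  tab <- feature_table(vals, class_labels = rep("x", 3))
  res <- impute_knn(tab, imputation_config("knn", k = 1))
  # nearest neighbour of f2 is f1 (partial distance 0): imputed value 3
  expect_equal(unname(res$completed$values[3, "f2"]), 3)
  expect_equal(res$fallback_count, 0L)
  expect_identical(res$completed$values, knn_oracle(tab$values, k = 1))
})

test_that("kNN equals the brute-force oracle on random small tables", {
  for (seed in 1:30) {
    set.seed(seed)
    p <- sample(3:6, 1)
    tab <- random_masked_table(n = sample(5:9, 1), p = p, miss = 0.25, seed = seed + 100)
    k <- sample(seq_len(p - 1), 1)
    res <- impute_knn(tab, imputation_config("knn", k = k))
    expect_identical(res$completed$values, knn_oracle(tab$values, k))
  }
})

test_that("samples-as-neighbours kNN equals the oracle on the transposed matrix", {
  tab <- random_masked_table(n = 7, p = 5, miss = 0.2, seed = 77)
  res <- impute_knn(tab, imputation_config("knn", k = 3, orientation = "samples"))
  expect_identical(res$completed$values, t(knn_oracle(t(tab$values), k = 3)))
  expect_error(impute_knn(tab, imputation_config("knn", k = 7, orientation = "samples")),
               "samples")
})

test_that("kNN falls back to the column mean when no neighbour is observed", {
  vals <- cbind(f1 = c(1, 2, NA), f2 = c(1, 2, NA), f3 = c(2, 6, NA), f4 = c(9, 9, 4))
  # at sample 3 every candidate neighbour of f1 within k = 2 is missing
  tab <- feature_table(vals, class_labels = rep("x", 3))
  res <- impute_knn(tab, imputation_config("knn", k = 2))
  expect_equal(unname(res$completed$values[3, "f1"]), mean(c(1, 2)))
  expect_gte(res$fallback_count, 1L)

  expect_error(impute_knn(tab, imputation_config("knn", k = 4)), "smaller")
})

test_that("random-forest imputation learns structure mean imputation cannot", {
  set.seed(31)
  n <- 200
  x <- stats::rlnorm(n)
  vals <- cbind(a = x, b = 2 * x, c = stats::rlnorm(n),
                d = stats::rlnorm(n), e = x * exp(stats::rnorm(n, sd = 0.05)),
                f = stats::rlnorm(n))
  holes <- matrix(stats::runif(n * 6) < 0.1, n, 6)
  v <- vals; v[holes] <- NA
  tab <- feature_table(v, class_labels = rep(c("x", "y"), n / 2))
  truth <- structure(list(table = tab,
                          truth = feature_table(vals, class_labels = tab$class_labels),
                          mask = holes, mechanism = "MCAR", target_fraction = 0.1),
                     class = "masked_dataset")
  rf <- impute_rf(tab, imputation_config("rf", n_trees = 50, seed = 3))
  mn <- impute_mean(tab)
  expect_lt(nrmse(rf, truth), nrmse(mn, truth))
  expect_gte(length(rf$convergence), 1)

  # determinism under a fixed seed
  rf2 <- impute_rf(tab, imputation_config("rf", n_trees = 50, seed = 3))
  expect_identical(rf2$completed$values, rf$completed$values)
  rf3 <- impute_rf(tab, imputation_config("rf", n_trees = 50, seed = 4))
  expect_false(identical(rf3$completed$values, rf$completed$values))
})

test_that("rf imputation is stable under feature reordering", {
  tab <- random_masked_table(n = 60, p = 6, miss = 0.15, seed = 41)
  truth_vals <- tab$values
  set.seed(41); truth_vals[is.na(truth_vals)] <- stats::rlnorm(sum(is.na(truth_vals)))
  mk_truth <- function(t) structure(list(table = t,
    truth = feature_table(truth_vals[, colnames(t$values)], class_labels = t$class_labels),
    mask = is.na(t$values), mechanism = "MCAR", target_fraction = 0.15),
    class = "masked_dataset")
  perm <- c(4, 1, 6, 3, 5, 2)
  tab_p <- feature_table(tab$values[, perm], class_labels = tab$class_labels)
  r1 <- impute_rf(tab, imputation_config("rf", n_trees = 60, seed = 9))
  r2 <- impute_rf(tab_p, imputation_config("rf", n_trees = 60, seed = 9))
  # forests are seed-dependent, so demand agreement in error, not bits
  e1 <- nrmse(r1, mk_truth(tab))
  e2 <- nrmse(r2, mk_truth(tab_p))
  expect_lt(abs(e1 - e2) / e1, 0.25)
})

test_that("nrmse identities hold", {
  tab <- generate_complete(generator_config(n_per_class = 10, n_features = 10,
                                            n_corr_blocks = 1, block_size = 5, seed = 2))
  ds <- apply_missingness(tab, missingness_spec("MCAR", 0.2, seed = 3))
  # perfect imputation scores 0
  expect_equal(nrmse(tab, ds), 0)
  # imputing the mean of the true masked values scores exactly 1
  filled <- ds$table$values
  filled[ds$mask] <- mean(ds$truth$values[ds$mask])
  expect_equal(nrmse(filled, ds), 1, tolerance = 1e-12)
  # any imputation is nonnegative
  expect_gte(nrmse(impute_zero(ds$table), ds), 0)
  # degenerate cases error
  ds0 <- apply_missingness(tab, missingness_spec("MCAR", 0))
  expect_error(nrmse(tab, ds0), "empty mask")
})
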