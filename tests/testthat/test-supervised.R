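test_that("lda_feasible implements the sample-size condition", {
  expect_false(lda_feasible(56, 3, 52))   # 52 > 52 is false
  expect_true(lda_feasible(100, 3, 52))   # 96 > 52
  expect_false(lda_feasible(10, 3, 52))
  expect_error(lda_feasible(-1, 3, 52), "positive")
})

test_that("dummy coding is one-hot with a defined class order", {
  d <- dummy_code(c("hypoxia", "normoxia", "anoxia", "normoxia"))
  expect_equal(d$class_order, c("anoxia", "hypoxia", "normoxia"))
  expect_true(all(rowSums(d$matrix) == 1))
  expect_true(all(d$matrix %in% c(0, 1)))
  expect_equal(unname(d$matrix[1, ]), c(0, 1, 0))
  d2 <- dummy_code(c("b", "a"), class_order = c("b", "a"))
  expect_equal(unname(d2$matrix[1, ]), c(1, 0))
})

test_that("internal LDA agrees with the MASS oracle", {
  skip_if_not_installed("MASS")
  set.seed(12)
  n <- 60
  scores <- rbind(matrix(rnorm(n, 0), n / 3, 3),
                  matrix(rnorm(n, 2), n / 3, 3),
                  matrix(rnorm(n, 4), n / 3, 3))
  labels <- factor(rep(c("a", "b", "c"), each = n / 3))
  test <- matrix(rnorm(30, 2), 10, 3)
  fit <- metamiss:::lda_fit(scores, labels)
  pred <- metamiss:::lda_predict(fit, test)$labels
  mass <- as.character(predict(MASS::lda(scores, labels), test)$class)
  expect_equal(pred, mass)
})

test_that("PC-LDA separates a separable fixture and respects proximity", {
  f <- make_separable()
  idx <- seq(1, 90, by = 3)
  res <- pc_lda_train_predict(f$x[-idx, ], f$labels[-idx], f$x[idx, ], n_pcs = 4)
  expect_equal(mean(res$labels == as.character(f$labels[idx])), 1)
  # a test sample identical to a training sample is predicted as its class
  res1 <- pc_lda_train_predict(f$x, f$labels, f$x[c(1, 45), , drop = FALSE], n_pcs = 4)
  expect_equal(res1$labels, as.character(f$labels[c(1, 45)]))
  expect_error(pc_lda_train_predict(f$x, f$labels, f$x, n_pcs = 500), "n_pcs")
})

test_that("PC-LDA accuracy under permuted labels is at chance", {
  f <- make_separable(n_per = 20)
  set.seed(14)
  accs <- replicate(20, {
    pl <- sample(f$labels)
    tr <- sample(60, 40)
    res <- pc_lda_train_predict(f$x[tr, ], pl[tr], f$x[-tr, ], n_pcs = 4)
    mean(res$labels == as.character(pl[-tr]))
  })
  expect_gt(mean(accs), 1 / 3 - 0.1)
  expect_lt(mean(accs), 1 / 3 + 0.1)
})

test_that("PLS-DA separates discriminant latent variables", {
  set.seed(15)
  # two classes along one direction: a single latent variable suffices
  n <- 40
  direction <- c(1, -1, 2, 0.5)
  shift2 <- rep(c(-4, 4), each = n / 2)
  x2 <- outer(shift2, direction) + matrix(rnorm(n * 4, sd = 0.2), n, 4)
  lab2 <- factor(rep(c("a", "b"), each = n / 2))
  res <- pls_da_train_predict(x2, lab2, x2, n_components = 1)
  expect_equal(mean(res$labels == as.character(lab2)), 1)
  expect_equal(dim(res$y_pred), c(n, 2L))

  # three classes with simplex-arranged centroids: two latent variables
  # (with collinear centroids the middle class is unrecoverable by argmax
  # on a linear response -- an intrinsic PLS-DA property, not a defect)
  n3 <- 60
  centers <- rbind(c(6, 0, 0, 0), c(0, 6, 0, 0), c(0, 0, 6, 0))
  lab3 <- factor(rep(c("a", "b", "c"), each = n3 / 3))
  x3 <- centers[as.integer(lab3), ] + matrix(rnorm(n3 * 4, sd = 0.2), n3, 4)
  res3 <- pls_da_train_predict(x3, lab3, x3, n_components = 2)
  expect_equal(mean(res3$labels == as.character(lab3)), 1)
  # near-exact dummy recovery at higher rank
  res4 <- pls_da_train_predict(x3, lab3, x3, n_components = 4)
  expect_lt(max(abs(res4$y_pred - dummy_code(lab3)$matrix)), 0.35)

  expect_error(pls_da_train_predict(x3, rep("a", n3), x3, 1), "2 training classes")
})

test_that("full-rank PLS2 predictions match the least-squares oracle", {
  set.seed(16)
  n <- 30; p <- 5
  x <- matrix(rnorm(n * p), n, p)
  labels <- factor(rep(c("a", "b", "c"), each = n / 3))
  res <- pls_da_train_predict(x, labels, x, n_components = p)
  # at full rank PLS regression coincides with ordinary least squares of
  # the centered dummy matrix on the scaled predictors
  sc <- scale(x)
  y <- dummy_code(labels)$matrix
  ols <- sapply(1:3, function(j) fitted(lm(y[, j] ~ sc)))
  expect_equal(unname(res$y_pred), unname(ols), tolerance = 1e-6)
})

test_that("first_local_maximum finds first effective peaks, plateaus and ripples", {
  flm <- metamiss:::first_local_maximum
  expect_equal(flm(c(5, 5, 5)), 1L)          # flat: tie rule selects 1
  expect_equal(flm(c(1, 3, 2, 4, 1)), 4L)    # later count beats 3 by > tol
  expect_equal(flm(c(62, 99, 99.5, 100, 100, 99.9)), 3L)  # within-tol plateau
  expect_equal(flm(c(1, 2, 3)), 3L)          # rising to the end
  expect_equal(flm(c(9, 1, 2)), 1L)          # dominant first point
  expect_equal(flm(7), 1L)
  # a Monte-Carlo ripple in a rising curve is not a maximum
  expect_equal(flm(c(66.7, 68.49, 68.47, 70.1, 72.4, 80, 86)), 7L)
  expect_equal(flm(c(1, 3, 2, 4, 1), tol = 0), 4L)  # tol 0: first global max
  expect_equal(flm(c(90, 95, 95.4, 94), tol = 0.5), 2L)  # near-peak early stop
})

test_that("bootstrap_evaluate composition and controls behave", {
  f <- make_separable()
  b_lda <- bootstrap_evaluate(f$x, f$labels, "pc_lda", max_components = 6,
                              n_boot = 60, seed = 2)
  b_pls <- bootstrap_evaluate(f$x, f$labels, "pls_da", max_components = 6,
                              n_boot = 60, seed = 2)
  expect_gt(b_lda$headline_rate, 97)
  expect_gt(b_pls$headline_rate, 97)
  # the two classifiers agree on strongly separable data
  expect_lt(abs(b_lda$headline_rate - b_pls$headline_rate), 2)
  # OOB fraction near (1 - 1/n)^n, distinct training fraction near 63.2%
  expect_equal(b_lda$oob_fraction, (1 - 1 / 90)^90, tolerance = 0.02)
  expect_equal(b_lda$train_distinct_fraction, 1 - (1 - 1 / 90)^90, tolerance = 0.02)
  expect_true(all(b_lda$accuracy >= 0 & b_lda$accuracy <= 1, na.rm = TRUE))
  expect_gte(b_lda$selected_components, 1)
  expect_error(bootstrap_evaluate(f$x, f$labels, n_boot = 0), "n_boot")
})

test_that("bootstrap_composition approaches the 63.2/36.8 split", {
  bc <- bootstrap_composition(300, n_boot = 100, seed = 5)
  expect_equal(bc$train_distinct_fraction, 1 - exp(-1), tolerance = 0.01)
  expect_equal(bc$oob_fraction, exp(-1), tolerance = 0.01)
})

test_that("QC samples are excluded from classification", {
  tab <- generate_complete(generator_config(n_per_class = 10, n_qc = 5, seed = 30))
  comp <- impute_zero(tab)$completed
  b <- bootstrap_evaluate(comp, max_components = 3, n_boot = 5, seed = 1)
  expect_equal(nrow(b$accuracy), 5L)
  expect_output(print(b), "bootstrap_result")
})
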