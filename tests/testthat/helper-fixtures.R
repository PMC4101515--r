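# Shared fixtures and independent oracles, all built in code.

# tiny table with a known missing pattern
make_small_table <- function() {
  vals <- matrix(c(1, 2, 3,
                   4, NA, 6,
                   7, 8, NA,
                   10, 11, 12), nrow = 4, byrow = TRUE)
  feature_table(vals, sample_ids = paste0("s", 1:4), feature_ids = c("fa", "fb", "fc"),
                class_labels = c("x", "x", "y", "y"))
}

# three well-separated spherical classes (for classifier controls)
make_separable <- function(n_per = 30, p = 20, sep = 10, seed = 1) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(3 * p), 3, p) * sep
  x <- centers[rep(1:3, each = n_per), ] +
    matrix(stats::rnorm(3 * n_per * p), 3 * n_per, p)
  list(x = x, labels = factor(rep(c("a", "b", "c"), each = n_per)))
}

# exactly rank-2 matrix whose row space survives per-fold centering/scaling
make_rank2 <- function(n = 40, p = 12, seed = 5) {
  set.seed(seed)
  u1 <- scale(stats::rnorm(n))
  u2 <- scale(stats::rnorm(n))
  u2 <- scale(u2 - u1 * sum(u1 * u2) / sum(u1^2))
  v1 <- stats::rnorm(p); v2 <- stats::rnorm(p)
  3 * u1 %*% t(v1) + 2 * u2 %*% t(v2)
}

# Independent brute-force reimplementation of feature-wise kNN imputation:
# exhaustive pairwise partial distances, k nearest by (distance, index),
# unweighted average of neighbours observed at the sample, column-mean
# fallback. Used as the oracle for impute_knn.
knn_oracle <- function(vals, k) {
  p <- ncol(vals)
  out <- vals
  for (f in seq_len(p)) {
    mis <- which(is.na(vals[, f]))
    if (!length(mis)) next
    dists <- rep(NA_real_, p)
    for (g in seq_len(p)) {
      if (g == f) next
      co <- which(!is.na(vals[, f]) & !is.na(vals[, g]))
      if (length(co)) dists[g] <- sqrt(mean((vals[co, f] - vals[co, g])^2))
    }
    cand <- which(!is.na(dists))
    nb <- cand[order(dists[cand], cand)][seq_len(min(k, length(cand)))]
    for (s in mis) {
      avail <- nb[!is.na(vals[s, nb])]
      out[s, f] <- if (length(avail)) mean(vals[s, avail])
                   else mean(vals[, f], na.rm = TRUE)
    }
  }
  out
}

# random small masked table for property tests (every feature keeps >= 1
# observed value; co-observation guaranteed dense enough at these sizes)
random_masked_table <- function(n = 8, p = 5, miss = 0.2, seed = 1) {
  set.seed(seed)
  vals <- matrix(stats::rlnorm(n * p), n, p)
  holes <- matrix(stats::runif(n * p) < miss, n, p)
  for (j in seq_len(p)) if (all(holes[, j])) holes[1, j] <- FALSE
  v <- vals
  v[holes] <- NA
  feature_table(v, class_labels = rep(c("u", "w"), length.out = n))
}
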