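# Independent oracle implementations used to cross-check the package's
# chi-squared metric, K-means, codeword assignment and sensitivity sweep.
# Deliberately naive (loops, enumeration) and kept free of any package
# internals.

# Chi-squared distance, direct elementwise evaluation.
chi2_ref <- function(u, v) {
  acc <- 0
  for (i in seq_along(u)) {
    s <- u[i] + v[i]
    if (s > 0) acc <- acc + (u[i] - v[i])^2 / s
  }
  acc / 2
}

# Exhaustive nearest-codeword search (lowest index wins ties).
assign_ref <- function(v, centroids) {
  d <- apply(centroids, 1L, function(w) chi2_ref(v, w))
  which(d == min(d))[1L]
}

# Plain Lloyd iteration under the chi-squared metric from random initial
# centroids; returns the final within-cluster objective.
lloyd_ref <- function(x, k, max_iter = 100L) {
  centroids <- x[sample.int(nrow(x), k), , drop = FALSE]
  asg_prev <- rep(0L, nrow(x))
  for (it in seq_len(max_iter)) {
    d <- matrix(0, nrow(x), k)
    for (j in seq_len(k))
      for (i in seq_len(nrow(x)))
        d[i, j] <- chi2_ref(x[i, ], centroids[j, ])
    asg <- apply(d, 1L, which.min)
    if (all(asg == asg_prev)) break
    asg_prev <- asg
    for (j in seq_len(k))
      if (any(asg == j))
        centroids[j, ] <- colMeans(x[asg == j, , drop = FALSE])
  }
  obj <- 0
  for (i in seq_len(nrow(x)))
    obj <- obj + chi2_ref(x[i, ], centroids[asg[i], ])
  obj
}

best_lloyd_ref <- function(x, k, restarts = 50L) {
  min(vapply(seq_len(restarts), function(r) lloyd_ref(x, k), numeric(1L)))
}

# Brute-force sensitivity maximization: evaluate the Jaccard accuracy of
# every achievable recognized set under the strict-threshold rule.
sweep_ref <- function(scores, truth) {
  jac <- function(rec, tr) {
    u <- length(union(rec, tr))
    if (u == 0L) 1 else length(intersect(rec, tr)) / u
  }
  best <- -1
  for (eps in c(sort(unique(scores)) - 1e-9, max(scores) + 1e-9)) {
    r <- jac(names(scores)[scores > eps], truth)
    if (r > best) best <- r
  }
  best
}

# Construct a codebook object directly from given centroids (bypasses
# K-means; for encoding/assignment tests).
make_codebook <- function(centroids, channel) {
  structure(list(channel = channel, centroids = centroids,
                 k = nrow(centroids), dim = ncol(centroids),
                 objective = NA_real_, trace = numeric(0),
                 iterations = 0L, seed = NA_integer_),
            class = "bow_codebook")
}

# Random non-negative feature matrix.
rand_feats <- function(n, d) matrix(stats::runif(n * d), n, d)
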