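# Two linearly separable histogram clusters for classifier tests.
separable_histograms <- function(n_per = 12, d = 10, seed = 6) {
  set.seed(seed)
  a <- rand_feats(n_per, d) * 0.05
  a[, 1] <- a[, 1] + 0.9
  b <- rand_feats(n_per, d) * 0.05
  b[, d] <- b[, d] + 0.9
  x <- rbind(a, b) / rowSums(rbind(a, b))
  list(x = x, labels = c(rep(list("apple"), n_per), rep(list("bread"), n_per)))
}

test_that("one-vs-rest training separates separable clusters", {
  sh <- separable_histograms()
  models <- train_ovr(sh$x, sh$labels)
  expect_s3_class(models, "bow_ovr")
  expect_equal(models$categories, c("apple", "bread"))
  sc <- score_histogram(models, sh$x)
  pred <- apply(sc, 1L, function(s) names(s)[which.max(s)])
  expect_equal(unname(pred), unlist(sh$labels))
  # retraining reproduces identical weights
  models2 <- train_ovr(sh$x, sh$labels)
  expect_equal(models$W, models2$W, tolerance = 1e-10)
  expect_equal(models$b, models2$b, tolerance = 1e-10)
})

test_that("multi-label images are positives for every category they contain", {
  sh <- separable_histograms()
  mixed <- (sh$x[1, ] + sh$x[13, ]) / 2
  x <- rbind(sh$x, mixed)
  labels <- c(sh$labels, list(c("apple", "bread")))
  models <- train_ovr(x, labels)
  sc <- score_histogram(models, mixed)
  # the mixed image must score higher than pure negatives for both models
  sc_neg_apple <- score_histogram(models, sh$x[20, ])["apple"]
  sc_neg_bread <- score_histogram(models, sh$x[5, ])["bread"]
  expect_gt(sc["apple"], sc_neg_apple)
  expect_gt(sc["bread"], sc_neg_bread)
  # a category with no positives (or no negatives) is a named error
  expect_error(train_ovr(sh$x, c(rep(list("apple"), 24))), "apple")
})

test_that("duplicating every training example leaves decision scores unchanged", {
  sh <- separable_histograms(n_per = 8)
  m1 <- train_ovr(sh$x, sh$labels)
  m2 <- train_ovr(rbind(sh$x, sh$x), c(sh$labels, sh$labels))
  set.seed(30)
  probe <- rand_feats(20, ncol(sh$x))
  probe <- probe / rowSums(probe)
  expect_equal(score_histogram(m1, probe), score_histogram(m2, probe),
               tolerance = 1e-6)
})

test_that("scores are the signed linear decision values", {
  m <- structure(list(categories = "thing",
                      W = matrix(c(1, -1, 0), 1), b = 0.2,
                      cost = 1, class_weight = TRUE, n_features = 3L),
                 class = "bow_ovr")
  expect_equal(unname(score_histogram(m, c(0.5, 0.3, 0.2))), 0.4)
  # constant model: zero weights, bias 0.5
  m0 <- structure(list(categories = "c", W = matrix(0, 1, 3), b = 0.5,
                       cost = 1, class_weight = TRUE, n_features = 3L),
                  class = "bow_ovr")
  expect_equal(unname(score_histogram(m0, runif(3))), 0.5)
  # linearity in the histogram
  h1 <- c(0.2, 0.5, 0.3); h2 <- c(0.6, 0.1, 0.3); al <- 0.3
  expect_equal(unname(score_histogram(m, al * h1 + (1 - al) * h2)),
               al * unname(score_histogram(m, h1)) +
                 (1 - al) * unname(score_histogram(m, h2)))
  expect_error(score_histogram(m, c(1, 2)), "length")
})

test_that("single-label rule is argmax with first-index tie-breaking", {
  sc <- c(beans = 0.2, carrots = 0.9, cheese = -0.1)
  expect_equal(predict_single(sc), "carrots")
  expect_equal(predict_single(c(only = -3)), "only")
  sc_tie <- c(a = 0.1, b = 0.7, c = 0.3, d = 0.7)
  expect_equal(predict_single(sc_tie), "b")
})

test_that("multi-label rule uses a strict threshold and is monotone in epsilon", {
  sc <- c(a = 0.4, b = -0.2, c = 0.4, d = 0.1)
  expect_setequal(predict_multi(sc, 0.1), c("a", "c"))
  expect_equal(predict_multi(sc, 0.5), character(0))
  expect_setequal(predict_multi(sc, -1), c("a", "b", "c", "d"))
  # strictness: epsilon equal to a score excludes it
  expect_setequal(predict_multi(sc, 0.4), character(0))
  set.seed(14)
  for (i in 1:100) {
    s <- setNames(rnorm(6), letters[1:6])
    eps <- sort(rnorm(20))
    sets <- lapply(eps, function(e) predict_multi(s, e))
    for (j in 2:20)
      expect_true(all(sets[[j]] %in% sets[[j - 1]]))
    # the argmax is in every thresholded set its score exceeds
    for (j in 1:20)
      if (max(s) > eps[j])
        expect_true(predict_single(s) %in% sets[[j]])
  }
})
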