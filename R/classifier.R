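# One-vs-rest linear classifiers over bag-of-words histograms, and the
# single-label (argmax) and multi-label (sensitivity-thresholded) decision
# rules.  The margin optimization is delegated to LIBSVM (e1071); each
# fitted classifier is reduced to an explicit linear model (weights, bias).

#' Train one-vs-rest linear classifiers
#'
#' For each category, fits a soft-margin linear SVM with positives = images
#' whose label set contains the category and negatives = all others
#' (multi-label images are positives for every category they contain).
#' Optional inverse-frequency class weighting (proportional to `1 / n_class`)
#' rebalances the hinge loss for the small positive sets typical of food
#' records; with it, duplicating every training example leaves the objective
#' — and hence the decision boundary — unchanged.
#'
#' @param histograms matrix of row histograms (or list of `bow_histogram`s).
#' @param label_sets list of character vectors, one per histogram row.
#' @param categories category vocabulary and ordering; defaults to the
#'   sorted union of the label sets.
#' @param cost regularization strength C of the soft margin (default 1).
#' @param class_weight logical: inverse-frequency class weighting
#'   (default TRUE).
#' @param tolerance optimizer termination tolerance (default 1e-6).
#' @return an object of class `bow_ovr`: list with `categories`, weight
#'   matrix `W` (one row per category), bias vector `b`, and the training
#'   configuration.
#' @export
train_ovr <- function(histograms, label_sets, categories = NULL, cost = 1,
                      class_weight = TRUE, tolerance = 1e-6) {
  if (is.list(histograms) && !is.matrix(histograms))
    histograms <- do.call(rbind, lapply(histograms, as.numeric))
  x <- unname(as.matrix(histograms))
  n <- nrow(x)
  stopifnot(length(label_sets) == n, cost > 0)
  if (is.null(categories))
    categories <- sort(unique(unlist(label_sets)))
  w_mat <- matrix(0, length(categories), ncol(x))
  b_vec <- numeric(length(categories))
  for (ci in seq_along(categories)) {
    cat_i <- categories[ci]
    pos <- vapply(label_sets, function(s) cat_i %in% s, logical(1L))
    n_pos <- sum(pos); n_neg <- n - n_pos
    if (n_pos == 0L || n_neg == 0L)
      stop("category '", cat_i, "' needs at least one positive and one ",
           "negative training example (has ", n_pos, " positives, ",
           n_neg, " negatives)")
    y <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
    cw <- if (class_weight) c(neg = 100 / n_neg, pos = 100 / n_pos) else NULL
    fit <- e1071::svm(x = x, y = y, kernel = "linear", scale = FALSE,
                      cost = cost, class.weights = cw,
                      tolerance = tolerance, fitted = FALSE)
    wv <- drop(crossprod(fit$coefs, fit$SV))
    bv <- -fit$rho
    dec <- drop(x %*% wv) + bv
    if (mean(dec[pos]) < mean(dec[!pos])) { wv <- -wv; bv <- -bv }
    w_mat[ci, ] <- wv
    b_vec[ci] <- bv
  }
  structure(list(categories = categories, W = w_mat, b = b_vec,
                 cost = cost, class_weight = class_weight,
                 n_features = ncol(x)),
            class = "bow_ovr")
}

#' @export
print.bow_ovr <- function(x, ...) {
  cat(sprintf("<bow_ovr> %d one-vs-rest linear classifiers over %d-dim histograms\n",
              length(x$categories), x$n_features))
  cat("  categories:", paste(x$categories, collapse = ", "), "\n")
  invisible(x)
}

#' Per-category decision scores
#'
#' Signed linear decision values `w_i . h + b_i` for every trained category.
#'
#' @param models a `bow_ovr` object.
#' @param h a histogram vector, or a matrix with one histogram per row.
#' @return a named numeric vector of scores (or a matrix, one row per input
#'   histogram).
#' @export
score_histogram <- function(models, h) {
  stopifnot(inherits(models, "bow_ovr"))
  m <- if (is.matrix(h)) h else matrix(as.numeric(h), nrow = 1L)
  if (ncol(m) != models$n_features)
    stop("histogram length ", ncol(m), " does not match model (",
         models$n_features, ")")
  sc <- m %*% t(models$W) + rep(models$b, each = nrow(m))
  colnames(sc) <- models$categories
  if (is.matrix(h)) sc else sc[1L, ]
}

#' Single-label prediction (argmax rule)
#'
#' Returns the category with the maximal score; ties are broken by the
#' model's category order (first wins).
#'
#' @param scores named numeric vector of per-category scores.
#' @return a category name.
#' @export
predict_single <- function(scores) {
  stopifnot(length(scores) >= 1L)
  names(scores)[which.max(scores)]
}

#' Multi-label prediction with a recognition-sensitivity threshold
#'
#' Returns every category whose score strictly exceeds the sensitivity
#' `epsilon`; the set may be empty.  Monotone in `epsilon`: raising the
#' threshold can only shrink the predicted set.
#'
#' @param scores named numeric vector of per-category scores.
#' @param epsilon recognition-sensitivity threshold.
#' @return character vector of category names (possibly empty).
#' @export
predict_multi <- function(scores, epsilon) {
  names(scores)[scores > epsilon]
}
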