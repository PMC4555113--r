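# Chi-squared vector quantization: distance, K-means codebook learning,
# best-matching-codeword assignment and bag-of-words encoding.

check_nonneg <- function(x, what = "vector") {
  if (any(!is.finite(x)) || any(x < 0))
    stop(what, " must be finite and non-negative (chi-squared metric)")
  invisible(x)
}

#' Chi-squared distance between two non-negative vectors
#'
#' `d(u, v) = 0.5 * sum_i (u_i - v_i)^2 / (u_i + v_i)`, with terms whose
#' denominator is zero contributing zero (the continuous limit).  Symmetric,
#' non-negative, and zero iff `u == v`.
#'
#' @param u,v non-negative numeric vectors of equal length.
#' @return a single non-negative number.
#' @export
chi2_distance <- function(u, v) {
  if (length(u) != length(v))
    stop("dimension mismatch: ", length(u), " vs ", length(v))
  check_nonneg(u, "u"); check_nonneg(v, "v")
  s <- u + v
  d <- (u - v)^2
  0.5 * sum(ifelse(s > 0, d / s, 0))
}

#' Chi-squared cross-distance matrix
#'
#' Pairwise chi-squared distances between the rows of `x` and the rows of
#' `centroids`.
#'
#' @param x numeric matrix (n x D), non-negative.
#' @param centroids numeric matrix (K x D), non-negative.
#' @return an n x K matrix of distances.
#' @export
chi2_cross <- function(x, centroids) {
  x <- as.matrix(x); centroids <- as.matrix(centroids)
  if (ncol(x) != ncol(centroids))
    stop("dimension mismatch: ", ncol(x), " vs ", ncol(centroids))
  check_nonneg(x, "x"); check_nonneg(centroids, "centroids")
  chi2_cross_cpp(x, centroids)
}

# Run one body of chi-squared Lloyd iterations from given initial centroids.
# Returns centroids, assignment, objective trace (non-increasing) and
# iteration count.
chi2_lloyd <- function(x, centroids, max_iter) {
  n <- nrow(x)
  assign_prev <- integer(0)
  trace <- numeric(0)
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    dm <- chi2_cross_cpp(x, centroids)
    asg <- max.col(-dm, ties.method = "first")
    obj <- sum(dm[cbind(seq_len(n), asg)])
    if (obj > obj_prev + 1e-12) {
      # the arithmetic-mean update is not guaranteed to decrease the
      # chi-squared objective; if it ever increases it, keep the previous
      # state and stop (keeps the recorded trace non-increasing)
      break
    }
    trace <- c(trace, obj)
    obj_prev <- obj
    prev_centroids <- centroids
    assign_prev_keep <- asg
    if (length(assign_prev) && all(asg == assign_prev)) break
    assign_prev <- asg
    # arithmetic-mean update
    cnt <- tabulate(asg, nbins = nrow(centroids))
    upd <- rowsum(x, asg)
    centroids[sort(unique(asg)), ] <- upd / cnt[sort(unique(asg))]
    # re-seed empty clusters with the points farthest from their centroids
    empty <- which(cnt == 0L)
    if (length(empty)) {
      resid <- dm[cbind(seq_len(n), asg)]
      for (k in empty) {
        far <- which.max(resid)
        centroids[k, ] <- x[far, ]
        resid[far] <- -Inf
      }
    }
  }
  list(centroids = prev_centroids, assignment = assign_prev_keep,
       objective = obj_prev, trace = trace, iterations = length(trace))
}

# k-means++-style seeding under the chi-squared metric (uses the current RNG
# stream).
chi2_pp_init <- function(x, k) {
  n <- nrow(x)
  centroids <- matrix(0, k, ncol(x))
  centroids[1L, ] <- x[sample.int(n, 1L), ]
  mind <- chi2_cross_cpp(x, centroids[1L, , drop = FALSE])[, 1L]
  for (j in seq_len(k - 1L) + 1L) {
    if (all(mind <= 0)) {
      cand <- which(mind == max(mind))
      pick <- cand[sample.int(length(cand), 1L)]
    } else {
      pick <- sample.int(n, 1L, prob = mind / sum(mind))
    }
    centroids[j, ] <- x[pick, ]
    mind <- pmin(mind, chi2_cross_cpp(x, centroids[j, , drop = FALSE])[, 1L])
  }
  centroids
}

#' Learn a codebook by chi-squared K-means
#'
#' Lloyd iterations with chi-squared assignment and arithmetic-mean centroid
#' updates, initialized by k-means++-style seeding under the chi-squared
#' metric.  Iterations stop when the assignment is unchanged, after
#' `max_iter` iterations, or if a mean update would increase the chi-squared
#' objective (the recorded objective trace is therefore non-increasing).
#' Empty clusters are re-seeded with the features farthest from their
#' centroids.  Fully reproducible for a fixed `seed`; the caller's RNG state
#' is left untouched.
#'
#' @param features non-negative numeric matrix (one feature per row) or list
#'   of equal-length vectors.
#' @param k number of codewords; requires at least `k` distinct features.
#' @param seed integer seed controlling initialization.
#' @param channel optional channel name stored in the codebook.
#' @param max_iter iteration cap (default 300).
#' @param nstart number of k-means++ starts; the run with the lowest final
#'   objective is kept (default 1).
#' @return an object of class `bow_codebook`: list with `channel`,
#'   `centroids` (K x D), `k`, `dim`, `objective`, `trace`, `iterations`,
#'   `seed`.
#' @export
kmeans_chi2 <- function(features, k, seed = 1L, channel = NA_character_,
                        max_iter = 300L, nstart = 1L) {
  if (is.list(features) && !is.data.frame(features))
    features <- do.call(rbind, features)
  x <- as.matrix(features)
  check_nonneg(x, "features")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  n_distinct <- nrow(unique(x))
  if (n_distinct < k)
    stop("need at least k = ", k, " distinct features, got ", n_distinct)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  best <- NULL
  for (st in seq_len(max(1L, as.integer(nstart)))) {
    init <- chi2_pp_init(x, k)
    run <- chi2_lloyd(x, init, max_iter)
    if (is.null(best) || run$objective < best$objective - 1e-12) best <- run
  }
  structure(list(channel = channel, centroids = best$centroids, k = k,
                 dim = ncol(x), objective = best$objective,
                 trace = best$trace, iterations = best$iterations,
                 seed = as.integer(seed)),
            class = "bow_codebook")
}

#' @export
print.bow_codebook <- function(x, ...) {
  cat(sprintf("<bow_codebook> channel=%s, K=%d, D=%d, objective=%.6g (%d iterations)\n",
              x$channel, x$k, x$dim, x$objective, x$iterations))
  invisible(x)
}

#' Best-matching codeword
#'
#' Returns the index of the codeword minimizing the chi-squared distance to
#' `v`; ties are broken by the lowest index.
#'
#' @param v non-negative feature vector (or matrix of such rows).
#' @param codebook a `bow_codebook`.
#' @return integer codeword index (or vector of indices for a matrix input).
#' @export
assign_codeword <- function(v, codebook) {
  stopifnot(inherits(codebook, "bow_codebook"))
  x <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  if (ncol(x) != codebook$dim)
    stop("dimension mismatch: ", ncol(x), " vs codebook dim ", codebook$dim)
  check_nonneg(x, "v")
  dm <- chi2_cross_cpp(x, codebook$centroids)
  idx <- max.col(-dm, ties.method = "first")
  if (is.matrix(v)) idx else idx[1L]
}

#' Encode a feature set as a bag-of-words histogram
#'
#' Per channel, counts best-matching-codeword assignments over all interest
#' points, L1-normalizes the counts, and concatenates the channel blocks in
#' the fixed order shape, texture, colour (restricted to the channels
#' present in `codebooks`).
#'
#' @param features a `bow_features` object from [extract_features()].
#' @param codebooks named list of `bow_codebook`s (names from
#'   `c("shape", "texture", "colour")`).
#' @return an object of class `bow_histogram`: a numeric vector with
#'   attributes `layout` (named per-channel block lengths) and `n_points`.
#' @export
encode_image <- function(features, codebooks) {
  stopifnot(inherits(features, "bow_features"))
  chans <- intersect(CHANNELS, names(codebooks))
  if (length(chans) == 0L) stop("no recognized channels in codebooks")
  n_pts <- nrow(features$points)
  if (n_pts == 0L)
    stop("unencodable image: no interest points detected")
  blocks <- lapply(chans, function(ch) {
    cb <- codebooks[[ch]]
    desc <- features[[ch]]
    if (is.null(desc)) stop("feature set lacks channel: ", ch)
    cnt <- tabulate(assign_codeword(desc, cb), nbins = cb$k)
    cnt / sum(cnt)
  })
  v <- unlist(blocks, use.names = FALSE)
  structure(v, layout = stats::setNames(vapply(codebooks[chans], `[[`, 1L, "k"),
                                        chans),
            n_points = n_pts, class = "bow_histogram")
}

#' @export
print.bow_histogram <- function(x, ...) {
  lay <- attr(x, "layout")
  cat(sprintf("<bow_histogram> length %d [%s], %d interest points\n",
              length(x), paste(sprintf("%s:%d", names(lay), lay), collapse = " | "),
              attr(x, "n_points")))
  invisible(x)
}
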