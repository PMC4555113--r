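# The main fitting function: manifest in, fitted bag-of-words recognizer
# out.  Follows the classic R modelling idiom: bowfood() returns a classed
# object with print/summary/coef/predict methods.

#' Fit a bag-of-visual-words food image recognizer
#'
#' Runs the full training pipeline on the train split of a manifest:
#' feature extraction (interest points + per-channel descriptors) on every
#' training image, per-channel codebook learning by chi-squared K-means over
#' the pooled training features, bag-of-words encoding of the training
#' images, and one-vs-rest linear SVM training.
#'
#' @param manifest a manifest `data.frame` or CSV path (columns
#'   `image_path`, `labels`, `split`); rows with `split == "train"` are used
#'   for fitting.
#' @param image_dir directory for resolving relative image paths.
#' @param channels feature channels to use, a subset of
#'   `c("shape", "texture", "colour")`.
#' @param codebook_k named per-channel codebook sizes
#'   (default shape 100, texture 40, colour 50).
#' @param cost SVM regularization strength C (default 1).
#' @param class_weight inverse-frequency class weighting (default TRUE).
#' @param seed integer seed for codebook initialization.
#' @param kmeans_nstart k-means++ restarts per codebook (default 1).
#' @param features optional named list (by `image_path`) of precomputed
#'   `bow_features` to reuse across fits (e.g. for channel ablation).
#' @param codebooks optional named list of precomputed `bow_codebook`s to
#'   reuse; missing channels are trained.
#' @param verbose log per-stage counts to stderr.
#' @return an object of class `bowfood`: list with `categories`, `channels`,
#'   `codebooks`, `models` (a `bow_ovr`), configuration and training counts.
#' @seealso [predict.bowfood()], [evaluate_bowfood()], [generate_dataset()]
#' @export
bowfood <- function(manifest, image_dir = NULL,
                    channels = c("shape", "texture", "colour"),
                    codebook_k = c(shape = 100L, texture = 40L, colour = 50L),
                    cost = 1, class_weight = TRUE, seed = 1L,
                    kmeans_nstart = 1L, features = NULL, codebooks = NULL,
                    verbose = FALSE) {
  channels <- match.arg(channels, several.ok = TRUE)
  stopifnot(length(channels) >= 1L, all(codebook_k >= 1L))
  man <- as_manifest(manifest, image_dir)
  train <- man[man$split == "train", , drop = FALSE]
  if (nrow(train) == 0L) stop("manifest has no training rows")
  labs <- strsplit(train$labels, ";", fixed = TRUE)

  note <- function(...) if (verbose) message(sprintf(...))
  note("extracting features from %d training images", nrow(train))
  feats <- vector("list", nrow(train))
  for (i in seq_len(nrow(train))) {
    feats[[i]] <- feature_for(train$abs_path[i], channels, features,
                              key = train$image_path[i])
    note("  %s: %d interest points", train$image_path[i],
         nrow(feats[[i]]$points))
  }
  encodable <- vapply(feats, function(f) nrow(f$points) > 0L, logical(1L))
  if (!all(encodable))
    warning(sum(!encodable), " unencodable training image(s) skipped",
            call. = FALSE)
  if (!any(encodable)) stop("no encodable training images")

  cbs <- list()
  for (ch in channels) {
    if (!is.null(codebooks[[ch]])) {
      cbs[[ch]] <- codebooks[[ch]]
      next
    }
    pool <- do.call(rbind, lapply(feats[encodable], `[[`, ch))
    note("training %s codebook: K = %d over %d features",
         ch, codebook_k[[ch]], nrow(pool))
    cbs[[ch]] <- kmeans_chi2(pool, k = codebook_k[[ch]],
                             seed = as.integer(seed) + match(ch, CHANNELS),
                             channel = ch, nstart = kmeans_nstart)
  }

  hs <- t(vapply(feats[encodable],
                 function(f) as.numeric(encode_image(f, cbs)),
                 numeric(sum(vapply(cbs, `[[`, integer(1L), "k")))))
  models <- train_ovr(hs, labs[encodable], cost = cost,
                      class_weight = class_weight)
  note("trained %d one-vs-rest classifiers on %d histograms of length %d",
       length(models$categories), nrow(hs), ncol(hs))

  structure(list(categories = models$categories, channels = channels,
                 codebooks = cbs, models = models,
                 config = list(codebook_k = codebook_k, cost = cost,
                               class_weight = class_weight,
                               seed = as.integer(seed)),
                 n_train = nrow(train), n_encodable = sum(encodable),
                 codebook_checksum = codebook_checksum(cbs),
                 call = match.call()),
            class = "bowfood")
}

# Stable checksum binding classifiers to the codebooks they were encoded
# against (prevents silently scoring with a mismatched codebook set).
codebook_checksum <- function(codebooks) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  centro <- lapply(codebooks[order(names(codebooks))], function(cb)
    list(cb$channel, cb$k, cb$dim, round(cb$centroids, 12L)))
  saveRDS(centro, tmp, version = 2L, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' @export
print.bowfood <- function(x, ...) {
  cat("Bag-of-visual-words food image recognizer\n")
  cat(sprintf("  channels: %s (histogram length %d)\n",
              paste(x$channels, collapse = " + "), x$models$n_features))
  cat(sprintf("  categories (%d): %s\n", length(x$categories),
              paste(x$categories, collapse = ", ")))
  cat(sprintf("  trained on %d images (%d encodable)\n",
              x$n_train, x$n_encodable))
  invisible(x)
}

#' @export
summary.bowfood <- function(object, ...) {
  print(object)
  for (ch in object$channels) print(object$codebooks[[ch]])
  cat(sprintf("  SVM: linear, C = %g, class weighting %s\n",
              object$config$cost,
              if (object$config$class_weight) "on" else "off"))
  invisible(object)
}

#' Classifier weights of a fitted recognizer
#'
#' @param object a `bowfood` model.
#' @param ... unused.
#' @return matrix of linear weights (one row per category) with the bias as
#'   the last column.
#' @export
coef.bowfood <- function(object, ...) {
  out <- cbind(object$models$W, bias = object$models$b)
  rownames(out) <- object$categories
  out
}

#' Predict food categories in new images
#'
#' Encodes each image against the model's codebooks and applies the trained
#' one-vs-rest classifiers.  `type = "single"` applies the argmax rule for
#' images known to contain one food; `type = "multi"` returns every category
#' whose score strictly exceeds `epsilon`; `type = "scores"` returns the raw
#' decision values.  Images on which no interest points are detected are
#' flagged as unencodable (score `-Inf`, no labels) rather than failing.
#'
#' @param object a fitted [bowfood()] model.
#' @param newdata character vector of image paths, a single
#'   [image_record()], a list of image records, or a list of precomputed
#'   `bow_features`.
#' @param type `"multi"`, `"single"` or `"scores"`.
#' @param epsilon recognition sensitivity for `type = "multi"` (default 0).
#' @param ... unused.
#' @return a list with one element per image: list with `image`, `scores`,
#'   `labels` and `encodable`.  For `type = "scores"` the scores matrix is
#'   attached as attribute `"scores"`.
#' @export
predict.bowfood <- function(object, newdata, type = c("multi", "single", "scores"),
                            epsilon = 0, ...) {
  type <- match.arg(type)
  items <- if (inherits(newdata, c("image_record", "bow_features")))
    list(newdata) else if (is.character(newdata)) as.list(newdata) else newdata
  out <- vector("list", length(items))
  for (i in seq_along(items)) {
    it <- items[[i]]
    nm <- if (is.character(it)) it
          else if (inherits(it, "image_record")) it$path
          else names(items)[i] %||% sprintf("image_%d", i)
    fs <- if (inherits(it, "bow_features")) it
          else if (inherits(it, "image_record"))
            extract_features(it, channels = object$channels)
          else extract_features(load_image(it), channels = object$channels)
    if (nrow(fs$points) == 0L) {
      out[[i]] <- list(image = nm,
                       scores = stats::setNames(rep(-Inf,
                         length(object$categories)), object$categories),
                       labels = character(0), encodable = FALSE)
      next
    }
    h <- encode_image(fs, object$codebooks[object$channels])
    sc <- score_histogram(object$models, as.numeric(h))
    labels <- switch(type,
                     multi = predict_multi(sc, epsilon),
                     single = predict_single(sc),
                     scores = character(0))
    out[[i]] <- list(image = nm, scores = sc, labels = labels,
                     encodable = TRUE)
  }
  if (type == "scores")
    attr(out, "scores") <- do.call(rbind, lapply(out, `[[`, "scores"))
  out
}

#' Save a fitted recognizer as a single archive
#'
#' Bundles codebooks, classifiers, configuration and a codebook checksum in
#' one versioned archive, so that mismatched encode/score pairs are
#' impossible.  Round-trips bit-exactly through [load_bowfood()].
#'
#' @param model a `bowfood` model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_bowfood <- function(model, path) {
  stopifnot(inherits(model, "bowfood"))
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp))
  saveRDS(list(format_version = 1L, model = model), tmp, version = 2L)
  file.rename(tmp, path)   # never leave a partial archive behind
  invisible(path)
}

#' Load a fitted recognizer archive
#'
#' @param path archive written by [save_bowfood()].
#' @return the `bowfood` model.
#' @export
load_bowfood <- function(path) {
  if (!file.exists(path)) stop("model archive not found: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$format_version))
    stop("not a bowfood model archive: ", path)
  if (obj$format_version != 1L)
    stop("unsupported archive format version: ", obj$format_version)
  model <- obj$model
  if (!identical(codebook_checksum(model$codebooks), model$codebook_checksum))
    stop("codebook checksum mismatch: archive is corrupt or was tampered with")
  model
}

#' Fit and evaluate all feature-channel configurations
#'
#' Extracts features once, learns each per-channel codebook once, then fits
#' and evaluates a model per configuration (each single channel plus the
#' combined set), mirroring a per-channel ablation table.
#'
#' @inheritParams bowfood
#' @param configs list of channel subsets to evaluate; defaults to the
#'   three single channels plus the combined configuration.
#' @return a named list of [eval_report()]s (one per configuration).
#' @export
bowfood_ablation <- function(manifest, image_dir = NULL,
                             configs = list(shape = "shape",
                                            texture = "texture",
                                            colour = "colour",
                                            combined = c("shape", "texture", "colour")),
                             codebook_k = c(shape = 100L, texture = 40L, colour = 50L),
                             cost = 1, class_weight = TRUE, seed = 1L,
                             verbose = FALSE) {
  man <- as_manifest(manifest, image_dir)
  all_ch <- unique(unlist(configs))
  feats <- stats::setNames(vector("list", nrow(man)), man$image_path)
  for (i in seq_len(nrow(man)))
    feats[[i]] <- extract_features(load_image(man$abs_path[i]),
                                   channels = all_ch)
  base <- bowfood(man, channels = all_ch, codebook_k = codebook_k,
                  cost = cost, class_weight = class_weight, seed = seed,
                  features = feats, verbose = verbose)
  out <- list()
  for (nm in names(configs)) {
    ch <- configs[[nm]]
    fit <- bowfood(man, channels = ch, codebook_k = codebook_k,
                   cost = cost, class_weight = class_weight, seed = seed,
                   features = feats, codebooks = base$codebooks[ch],
                   verbose = verbose)
    rep_i <- evaluate_bowfood(fit, man, features = feats)
    rep_i$config <- nm
    out[[nm]] <- rep_i
  }
  out
}
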