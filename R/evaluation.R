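# Jaccard-index recognition accuracy, the per-category sensitivity sweep
# r_i = max over epsilon of r_i(epsilon), and dataset-level reporting with
# optional feature-channel ablation.

#' Jaccard recognition accuracy between two image-id sets
#'
#' `|recognized intersect truth| / |recognized union truth|`.  When both
#' sets are empty the accuracy is defined as 1 (nothing to find, nothing
#' claimed); this degenerate case is reported via `message()` when it
#' occurs.
#'
#' @param recognized character vector of image ids recognized as containing
#'   the category.
#' @param truth character vector of image ids truly containing it.
#' @return a number in `[0, 1]`.
#' @export
jaccard_accuracy <- function(recognized, truth) {
  recognized <- unique(as.character(recognized))
  truth <- unique(as.character(truth))
  u <- length(union(recognized, truth))
  if (u == 0L) {
    message("jaccard_accuracy: both sets empty; returning 1 by convention")
    return(1)
  }
  length(intersect(recognized, truth)) / u
}

#' Sweep the recognition sensitivity for one category
#'
#' Evaluates the Jaccard accuracy `r(epsilon)` of the strict-inequality
#' recognition rule `score > epsilon` over the candidate grid
#' `{s - delta : s a distinct observed score} + {max score + delta}`
#' (`delta = 1e-9`), which realizes every achievable recognized set, and
#' returns the maximizing sensitivity (the smallest maximizer on ties)
#' together with its accuracy.
#'
#' @param scores named numeric vector: per-test-image decision score for the
#'   category (names are image ids).
#' @param truth character vector of image ids containing the category.
#' @return a list with `epsilon`, `r`, and `recognized` (the image ids
#'   recognized at the best sensitivity).
#' @export
sweep_sensitivity <- function(scores, truth) {
  if (length(scores) == 0L) stop("empty test set: no scores to sweep")
  if (is.null(names(scores)) || anyNA(names(scores)))
    stop("scores must be named by image id")
  delta <- 1e-9
  finite <- scores[is.finite(scores)]
  cand <- if (length(finite))
    c(sort(unique(finite)) - delta, max(finite) + delta)
  else 0   # all images unencodable: any threshold recognizes nothing
  best_r <- -1; best_eps <- NA_real_; best_rec <- character(0)
  for (eps in cand) {
    rec <- names(scores)[scores > eps]
    r <- suppressMessages(jaccard_accuracy(rec, truth))
    if (r > best_r + 1e-15) {
      best_r <- r; best_eps <- eps; best_rec <- rec
    }
  }
  list(epsilon = best_eps, r = best_r, recognized = best_rec)
}

#' Build an evaluation report from per-category accuracies
#'
#' Assembles the per-category accuracies and the overall row (their
#' unweighted arithmetic mean) into an `eval_report` object.  Used both by
#' [evaluate_bowfood()] and directly when aggregating externally computed
#' per-category accuracies.
#'
#' @param categories character vector of category names.
#' @param r per-category Jaccard accuracies in `[0, 1]`.
#' @param epsilon per-category best sensitivities (optional).
#' @param n_truth per-category test-image counts `|M_i|` (optional).
#' @param n_recognized per-category recognized counts at the best
#'   sensitivity (optional).
#' @param config label for the feature configuration (default "combined").
#' @return an object of class `eval_report`: a list with `table` (one row
#'   per category) and `overall`.
#' @export
eval_report <- function(categories, r, epsilon = NA_real_,
                        n_truth = NA_integer_, n_recognized = NA_integer_,
                        config = "combined") {
  stopifnot(length(categories) == length(r), all(r >= 0 & r <= 1))
  tab <- data.frame(category = as.character(categories),
                    epsilon = as.numeric(epsilon),
                    r = as.numeric(r),
                    n_truth = as.integer(n_truth),
                    n_recognized = as.integer(n_recognized),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, overall = mean(tab$r), config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 2L, ...) {
  cat(sprintf("Recognition accuracy (%s features)\n", x$config))
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-14s r = %.*f%s\n", tab$category[i], digits, tab$r[i],
                if (is.finite(tab$epsilon[i]))
                  sprintf("  (epsilon* = %.4g, |M_i| = %d, recognized = %d)",
                          tab$epsilon[i], tab$n_truth[i], tab$n_recognized[i])
                else ""))
  cat(sprintf("  %-14s r = %.*f\n", "Overall", digits, x$overall))
  invisible(x)
}

#' @export
plot.eval_report <- function(x, ...) {
  graphics::barplot(c(x$table$r, x$overall),
                    names.arg = c(x$table$category, "Overall"),
                    las = 2, ylim = c(0, 1), ylab = "Jaccard accuracy r",
                    main = sprintf("Recognition accuracy (%s)", x$config), ...)
  graphics::abline(h = x$overall, lty = 2)
  invisible(x)
}

#' Evaluate a fitted model on the test split of a manifest
#'
#' Scores every test image, runs the sensitivity sweep per category, and
#' reports per-category accuracies plus their unweighted mean as the
#' overall accuracy.  Images on which no interest points can be detected
#' are counted as "not recognized" for every category and reported with a
#' warning.
#'
#' @param model a fitted [bowfood()] model.
#' @param manifest a manifest `data.frame` (or CSV path, see
#'   [read_manifest()]); rows with `split == "test"` are used.
#' @param image_dir directory against which relative manifest paths are
#'   resolved; defaults to the manifest's directory when a path is given.
#' @param features optional named list (by image path) of precomputed
#'   `bow_features`, as produced by [extract_features()]; avoids re-running
#'   feature extraction.
#' @return an [eval_report()].
#' @export
evaluate_bowfood <- function(model, manifest, image_dir = NULL,
                             features = NULL) {
  stopifnot(inherits(model, "bowfood"))
  man <- as_manifest(manifest, image_dir)
  test <- man[man$split == "test", , drop = FALSE]
  if (nrow(test) == 0L) stop("manifest has no test rows")
  labs <- strsplit(test$labels, ";", fixed = TRUE)
  unknown <- setdiff(unique(unlist(labs)), model$categories)
  if (length(unknown))
    stop("categories present in manifest but absent from model: ",
         paste(unknown, collapse = ", "))
  ids <- test$image_path
  sc <- matrix(-Inf, nrow(test), length(model$categories),
               dimnames = list(ids, model$categories))
  n_bad <- 0L
  for (i in seq_len(nrow(test))) {
    fs <- feature_for(test$abs_path[i], model$channels, features,
                      key = test$image_path[i])
    if (nrow(fs$points) == 0L) { n_bad <- n_bad + 1L; next }
    h <- encode_image(fs, model$codebooks[model$channels])
    sc[i, ] <- score_histogram(model$models, as.numeric(h))
  }
  if (n_bad > 0L)
    warning(n_bad, " unencodable test image(s): counted as not recognized",
            call. = FALSE)
  res <- lapply(model$categories, function(cat_i) {
    truth <- ids[vapply(labs, function(s) cat_i %in% s, logical(1L))]
    sweep_sensitivity(stats::setNames(sc[, cat_i], ids), truth)
  })
  eval_report(categories = model$categories,
              r = vapply(res, `[[`, numeric(1L), "r"),
              epsilon = vapply(res, `[[`, numeric(1L), "epsilon"),
              n_truth = vapply(model$categories, function(cat_i)
                sum(vapply(labs, function(s) cat_i %in% s, logical(1L))),
                integer(1L)),
              n_recognized = vapply(res, function(z)
                length(z$recognized), integer(1L)),
              config = paste(model$channels, collapse = "+"))
}

#' Write an evaluation report as JSON
#'
#' @param report an [eval_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  obj <- list(config = report$config,
              categories = report$table,
              overall = report$overall)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Write one or more evaluation reports as a flat CSV
#'
#' Rows are the categories plus an `Overall` row; one accuracy column per
#' feature configuration (mirroring a per-channel ablation layout).
#'
#' @param reports an [eval_report()] or a list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_eval_csv <- function(reports, path) {
  if (inherits(reports, "eval_report")) reports <- list(reports)
  cats <- reports[[1L]]$table$category
  out <- data.frame(category = c(cats, "Overall"), stringsAsFactors = FALSE)
  for (rep_i in reports) {
    stopifnot(identical(rep_i$table$category, cats))
    out[[rep_i$config]] <- c(rep_i$table$r, rep_i$overall)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# Fetch (or compute) the feature set for one image path.
feature_for <- function(abs_path, channels, features, key = abs_path) {
  if (!is.null(features)) {
    fs <- features[[key]]
    if (is.null(fs)) fs <- features[[abs_path]]
    if (!is.null(fs)) return(fs)
  }
  if (!file.exists(abs_path)) stop("missing image file: ", abs_path)
  extract_features(load_image(abs_path), channels = channels)
}
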