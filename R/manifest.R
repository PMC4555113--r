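# Dataset manifests: CSV files with columns image_path, labels
# (semicolon-separated), split ("train" or "test").

#' Read a dataset manifest CSV
#'
#' @param path CSV file with header columns `image_path`, `labels`
#'   (semicolon-separated category names) and `split` (`train`/`test`).
#' @param image_dir directory against which relative image paths are
#'   resolved; defaults to the manifest's directory.
#' @return a `data.frame` with the manifest columns plus `abs_path`.
#' @export
read_manifest <- function(path, image_dir = NULL) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_manifest(man, image_dir %||% dirname(path))
}

#' Write a dataset manifest CSV
#'
#' @param manifest a manifest `data.frame`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("image_path", "labels", "split") %in% names(manifest)))
  utils::write.csv(manifest[, c("image_path", "labels", "split")], path,
                   row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Normalize a manifest (data.frame or CSV path) and attach absolute paths.
as_manifest <- function(manifest, image_dir = NULL) {
  if (is.character(manifest) && length(manifest) == 1L)
    return(read_manifest(manifest, image_dir))
  man <- as.data.frame(manifest, stringsAsFactors = FALSE)
  need <- c("image_path", "labels", "split")
  if (!all(need %in% names(man)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  if (!all(man$split %in% c("train", "test")))
    stop("manifest split values must be 'train' or 'test'")
  leak <- intersect(man$image_path[man$split == "train"],
                    man$image_path[man$split == "test"])
  if (length(leak))
    stop("image(s) present in both train and test splits: ",
         paste(utils::head(leak, 3L), collapse = ", "))
  man$abs_path <- if (!is.null(man$abs_path)) man$abs_path
    else ifelse(grepl("^(/|[A-Za-z]:)", man$image_path), man$image_path,
                file.path(image_dir %||% ".", man$image_path))
  man
}
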