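#' Labeled image collections
#'
#' An `image_collection` bundles preprocessed images with their class labels
#' and a declared role in the meta-learning protocol: `"source"` collections
#' feed episodic meta-training, `"target"` collections are held out for
#' frozen-model evaluation and must not share classes with the source.
#'
#' Each record is a list with fields `id` (opaque identifier), `class`
#' (label), `path` (relative file path or `NA` for in-memory images) and
#' `pixels`, a `size x size x 3` array with values in `[0, 1]`.
#'
#' @param role `"source"` or `"target"`.
#' @param records List of records as described above.
#' @param classes Optional ordered class list; defaults to the sorted unique
#'   labels found in `records`.
#' @return An object of class `image_collection`.
#' @export
new_collection <- function(role = c("source", "target"), records, classes = NULL) {
  role <- match.arg(role)
  labels <- vapply(records, function(r) r$class, character(1))
  if (is.null(classes)) classes <- sort(unique(labels))
  if (!all(labels %in% classes))
    stopf("record labels outside the declared class list: %s",
          paste(setdiff(labels, classes), collapse = ", "))
  missing_cls <- setdiff(classes, labels)
  if (length(missing_cls))
    stopf("class with zero records: %s", paste(missing_cls, collapse = ", "))
  structure(
    list(role = role, classes = classes, records = records),
    class = "image_collection"
  )
}

#' @export
print.image_collection <- function(x, ...) {
  cat(sprintf("<image_collection> role=%s, %d classes, %d records\n",
              x$role, length(x$classes), length(x$records)))
  invisible(x)
}

#' @export
summary.image_collection <- function(object, ...) {
  labels <- vapply(object$records, function(r) r$class, character(1))
  tab <- table(factor(labels, levels = object$classes))
  cat(sprintf("image_collection (%s): %d classes, %d records\n",
              object$role, length(object$classes), length(object$records)))
  print(tab)
  invisible(tab)
}

#' Record labels of a collection
#' @param collection An `image_collection`.
#' @return Character vector of per-record class labels.
#' @export
collection_labels <- function(collection) {
  vapply(collection$records, function(r) r$class, character(1))
}

#' Preprocess raw pixel data to the network input format
#'
#' Decoded images of any size are converted to a `size x size x 3` array with
#' values in `[0, 1]`: grayscale images are replicated across channels, alpha
#' channels are dropped, 8-bit integer ranges are divided by 255, and the
#' image is resized bilinearly with no aspect-ratio preservation. The
#' operation is idempotent: an already conforming array is returned unchanged.
#'
#' @param pixels Numeric array, 2-d (grayscale) or 3-d (channels last).
#' @param size Target square side in pixels (default 96).
#' @return `size x size x 3` array in `[0, 1]`.
#' @export
preprocess_pixels <- function(pixels, size = 96L) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  d <- dim(pixels)
  if (length(d) != 3L) stopf("expected 2-d or 3-d pixel array, got %d-d", length(d))
  if (d[3] > 3L) pixels <- pixels[, , 1:3, drop = FALSE]
  if (d[3] < 3L) pixels <- array(rep(pixels[, , 1L], 3L), c(d[1], d[2], 3L))
  mx <- max(pixels)
  if (mx > 1 + 1e-9) pixels <- pixels / 255
  d <- dim(pixels)
  if (d[1] != size || d[2] != size) {
    img <- EBImage::Image(pixels, colormode = "Color")
    pixels <- as.numeric(EBImage::resize(img, w = size, h = size))
    dim(pixels) <- c(size, size, 3L)
  }
  pixels[pixels < 0] <- 0
  pixels[pixels > 1] <- 1
  pixels
}

#' Load a directory-per-class image tree into a labeled collection
#'
#' `root` must contain one subdirectory per class holding decodable RGB
#' images (PNG/JPEG/TIFF). Class labels are the subdirectory names, sorted
#' lexicographically. Every image is decoded, resized to `size x size` and
#' scaled to `[0, 1]`. Undecodable files are skipped with a warning and
#' listed in the `load_report` attribute; a class with no decodable image is
#' an error.
#'
#' @param root Directory containing one subdirectory per class.
#' @inheritParams new_collection
#' @param size Target image side in pixels.
#' @return An `image_collection`; attribute `load_report` lists skipped files.
#' @export
load_collection <- function(root, role = c("source", "target"), size = 96L) {
  role <- match.arg(role)
  if (!dir.exists(root)) stopf("data directory not found: %s", root)
  class_dirs <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  class_dirs <- class_dirs[nzchar(class_dirs)]
  if (!length(class_dirs)) stopf("no class subdirectories under %s", root)
  records <- list()
  skipped <- character()
  for (cls in class_dirs) {
    files <- sort(list.files(file.path(root, cls), full.names = FALSE))
    n_ok <- 0L
    for (f in files) {
      fp <- file.path(root, cls, f)
      px <- tryCatch(
        preprocess_pixels(as.numeric_array(EBImage::readImage(fp)), size = size),
        error = function(e) NULL
      )
      if (is.null(px)) {
        warning(sprintf("skipping undecodable image: %s", fp), call. = FALSE)
        skipped <- c(skipped, file.path(cls, f))
        next
      }
      n_ok <- n_ok + 1L
      records[[length(records) + 1L]] <- list(
        id = file.path(cls, f), class = cls,
        path = file.path(cls, f), pixels = px
      )
    }
    if (n_ok == 0L)
      stopf("class '%s' has no decodable images", cls)
  }
  out <- new_collection(role, records, classes = class_dirs)
  attr(out, "load_report") <- skipped
  out
}

#' @noRd
as.numeric_array <- function(img) {
  a <- EBImage::imageData(img)
  storage.mode(a) <- "double"
  a
}

#' Write / read a collection manifest
#'
#' The manifest is a plain CSV with header `id,path,class,role`, one row per
#' image. Round-tripping preserves the role, the class list and the per-class
#' record counts exactly. `read_manifest()` returns the manifest metadata
#' (not pixel data); set `validate_root` to also check that every referenced
#' file exists.
#'
#' @param collection An `image_collection`.
#' @param path Manifest file path.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   returns a `collection_manifest`: a list with `role`, `classes`, `counts`
#'   (named integer vector) and `entries` (the manifest data frame).
#' @export
write_manifest <- function(collection, path) {
  df <- data.frame(
    id = vapply(collection$records, function(r) r$id, character(1)),
    path = vapply(collection$records, function(r) as.character(r$path %||% NA_character_), character(1)),
    class = collection_labels(collection),
    role = collection$role,
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param validate_root Optional directory against which `path` entries are
#'   checked for existence; missing files are a fatal error listing their ids.
#' @export
read_manifest <- function(path, validate_root = NULL) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stopf("malformed manifest %s: %s", path, conditionMessage(e))
  )
  need <- c("id", "path", "class", "role")
  if (!identical(sort(names(df)), sort(need)))
    stopf("manifest %s: expected columns %s, found %s",
          path, paste(need, collapse = ","), paste(names(df), collapse = ","))
  if (!nrow(df)) stopf("manifest %s: no records", path)
  bad <- which(!nzchar(df$id) | !nzchar(df$class))
  if (length(bad))
    stopf("manifest %s: empty id/class at line(s) %s",
          path, paste(bad + 1L, collapse = ", "))
  roles <- unique(df$role)
  if (length(roles) != 1L || !roles %in% c("source", "target"))
    stopf("manifest %s: role must be a single value in {source, target}, found: %s",
          path, paste(roles, collapse = ", "))
  if (!is.null(validate_root)) {
    has_path <- !is.na(df$path) & df$path != "NA" & nzchar(df$path)
    missing <- df$id[has_path][!file.exists(file.path(validate_root, df$path[has_path]))]
    if (length(missing))
      stopf("manifest %s: missing files for id(s): %s",
            path, paste(missing, collapse = ", "))
  }
  classes <- sort(unique(df$class))
  counts <- vapply(classes, function(cl) sum(df$class == cl), integer(1))
  structure(
    list(role = roles, classes = classes, counts = counts, entries = df),
    class = "collection_manifest"
  )
}

#' @export
print.collection_manifest <- function(x, ...) {
  cat(sprintf("<collection_manifest> role=%s, %d classes, %d records\n",
              x$role, length(x$classes), nrow(x$entries)))
  invisible(x)
}

#' Check that two collections have disjoint class sets
#' @param a,b `image_collection` objects (typically source and target).
#' @return `TRUE` invisibly; errors if classes overlap.
#' @export
assert_disjoint_classes <- function(a, b) {
  common <- intersect(a$classes, b$classes)
  if (length(common))
    stopf("source/target class sets overlap: %s", paste(common, collapse = ", "))
  invisible(TRUE)
}

#' Stack a set of records into a (H, W, B, C) batch array
#' @noRd
stack_pixels <- function(records, idx = seq_along(records)) {
  n <- length(idx)
  d <- dim(records[[idx[1]]]$pixels)
  x <- array(0, c(d[1], d[2], n, d[3]))
  for (j in seq_len(n)) x[, , j, ] <- records[[idx[j]]]$pixels
  x
}
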