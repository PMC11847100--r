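# Manifest-driven image loading, the three dataset-balancing augmentation
# operators (flip left, flip right, rotate 90), and resizing to the network
# input shape.

#' Read a dataset manifest
#'
#' A manifest is a CSV with header `path,label,split` (`split` is `train` or
#' `test`); paths are relative to the manifest's directory.
#'
#' @param path Path to the CSV file.
#' @param check_paths Verify that every referenced image exists.
#' @return A `data.frame` with attributes `dir` and `class_names`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "label", "split")
  if (!all(need %in% names(m)))
    stop("manifest must have columns path,label,split", call. = FALSE)
  if (!all(m$split %in% c("train", "test")))
    stop("split must be 'train' or 'test'", call. = FALSE)
  dir <- dirname(path)
  if (check_paths) {
    missing <- !file.exists(file.path(dir, m$path))
    if (any(missing))
      stop(sprintf("%d manifest path(s) missing, e.g. %s",
                   sum(missing), m$path[which(missing)[1]]), call. = FALSE)
  }
  attr(m, "dir") <- dir
  attr(m, "class_names") <- sort(unique(m$label))
  m
}

#' Write a dataset manifest
#' @param manifest Manifest `data.frame`.
#' @param path Output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[c("path", "label", "split")], path, row.names = FALSE)
  invisible(path)
}

.check_image3d <- function(image, op) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop(sprintf("%s: expected an (H, W, 3) image array", op), call. = FALSE)
}

#' Augmentation operators
#'
#' The three dataset-balancing operators. Each is a bijection on the pixel
#' grid, so the multiset of pixel values is preserved and class identity is
#' untouched. `flip_left()` mirrors horizontally (output `(r, c)` = input
#' `(r, W-1-c)` in 0-based terms), `flip_right()` mirrors vertically, and
#' `rotate90()` rotates 90 degrees counter-clockwise (an `(H, W, 3)` image
#' becomes `(W, H, 3)`).
#'
#' @param image An `(H, W, 3)` numeric array.
#' @return The transformed image array.
#' @export
flip_left <- function(image) {
  .check_image3d(image, "flip_left")
  image[, dim(image)[2]:1, , drop = FALSE]
}

#' @rdname flip_left
#' @export
flip_right <- function(image) {
  .check_image3d(image, "flip_right")
  image[dim(image)[1]:1, , , drop = FALSE]
}

#' @rdname flip_left
#' @export
rotate90 <- function(image) {
  .check_image3d(image, "rotate90")
  out <- aperm(image, c(2, 1, 3))
  out[dim(out)[1]:1, , , drop = FALSE]
}

# the dihedral augmentation vocabulary: the three primitive ops, then their
# compositions, giving 7 distinct non-identity grid bijections
.aug_ops <- list(
  flip_left = flip_left,
  flip_right = flip_right,
  rotate90 = rotate90,
  flip_left_rotate90 = function(x) flip_left(rotate90(x)),
  flip_right_rotate90 = function(x) flip_right(rotate90(x)),
  rotate180 = function(x) flip_left(flip_right(x)),
  rotate270 = function(x) rotate90(rotate90(rotate90(x)))
)

#' Augment a dataset until every class reaches a target size
#'
#' Originals are always retained; each class with fewer than
#' `target_per_class` records is topped up with augmented copies that cycle
#' deterministically (given `seed`) through the three primitive operators and
#' then their compositions, over the class's source images. If a class needs
#' more copies than there are distinct (source, operator) pairs, sampling
#' continues with repetition after a warning. Augmented images are written
#' under `out_dir` and inherit the label and split of their source record.
#'
#' @param manifest Manifest `data.frame` (with `dir` attribute).
#' @param target_per_class Desired records per class.
#' @param seed Integer seed controlling source order.
#' @param out_subdir Subdirectory of the manifest directory receiving the
#'   augmented images (default `"augmented"`).
#' @param split Restrict augmentation to records of this split (default
#'   `"train"`); other splits pass through untouched. Use `NULL` to augment
#'   across all records.
#' @param minority_only Allow `target_per_class` below the largest class
#'   size; only smaller classes are then upsampled. Without this flag a
#'   too-small target is an error.
#' @return The enlarged manifest.
#' @export
augment_to_target <- function(manifest, target_per_class, seed = 1L,
                              out_subdir = "augmented", split = "train",
                              minority_only = FALSE) {
  dir <- attr(manifest, "dir")
  if (is.null(dir)) stop("manifest lacks a 'dir' attribute", call. = FALSE)
  out_dir <- file.path(dir, out_subdir)
  pool <- if (is.null(split)) manifest else manifest[manifest$split == split, ]
  sizes <- table(pool$label)
  if (target_per_class < max(sizes) && !minority_only)
    stop(sprintf(
      "target_per_class (%d) below largest class (%d); set minority_only = TRUE to upsample only smaller classes",
      target_per_class, max(sizes)), call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  new_rows <- list()
  for (lab in names(sizes)) {
    src <- pool[pool$label == lab, ]
    m_extra <- target_per_class - nrow(src)
    if (m_extra <= 0) next
    n <- nrow(src)
    src <- src[sample.int(n), ]                 # seeded source order
    n_ops <- length(.aug_ops)
    if (m_extra > n * n_ops) {
      warning(sprintf(
        "class %s: %d augmented records requested but only %d distinct (source, op) pairs; sampling with repetition",
        lab, m_extra, n * n_ops))
    }
    adir <- file.path(out_dir, lab)
    dir.create(adir, showWarnings = FALSE)
    for (i in seq_len(m_extra)) {
      j <- (i - 1L) %% (n * n_ops)
      op_idx <- j %% n_ops + 1L                 # ops cycle fastest
      src_idx <- j %/% n_ops + 1L
      img <- load_image(file.path(dir, src$path[src_idx]))
      out <- .aug_ops[[op_idx]](img)
      rel <- file.path(out_subdir, lab,
                       sprintf("aug_%04d_%s.png", i, names(.aug_ops)[op_idx]))
      png::writePNG(out, file.path(dir, rel))
      new_rows[[length(new_rows) + 1L]] <-
        data.frame(path = rel, label = lab, split = src$split[src_idx])
    }
  }
  out <- rbind(manifest[c("path", "label", "split")], do.call(rbind, new_rows))
  attr(out, "dir") <- dir
  attr(out, "class_names") <- attr(manifest, "class_names")
  out
}

#' Load a single image
#'
#' Reads PNG (or JPEG when the jpeg package is available), drops any alpha
#' channel, and returns values in `[0, 1]`.
#'
#' @param path Image file path.
#' @return `(H, W, 3)` array (grayscale images come back as `(H, W)` and are
#'   expanded by [resize_to_input()]).
#' @export
load_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("JPEG input needs the 'jpeg' package", call. = FALSE)
    jpeg::readJPEG(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  img
}

#' Resize an image to the network input shape
#'
#' Bilinear resize to `size x size x 3` with values in `[0, 1]`. Grayscale
#' input is replicated across the three channels with a warning. Inputs
#' already at the target size pass through numerically unchanged.
#'
#' @param image `(H, W, 3)` or `(H, W)` numeric array.
#' @param size Target spatial size (default 224, the network input).
#' @return `(size, size, 3)` array.
#' @export
resize_to_input <- function(image, size = 224L) {
  if (is.matrix(image) || (length(dim(image)) == 3L && dim(image)[3] == 1L)) {
    warning("grayscale input replicated to 3 channels")
    image <- array(rep(as.vector(image[, , drop = TRUE]), 3),
                   dim = c(dim(image)[1], dim(image)[2], 3))
  }
  .check_image3d(image, "resize_to_input")
  if (max(image) > 1 + 1e-8) image <- image / 255
  d <- dim(image)
  if (d[1] == size && d[2] == size) return(image)
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(image, colormode = "Color"),
                                            w = size, h = size, filter = "bilinear"))
  dim(out) <- c(size, size, 3L)
  pmin(pmax(out, 0), 1)
}

#' Load all images referenced by a manifest as a batch
#'
#' @param manifest Manifest `data.frame` with `dir` attribute.
#' @param split Optional split filter (`"train"` / `"test"`).
#' @param input_size Spatial size every image is resized to.
#' @return List with `x` (`(S, S, 3, N)` array), `labels` (factor over the
#'   manifest's class vocabulary) and `rows` (the manifest rows used).
#' @export
load_images <- function(manifest, split = NULL, input_size = 224L) {
  dir <- attr(manifest, "dir")
  rows <- if (is.null(split)) manifest else manifest[manifest$split == split, ]
  if (!nrow(rows))
    stop(if (is.null(split)) "empty manifest"
         else sprintf("no records in the '%s' split", split), call. = FALSE)
  x <- array(NA_real_, dim = c(input_size, input_size, 3L, nrow(rows)))
  for (i in seq_len(nrow(rows)))
    x[, , , i] <- resize_to_input(load_image(file.path(dir, rows$path[i])), input_size)
  labels <- factor(rows$label, levels = attr(manifest, "class_names"))
  list(x = x, labels = labels, rows = rows)
}

#' Stack a list of images into a batch array
#' @param images List of `(H, W, 3)` arrays.
#' @param size Target spatial size.
#' @return `(size, size, 3, N)` array.
#' @export
stack_images <- function(images, size = 224L) {
  x <- array(NA_real_, dim = c(size, size, 3L, length(images)))
  for (i in seq_along(images)) x[, , , i] <- resize_to_input(images[[i]], size)
  x
}
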