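# Synthetic leaf-like images and planted-signal feature tables. These are the
# package's stand-in for a real multi-class plant-image collection: every
# downstream stage (augmentation, CNN training, fusion, selection, evaluation,
# Grad-CAM) is exercisable with no external download.

#' Describe one synthetic leaf class
#'
#' A class is a point in a small generative parameter space: silhouette
#' elongation, margin serration, vein orientation, hue, and texture noise.
#' Silhouettes are a parametric polar curve (an ellipse modulated by a
#' sinusoidal serration term), drawn over a textured noise background so that
#' figure/ground is meaningful for Grad-CAM.
#'
#' @param class_id Integer class label.
#' @param aspect_ratio Silhouette elongation (> 0, unitless).
#' @param serration_freq Margin oscillations per perimeter (>= 0).
#' @param vein_angle Vein orientation in degrees.
#' @param hue Leaf hue in degrees, `[0, 360)`.
#' @param texture_noise_sd Pixel-intensity noise inside the leaf (>= 0).
#' @return A `leaf_class_spec` list.
#' @export
leaf_class_spec <- function(class_id, aspect_ratio = 1.8, serration_freq = 6,
                            vein_angle = 60, hue = 120, texture_noise_sd = 0.04) {
  stopifnot(aspect_ratio > 0, serration_freq >= 0, texture_noise_sd >= 0)
  structure(list(class_id = as.integer(class_id),
                 aspect_ratio = aspect_ratio, serration_freq = serration_freq,
                 vein_angle = vein_angle %% 180, hue = hue %% 360,
                 texture_noise_sd = texture_noise_sd),
            class = "leaf_class_spec")
}

#' Default leaf class specs
#'
#' A deterministic grid of `n_classes` specs spread across the generative
#' parameter space. `separation` scales how far apart the class parameters
#' sit around their common center: 0 collapses all classes onto one spec,
#' 1 is the default spread, larger values increase inter-class contrast.
#'
#' @param n_classes Number of classes (default 30, mirroring the study
#'   dataset's class count).
#' @param separation Non-negative spread multiplier.
#' @return List of [leaf_class_spec] objects.
#' @export
default_leaf_specs <- function(n_classes = 30L, separation = 1) {
  stopifnot(n_classes >= 1L, separation >= 0)
  k <- seq_len(n_classes)
  ctr <- (n_classes + 1) / 2
  dev <- (k - ctr) / max(ctr - 1, 1)       # in [-1, 1]
  lapply(k, function(i) {
    leaf_class_spec(
      class_id = i,
      aspect_ratio = max(2.1 + 1.4 * dev[i] * separation, 0.3),
      serration_freq = max(6 + 5.5 * dev[i] * separation, 0),
      vein_angle = 90 + 80 * dev[i] * separation,
      hue = 110 + 85 * dev[i] * separation,
      texture_noise_sd = max(0.05 + 0.025 * dev[i] * separation, 0.005))
  })
}

# vectorized numeric HSV (h in degrees) -> RGB in [0,1]
.hsv2rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0 | i == 5, v, ifelse(i == 1, q, ifelse(i == 4, t, p)))
  g <- ifelse(i == 1 | i == 2, v, ifelse(i == 0, t, ifelse(i == 3, q, p)))
  b <- ifelse(i == 3 | i == 4, v, ifelse(i == 2, t, ifelse(i == 5, q, p)))
  list(r = r, g = g, b = b)
}

# Render one leaf image; returns list(image = (S,S,3) array in [0,1],
# mask = logical S x S foreground). Consumes the current RNG stream.
render_leaf <- function(spec, size) {
  S <- as.integer(size)
  ax <- matrix(rep(seq(-1, 1, length.out = S), S), S, S)        # x: columns
  ay <- matrix(rep(seq(-1, 1, length.out = S), each = S), S, S) # y: rows
  # per-image jitter: small shift, rotation, scale
  cx <- stats::runif(1, -0.08, 0.08); cy <- stats::runif(1, -0.08, 0.08)
  rot <- stats::runif(1, -0.3, 0.3)
  scl <- stats::runif(1, 0.85, 1.05)
  xr <- (ax - cx) * cos(rot) + (ay - cy) * sin(rot)
  yr <- -(ax - cx) * sin(rot) + (ay - cy) * cos(rot)
  a <- 0.62 * scl
  b <- a / spec$aspect_ratio
  u <- xr / a; v <- yr / b
  rho <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  mask <- rho <= 1 + 0.1 * sin(spec$serration_freq * theta)

  # textured background: coarse blotches plus pixel noise, dull brown-gray
  ph1 <- stats::runif(2, 0, 2 * pi)
  tex <- 0.06 * sin(5.3 * ax + ph1[1]) * cos(4.1 * ay + ph1[2]) +
    matrix(stats::rnorm(S * S, sd = 0.09), S, S)
  bgv <- pmin(pmax(0.45 + tex, 0), 1)
  bg <- .hsv2rgb(35 + 20 * tex, 0.25, bgv)

  # leaf surface: hue with veins (stripes at vein_angle) and a darker midrib
  va <- spec$vein_angle * pi / 180
  tco <- xr * cos(va) + yr * sin(va)
  veins <- 0.1 * sin(2 * pi * 5 * tco)
  midrib <- -0.18 * exp(-(yr / (0.06 * b / 0.3))^2)
  val <- 0.55 + veins + midrib +
    matrix(stats::rnorm(S * S, sd = spec$texture_noise_sd), S, S)
  val <- pmin(pmax(val, 0), 1)
  hue <- spec$hue + stats::rnorm(1, sd = 3)
  fg <- .hsv2rgb(hue, 0.62, val)

  img <- array(0, dim = c(S, S, 3))
  img[, , 1] <- ifelse(mask, fg$r, bg$r)
  img[, , 2] <- ifelse(mask, fg$g, bg$g)
  img[, , 3] <- ifelse(mask, fg$b, bg$b)
  list(image = img, mask = mask)
}

#' Generate a labeled synthetic leaf-image dataset
#'
#' Writes 8-bit RGB PNGs (one directory per class) plus a CSV manifest with
#' header `path,label,split`. The split is a stratified half/half
#' train/test partition. Pixel content is a pure function of `seed`: the same
#' call twice produces byte-identical files.
#'
#' @param specs List of [leaf_class_spec] objects.
#' @param per_class_counts Integer vector aligned with `specs`.
#' @param dir Output directory (created if needed).
#' @param image_size Square image size in pixels (>= 32).
#' @param seed Integer seed.
#' @param keep_masks If `TRUE`, foreground masks are also written as
#'   grayscale PNGs next to each image (suffix `_mask`).
#' @param train_fraction Fraction of each class assigned to the train split.
#' @return The manifest `data.frame` (`path`, `label`, `split`), invisibly
#'   also written to `file.path(dir, "manifest.csv")`. Paths are relative to
#'   `dir`; the manifest carries `dir` and the class vocabulary as attributes.
#' @export
generate_leaf_dataset <- function(specs, per_class_counts, dir,
                                  image_size = 64L, seed = 1L,
                                  keep_masks = FALSE, train_fraction = 0.5) {
  if (!length(specs)) stop("empty specs", call. = FALSE)
  if (length(per_class_counts) != length(specs))
    stop("per_class_counts must align with specs", call. = FALSE)
  if (image_size < 32L) stop("image_size must be >= 32", call. = FALSE)
  ids <- vapply(specs, `[[`, integer(1), "class_id")
  if (anyDuplicated(ids)) stop("duplicate class_id in specs", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop(sprintf("output directory '%s' is not writable", dir), call. = FALSE)

  set.seed(seed)
  rows <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    label <- sprintf("class_%02d", sp$class_id)
    cdir <- file.path(dir, label)
    dir.create(cdir, showWarnings = FALSE)
    n <- per_class_counts[k]
    n_train <- ceiling(n * train_fraction)
    split <- rep("test", n)
    split[sample.int(n, n_train)] <- "train"
    for (i in seq_len(n)) {
      rl <- render_leaf(sp, image_size)
      rel <- file.path(label, sprintf("img_%04d.png", i))
      png::writePNG(rl$image, file.path(dir, rel))
      if (keep_masks)
        png::writePNG(rl$mask * 1, file.path(dir, sub("\\.png$", "_mask.png", rel)))
      rows[[length(rows) + 1L]] <- data.frame(path = rel, label = label,
                                              split = split[i])
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  attr(manifest, "dir") <- dir
  attr(manifest, "class_names") <- sort(unique(manifest$label))
  invisible(manifest)
}

#' Describe a planted-signal feature table
#'
#' @param n_samples Number of rows.
#' @param n_features Number of columns.
#' @param informative_idx 1-based indices of the informative columns.
#' @param effect_size Standardized class-conditional mean shift (adjacent
#'   classes differ by `effect_size * noise_sd` on informative columns).
#' @param noise_sd Noise standard deviation for all columns.
#' @param seed Integer seed; the table is a pure function of it.
#' @return A `planted_feature_spec` list.
#' @export
planted_feature_spec <- function(n_samples = 300L, n_features = 50L,
                                 informative_idx = 1:5, effect_size = 3,
                                 noise_sd = 1, seed = 1L) {
  stopifnot(effect_size >= 0, noise_sd > 0)
  informative_idx <- as.integer(informative_idx)
  if (any(informative_idx < 1L) || any(informative_idx > n_features))
    stop("informative_idx out of range", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 informative_idx = informative_idx,
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "planted_feature_spec")
}

#' Generate a feature table with planted informative columns
#'
#' Rows are assigned to `n_classes` balanced classes. All columns are i.i.d.
#' Gaussian noise; on the informative columns, class `c` additionally receives
#' a mean shift of `effect_size * noise_sd * (c - 1)`, so informative columns
#' carry class signal and the rest are exchangeable noise. With
#' `effect_size = 0` every column is exchangeable.
#'
#' @param spec A [planted_feature_spec].
#' @param n_classes Number of classes (>= 2).
#' @return A [feature_matrix] with planted indices recorded in
#'   `attr(, "informative_idx")`.
#' @export
generate_feature_table <- function(spec, n_classes = 5L) {
  stopifnot(inherits(spec, "planted_feature_spec"))
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  if (spec$n_samples < n_classes) stop("need n_samples >= n_classes", call. = FALSE)
  set.seed(spec$seed)
  n <- spec$n_samples; d <- spec$n_features
  y <- factor(sprintf("c%02d", rep_len(seq_len(n_classes), n)))
  x <- matrix(stats::rnorm(n * d, sd = spec$noise_sd), n, d)
  shift <- spec$effect_size * spec$noise_sd * (as.integer(y) - 1)
  for (j in spec$informative_idx) x[, j] <- x[, j] + shift
  fm <- feature_matrix(x, labels = y, origin = "planted")
  attr(fm, "informative_idx") <- spec$informative_idx
  fm
}
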