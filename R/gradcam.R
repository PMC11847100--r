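# Grad-CAM: gradient-weighted class activation maps at the last convolutional
# layer before the global average pool.

#' Compute a Grad-CAM heatmap
#'
#' For the requested class, channel weights are the spatial mean of the
#' gradient of the class score (the pre-softmax logit) with respect to the
#' target layer's activations; the map is the ReLU of the weighted activation
#' sum, min-max normalized to `[0, 1]` and bilinearly upsampled to the input
#' size. The target layer defaults to the last convolutional node before the
#' global average pool.
#'
#' @param net A trained `medleaf_net`.
#' @param image `(H, W, 3)` array (resized to the network input if needed).
#' @param target_class Class label (matching `net$classes`) or class index.
#' @param target_layer Optional node name or id overriding the default.
#' @return A `gradcam_heatmap`: `values` (input-sized matrix in `[0, 1]`),
#'   `target_class`, `target_layer`. A map that is zero everywhere (zero
#'   gradient) is returned as-is with a warning.
#' @export
compute_gradcam <- function(net, image, target_class, target_layer = NULL) {
  stopifnot(inherits(net, "medleaf_net"))
  size <- net$input_size
  x <- stack_images(list(image), size)
  tgt <- if (is.null(target_layer)) .last_conv_before_gap(net$graph)
         else .resolve_node(net$graph, target_layer)
  cls <- if (is.character(target_class)) {
    if (is.null(net$classes) || !(target_class %in% net$classes))
      stop("unknown class label", call. = FALSE)
    match(target_class, net$classes)
  } else as.integer(target_class)
  if (cls < 1L || cls > net$graph$n_classes) stop("class index out of range", call. = FALSE)

  kinds <- vapply(net$graph$nodes, `[[`, character(1), "kind")
  fc_id <- which(kinds == "fc")[1]
  fw <- net_forward(net, x, training = FALSE, upto = fc_id)
  dfc <- matrix(0, net$graph$n_classes, 1)
  dfc[cls, 1] <- 1
  bw <- net_backward(net, fw, dfc, training = FALSE)
  act <- fw$acts[[tgt]]
  grad <- bw$agrads[[tgt]]
  if (is.null(grad)) stop("target layer does not feed the class score", call. = FALSE)
  d <- dim(act)
  # channel weights: spatial mean of the gradient; map: ReLU of weighted sum
  w <- colMeans(matrix(grad[, , , 1], nrow = d[1] * d[2]))
  map <- matrix(matrix(act[, , , 1], nrow = d[1] * d[2]) %*% w, d[1], d[2])
  map <- pmax(map, 0)
  if (max(map) == 0) {
    warning("zero gradient everywhere: all-zero heatmap")
  } else {
    map <- (map - min(map)) / (max(map) - min(map))
  }
  up <- EBImage::imageData(EBImage::resize(EBImage::Image(map), w = size,
                                           h = size, filter = "bilinear"))
  up <- matrix(pmin(pmax(up, 0), 1), size, size)
  if (max(up) > 0) up <- up / max(up)   # interpolation must not break max = 1
  structure(list(values = up, target_class = target_class,
                 target_layer = net$graph$nodes[[tgt]]$name),
            class = "gradcam_heatmap")
}

#' Overlay a heatmap on its image
#'
#' Blends the heatmap (warm/brown tones for high relevance) over the RGB
#' image and optionally writes a PNG.
#'
#' @param heatmap A `gradcam_heatmap`.
#' @param image The `(H, W, 3)` image it was computed from.
#' @param path Optional PNG output path.
#' @param alpha Blend weight of the heatmap.
#' @return The blended `(H, W, 3)` array, invisibly.
#' @export
gradcam_overlay <- function(heatmap, image, path = NULL, alpha = 0.45) {
  size <- nrow(heatmap$values)
  img <- resize_to_input(image, size)
  ramp <- grDevices::colorRamp(c("#2b2b20", "#8a5a2b", "#c87f2f", "#f0a830"))
  cols <- ramp(as.vector(heatmap$values)) / 255
  hm <- array(cols, dim = c(size, size, 3))
  out <- (1 - alpha) * img + alpha * hm
  if (!is.null(path)) png::writePNG(out, path)
  invisible(out)
}

#' @export
print.gradcam_heatmap <- function(x, ...) {
  cat(sprintf("<gradcam_heatmap> %dx%d, class %s, layer %s, max %.3f\n",
              nrow(x$values), ncol(x$values), as.character(x$target_class),
              x$target_layer, max(x$values)))
  invisible(x)
}
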