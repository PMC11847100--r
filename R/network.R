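# Realized networks: weights attached to an arch_graph, forward/backward
# passes, and deep-feature extraction at the global average pool.
#
# Activation layout is (H, W, C, N) throughout; vector-valued nodes (gap, fc,
# softmax) carry (d, N) matrices.

#' Initialize network weights
#'
#' He-normal initialization for conv/grouped-conv/fc weights, zero biases,
#' unit-scale/zero-offset batch norm with zero-mean/unit-variance running
#' statistics.
#'
#' @param graph A validated `arch_graph`.
#' @param seed Integer seed; initialization is a pure function of it.
#' @param input_size Spatial input size the network will be run at.
#' @return A `medleaf_net` object (untrained).
#' @export
init_network <- function(graph, seed = 1L, input_size = 224L) {
  validate_graph(graph, input_size)
  shp <- infer_shapes(graph, input_size)
  set.seed(seed)
  weights <- vector("list", length(graph$nodes))
  for (nd in graph$nodes) {
    weights[nd$id] <- list(switch(nd$kind,
      conv = ,
      grouped_conv = {
        cin_g <- shp[[nd$inputs[1]]][3] / nd$groups
        fan_in <- prod(nd$kernel) * cin_g
        w <- array(stats::rnorm(prod(nd$kernel) * cin_g * nd$depth,
                                sd = sqrt(2 / fan_in)),
                   dim = c(nd$kernel, cin_g, nd$depth))
        list(w = w, b = numeric(nd$depth))
      },
      batchnorm = {
        s <- shp[[nd$inputs[1]]]
        C <- s[length(s)]
        list(gamma = rep(1, C), beta = numeric(C),
             run_mean = numeric(C), run_var = rep(1, C))
      },
      fc = {
        din <- shp[[nd$inputs[1]]]
        list(w = matrix(stats::rnorm(din * graph$n_classes, sd = sqrt(2 / din)),
                        graph$n_classes, din),
             b = numeric(graph$n_classes))
      },
      NULL))
  }
  structure(list(graph = graph, weights = weights, input_size = as.integer(input_size),
                 classes = NULL, trace = NULL, trained = FALSE),
            class = "medleaf_net")
}

.bn_momentum <- 0.1
.bn_eps <- 1e-5

# channel-wise moments of an (H, W, C, N) array
.channel_moments <- function(x) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  mu <- colMeans(xm)
  v <- colMeans(xm * xm) - mu^2
  list(mean = mu, var = pmax(v, 0))
}

.bcast_channel <- function(vals, d) {
  # expand a per-channel vector to an (H, W, C, N) array
  aperm(array(vals, dim = c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
}

#' Forward pass through a network
#'
#' @param net A `medleaf_net`.
#' @param x Input batch, array `(H, W, 3, N)`.
#' @param training Logical; `TRUE` uses batch statistics in batch norm (and
#'   updates running statistics in the returned cache), `FALSE` uses running
#'   statistics.
#' @param upto Optional node name or id at which to stop.
#' @return A list with `acts` (per-node activations) and `cache` (batch-norm
#'   intermediates needed for the backward pass).
#' @export
net_forward <- function(net, x, training = FALSE, upto = NULL) {
  g <- net$graph
  acts <- vector("list", length(g$nodes))
  cache <- vector("list", length(g$nodes))
  stop_id <- .resolve_node(g, upto)
  for (nd in g$nodes) {
    W <- net$weights[[nd$id]]
    acts[[nd$id]] <- switch(nd$kind,
      input = {
        if (length(dim(x)) != 4L || dim(x)[3] != 3L)
          stop("input must be an (H, W, 3, N) array", call. = FALSE)
        x
      },
      conv = ,
      grouped_conv = .conv2d_fwd(acts[[nd$inputs[1]]], W$w, W$b,
                                 nd$stride, nd$padding == "same", nd$groups),
      batchnorm = {
        a <- acts[[nd$inputs[1]]]
        d <- dim(a)
        if (training) {
          mom <- .channel_moments(a)
          mu <- mom$mean; v <- mom$var
        } else {
          mu <- W$run_mean; v <- W$run_var
        }
        invstd <- 1 / sqrt(v + .bn_eps)
        xhat <- (a - .bcast_channel(mu, d)) * .bcast_channel(invstd, d)
        cache[[nd$id]] <- list(xhat = xhat, invstd = invstd,
                               batch_mean = mu, batch_var = v)
        xhat * .bcast_channel(W$gamma, d) + .bcast_channel(W$beta, d)
      },
      relu = pmax(acts[[nd$inputs[1]]], 0),
      add = Reduce(`+`, acts[nd$inputs]),
      gap = {
        a <- acts[[nd$inputs[1]]]
        d <- dim(a)
        matrix(colMeans(matrix(a, nrow = d[1] * d[2])), nrow = d[3])
      },
      fc = W$w %*% acts[[nd$inputs[1]]] + W$b,
      softmax = {
        z <- acts[[nd$inputs[1]]]
        z <- sweep(z, 2, apply(z, 2, max))
        e <- exp(z)
        sweep(e, 2, colSums(e), "/")
      },
      classification = acts[[nd$inputs[1]]]
    )
    if (!is.null(stop_id) && nd$id == stop_id) break
  }
  list(acts = acts, cache = cache)
}

.resolve_node <- function(graph, node) {
  if (is.null(node)) return(NULL)
  if (is.numeric(node)) return(as.integer(node))
  nm <- vapply(graph$nodes, `[[`, character(1), "name")
  id <- which(nm == node)
  if (!length(id)) stop(sprintf("no node named '%s'", node), call. = FALSE)
  id
}

# id of the gap node / of the last conv-like node before it
.gap_node <- function(graph) {
  kinds <- vapply(graph$nodes, `[[`, character(1), "kind")
  which(kinds == "gap")[1]
}

.last_conv_before_gap <- function(graph) {
  kinds <- vapply(graph$nodes, `[[`, character(1), "kind")
  conv_ids <- which(kinds %in% c("conv", "grouped_conv"))
  max(conv_ids[conv_ids < .gap_node(graph)])
}

#' Backward pass from a gradient at the FC output
#'
#' Propagates `dfc` (gradient of a scalar objective with respect to the FC
#' logits, shape `K x N`) back through the graph, returning weight gradients
#' and per-node activation gradients (needed for Grad-CAM).
#'
#' @param training Logical; matches the mode of the forward pass that produced
#'   `fwd` (batch-norm backward differs between the two).
#' @export
net_backward <- function(net, fwd, dfc, training = TRUE, need_input_grad = FALSE) {
  g <- net$graph
  acts <- fwd$acts
  grads <- vector("list", length(g$nodes))   # d objective / d node output
  wgrads <- vector("list", length(g$nodes))
  kinds <- vapply(g$nodes, `[[`, character(1), "kind")
  fc_id <- which(kinds == "fc")[1]
  grads[[fc_id]] <- dfc
  for (id in rev(seq_len(fc_id))) {
    nd <- g$nodes[[id]]
    gy <- grads[[id]]
    if (is.null(gy)) next
    W <- net$weights[[id]]
    if (nd$kind == "input") next
    if (nd$kind == "fc") {
      a_in <- acts[[nd$inputs[1]]]
      wgrads[[id]] <- list(w = gy %*% t(a_in), b = rowSums(gy))
      gx <- t(W$w) %*% gy
      .acc(grads, nd$inputs[1]) <- gx
    } else if (nd$kind == "gap") {
      a_in <- acts[[nd$inputs[1]]]
      d <- dim(a_in)
      gx <- aperm(array(t(gy) , dim = c(d[4], d[3], d[1], d[2])), c(3, 4, 2, 1)) /
        (d[1] * d[2])
      .acc(grads, nd$inputs[1]) <- gx
    } else if (nd$kind == "relu") {
      .acc(grads, nd$inputs[1]) <- gy * (acts[[id]] > 0)
    } else if (nd$kind == "add") {
      for (i in nd$inputs) .acc(grads, i) <- gy
    } else if (nd$kind == "batchnorm") {
      cc <- fwd$cache[[id]]
      d <- dim(gy)
      nch <- d[3]
      gym <- matrix(aperm(gy, c(1, 2, 4, 3)), ncol = nch)
      xhm <- matrix(aperm(cc$xhat, c(1, 2, 4, 3)), ncol = nch)
      dgamma <- colSums(gym * xhm)
      dbeta <- colSums(gym)
      wgrads[[id]] <- list(gamma = dgamma, beta = dbeta)
      if (training) {
        m <- nrow(gym)
        dxhat <- gym * rep(W$gamma, each = m)
        dxm <- (dxhat - rep(colMeans(dxhat), each = m) -
                  xhm * rep(colMeans(dxhat * xhm), each = m)) *
          rep(cc$invstd, each = m)
      } else {
        dxm <- gym * rep(W$gamma * cc$invstd, each = m <- nrow(gym))
      }
      gx <- aperm(array(dxm, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      .acc(grads, nd$inputs[1]) <- gx
    } else if (nd$kind %in% c("conv", "grouped_conv")) {
      a_in <- acts[[nd$inputs[1]]]
      need_dx <- nd$inputs[1] > 1L || need_input_grad
      bw <- .conv2d_bwd(a_in, W$w, gy, nd$stride, nd$padding == "same",
                        nd$groups, need_dx)
      wgrads[[id]] <- list(w = bw$dw, b = bw$db)
      if (need_dx) .acc(grads, nd$inputs[1]) <- bw$dx
    }
  }
  list(wgrads = wgrads, agrads = grads)
}

# accumulate into a grads slot (sum over fan-out)
`.acc<-` <- function(grads, id, value) {
  grads[[id]] <- if (is.null(grads[[id]])) value else grads[[id]] + value
  grads
}

# update batch-norm running statistics from a training-mode forward cache
.update_bn_running <- function(net, cache) {
  for (id in seq_along(cache)) {
    cc <- cache[[id]]
    if (is.null(cc) || is.null(cc$batch_mean)) next
    W <- net$weights[[id]]
    net$weights[[id]]$run_mean <- (1 - .bn_momentum) * W$run_mean +
      .bn_momentum * cc$batch_mean
    net$weights[[id]]$run_var <- (1 - .bn_momentum) * W$run_var +
      .bn_momentum * cc$batch_var
  }
  net
}

#' Extract deep features at the global average pool
#'
#' Runs the batch through the network in inference mode and returns the
#' activations of the global-average-pool node: one `feature_dim`-length deep
#' feature vector per image, in input order.
#'
#' @param net A `medleaf_net` (typically trained).
#' @param images Either an `(H, W, 3, N)` array or a list of `(H, W, 3)`
#'   images (resized to the network input size if needed).
#' @param labels Optional length-N labels attached to the rows.
#' @param batch_size Images per forward pass.
#' @return A [feature_matrix] of dimension `N x feature_dim`.
#' @export
extract_features <- function(net, images, labels = NULL, batch_size = 16L) {
  if (is.list(images))
    images <- stack_images(images, net$input_size)
  d <- dim(images)
  if (length(d) != 4L) stop("images must be an (H, W, 3, N) array", call. = FALSE)
  if (d[1] != net$input_size)
    stop(sprintf("image size %d does not match network input size %d",
                 d[1], net$input_size), call. = FALSE)
  N <- d[4]
  gap_id <- .gap_node(net$graph)
  out <- matrix(NA_real_, N, net$graph$feature_dim)
  for (start in seq(1, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, N)
    fw <- net_forward(net, images[, , , idx, drop = FALSE],
                      training = FALSE, upto = gap_id)
    out[idx, ] <- t(fw$acts[[gap_id]])
  }
  if (any(!is.finite(out))) stop("non-finite deep features", call. = FALSE)
  feature_matrix(out, labels = labels, origin = net$graph$name)
}

#' Predict class probabilities / labels
#'
#' @param object A trained `medleaf_net`.
#' @param images `(H, W, 3, N)` array or list of images.
#' @param type `"prob"` for the softmax matrix, `"class"` for labels.
#' @param ... Unused.
#' @export
predict.medleaf_net <- function(object, images, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.list(images)) images <- stack_images(images, object$input_size)
  kinds <- vapply(object$graph$nodes, `[[`, character(1), "kind")
  sm_id <- which(kinds == "softmax")[1]
  N <- dim(images)[4]
  probs <- matrix(NA_real_, object$graph$n_classes, N)
  for (start in seq(1, N, by = 16L)) {
    idx <- start:min(start + 15L, N)
    fw <- net_forward(object, images[, , , idx, drop = FALSE],
                      training = FALSE, upto = sm_id)
    probs[, idx] <- fw$acts[[sm_id]]
  }
  if (type == "prob") return(t(probs))
  cls <- apply(probs, 2, which.max)
  if (!is.null(object$classes)) object$classes[cls] else cls
}

#' @export
print.medleaf_net <- function(x, ...) {
  cat(sprintf("<medleaf_net '%s'> %s, input %dx%dx3\n", x$graph$name,
              if (isTRUE(x$trained)) "trained" else "untrained",
              x$input_size, x$input_size))
  print(x$graph)
  invisible(x)
}
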