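# CNN training: stochastic gradient descent with momentum (SGDM) on the
# softmax cross-entropy, at the study protocol's hyperparameters.

#' Training configuration
#'
#' Defaults follow the study protocol: SGDM optimizer, mini-batch 16,
#' learning rate 1e-4, 10 epochs. Momentum is 0.9 (the conventional SGDM
#' value; only the optimizer family is prescribed).
#'
#' @param optimizer Only `"sgdm"` is supported.
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param mini_batch Mini-batch size (>= 1).
#' @param learning_rate Per-step learning rate (> 0).
#' @param epochs Number of passes over the training split (>= 1).
#' @param seed Integer seed controlling initialization and batch order.
#' @return A `train_config` list.
#' @export
train_config <- function(optimizer = "sgdm", momentum = 0.9, mini_batch = 16L,
                         learning_rate = 1e-4, epochs = 10L, seed = 1L) {
  optimizer <- match.arg(optimizer, "sgdm")
  stopifnot(learning_rate > 0, epochs >= 1L, mini_batch >= 1L,
            momentum >= 0, momentum < 1)
  structure(list(optimizer = optimizer, momentum = momentum,
                 mini_batch = as.integer(mini_batch),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

.learnable_fields <- function(kind) {
  switch(kind, conv = , grouped_conv = , fc = c("w", "b"),
         batchnorm = c("gamma", "beta"), character(0))
}

#' Train a network on the train split of a manifest
#'
#' Runs mini-batch SGDM on the softmax cross-entropy. The loss/accuracy of
#' every step is recorded in the training trace; the epoch with the lowest
#' mean loss supplies the "best" checkpoint. Fully reproducible given
#' `config$seed`.
#'
#' @param graph An `arch_graph` (or an already-initialized `medleaf_net`
#'   whose weights are used as the starting point).
#' @param manifest Dataset manifest with a non-empty `train` split.
#' @param config A [train_config].
#' @param input_size Spatial size images are resized to (default 224).
#' @param out_dir Optional directory; when given, the final and best
#'   checkpoints (`.rds`) and the trace CSV are written there.
#' @param verbose Print per-epoch progress.
#' @return A trained `medleaf_net` with elements `trace` (data.frame: epoch,
#'   step, loss, acc), `best_weights`, and `classes`.
#' @export
train_network <- function(graph, manifest, config = train_config(),
                          input_size = 224L, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  tr <- load_images(manifest, split = "train", input_size = input_size)
  if (!nrow(tr$rows)) stop("empty train split", call. = FALSE)
  net <- if (inherits(graph, "medleaf_net")) graph
         else init_network(graph, seed = config$seed, input_size = input_size)
  net$classes <- levels(tr$labels)
  K <- net$graph$n_classes
  if (nlevels(tr$labels) > K)
    stop("more classes in manifest than network outputs", call. = FALSE)
  y <- as.integer(tr$labels)
  N <- length(y)

  vel <- lapply(seq_along(net$weights), function(i) {
    fields <- .learnable_fields(net$graph$nodes[[i]]$kind)
    if (!length(fields)) return(NULL)
    stats::setNames(lapply(fields, function(f) net$weights[[i]][[f]] * 0), fields)
  })

  set.seed(config$seed + 1L)
  trace <- list()
  best <- list(loss = Inf, weights = NULL, epoch = NA_integer_)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(N)
    starts <- seq(1, N, by = config$mini_batch)
    epoch_losses <- numeric(0)
    for (si in seq_along(starts)) {
      idx <- ord[starts[si]:min(starts[si] + config$mini_batch - 1L, N)]
      xb <- tr$x[, , , idx, drop = FALSE]
      yb <- y[idx]
      fw <- net_forward(net, xb, training = TRUE)
      kinds <- vapply(net$graph$nodes, `[[`, character(1), "kind")
      p <- fw$acts[[which(kinds == "softmax")[1]]]
      nb <- length(idx)
      loss <- -mean(log(pmax(p[cbind(yb, seq_len(nb))], 1e-12)))
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d step %d; try a smaller learning rate",
                     epoch, si), call. = FALSE)
      acc <- mean(apply(p, 2, which.max) == yb)
      # d CE / d logits = (p - onehot) / batch size
      dfc <- p
      dfc[cbind(yb, seq_len(nb))] <- dfc[cbind(yb, seq_len(nb))] - 1
      dfc <- dfc / nb
      bw <- net_backward(net, fw, dfc, training = TRUE)
      for (i in seq_along(vel)) {
        if (is.null(vel[[i]]) || is.null(bw$wgrads[[i]])) next
        for (f in names(vel[[i]])) {
          vel[[i]][[f]] <- config$momentum * vel[[i]][[f]] -
            config$learning_rate * bw$wgrads[[i]][[f]]
          net$weights[[i]][[f]] <- net$weights[[i]][[f]] + vel[[i]][[f]]
        }
      }
      net <- .update_bn_running(net, fw$cache)
      epoch_losses <- c(epoch_losses, loss)
      trace[[length(trace) + 1L]] <-
        data.frame(epoch = epoch, step = si, loss = loss, acc = acc)
    }
    mean_loss <- mean(epoch_losses)
    if (mean_loss < best$loss)
      best <- list(loss = mean_loss, weights = net$weights, epoch = epoch)
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f", epoch, config$epochs, mean_loss))
  }
  net$trace <- do.call(rbind, trace)
  net$best_weights <- best$weights
  net$best_epoch <- best$epoch
  net$config <- config
  net$trained <- TRUE
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(net, file.path(out_dir, paste0(net$graph$name, "_final.rds")))
    best_net <- net; best_net$weights <- best$weights
    saveRDS(best_net, file.path(out_dir, paste0(net$graph$name, "_best.rds")))
    utils::write.csv(net$trace, file.path(out_dir, paste0(net$graph$name, "_trace.csv")),
                     row.names = FALSE)
  }
  net
}
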