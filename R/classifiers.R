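# The five shallow neural-network classifier presets (narrow / medium / wide /
# bilayered / trilayered), a small deterministic MLP trainer for them, and the
# stratified k-fold cross-validated metric suite.

.preset_widths <- list(NNN = 10L, MNN = 25L, WNN = 100L,
                       BNN = c(10L, 10L), TNN = c(10L, 10L, 10L))

#' Shallow neural-network classifier presets
#'
#' The canonical narrow/medium/wide/bilayered/trilayered family: NNN `[10]`,
#' MNN `[25]`, WNN `[100]`, BNN `[10, 10]`, TNN `[10, 10, 10]` hidden ReLU
#' layers.
#'
#' @param name One of `"NNN"`, `"MNN"`, `"WNN"`, `"BNN"`, `"TNN"`.
#' @param max_epochs Full-batch training epochs.
#' @return A `classifier_preset` list.
#' @export
classifier_preset <- function(name = c("NNN", "MNN", "WNN", "BNN", "TNN"),
                              max_epochs = 300L) {
  name <- match.arg(name)
  structure(list(name = name, hidden = .preset_widths[[name]],
                 activation = "relu", max_epochs = as.integer(max_epochs)),
            class = "classifier_preset")
}

#' Fit a small multilayer perceptron
#'
#' Full-batch gradient descent with momentum on the softmax cross-entropy,
#' ReLU hidden layers, He initialization, inputs standardized column-wise.
#' Deterministic given `seed`.
#'
#' @param x Numeric matrix `n x d`.
#' @param y Labels (factor or coercible).
#' @param hidden Integer vector of hidden-layer widths.
#' @param max_epochs Training epochs.
#' @param lr Learning rate.
#' @param momentum Momentum coefficient.
#' @param seed Integer seed.
#' @return An `mlp_model`.
#' @export
mlp_fit <- function(x, y, hidden = 100L, max_epochs = 300L, lr = 0.05,
                    momentum = 0.9, seed = 1L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  if (K < 2L) stop("need at least two classes", call. = FALSE)
  n <- nrow(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  sizes <- c(ncol(x), hidden, K)
  L <- length(sizes) - 1L
  set.seed(seed)
  W <- lapply(seq_len(L), function(l)
    matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1]))
  B <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
  vW <- lapply(W, function(w) w * 0); vB <- lapply(B, function(b) b * 0)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), as.integer(y))] <- 1
  for (epoch in seq_len(max_epochs)) {
    A <- vector("list", L + 1L); A[[1]] <- xs
    for (l in seq_len(L)) {
      z <- A[[l]] %*% W[[l]] + rep(B[[l]], each = n)
      A[[l + 1]] <- if (l < L) pmax(z, 0) else z
    }
    z <- A[[L + 1]] - apply(A[[L + 1]], 1, max)
    P <- exp(z); P <- P / rowSums(P)
    delta <- (P - Y) / n
    for (l in rev(seq_len(L))) {
      gW <- crossprod(A[[l]], delta)
      gB <- colSums(delta)
      if (l > 1L) delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
      vW[[l]] <- momentum * vW[[l]] - lr * gW
      vB[[l]] <- momentum * vB[[l]] - lr * gB
      W[[l]] <- W[[l]] + vW[[l]]
      B[[l]] <- B[[l]] + vB[[l]]
    }
  }
  structure(list(W = W, B = B, center = ctr, scale = scl, classes = levels(y)),
            class = "mlp_model")
}

#' Predict with a fitted MLP
#' @param model An `mlp_model`.
#' @param x New data matrix.
#' @param type `"class"` or `"prob"`.
#' @return Factor of predicted labels, or a probability matrix.
#' @export
mlp_predict <- function(model, x, type = c("class", "prob")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  n <- nrow(x)
  a <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  L <- length(model$W)
  for (l in seq_len(L)) {
    a <- a %*% model$W[[l]] + rep(model$B[[l]], each = n)
    if (l < L) a <- pmax(a, 0)
  }
  p <- exp(a - apply(a, 1, max)); p <- p / rowSums(p)
  colnames(p) <- model$classes
  if (type == "prob") return(p)
  factor(model$classes[max.col(p, ties.method = "first")], levels = model$classes)
}

#' Metrics from a confusion matrix
#'
#' Rows index the true class, columns the predicted class. Accuracy is
#' `100 * trace / total`; precision and recall are macro-averaged over
#' classes; F1 is the harmonic mean of macro precision and macro recall.
#' Classes never predicted get precision 0 (with a message). `error` is
#' `100 - accuracy` and the macro false-negative rate is `100 - recall`.
#'
#' @param confusion Square non-negative count matrix.
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `error`, `fnr`
#'   (all percentages) and the per-class precision/recall vectors.
#' @export
compute_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square", call. = FALSE)
  if (any(confusion < 0)) stop("negative counts", call. = FALSE)
  total <- sum(confusion)
  if (total == 0) stop("all-zero confusion matrix", call. = FALSE)
  tp <- diag(confusion)
  pred_n <- colSums(confusion)
  true_n <- rowSums(confusion)
  prec <- ifelse(pred_n > 0, tp / pred_n, 0)
  if (any(pred_n == 0))
    message(sprintf("%d class(es) never predicted; precision set to 0",
                    sum(pred_n == 0)))
  rec <- ifelse(true_n > 0, tp / true_n, 0)
  macro_p <- 100 * mean(prec)
  macro_r <- 100 * mean(rec)
  acc <- 100 * sum(tp) / total
  f1 <- if (macro_p + macro_r > 0) 2 * macro_p * macro_r / (macro_p + macro_r) else 0
  list(accuracy = acc, precision = macro_p, recall = macro_r, f1 = f1,
       error = 100 - acc, fnr = 100 - macro_r,
       per_class_precision = 100 * prec, per_class_recall = 100 * rec)
}

#' Cross-validated evaluation of a classifier preset
#'
#' Stratified k-fold cross-validation: the model is fit on k-1 folds and the
#' held-out fold's predictions are accumulated into a pooled confusion
#' matrix, from which all metrics are computed. Per-fold metrics are also
#' reported. Wall time is recorded but never asserted on.
#'
#' @param features A labeled [feature_matrix].
#' @param preset A [classifier_preset] or preset name.
#' @param k Number of folds (default 10, the study protocol).
#' @param seed Seed fixing fold assignment and model initialization.
#' @return An `eval_report`: `confusion`, `accuracy`, `precision`, `recall`,
#'   `f1`, `error`, `fnr`, `per_fold`, `wall_time`, `preset`.
#' @export
crossval_evaluate <- function(features, preset = "WNN", k = 10L, seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"))
  if (is.character(preset)) preset <- classifier_preset(preset)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  y <- droplevels(as.factor(features$labels))
  if (is.null(features$labels)) stop("features need labels", call. = FALSE)
  cls_n <- table(y)
  if (any(cls_n < k))
    stop(sprintf("class '%s' has %d < k = %d members; use a smaller k",
                 names(cls_n)[which.min(cls_n)], min(cls_n), k), call. = FALSE)
  x <- features$values
  K <- nlevels(y)
  t0 <- proc.time()[["elapsed"]]
  folds <- .stratified_folds(y, k, seed)
  confusion <- matrix(0L, K, K, dimnames = list(true = levels(y), pred = levels(y)))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    te <- folds == f
    fit <- mlp_fit(x[!te, , drop = FALSE], y[!te], hidden = preset$hidden,
                   max_epochs = preset$max_epochs, seed = seed + f)
    pred <- mlp_predict(fit, x[te, , drop = FALSE])
    pred <- factor(as.character(pred), levels = levels(y))
    cm <- table(true = y[te], pred = pred)
    confusion <- confusion + as.matrix(cm)
    per_fold[[f]] <- list(fold = f, n = sum(te),
                          accuracy = 100 * mean(pred == y[te]))
  }
  metrics <- suppressMessages(compute_metrics(confusion))
  structure(c(list(confusion = confusion, preset = preset$name, k = k,
                   per_fold = per_fold,
                   wall_time = proc.time()[["elapsed"]] - t0),
              metrics),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %d-fold CV (n = %d)\n", x$preset, x$k,
              sum(x$confusion)))
  cat(sprintf("  accuracy %.1f  precision %.1f  recall %.1f  F1 %.1f  (%.1fs)\n",
              x$accuracy, x$precision, x$recall, x$f1, x$wall_time))
  invisible(x)
}

#' Plot a confusion-matrix heatmap
#'
#' @param report An `eval_report`.
#' @param path Optional PNG output path.
#' @export
plot_confusion <- function(report, path = NULL) {
  cm <- report$confusion
  if (!is.null(path)) grDevices::png(path, width = 600, height = 600)
  graphics::image(seq_len(ncol(cm)), seq_len(nrow(cm)), t(cm[nrow(cm):1, ]),
                  col = grDevices::hcl.colors(25, "YlOrBr", rev = TRUE),
                  xlab = "predicted", ylab = "true", axes = FALSE,
                  main = sprintf("%s confusion (accuracy %.1f%%)",
                                 report$preset, report$accuracy))
  graphics::box()
  if (!is.null(path)) grDevices::dev.off()
  invisible(report)
}
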