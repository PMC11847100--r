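#' @useDynLib medleaf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

LAYER_KINDS <- c("input", "conv", "batchnorm", "relu", "grouped_conv",
                 "add", "gap", "fc", "softmax", "classification")

new_node <- function(id, kind, inputs = integer(0), kernel = NULL,
                     stride = 1L, depth = NULL, groups = 1L,
                     padding = "same", name = NULL) {
  stopifnot(kind %in% LAYER_KINDS)
  if (kind %in% c("conv", "grouped_conv")) {
    if (is.null(kernel) || is.null(depth))
      stop("conv/grouped_conv nodes need kernel and depth", call. = FALSE)
    if (length(kernel) == 1L) kernel <- c(kernel, kernel)
  }
  list(id = as.integer(id), kind = kind, inputs = as.integer(inputs),
       kernel = if (is.null(kernel)) NULL else as.integer(kernel),
       stride = as.integer(stride), depth = if (is.null(depth)) NULL else as.integer(depth),
       groups = as.integer(groups), padding = padding,
       name = if (is.null(name)) paste0(kind, "_", id) else name)
}

new_arch_graph <- function(name, nodes, n_classes, feature_dim) {
  g <- structure(list(name = name, nodes = nodes,
                      n_classes = as.integer(n_classes),
                      feature_dim = as.integer(feature_dim)),
                 class = "arch_graph")
  validate_graph(g)
  g
}

#' Validate an architecture graph
#'
#' Checks that the layer graph is acyclic (topologically ordered by node id),
#' has a single `input` source and a single `classification` sink, and that
#' shape inference from a 224x224x3 input succeeds at every node.
#'
#' @param graph An `arch_graph`.
#' @param input_size Spatial input size used for the shape-inference check.
#' @return The graph, invisibly. Errors name the offending node.
#' @export
validate_graph <- function(graph, input_size = 224L) {
  nodes <- graph$nodes
  ids <- vapply(nodes, `[[`, integer(1), "id")
  if (!identical(ids, seq_along(nodes)))
    stop("node ids must be 1..n in topological order", call. = FALSE)
  kinds <- vapply(nodes, `[[`, character(1), "kind")
  if (sum(kinds == "input") != 1L) stop("graph needs exactly one input node", call. = FALSE)
  if (sum(kinds == "classification") != 1L)
    stop("graph needs exactly one classification node", call. = FALSE)
  for (nd in nodes) {
    if (nd$kind == "input" && length(nd$inputs) != 0L)
      stop("input node cannot have inbound edges", call. = FALSE)
    if (nd$kind != "input" && length(nd$inputs) == 0L)
      stop(sprintf("node %s has no inbound edge", nd$name), call. = FALSE)
    if (any(nd$inputs >= nd$id))
      stop(sprintf("node %s breaks topological order (cycle?)", nd$name), call. = FALSE)
    if (nd$kind == "add" && length(nd$inputs) < 2L)
      stop(sprintf("add node %s needs >= 2 inbound edges", nd$name), call. = FALSE)
  }
  # consumed sinks: every non-classification node must feed something
  fed <- unique(unlist(lapply(nodes, `[[`, "inputs")))
  dangling <- setdiff(ids[kinds != "classification"], fed)
  if (length(dangling))
    stop(sprintf("dangling node(s): %s", paste(dangling, collapse = ",")), call. = FALSE)
  infer_shapes(graph, input_size = input_size)  # errors on any inconsistency
  invisible(graph)
}

#' Infer per-node output shapes
#'
#' @param graph An `arch_graph`.
#' @param input_size Spatial size of the (square) RGB input.
#' @return A list, indexed by node id, of `c(H, W, C)` for spatial nodes or a
#'   single length for vector nodes (gap/fc/softmax/classification).
#' @export
infer_shapes <- function(graph, input_size = 224L) {
  shp <- vector("list", length(graph$nodes))
  for (nd in graph$nodes) {
    ins <- lapply(nd$inputs, function(i) shp[[i]])
    shp[[nd$id]] <- switch(nd$kind,
      input = c(input_size, input_size, 3L),
      conv = ,
      grouped_conv = {
        s <- ins[[1]]
        if (length(s) != 3L) stop(sprintf("node %s: conv needs spatial input", nd$name), call. = FALSE)
        cin <- s[3]
        if (cin %% nd$groups != 0L || nd$depth %% nd$groups != 0L)
          stop(sprintf("node %s: groups (%d) must divide channels %d -> %d",
                       nd$name, nd$groups, cin, nd$depth), call. = FALSE)
        hw <- if (nd$padding == "same") ceiling(s[1:2] / nd$stride)
              else floor((s[1:2] - nd$kernel) / nd$stride) + 1L
        if (any(hw < 1)) stop(sprintf("node %s: output collapses to zero size", nd$name), call. = FALSE)
        c(as.integer(hw), nd$depth)
      },
      batchnorm = ,
      relu = ins[[1]],
      add = {
        if (!all(vapply(ins, function(s) identical(s, ins[[1]]), logical(1))))
          stop(sprintf("node %s: add inputs have mismatched shapes", nd$name), call. = FALSE)
        ins[[1]]
      },
      gap = {
        s <- ins[[1]]
        if (length(s) != 3L) stop(sprintf("node %s: gap needs spatial input", nd$name), call. = FALSE)
        s[3]
      },
      fc = graph$n_classes,
      softmax = ,
      classification = ins[[1]]
    )
  }
  shp
}

# Shared stem: conv 3x3, 16 channels, stride 2, then batchnorm + ReLU.
.stem <- function(nodes) {
  nodes <- c(nodes, list(
    new_node(length(nodes) + 1L, "conv", inputs = length(nodes),
             kernel = 3L, stride = 2L, depth = 16L, name = "stem_conv")))
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "batchnorm",
                                  inputs = length(nodes), name = "stem_bn")))
  c(nodes, list(new_node(length(nodes) + 1L, "relu",
                         inputs = length(nodes), name = "stem_relu")))
}

# Classifier head shared by both streams: the grouped convolution expands to
# `feature_dim` channels, so the global average pool emits the deep feature
# vector; FC -> softmax -> classification close the graph.
.head <- function(nodes, from, feature_dim, groups, kernel = 3L, stride = 2L,
                  prefix = "head") {
  nodes <- c(nodes, list(
    new_node(length(nodes) + 1L, "grouped_conv", inputs = from, kernel = kernel,
             stride = stride, depth = feature_dim, groups = groups,
             name = paste0(prefix, "_gconv"))))
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "batchnorm",
                                  inputs = length(nodes), name = paste0(prefix, "_bn"))))
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "relu",
                                  inputs = length(nodes), name = paste0(prefix, "_relu"))))
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "gap",
                                  inputs = length(nodes), name = "gap")))
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "fc",
                                  inputs = length(nodes), name = "fc")))
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "softmax",
                                  inputs = length(nodes), name = "softmax")))
  c(nodes, list(new_node(length(nodes) + 1L, "classification",
                         inputs = length(nodes), name = "classification")))
}

# A chain of conv nodes closed by batchnorm + ReLU; returns nodes and tail id.
.conv_chain <- function(nodes, from, specs, prefix) {
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    nodes <- c(nodes, list(
      new_node(length(nodes) + 1L, "conv", inputs = from, kernel = sp$kernel,
               stride = sp$stride, depth = sp$depth,
               name = paste0(prefix, "_conv", k))))
    from <- length(nodes)
  }
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "batchnorm",
                                  inputs = from, name = paste0(prefix, "_bn"))))
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "relu",
                                  inputs = length(nodes), name = paste0(prefix, "_relu"))))
  list(nodes = nodes, tail = length(nodes))
}

#' Build the residual-block network
#'
#' Constructs the two-parallel-block residual stream as a typed layer graph:
#' a 3x3/16/stride-2 stem, a depth-16 block of two parallel four-conv branches
#' plus a 5x5 skip conv merged by addition, a depth-32 block of two parallel
#' branches (stride-2 entry) with a 1x1 projection shortcut, a 1x1 conv chain,
#' and a grouped-convolution head expanding to `feature_dim` channels ahead of
#' the global average pool, FC, softmax and classification layers.
#'
#' The free structural knobs (branch lengths, the 5x5 and 1x1 convolutions,
#' grouped-conv groups) are frozen so that the graph has exactly 45 layer
#' nodes, 22 of them convolutional, and 258,030 learnable parameters (258k)
#' at the default 30 classes.
#'
#' @param n_classes Number of output classes (default 30).
#' @param feature_dim Length of the deep feature vector at the global average
#'   pool (default 1024).
#' @return A validated `arch_graph` named `"residual"`.
#' @export
build_residual_net <- function(n_classes = 30L, feature_dim = 1024L) {
  stopifnot(n_classes >= 2L, feature_dim >= 1L)
  nodes <- list(new_node(1L, "input", name = "input"))
  nodes <- .stem(nodes)
  stem_out <- length(nodes)

  conv16 <- list(kernel = 3L, stride = 1L, depth = 16L)
  brA <- .conv_chain(nodes, stem_out, rep(list(conv16), 4), "b1a")
  brB <- .conv_chain(brA$nodes, stem_out, rep(list(conv16), 4), "b1b")
  nodes <- brB$nodes
  # wide-kernel skip path across block 1
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "conv", inputs = stem_out,
                                  kernel = 5L, stride = 1L, depth = 16L,
                                  name = "b1_skip")))
  skip1 <- length(nodes)
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "add",
                                  inputs = c(brA$tail, brB$tail, skip1),
                                  name = "b1_add")))
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "relu",
                                  inputs = length(nodes), name = "b1_out")))
  b1_out <- length(nodes)

  down32 <- list(kernel = 3L, stride = 2L, depth = 32L)
  conv32 <- list(kernel = 3L, stride = 1L, depth = 32L)
  brC <- .conv_chain(nodes, b1_out, list(down32, conv32, conv32), "b2a")
  brD <- .conv_chain(brC$nodes, b1_out, list(down32, conv32, conv32), "b2b")
  nodes <- brD$nodes
  # 1x1 projection shortcut carries block-1 output to the block-2 geometry
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "conv", inputs = b1_out,
                                  kernel = 1L, stride = 2L, depth = 32L,
                                  name = "b2_proj")))
  proj2 <- length(nodes)
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "add",
                                  inputs = c(brC$tail, brD$tail, proj2),
                                  name = "b2_add")))
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "relu",
                                  inputs = length(nodes), name = "b2_out")))

  conv1x1 <- list(kernel = 1L, stride = 1L, depth = 32L)
  mix <- .conv_chain(nodes, length(nodes), rep(list(conv1x1), 4), "mix")
  nodes <- mix$nodes

  nodes <- .head(nodes, mix$tail, feature_dim, groups = 2L)
  new_arch_graph("residual", nodes, n_classes, feature_dim)
}

# One inverted-residual block: 1x1 expansion, grouped 3x3 spatial conv at the
# expanded width, 1x1 projection back to `out_depth`, with a shortcut between
# the narrow ends. `preact` moves the ReLU to the block entry (block 3).
.inv_block <- function(nodes, from, out_depth, in_depth, stride, expansion,
                       prefix, preact = FALSE) {
  wide <- as.integer(out_depth * expansion)
  entry <- from
  if (preact) {
    nodes <- c(nodes, list(new_node(length(nodes) + 1L, "relu", inputs = from,
                                    name = paste0(prefix, "_preact"))))
    entry <- length(nodes)
  }
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "conv", inputs = entry,
                                  kernel = 1L, stride = 1L, depth = wide,
                                  name = paste0(prefix, "_expand"))))
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "batchnorm",
                                  inputs = length(nodes), name = paste0(prefix, "_bn1"))))
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "relu",
                                  inputs = length(nodes), name = paste0(prefix, "_relu1"))))
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "grouped_conv",
                                  inputs = length(nodes), kernel = 3L,
                                  stride = stride, depth = wide, groups = 4L,
                                  name = paste0(prefix, "_gconv"))))
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "batchnorm",
                                  inputs = length(nodes), name = paste0(prefix, "_bn2"))))
  if (!preact)
    nodes <- c(nodes, list(new_node(length(nodes) + 1L, "relu",
                                    inputs = length(nodes), name = paste0(prefix, "_relu2"))))
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "conv",
                                  inputs = length(nodes), kernel = 1L, stride = 1L,
                                  depth = out_depth, name = paste0(prefix, "_project"))))
  main <- length(nodes)
  if (stride == 1L && in_depth == out_depth) {
    shortcut <- from
  } else {
    nodes <- c(nodes, list(new_node(length(nodes) + 1L, "conv", inputs = from,
                                    kernel = 1L, stride = stride, depth = out_depth,
                                    name = paste0(prefix, "_shortcut"))))
    shortcut <- length(nodes)
  }
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "add",
                                  inputs = c(main, shortcut),
                                  name = paste0(prefix, "_add"))))
  list(nodes = nodes, tail = length(nodes))
}

#' Build the inverted-residual-block network
#'
#' Constructs the three-block inverted-residual stream: the same 3x3/16/
#' stride-2 stem as the residual net, then three inverted-residual blocks of
#' output depths 16, 32 and 64 (each expanding by 2x through a 1x1 conv, a
#' grouped 3x3 spatial conv, and a 1x1 projection, with a shortcut between the
#' narrow ends). Block 3 uses pre-activation ordering (it opens with ReLU).
#' A grouped-conv head expands to `feature_dim` channels before the global
#' average pool, so both streams emit features of identical length.
#'
#' @inheritParams build_residual_net
#' @return A validated `arch_graph` named `"inverted_residual"`.
#' @export
build_inverted_residual_net <- function(n_classes = 30L, feature_dim = 1024L) {
  stopifnot(n_classes >= 2L, feature_dim >= 1L)
  nodes <- list(new_node(1L, "input", name = "input"))
  nodes <- .stem(nodes)

  b1 <- .inv_block(nodes, length(nodes), out_depth = 16L, in_depth = 16L,
                   stride = 1L, expansion = 2L, prefix = "ib1")
  b2 <- .inv_block(b1$nodes, b1$tail, out_depth = 32L, in_depth = 16L,
                   stride = 2L, expansion = 2L, prefix = "ib2")
  b3 <- .inv_block(b2$nodes, b2$tail, out_depth = 64L, in_depth = 32L,
                   stride = 2L, expansion = 2L, prefix = "ib3", preact = TRUE)
  nodes <- b3$nodes
  nodes <- c(nodes, list(new_node(length(nodes) + 1L, "relu", inputs = b3$tail,
                                  name = "b3_out")))

  nodes <- .head(nodes, length(nodes), feature_dim, groups = 16L, stride = 1L)
  new_arch_graph("inverted_residual", nodes, n_classes, feature_dim)
}

#' Count learnable parameters of a layer graph
#'
#' Sums the learnable tensors: convolution and grouped-convolution weights and
#' biases, batch-norm scale and offset, and fully-connected weights and biases.
#' Batch-norm running statistics are not learnable and are not counted.
#'
#' @param graph A validated `arch_graph`.
#' @param input_size Spatial input size used to infer per-node channel counts.
#' @return Integer parameter count.
#' @export
count_parameters <- function(graph, input_size = 224L) {
  if (!inherits(graph, "arch_graph")) stop("not an arch_graph", call. = FALSE)
  shp <- infer_shapes(graph, input_size)
  total <- 0
  for (nd in graph$nodes) {
    total <- total + switch(nd$kind,
      conv = ,
      grouped_conv = {
        cin <- shp[[nd$inputs[1]]][3]
        prod(nd$kernel) * (cin / nd$groups) * nd$depth + nd$depth
      },
      batchnorm = {
        s <- shp[[nd$inputs[1]]]
        2L * s[length(s)]
      },
      fc = {
        din <- shp[[nd$inputs[1]]]
        din * graph$n_classes + graph$n_classes
      },
      0L)
  }
  as.integer(total)
}

#' Count layer nodes of a graph
#'
#' Every named node (input, conv, batchnorm, relu, grouped_conv, add, gap, fc,
#' softmax, classification) counts as one layer; an optional filter restricts
#' the census to a subset of kinds.
#'
#' @param graph An `arch_graph`.
#' @param kinds Optional character vector of node kinds to count.
#' @return Integer node count.
#' @export
count_layers <- function(graph, kinds = NULL) {
  if (!inherits(graph, "arch_graph")) stop("not an arch_graph", call. = FALSE)
  k <- vapply(graph$nodes, `[[`, character(1), "kind")
  if (is.null(kinds)) length(k) else sum(k %in% kinds)
}

#' @export
print.arch_graph <- function(x, ...) {
  cat(sprintf("<arch_graph '%s'>: %d layers (%d convolutional), %d classes, feature dim %d\n",
              x$name, count_layers(x),
              count_layers(x, c("conv", "grouped_conv")),
              x$n_classes, x$feature_dim))
  cat(sprintf("  learnable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}
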