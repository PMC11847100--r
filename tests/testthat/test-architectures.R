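# Layer graphs: builders, census, parameter accounting, shape inference.

test_that("residual builder satisfies the printed structural constraints", {
  g <- build_residual_net()
  expect_equal(count_layers(g), 45)
  expect_equal(count_layers(g, c("conv", "grouped_conv")), 22)
  expect_equal(g$feature_dim, 1024L)
  expect_equal(round(count_parameters(g) / 1000), 258)
})

test_that("inverted-residual builder has blocks of depth 16, 32, 64 and the shared stem", {
  g <- build_inverted_residual_net()
  nm <- vapply(g$nodes, `[[`, character(1), "name")
  depths <- vapply(g$nodes[grep("_project$", nm)], `[[`, integer(1), "depth")
  expect_equal(depths, c(16L, 32L, 64L))
  expect_equal(g$feature_dim, 1024L)
  # identical stem in both streams: conv 3x3, 16 channels, stride 2
  for (b in list(build_residual_net(), g)) {
    stem <- b$nodes[[2]]
    expect_equal(stem$kind, "conv")
    expect_equal(stem$kernel, c(3L, 3L))
    expect_equal(stem$depth, 16L)
    expect_equal(stem$stride, 2L)
  }
  # block 3 opens with a ReLU (pre-activation ordering)
  ib3_first <- g$nodes[[grep("ib3", nm)[1]]]
  expect_equal(ib3_first$kind, "relu")
  expect_silent(validate_graph(g))
})

test_that("builders are pure: same arguments give identical graphs", {
  expect_identical(build_residual_net(7), build_residual_net(7))
  expect_identical(build_inverted_residual_net(7), build_inverted_residual_net(7))
})

test_that("count_parameters matches hand and brute-force enumeration", {
  # single 3x3 conv 3 -> 16 with bias
  nodes <- list(
    medleaf:::new_node(1, "input"),
    medleaf:::new_node(2, "conv", 1, kernel = 3, stride = 2, depth = 16),
    medleaf:::new_node(3, "batchnorm", 2),
    medleaf:::new_node(4, "relu", 3),
    medleaf:::new_node(5, "gap", 4),
    medleaf:::new_node(6, "fc", 5),
    medleaf:::new_node(7, "softmax", 6),
    medleaf:::new_node(8, "classification", 7))
  g <- medleaf:::new_arch_graph("toy", nodes, n_classes = 4, feature_dim = 16)
  expect_equal(count_layers(g, "conv"), 1)
  expect_equal(count_layers(g), 8)
  # 3*3*3*16+16 = 448 conv, 32 bn, 16*4+4 fc
  expect_equal(count_parameters(g), 448L + 32L + 68L)

  # grouped 3x3 conv 32 -> 1024, groups 2, bias: 3*3*16*1024 + 1024
  nodes2 <- list(
    medleaf:::new_node(1, "input"),
    medleaf:::new_node(2, "conv", 1, kernel = 1, stride = 2, depth = 32),
    medleaf:::new_node(3, "grouped_conv", 2, kernel = 3, stride = 2,
                       depth = 1024, groups = 2),
    medleaf:::new_node(4, "gap", 3),
    medleaf:::new_node(5, "fc", 4),
    medleaf:::new_node(6, "softmax", 5),
    medleaf:::new_node(7, "classification", 6))
  g2 <- medleaf:::new_arch_graph("toy2", nodes2, n_classes = 2, feature_dim = 1024)
  expect_equal(count_parameters(g2),
               (1 * 3 * 32 + 32) + 148480L + (1024 * 2 + 2))

  # the accountant agrees with brute-force enumeration of realized tensors
  for (g in list(build_residual_net(5), build_inverted_residual_net(5))) {
    net <- init_network(g, seed = 1, input_size = 64)
    realized <- sum(vapply(seq_along(net$weights), function(i) {
      W <- net$weights[[i]]
      if (is.null(W)) return(0L)
      fields <- medleaf:::.learnable_fields(net$graph$nodes[[i]]$kind)
      sum(vapply(fields, function(f) length(W[[f]]), integer(1)))
    }, integer(1)))
    expect_equal(count_parameters(g, input_size = 64), realized)
    # parameter count is independent of spatial input size
    expect_equal(count_parameters(g, input_size = 64),
                 count_parameters(g, input_size = 224))
  }
})

test_that("forward pass matches inferred shapes at every node", {
  g <- build_residual_net(4)
  net <- init_network(g, seed = 2, input_size = 64)
  shp <- infer_shapes(g, input_size = 64)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  fw <- net_forward(net, x, training = TRUE)
  for (nd in g$nodes) {
    a <- fw$acts[[nd$id]]
    s <- shp[[nd$id]]
    if (length(s) == 3) {
      expect_equal(dim(a)[1:3], as.integer(s), info = nd$name)
    } else {
      expect_equal(nrow(a), as.integer(s), info = nd$name)
    }
  }
})

test_that("graph validation catches malformed graphs", {
  nodes <- list(
    medleaf:::new_node(1, "input"),
    medleaf:::new_node(2, "conv", 1, kernel = 3, stride = 1, depth = 15),
    medleaf:::new_node(3, "grouped_conv", 2, kernel = 3, stride = 1,
                       depth = 30, groups = 4),   # 4 does not divide 15
    medleaf:::new_node(4, "gap", 3),
    medleaf:::new_node(5, "fc", 4),
    medleaf:::new_node(6, "softmax", 5),
    medleaf:::new_node(7, "classification", 6))
  expect_error(medleaf:::new_arch_graph("bad", nodes, 2, 30), "groups")
  # add nodes need at least two inbound edges
  expect_error(medleaf:::new_node(3, "add", inputs = 2), NA)
  nodes_add <- list(
    medleaf:::new_node(1, "input"),
    medleaf:::new_node(2, "conv", 1, kernel = 3, stride = 1, depth = 8),
    medleaf:::new_node(3, "add", 2),
    medleaf:::new_node(4, "gap", 3),
    medleaf:::new_node(5, "fc", 4),
    medleaf:::new_node(6, "softmax", 5),
    medleaf:::new_node(7, "classification", 6))
  expect_error(medleaf:::new_arch_graph("bad2", nodes_add, 2, 8), "add")
})

test_that("deep features have the documented shape and inference determinism", {
  g <- build_residual_net(3)
  net <- init_network(g, seed = 5, input_size = 64)
  x7 <- array(runif(64 * 64 * 3 * 7), c(64, 64, 3, 7))
  fm <- extract_features(net, x7)
  expect_equal(dim(fm), c(7L, 1024L))
  # duplicated image -> identical feature rows
  x2 <- x7[, , , c(1, 1), drop = FALSE]
  fm2 <- extract_features(net, x2)
  expect_equal(fm2$values[1, ], fm2$values[2, ])
  # all-zero input -> finite features
  z <- array(0, c(64, 64, 3, 1))
  expect_true(all(is.finite(extract_features(net, z)$values)))
})
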