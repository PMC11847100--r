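# Augmentation operators, manifest plumbing and resizing.

toy_img <- function(vals, H, W) array(vals, dim = c(H, W, 3))

test_that("flip_left mirrors columns and is an involution", {
  img <- toy_img(1:6, 1, 2)                 # [[A, B]] per channel
  out <- flip_left(img)
  expect_equal(out[1, 1, ], img[1, 2, ])
  expect_equal(out[1, 2, ], img[1, 1, ])
  rnd <- toy_img(runif(5 * 4 * 3), 5, 4)
  expect_equal(flip_left(flip_left(rnd)), rnd)
  # column-constant image is a fixed point
  cc <- toy_img(rep(rep(1:5, times = 4), 3), 5, 4)
  expect_equal(flip_left(cc), cc)
  expect_error(flip_left(matrix(1, 2, 2)), "image")
})

test_that("flip_right mirrors rows and composes with flip_left to rotate180", {
  img <- toy_img(1:6, 2, 1)                 # [[A], [B]] per channel
  out <- flip_right(img)
  expect_equal(out[1, 1, ], img[2, 1, ])
  expect_equal(out[2, 1, ], img[1, 1, ])
  rnd <- toy_img(runif(4 * 6 * 3), 4, 6)
  expect_equal(flip_right(flip_right(rnd)), rnd)
  rot180 <- rotate90(rotate90(rnd))
  expect_equal(flip_left(flip_right(rnd)), rot180)
})

test_that("rotate90 turns counter-clockwise, four turns are the identity", {
  img <- toy_img(c(1, 2, 3, 4, 5, 6), 1, 2)  # [[A, B]]
  out <- rotate90(img)
  expect_equal(dim(out), c(2L, 1L, 3L))
  expect_equal(out[1, 1, ], img[1, 2, ])     # [[B], [A]]
  expect_equal(out[2, 1, ], img[1, 1, ])
  rnd <- toy_img(runif(100 * 60 * 3), 100, 60)
  expect_equal(dim(rotate90(rnd)), c(60L, 100L, 3L))
  expect_equal(rotate90(rotate90(rotate90(rotate90(rnd)))), rnd)
})

test_that("all augmentation ops preserve the pixel-value multiset", {
  rnd <- toy_img(runif(7 * 9 * 3), 7, 9)
  for (op in list(flip_left, flip_right, rotate90))
    expect_equal(sort(as.vector(op(rnd))), sort(as.vector(rnd)))
})

test_that("augment_to_target balances classes deterministically", {
  fx <- fixture_leaf2_small()               # class sizes 10 and 5
  man <- fx$manifest
  aug <- augment_to_target(man, 5, seed = 3, split = NULL,
                           out_subdir = "aug_a", minority_only = TRUE)
  expect_true(all(table(aug$label) == c(10, 5)))  # larger classes untouched

  aug10 <- augment_to_target(man, 10, seed = 3, split = NULL,
                             out_subdir = "aug_b")
  expect_true(all(table(aug10$label) == 10))
  expect_equal(nrow(aug10), nrow(man) + 5)
  # originals retained, augmented records inherit the source label
  expect_true(all(man$path %in% aug10$path))
  added <- aug10[!(aug10$path %in% man$path), ]
  expect_true(all(added$label == "class_02"))

  # determinism: same seed, same result
  aug10b <- augment_to_target(man, 10, seed = 3, split = NULL,
                              out_subdir = "aug_c")
  expect_equal(aug10$label, aug10b$label)
  expect_equal(basename(aug10$path), basename(aug10b$path))

  # target equal to current size: no-op
  same <- augment_to_target(man, 10, seed = 3, split = NULL,
                            out_subdir = "aug_d", minority_only = TRUE)
  expect_equal(nrow(same), nrow(man) + 5)   # only the 5-class tops up
  expect_error(augment_to_target(man, 4, split = NULL), "minority_only")

  # asking for more records than distinct (source, op) pairs warns
  expect_warning(augment_to_target(man, 50, seed = 3, split = NULL,
                                   out_subdir = "aug_e"), "repetition")
})

test_that("resize_to_input produces the 224x224x3 network input", {
  img <- toy_img(runif(500 * 500 * 3), 500, 500)
  out <- resize_to_input(img)
  expect_equal(dim(out), c(224L, 224L, 3L))
  expect_true(all(out >= 0 & out <= 1))
  # identity at target size
  at_size <- toy_img(runif(224 * 224 * 3), 224, 224)
  expect_identical(resize_to_input(at_size), at_size)
  # a constant image stays constant under bilinear interpolation
  const <- toy_img(0.37, 100, 80)
  expect_equal(unique(as.vector(resize_to_input(const, 64))), 0.37,
               tolerance = 1e-12)
  # grayscale is replicated with a warning
  expect_warning(g <- resize_to_input(matrix(0.5, 40, 40), 32), "grayscale")
  expect_equal(dim(g), c(32L, 32L, 3L))
})

test_that("manifests round-trip and validate", {
  fx <- fixture_leaf2_small()
  p <- file.path(fx$dir, "manifest.csv")
  m <- read_manifest(p)
  expect_equal(nrow(m), 15)
  expect_setequal(attr(m, "class_names"), c("class_01", "class_02"))
  bad <- m; bad$path[1] <- "nope.png"
  p2 <- file.path(fx$dir, "bad.csv")
  write_manifest(bad, p2)
  expect_error(read_manifest(p2), "missing")
})
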