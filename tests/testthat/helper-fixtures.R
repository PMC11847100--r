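# Shared fixtures, built lazily once per session and reused across test
# files (several tests need the same trained network or dataset).

.fixtures <- new.env(parent = emptyenv())

# 3-class, strongly separated leaf dataset (60 images/class, 64 px) with
# foreground masks; the scale at which 10 epochs of SGDM at the default
# hyperparameters fit the training split.
fixture_leaf3 <- function() {
  if (is.null(.fixtures$leaf3)) {
    dir <- file.path(tempdir(), "medleaf-fixture-leaf3")
    specs <- default_leaf_specs(3, separation = 2)
    man <- generate_leaf_dataset(specs, rep(60, 3), dir, image_size = 64,
                                 seed = 7, keep_masks = TRUE)
    .fixtures$leaf3 <- list(manifest = man, dir = dir)
  }
  .fixtures$leaf3
}

# residual net trained on the fixture above with the default protocol
fixture_trained_net <- function() {
  if (is.null(.fixtures$net3)) {
    fx <- fixture_leaf3()
    .fixtures$net3 <- train_network(build_residual_net(3), fx$manifest,
                                    train_config(seed = 3), input_size = 64)
  }
  .fixtures$net3
}

# tiny 2-class dataset for fast bookkeeping tests
fixture_leaf2_small <- function() {
  if (is.null(.fixtures$leaf2)) {
    dir <- file.path(tempdir(), "medleaf-fixture-leaf2")
    specs <- default_leaf_specs(2, separation = 1)
    man <- generate_leaf_dataset(specs, c(10, 5), dir, image_size = 32, seed = 11)
    .fixtures$leaf2 <- list(manifest = man, dir = dir)
  }
  .fixtures$leaf2
}

# load a rendered foreground mask written by generate_leaf_dataset
load_mask <- function(dir, image_rel_path) {
  m <- load_image(file.path(dir, sub("\\.png$", "_mask.png", image_rel_path)))
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

# brute-force transcription of the four-leader position update (scalar or
# vector), kept deliberately naive: the independent oracle for choa_step
choa_update_bruteforce <- function(x, leaders, A, C, m) {
  P <- nrow(x); d <- ncol(x)
  out <- matrix(NA_real_, P, d)
  for (p in seq_len(P)) {
    for (j in seq_len(d)) {
      xs <- numeric(4)
      for (i in 1:4) {
        D <- abs(C[[i]][p, j] * leaders[i, j] - m[p] * x[p, j])
        xs[i] <- leaders[i, j] - A[[i]][p, j] * D
      }
      out[p, j] <- (xs[1] + xs[2] + xs[3] + xs[4]) / 4
    }
  }
  out
}
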