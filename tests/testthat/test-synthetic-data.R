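# Synthetic leaf images and planted-signal feature tables.

test_that("leaf dataset generation keeps counts, labels and imbalance", {
  dir <- withr::local_tempdir()
  specs <- default_leaf_specs(3)
  man <- generate_leaf_dataset(specs, rep(10, 3), dir, image_size = 64, seed = 1)
  expect_equal(nrow(man), 30)
  expect_equal(length(unique(man$label)), 3)
  expect_true(all(table(man$label) == 10))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(all(file.exists(file.path(dir, man$path))))
  # splits partition the records half/half per class
  expect_true(all(table(man$label, man$split) == 5))

  # imbalance is reproduced as requested
  dir2 <- withr::local_tempdir()
  man2 <- generate_leaf_dataset(default_leaf_specs(2), c(20, 5), dir2,
                                image_size = 32, seed = 2)
  cnt <- table(man2$label)
  expect_equal(unname(cnt[1] / cnt[2]), 4)
})

test_that("leaf dataset generation is byte-identical under a fixed seed", {
  specs <- default_leaf_specs(2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_leaf_dataset(specs, c(3, 3), d1, image_size = 32, seed = 9)
  m2 <- generate_leaf_dataset(specs, c(3, 3), d2, image_size = 32, seed = 9)
  for (p in m1$path)
    expect_identical(readBin(file.path(d1, p), "raw", 1e6),
                     readBin(file.path(d2, p), "raw", 1e6))
  # a different seed changes pixel content
  d3 <- withr::local_tempdir()
  m3 <- generate_leaf_dataset(specs, c(3, 3), d3, image_size = 32, seed = 10)
  expect_false(identical(readBin(file.path(d1, m1$path[1]), "raw", 1e6),
                         readBin(file.path(d3, m3$path[1]), "raw", 1e6)))
})

test_that("generator validates its inputs", {
  dir <- withr::local_tempdir()
  expect_error(generate_leaf_dataset(list(), integer(0), dir), "empty")
  expect_error(generate_leaf_dataset(default_leaf_specs(2), c(3, 3), dir,
                                     image_size = 16), ">= 32")
  expect_error(generate_leaf_dataset(default_leaf_specs(2), c(3), dir),
               "align")
  expect_error(leaf_class_spec(1, aspect_ratio = -1))
  expect_error(planted_feature_spec(informative_idx = c(1, 99)), "range")
})

test_that("planted informative columns out-rank every noise column by t statistic", {
  spec <- planted_feature_spec(n_samples = 300, n_features = 50,
                               informative_idx = 1:5, effect_size = 3,
                               noise_sd = 1, seed = 4)
  fm <- generate_feature_table(spec, n_classes = 2)
  y <- fm$labels
  tstat <- abs(apply(fm$values, 2, function(v)
    t.test(v[y == levels(y)[1]], v[y == levels(y)[2]])$statistic))
  expect_true(min(tstat[1:5]) > max(tstat[-(1:5)]))
})

test_that("planted-table generation is deterministic and null at zero effect", {
  spec <- planted_feature_spec(seed = 8)
  f1 <- generate_feature_table(spec, 5)
  f2 <- generate_feature_table(spec, 5)
  expect_identical(f1$values, f2$values)

  # effect 0: informative columns carry no class signal (ANOVA F in the
  # null range across all columns)
  spec0 <- planted_feature_spec(effect_size = 0, seed = 8)
  f0 <- generate_feature_table(spec0, 5)
  pvals <- apply(f0$values, 2, function(v)
    stats::anova(stats::lm(v ~ f0$labels))[["Pr(>F)"]][1])
  expect_gt(min(p.adjust(pvals, "bonferroni")), 0.01)
})

test_that("ANOVA F ranks all informative columns first in >99% of seeds", {
  hits <- vapply(1:20, function(s) {
    fm <- generate_feature_table(planted_feature_spec(seed = s), n_classes = 5)
    fstat <- apply(fm$values, 2, function(v)
      stats::anova(stats::lm(v ~ fm$labels))[["F value"]][1])
    min(fstat[attr(fm, "informative_idx")]) >
      max(fstat[-attr(fm, "informative_idx")])
  }, logical(1))
  expect_true(all(hits))
})

test_that("classification accuracy is monotone in class separation", {
  acc_at <- function(sep) {
    dir <- withr::local_tempdir()
    man <- generate_leaf_dataset(default_leaf_specs(3, separation = sep),
                                 rep(12, 3), dir, image_size = 32, seed = 5)
    im <- load_images(man, input_size = 32)
    x <- t(apply(im$x, 4, identity))       # raw pixels as features
    folds <- medleaf:::.stratified_folds(im$labels, 3, 1)
    medleaf:::.knn_cv_accuracy(x, im$labels, folds)
  }
  accs <- vapply(c(0.15, 0.7, 1.6), acc_at, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], accs[1])
})
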