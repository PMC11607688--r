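# Feature bank, pixel classifier, watershed and mask selection.

test_that("downsampling averages blocks and keeps constants constant", {
  m <- matrix(seq_len(16), 4, 4)
  d <- downsample(m, 2)
  expect_equal(dim(d), c(2, 2))
  expect_equal(d[1, 1], mean(m[1:2, 1:2]))

  expect_identical(downsample(m, 1), m)
  cm <- matrix(7, 8, 8)
  expect_true(all(downsample(cm, 2) == 7))

  s <- make_benchmark_sample(1)
  ds <- downsample(s$image, 2)
  expect_equal(dim(ds$channels$BF), c(128, 128))
  expect_error(downsample(matrix(0, 4, 4), 8), "factor")
})

test_that("feature bank has ~350 deterministic features, zero derivatives on constants", {
  cfg <- bank_config()
  img <- matrix(runif(64 * 64), 64, 64)
  fs <- extract_features(img, cfg)
  expect_gte(length(fs$feature_names), 330)
  expect_lte(length(fs$feature_names), 370)
  expect_equal(ncol(fs$features), length(fs$feature_names))

  fs2 <- extract_features(img, cfg)
  expect_identical(fs$features, fs2$features)

  const <- extract_features(matrix(42, 64, 64), cfg)
  deriv <- !grepl("^gauss_", const$feature_names)
  expect_true(all(abs(const$features[, deriv]) < 1e-8))
  expect_error(extract_features(matrix(NA_real_, 8, 8)), "finite")
})

test_that("classifier training validates classes and yields unit-sum probabilities", {
  s <- make_benchmark_sample(7)
  empty <- list(list(image = s$image, mask = matrix(0, 256, 256)))
  expect_error(train_pixel_classifier(empty, seed = 1), "inside")

  clf <- bench_classifier()
  expect_s3_class(clf, "pixel_classifier")
  cls <- classify(clf, s$image)
  psum <- cls$prob_maps$background + cls$prob_maps$inside + cls$prob_maps$edge
  expect_true(all(abs(psum - 1) < 1e-6))

  # noise-free sample: labels match the 3-class ground truth on >= 95% of pixels
  s0 <- make_benchmark_sample(8, noise_sd = 0)
  cls0 <- classify(clf, s0$image)
  mask_ds <- (gastroquant:::block_reduce(s0$true_mask, 2) > 0.5) * 1
  gt <- gastroquant:::three_class_gt(mask_ds, clf$edge_band_px)
  expect_gt(mean(cls0$labels == gt), 0.95)

  # tidiers
  td <- tidy(clf)
  expect_equal(nrow(td), length(clf$feature_names) * 3)
  expect_equal(glance(clf)$n_training_images, 3)
})

test_that("classification is deterministic and ties break by fixed class order", {
  clf <- bench_classifier()
  s <- make_benchmark_sample(9)
  c1 <- classify(clf, s$image)
  c2 <- classify(clf, s$image)
  expect_identical(c1$prob_maps, c2$prob_maps)

  # constructed exact tie resolves to the earlier class in the fixed order
  probs <- cbind(background = c(0.4, 1 / 3), inside = c(0.4, 1 / 3),
                 edge = c(0.2, 1 / 3))
  lab <- max.col(probs, ties.method = "first")
  expect_equal(clf$classes[lab], c("background", "background"))
})

test_that("watershed floods the edge-probability landscape from seeds", {
  # crisp synthetic ring: inside blob, edge ring, background
  d <- disk_mask(30, 101)
  ring <- disk_mask(33, 101) - d
  edge_p <- ring * 0.9
  inside_p <- d * 0.95
  bg_p <- 1 - pmax(d, disk_mask(33, 101))
  wm <- watershed_mask(edge_p, inside_p, bg_p)
  expect_gte(mask_iou(wm, disk_mask(31, 101)), 0.9)

  expect_error(watershed_mask(edge_p, inside_p * 0, bg_p), "inside seed")
})

test_that("mask selection prefers watershed, falls back, and obeys manual override", {
  good <- disk_mask(25, 101)
  frag <- good
  frag[, 45:47] <- 0   # split into pieces
  res <- select_mask(good, frag, upsample_factor = 1)
  expect_equal(res$provenance, "watershed")

  res2 <- select_mask(frag, good, upsample_factor = 1)
  expect_equal(res2$provenance, "classifier")
  expect_gt(length(res2$qc_flags), 0)

  manual <- disk_mask(20, 101)
  res3 <- select_mask(frag, frag, manual = manual, upsample_factor = 1)
  expect_equal(res3$provenance, "manual")

  expect_error(select_mask(frag, frag, upsample_factor = 1), "plausibility")

  # smoothing leaves a single component
  expect_equal(max(EBImage::bwlabel(res2$mask)), 1)
})

test_that("segmentation is robust to global intensity rescaling after retraining", {
  scale <- 1.7
  train_a <- lapply(1:2, function(i) {
    s <- make_benchmark_sample(300 + i)
    list(image = s$image, mask = s$true_mask)
  })
  train_b <- lapply(train_a, function(tr) {
    img <- tr$image
    img$channels <- lapply(img$channels, function(m) m * scale)
    list(image = img, mask = tr$mask)
  })
  clf_a <- train_pixel_classifier(train_a, seed = 2)
  clf_b <- train_pixel_classifier(train_b, seed = 2)
  s <- make_benchmark_sample(310)
  img_b <- s$image
  img_b$channels <- lapply(img_b$channels, function(m) m * scale)
  m_a <- segment_sample(clf_a, s$image)$mask
  m_b <- segment_sample(clf_b, img_b)$mask
  expect_gt(mask_iou(m_a, m_b), 0.95)
})
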