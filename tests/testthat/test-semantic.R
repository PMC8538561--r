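test_that("feature extractor preserves shape, bounds and determinism", {
  fx <- build_feature_extractor(c(4L, 6L, 6L), seed = 61)
  ph <- generate_phantom(2, seed = 62, height = 48, width = 48)
  f1 <- extract_features(fx, ph$image)
  expect_equal(dim(f1), c(48L, 48L, 6L))
  expect_true(all(f1 > 0 & f1 < 1))
  fx2 <- build_feature_extractor(c(4L, 6L, 6L), seed = 61)
  expect_identical(f1, extract_features(fx2, ph$image))
  fx3 <- build_feature_extractor(c(4L, 6L, 6L), seed = 99)
  expect_false(identical(f1, extract_features(fx3, ph$image)))
  expect_error(build_feature_extractor(c(0L, 4L, 4L)), "positive")
})

test_that("single-label training yields a constant predictor", {
  set.seed(63)
  feats <- array(runif(16 * 16 * 4), c(16, 16, 4))
  mask <- matrix(3L, 16, 16)
  clf <- train_pixel_classifier(feats, mask, num_trees = 10, seed = 1)
  pred <- predict_mask(clf, features = array(runif(16 * 16 * 4),
                                             c(16, 16, 4)))
  expect_true(all(pred == 3L))
})

test_that("training is invariant to pixel order given a fixed seed", {
  set.seed(64)
  n <- 20 * 20
  feats <- array(runif(n * 3), c(20, 20, 3))
  mask <- matrix(sample(0:2, n, replace = TRUE), 20, 20)
  perm <- sample(n)
  feats_p <- array(matrix(feats, n, 3)[perm, ], c(20, 20, 3))
  mask_p <- matrix(as.vector(mask)[perm], 20, 20)
  test_feats <- array(runif(12 * 12 * 3), c(12, 12, 3))
  p1 <- predict_mask(train_pixel_classifier(feats, mask, num_trees = 20,
                                            seed = 5),
                     features = test_feats)
  p2 <- predict_mask(train_pixel_classifier(feats_p, mask_p, num_trees = 20,
                                            seed = 5),
                     features = test_feats)
  expect_identical(p1, p2)
})

test_that("self-consistency: an easy phantom is re-labelled accurately", {
  ph <- generate_phantom(2, seed = 65, height = 64, width = 64)
  seg <- train_pixel_segmenter(list(ph$image), list(ph$mask),
                               cnn_steps = 25L, num_trees = 50L, seed = 66)
  pred <- predict_mask(seg, ph$image)
  expect_gte(mean(pred == ph$mask), 0.90)
  # label-set closure
  expect_true(all(pred %in% sort(unique(as.vector(ph$mask)))))
})

test_that("pixel classification generalises to held-out phantoms", {
  train <- phantom_set(rep(c(2, 3, 4), 3), size = 64, seed0 = 300)
  seg <- train_pixel_segmenter(lapply(train, `[[`, "image"),
                               lapply(train, `[[`, "mask"),
                               cnn_steps = 30L, num_trees = 60L, seed = 67)
  lab <- mask_labels()
  dices <- sapply(phantom_set(c(2, 3, 4), size = 64, seed0 = 400),
                  function(ph) {
    pred <- predict_mask(seg, ph$image)
    truth <- ph$mask == lab[["bright_lesion"]]
    got <- pred == lab[["bright_lesion"]]
    2 * sum(truth & got) / (sum(truth) + sum(got))
  })
  expect_gte(mean(dices), 0.6)
})

test_that("a lesion-free phantom draws almost no lesion pixels", {
  train <- phantom_set(c(0, 2, 4), size = 64, seed0 = 500)
  seg <- train_pixel_segmenter(lapply(train, `[[`, "image"),
                               lapply(train, `[[`, "mask"),
                               cnn_steps = 25L, num_trees = 50L, seed = 68)
  ph0 <- generate_phantom(0, seed = 501, height = 64, width = 64)
  pred <- predict_mask(seg, ph0$image)
  expect_lt(mean(pred %in% 4:5), 0.01)
})

test_that("the forest stage is equivariant under spatial flips of its features", {
  set.seed(69)
  feats <- array(runif(24 * 24 * 3), c(24, 24, 3))
  mask <- matrix(sample(0:1, 24 * 24, replace = TRUE,
                        prob = c(0.7, 0.3)), 24, 24)
  clf <- train_pixel_classifier(feats, mask, num_trees = 25, seed = 7)
  test_feats <- array(runif(24 * 24 * 3), c(24, 24, 3))
  flipped <- test_feats[, rev(seq_len(24)), , drop = FALSE]
  p <- predict_mask(clf, features = test_feats)
  pf <- predict_mask(clf, features = flipped)
  expect_identical(pf, p[, rev(seq_len(24))])
})
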