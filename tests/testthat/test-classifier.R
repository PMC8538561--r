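test_that("feature-map counts follow the dense concatenation rule", {
  expect_equal(feature_map_count(1, 32, 64), 64)
  expect_equal(feature_map_count(3, 32, 64), 128)
  expect_error(feature_map_count(0, 32, 64), ">= 1")
})

test_that("built networks realise the dense-block channel arithmetic exactly", {
  for (cfg in list(densenet_config(input_size = 64L),
                   densenet_config(growth_rate = 4L, initial_channels = 8L,
                                   layers_per_block = c(2L, 3L, 2L, 1L),
                                   input_size = 64L))) {
    net <- build_densenet(cfg, seed = 81)
    k <- cfg$growth_rate
    ch <- cfg$initial_channels
    for (b in 1:4) {
      k0_block <- ch
      for (l in seq_len(cfg$layers_per_block[b])) {
        id <- paste0("b", b, "l", l)
        st <- net$structure[[id]]
        # Eq-style count vs the realised layer input
        expect_equal(st$in_channels, feature_map_count(l, k, k0_block))
        # bottleneck emits 4k maps
        expect_equal(st$bottleneck_channels, 4L * k)
        # parameter tensors agree with the recorded structure
        expect_equal(dim(net$params[[paste0(id, "_cv1")]]$W),
                     c(st$in_channels, 4L * k))
        expect_equal(dim(net$params[[paste0(id, "_cv2")]]$W),
                     c(4L * k * 9L, k))
        ch <- ch + k
      }
      if (b < 4) ch <- max(1L, as.integer(floor(ch * cfg$compression)))
    }
    # classification head: dense 128 then dense 64 then 5-way softmax
    expect_equal(ncol(net$params$fc1$W), cfg$head_widths[1])
    expect_equal(ncol(net$params$fc2$W), cfg$head_widths[2])
    expect_equal(dim(net$params$fc_out$W), c(cfg$head_widths[2], 5L))
  }
  expect_equal(densenet_config()$head_widths, c(128L, 64L))
  expect_error(densenet_config(layers_per_block = c(2L, 2L, 2L)), "4 dense")
})

test_that("forward pass emits probability rows over the five grades", {
  net <- build_densenet(densenet_config(input_size = 64L), seed = 82)
  set.seed(83)
  X <- matrix(runif(3 * 64 * 64 * 3), 3 * 4096, 3)
  prob <- fundushr:::densenet_forward(net, X, 3L, 64L, 64L)$prob
  expect_equal(dim(prob), c(3L, 5L))
  expect_equal(rowSums(prob), rep(1, 3), tolerance = 1e-9)
  expect_true(all(prob >= 0))
})

test_that("KL-divergence loss matches its analytic identities", {
  u <- rep(0.2, 5)
  onehot <- c(1, 0, 0, 0, 0)
  expect_equal(kld_loss(u, u), 0)
  expect_equal(kld_loss(onehot, u), log(5), tolerance = 1e-9)
  set.seed(84)
  for (i in 1:1000) {
    t <- runif(5); t <- t / sum(t)
    p <- runif(5); p <- p / sum(p)
    kl <- kld_loss(t, p)
    expect_gte(kl, 0)
    # cross-entropy minus target entropy
    ce <- -sum(t * log(pmax(p, 1e-7)))
    h <- -sum(t * log(t))
    expect_equal(kl, ce - h, tolerance = 1e-9)
  }
  expect_error(kld_loss(c(0.5, 0.5, 0.5, 0, 0), u), "summing to 1")
})

test_that("training is deterministic and reduces the loss at overfit scale", {
  dir <- withr::local_tempdir()
  m <- generate_dataset(c(4L, 4L, 4L, 4L, 4L), seed = 85, out_dir = dir,
                        height = 64L, width = 64L)
  tcfg <- train_config(epochs = 8L, batch_size = 10L, seed = 85,
                       enhance = FALSE)
  run <- function() {
    net <- build_densenet(densenet_config(input_size = 64L), seed = 85)
    train_classifier(net, m, tcfg)
  }
  m1 <- run()
  expect_lt(tail(m1$curves$train_loss, 1), m1$curves$train_loss[1])
  m2 <- run()
  expect_equal(m1$curves, m2$curves)
  # tidy/glance surfaces
  expect_identical(tidy(m1), m1$curves)
  expect_equal(glance(m1)$epochs, 8L)
})

test_that("grade prediction is a deterministic simplex output", {
  dir <- withr::local_tempdir()
  m <- generate_dataset(c(3L, 3L, 3L, 3L, 3L), seed = 86, out_dir = dir,
                        height = 64L, width = 64L)
  net <- build_densenet(densenet_config(input_size = 64L), seed = 86)
  model <- train_classifier(net, m, train_config(epochs = 2L, seed = 86,
                                                 enhance = FALSE))
  img <- read_image(m$image[1])
  p1 <- predict_grade(model, img)
  p2 <- predict_grade(model, img)
  expect_equal(sum(p1$probabilities), 1, tolerance = 1e-9)
  expect_identical(p1$probabilities, p2$probabilities)
  expect_true(p1$grade %in% 0:4)
  expect_equal(p1$grade, which.max(p1$probabilities) - 1L)
  raw <- build_densenet(densenet_config(input_size = 64L), seed = 87)
  expect_error(predict_grade(raw, img), "untrained")
})

test_that("region conditioning feeds a fourth input plane", {
  dir <- withr::local_tempdir()
  m <- generate_dataset(c(3L, 3L, 3L, 3L, 3L), seed = 88, out_dir = dir,
                        height = 64L, width = 64L)
  net4 <- build_densenet(densenet_config(input_size = 64L, in_channels = 4L),
                         seed = 88)
  regions <- lapply(seq_len(nrow(m)), function(i) {
    msk <- read_mask(m$mask[i])
    matrix(as.integer(msk %in% 4:5), nrow(msk), ncol(msk))
  })
  model <- train_classifier(net4, m, train_config(epochs = 2L, seed = 88,
                                                  enhance = FALSE),
                            regions = regions)
  img <- read_image(m$image[1])
  p <- predict_grade(model, img, regions = regions[[1]])
  expect_equal(sum(p$probabilities), 1, tolerance = 1e-9)
  # channel mismatch is rejected
  expect_error(predict_grade(model, img), "channel")
  net3 <- build_densenet(densenet_config(input_size = 64L), seed = 88)
  expect_error(train_classifier(net3, m, train_config(epochs = 1L, seed = 1,
                                                      enhance = FALSE),
                                regions = regions), "4-channel")
})
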