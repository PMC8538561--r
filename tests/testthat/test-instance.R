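test_that("Otsu threshold maximises between-class variance (brute force)", {
  brute_otsu <- function(gray) {
    lev <- as.integer(round(gray * 255))
    counts <- tabulate(lev + 1L, nbins = 256L)
    best <- -Inf; best_t <- NA
    n <- length(lev)
    for (t in 0:254) {
      w0 <- sum(counts[1:(t + 1)]) / n
      w1 <- 1 - w0
      if (w0 == 0 || w1 == 0) next
      mu0 <- sum(counts[1:(t + 1)] * (0:t)) / sum(counts[1:(t + 1)])
      mu1 <- sum(counts[(t + 2):256] * ((t + 1):255)) /
        sum(counts[(t + 2):256])
      sb <- w0 * w1 * (mu0 - mu1)^2
      if (sb > best + 1e-12) { best <- sb; best_t <- t }
    }
    (best_t + 0.5) / 255
  }
  set.seed(71)
  for (i in 1:20) {
    g <- matrix(sample(seq(0, 1, by = 1 / 255), 64, replace = TRUE,
                       prob = runif(256)^2), 8, 8)
    if (length(unique(as.vector(g))) < 2) next
    expect_equal(otsu_threshold(g)$threshold, brute_otsu(g),
                 tolerance = 1e-12)
  }
})

test_that("Otsu separates a bimodal image and behaves under inversion", {
  g <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10, 10)
  ot <- otsu_threshold(g)
  expect_true(all(ot$binary == (g > 0.5)))
  inv <- otsu_threshold(1 - g)
  expect_true(all(inv$binary == !ot$binary))
  expect_warning(res <- otsu_threshold(matrix(0.4, 5, 5)), "constant")
  expect_true(all(!res$binary))
  expect_true(is.na(res$threshold))
})

test_that("watershed separates touching discs that plain labelling merges", {
  b <- disc_mask(list(c(128, 108), c(128, 148)), r = 30)
  res <- watershed_postprocess(b)
  plain <- max(fundushr:::label_components_4(matrix(as.integer(b), 256)))
  expect_equal(res$n_instances, 2)
  expect_equal(plain, 1)
  # disjoint discs are trivially two instances
  b2 <- disc_mask(list(c(128, 80), c(128, 176)), r = 30)
  expect_equal(watershed_postprocess(b2)$n_instances, 2)
  expect_equal(watershed_postprocess(matrix(0, 64, 64))$n_instances, 0)
})

test_that("watershed output satisfies its structural invariants", {
  set.seed(72)
  for (i in 1:5) {
    centers <- lapply(1:3, function(j) c(runif(1, 60, 196), runif(1, 60, 196)))
    b <- disc_mask(centers, r = runif(1, 15, 28))
    res <- watershed_postprocess(b)
    labs <- sort(unique(as.vector(res$labels)))
    # consecutive labels 0..n
    expect_identical(labs, 0:res$n_instances)
    # watershed adds no foreground
    expect_true(all(b[res$labels > 0]))
    # count invariant under horizontal flip
    resf <- watershed_postprocess(b[, rev(seq_len(ncol(b)))])
    expect_equal(resf$n_instances, res$n_instances)
    # each instance 4-connected
    for (l in seq_len(res$n_instances)) {
      one <- matrix(as.integer(res$labels == l), nrow(res$labels))
      expect_equal(max(fundushr:::label_components_4(one)), 1)
    }
  }
})

test_that("mask network contracts: divisibility, shape, sigmoid range", {
  expect_error(build_unet(input_size = 100L, depth = 4L), "divisible")
  net <- build_unet(input_size = 64L, depth = 3L, base_channels = 4L,
                    seed = 73)
  ph <- generate_phantom(2, seed = 74, height = 64, width = 64)
  prob <- predict_prob_mask(net, ph$image)
  expect_equal(dim(prob), c(64L, 64L))
  expect_true(all(prob >= 0 & prob <= 1))
  # identical seeds build identical networks
  net2 <- build_unet(input_size = 64L, depth = 3L, base_channels = 4L,
                     seed = 73)
  expect_identical(predict_prob_mask(net2, ph$image), prob)
})

test_that("the mask network overfits a handful of phantoms", {
  ph <- phantom_set(c(2, 3, 4), size = 64, seed0 = 600)
  net <- build_unet(input_size = 64L, depth = 3L, base_channels = 8L,
                    seed = 75)
  net <- train_unet(net, lapply(ph, `[[`, "image"),
                    lapply(ph, function(p) lesion_binary(p$mask)),
                    steps = 150L, batch_size = 3L, seed = 75)
  expect_gte(tail(net$history$dice, 1), 0.8)
})

test_that("end-to-end instance segmentation finds the planted lesions", {
  # k large well-separated bright lesions, no dark ones
  spec_k <- function(k) grade_spec(n_bright = c(0L, 0L, k, k, k),
                                   n_dark = rep(0L, 5),
                                   bright_radius_frac = c(0.12, 0.15))
  train <- lapply(1:6, function(i)
    generate_phantom(2, spec_k(3L), seed = 700 + i, height = 64, width = 64))
  net <- build_unet(input_size = 64L, depth = 3L, base_channels = 8L,
                    seed = 76)
  net <- train_unet(net, lapply(train, `[[`, "image"),
                    lapply(train, function(p) lesion_binary(p$mask)),
                    steps = 150L, batch_size = 3L, seed = 76)
  hits <- 0L
  for (k in 1:3) {
    ph <- generate_phantom(2, spec_k(k), seed = 800 + k,
                           height = 64, width = 64)
    # ground truth = connected lesion components actually planted
    truth <- max(fundushr:::label_components_4(
      matrix(as.integer(ph$mask == 4L), 64)))
    res <- segment_instances(ph$image, net)
    expect_equal(dim(res$labels), c(64L, 64L))
    labs <- sort(unique(as.vector(res$labels)))
    expect_identical(labs, 0:res$n_instances)
    if (res$n_instances == truth) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
  # a clean mask on a lesion-free phantom yields no instances
  ph0 <- generate_phantom(0, spec_k(3L), seed = 900, height = 64, width = 64)
  res0 <- segment_instances(ph0$image, net)
  expect_lte(res0$n_instances, 1L)
})
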