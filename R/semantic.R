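#' Build the shallow convolutional pixel-feature extractor
#'
#' Three 3 x 3 convolution layers with "same" padding (spatial shape is
#' preserved) and a sigmoid on the final activations, giving each pixel a
#' feature vector in (0, 1)^F. Initialisation is deterministic for a fixed
#' seed. The extractor can be used with random weights or trained end-to-end
#' as a per-pixel classifier (see [train_pixel_segmenter()]) before its
#' features are handed to the random-forest stage.
#'
#' @param channels_per_layer Integer vector of length 3: output channels of
#'   each convolution.
#' @param seed Integer seed for weight initialisation.
#' @param in_channels Input planes (3 for RGB).
#' @return A `pixel_feature_extractor` object.
#' @export
build_feature_extractor <- function(channels_per_layer = c(8L, 16L, 16L),
                                    seed = 1L, in_channels = 3L) {
  if (length(channels_per_layer) != 3 || any(channels_per_layer < 1))
    stop("channels_per_layer must be 3 positive integers", call. = FALSE)
  params <- with_seed(seed, list(
    c1 = nn_conv_init(in_channels, channels_per_layer[1], 3L),
    c2 = nn_conv_init(channels_per_layer[1], channels_per_layer[2], 3L),
    c3 = nn_conv_init(channels_per_layer[2], channels_per_layer[3], 3L)))
  structure(list(params = params, channels = channels_per_layer,
                 in_channels = in_channels, seed = seed, trained = FALSE),
            class = "pixel_feature_extractor")
}

fx_forward <- function(fx, X, B, H, W, with_cache = FALSE) {
  f1 <- nn_conv_fw(X, B, H, W, fx$params$c1, 3L)
  a1 <- nn_relu_fw(f1$out)
  f2 <- nn_conv_fw(a1, B, H, W, fx$params$c2, 3L)
  a2 <- nn_relu_fw(f2$out)
  f3 <- nn_conv_fw(a2, B, H, W, fx$params$c3, 3L)
  s3 <- nn_sigmoid_fw(f3$out)
  out <- list(out = s3)
  if (with_cache)
    out$cache <- list(f1 = f1, pre1 = f1$out, f2 = f2, pre2 = f2$out,
                      f3 = f3, s3 = s3)
  out
}

#' Extract per-pixel features from an image
#'
#' @param fx A [build_feature_extractor()] object.
#' @param img H x W x 3 array in [0, 1].
#' @return H x W x F feature array with values in (0, 1).
#' @export
extract_features <- function(fx, img) {
  stopifnot(inherits(fx, "pixel_feature_extractor"))
  assert_rgb_image(img)
  d <- dim(img)
  fm <- fx_forward(fx, img_to_fm(img), 1L, d[1], d[2])$out
  fm_to_img(fm, d[1], d[2])
}

# supervised fine-tuning of the extractor: an auxiliary 1x1 softmax head is
# trained per pixel against the mask, then discarded
train_extractor <- function(fx, images, masks, steps = 40L, lr = 1e-3,
                            seed = 1L, subsample = 20000L) {
  labels <- sort(unique(unlist(lapply(masks, as.vector))))
  K <- length(labels)
  d <- dim(images[[1]])
  H <- d[1]; W <- d[2]
  with_seed(seed, {
    head <- nn_dense_init(fx$channels[3], K)
    params <- list(c1W = fx$params$c1$W, c1b = fx$params$c1$b,
                   c2W = fx$params$c2$W, c2b = fx$params$c2$b,
                   c3W = fx$params$c3$W, c3b = fx$params$c3$b,
                   hW = head$W, hb = head$b)
    st <- adam_init(params)
    xs_all <- lapply(images, img_to_fm)
    ys_all <- lapply(masks, function(m) match(as.vector(m), labels))
    for (step in seq_len(steps)) {
      i <- sample.int(length(images), 1)
      fx$params <- list(c1 = list(W = params$c1W, b = params$c1b),
                        c2 = list(W = params$c2W, b = params$c2b),
                        c3 = list(W = params$c3W, b = params$c3b))
      fwd <- fx_forward(fx, xs_all[[i]], 1L, H, W, with_cache = TRUE)
      F3 <- fwd$out
      idx <- sample.int(H * W, min(subsample, H * W))
      Z <- sweep(F3[idx, , drop = FALSE] %*% params$hW, 2, params$hb, `+`)
      P <- nn_softmax(Z)
      Tm <- matrix(0, length(idx), K)
      Tm[cbind(seq_along(idx), ys_all[[i]][idx])] <- 1
      dZ <- (P - Tm) / length(idx)
      gH <- crossprod(F3[idx, , drop = FALSE], dZ)
      gHb <- colSums(dZ)
      dF3 <- matrix(0, H * W, fx$channels[3])
      dF3[idx, ] <- dZ %*% t(params$hW)
      ca <- fwd$cache
      d3 <- nn_sigmoid_bw(dF3, ca$s3)
      b3 <- nn_conv_bw(d3, fx$params$c3, ca$f3$cache)
      d2 <- nn_relu_bw(b3$dx, ca$pre2)
      b2 <- nn_conv_bw(d2, fx$params$c2, ca$f2$cache)
      d1 <- nn_relu_bw(b2$dx, ca$pre1)
      b1 <- nn_conv_bw(d1, fx$params$c1, ca$f1$cache)
      grads <- list(c1W = b1$dW, c1b = b1$db, c2W = b2$dW, c2b = b2$db,
                    c3W = b3$dW, c3b = b3$db, hW = gH, hb = gHb)
      upd <- adam_step(params, grads, st, lr)
      params <- upd$params; st <- upd$st
    }
    fx$params <- list(c1 = list(W = params$c1W, b = params$c1b),
                      c2 = list(W = params$c2W, b = params$c2b),
                      c3 = list(W = params$c3W, b = params$c3b))
    fx$trained <- TRUE
    fx
  })
}

#' Train the random-forest pixel classifier
#'
#' Takes per-pixel feature maps and aligned label masks and fits a seeded
#' random-forest ensemble over the pixel feature vectors. Training rows are
#' canonically ordered (by label, then feature values) before the seeded
#' subsample, so permuting pixel order leaves the fitted forest unchanged.
#'
#' @param features One H x W x F array or a list of them.
#' @param masks Matching H x W integer mask(s).
#' @param num_trees Trees in the ensemble.
#' @param max_pixels Per-image cap on training pixels.
#' @param seed Integer seed.
#' @param extractor Optional [build_feature_extractor()] object embedded in
#'   the returned classifier so [predict_mask()] can run end-to-end.
#' @return A `pixel_classifier` object.
#' @export
train_pixel_classifier <- function(features, masks, num_trees = 100L,
                                   max_pixels = 50000L, seed = 1L,
                                   extractor = NULL) {
  if (is.array(features) && !is.list(features)) features <- list(features)
  if (is.matrix(masks)) masks <- list(masks)
  if (length(features) != length(masks))
    stop("features and masks must pair up", call. = FALSE)
  xs <- list(); ys <- list()
  for (i in seq_along(features)) {
    f <- features[[i]]; m <- masks[[i]]
    if (!all(dim(f)[1:2] == dim(m)))
      stop("feature map and mask shapes differ", call. = FALSE)
    X <- img_to_fm(f)
    y <- as.vector(m)
    keep <- with_seed(seed + i, {
      ord <- do.call(order, c(list(y), lapply(seq_len(ncol(X)),
                                              function(j) X[, j])))
      if (length(ord) > max_pixels) sort(sample(ord, max_pixels)) else ord
    })
    # canonical order first, then a seeded subsample of the ordered rows
    xs[[i]] <- X[keep, , drop = FALSE]
    ys[[i]] <- y[keep]
  }
  X <- do.call(rbind, xs)
  y <- factor(unlist(ys))
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df$.label <- y
  fit <- ranger::ranger(dependent.variable.name = ".label", data = df,
                        num.trees = num_trees, seed = seed,
                        num.threads = 1L, verbose = FALSE)
  structure(list(forest = fit, labels = as.integer(levels(y)),
                 n_features = ncol(X), extractor = extractor, seed = seed),
            class = "pixel_classifier")
}

#' Predict a per-pixel lesion mask
#'
#' Runs the embedded feature extractor on the image and classifies every
#' pixel with the trained forest. Predictions never leave the trained label
#' set.
#'
#' @param classifier A [train_pixel_classifier()] object with an embedded
#'   extractor, or pass `features` directly.
#' @param image H x W x 3 array (enhanced image, by pipeline convention).
#' @param features Optional precomputed H x W x F feature array.
#' @return H x W integer label mask.
#' @export
predict_mask <- function(classifier, image = NULL, features = NULL) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  if (is.null(features)) {
    if (is.null(classifier$extractor))
      stop("classifier has no embedded extractor; supply `features`",
           call. = FALSE)
    if (is.null(image)) stop("supply `image` or `features`", call. = FALSE)
    features <- extract_features(classifier$extractor, image)
  }
  d <- dim(features)
  X <- img_to_fm(features)
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  # tie votes are broken with the RNG; seed the prediction for determinism
  pred <- predict(classifier$forest, data = df, num.threads = 1L,
                  seed = classifier$seed)$predictions
  matrix(as.integer(as.character(pred)), d[1], d[2])
}

#' Train the full semantic segmentation stage
#'
#' Convenience wrapper implementing the pipeline's semantic track: build the
#' shallow extractor, optionally fine-tune it per pixel against the masks,
#' freeze it, extract features, and fit the random-forest pixel classifier.
#'
#' @param images List of H x W x 3 arrays.
#' @param masks List of aligned H x W integer masks.
#' @param channels_per_layer Extractor widths.
#' @param train_cnn Fine-tune the extractor before the forest ("trained
#'   features"), or keep random initialisation ("random features" ablation)?
#' @param cnn_steps Fine-tuning steps.
#' @param num_trees,max_pixels Forest settings.
#' @param seed Integer seed.
#' @return A `pixel_classifier` with embedded extractor.
#' @export
train_pixel_segmenter <- function(images, masks,
                                  channels_per_layer = c(8L, 16L, 16L),
                                  train_cnn = TRUE, cnn_steps = 40L,
                                  num_trees = 100L, max_pixels = 50000L,
                                  seed = 1L) {
  fx <- build_feature_extractor(channels_per_layer, seed = seed)
  if (train_cnn) fx <- train_extractor(fx, images, masks, steps = cnn_steps,
                                       seed = seed)
  feats <- lapply(images, function(im) extract_features(fx, im))
  train_pixel_classifier(feats, masks, num_trees = num_trees,
                         max_pixels = max_pixels, seed = seed, extractor = fx)
}
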