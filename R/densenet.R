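#' Input feature-map count of a dense-block layer
#'
#' In a dense block every layer receives the concatenation of all preceding
#' layers' outputs, so layer `l` (1-based) sees `k * (l - 1) + k0` input
#' feature maps, where `k` is the growth rate and `k0` the channels entering
#' the block.
#'
#' @param l Layer index within the block (>= 1).
#' @param k Growth rate.
#' @param k0 Channels entering the block.
#' @return Integer feature-map count.
#' @export
feature_map_count <- function(l, k, k0) {
  if (any(l < 1) || any(l != round(l)))
    stop("layer index `l` must be an integer >= 1", call. = FALSE)
  k * (l - 1) + k0
}

#' Dense-block classifier configuration
#'
#' Exactly four dense blocks separated by transition layers (batch
#' normalisation, 1 x 1 convolution with compression, 2 x 2 average
#' pooling). Each dense layer is BN -> ReLU -> 1 x 1 bottleneck emitting
#' `bottleneck_factor * k` maps -> BN -> ReLU -> 3 x 3 convolution emitting
#' `k` maps, concatenated onto the block's running state. The classification
#' head is global average pooling -> dense 128 -> dense 64 -> tanh -> linear
#' -> softmax over the five grades.
#'
#' `densenet169_config()` is the full-scale preset (growth 32, stem 64,
#' blocks 6/12/32/32); `desk_config()` is the small preset the test suite
#' trains.
#'
#' @param growth_rate k, feature maps added per dense layer.
#' @param initial_channels k0, channels produced by the stem convolution.
#' @param layers_per_block Integer vector of length 4.
#' @param bottleneck_factor Bottleneck output = factor * k (4k).
#' @param head_widths Widths of the two dense head layers (128, 64).
#' @param n_classes Number of grades.
#' @param dropout Dropout rate in the head.
#' @param compression Transition-layer channel compression in (0, 1].
#' @param input_size Square input side.
#' @param in_channels Input planes (3, or 4 with a lesion-region plane).
#' @return A `densenet_config` list.
#' @export
densenet_config <- function(growth_rate = 8L, initial_channels = 16L,
                            layers_per_block = c(2L, 2L, 2L, 2L),
                            bottleneck_factor = 4L, head_widths = c(128L, 64L),
                            n_classes = 5L, dropout = 0.2, compression = 0.5,
                            input_size = 128L, in_channels = 3L) {
  if (length(layers_per_block) != 4L)
    stop("the architecture uses exactly 4 dense blocks", call. = FALSE)
  if (growth_rate < 1 || initial_channels < 1 || any(layers_per_block < 1))
    stop("growth rate, initial channels and block sizes must be positive",
         call. = FALSE)
  stopifnot(length(head_widths) == 2, dropout >= 0, dropout < 1,
            compression > 0, compression <= 1)
  if (input_size %% 32L != 0L)
    stop("input_size must be divisible by 32 (stem stride, pool, 3 transitions)",
         call. = FALSE)
  structure(list(growth_rate = as.integer(growth_rate),
                 initial_channels = as.integer(initial_channels),
                 layers_per_block = as.integer(layers_per_block),
                 bottleneck_factor = as.integer(bottleneck_factor),
                 head_widths = as.integer(head_widths),
                 n_classes = as.integer(n_classes), dropout = dropout,
                 compression = compression,
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels)),
            class = "densenet_config")
}

#' @rdname densenet_config
#' @export
densenet169_config <- function(input_size = 224L, in_channels = 3L) {
  densenet_config(growth_rate = 32L, initial_channels = 64L,
                  layers_per_block = c(6L, 12L, 32L, 32L),
                  input_size = input_size, in_channels = in_channels)
}

#' @rdname densenet_config
#' @export
desk_config <- function(input_size = 128L, in_channels = 3L) {
  densenet_config(input_size = input_size, in_channels = in_channels)
}

#' Build the dense-block grading network
#'
#' @param cfg A [densenet_config()].
#' @param seed Integer seed for initialisation.
#' @return A `densenet` object. Its `structure` element records, for every
#'   dense layer, the realised input channel count and the bottleneck output
#'   count (used by the architecture-fidelity tests).
#' @export
build_densenet <- function(cfg = densenet_config(), seed = 1L) {
  stopifnot(inherits(cfg, "densenet_config"))
  k <- cfg$growth_rate
  params <- list()
  struct <- list()
  with_seed(seed, {
    params$stem <- nn_conv_init(cfg$in_channels, cfg$initial_channels, 3L)
    ch <- cfg$initial_channels
    for (b in 1:4) {
      for (l in seq_len(cfg$layers_per_block[b])) {
        id <- paste0("b", b, "l", l)
        params[[paste0(id, "_bn1")]] <- nn_bn_init(ch)
        params[[paste0(id, "_cv1")]] <- nn_conv_init(ch, cfg$bottleneck_factor * k, 1L)
        params[[paste0(id, "_bn2")]] <- nn_bn_init(cfg$bottleneck_factor * k)
        params[[paste0(id, "_cv2")]] <- nn_conv_init(cfg$bottleneck_factor * k, k, 3L)
        struct[[id]] <- list(block = b, layer = l, in_channels = ch,
                              bottleneck_channels = cfg$bottleneck_factor * k,
                              out_channels = k)
        ch <- ch + k
      }
      if (b < 4) {
        tid <- paste0("t", b)
        out_ch <- max(1L, floor(ch * cfg$compression))
        params[[paste0(tid, "_bn")]] <- nn_bn_init(ch)
        params[[paste0(tid, "_cv")]] <- nn_conv_init(ch, out_ch, 1L)
        struct[[tid]] <- list(in_channels = ch, out_channels = out_ch)
        ch <- out_ch
      }
    }
    params$final_bn <- nn_bn_init(ch)
    params$fc1 <- nn_dense_init(ch, cfg$head_widths[1])
    params$fc2 <- nn_dense_init(cfg$head_widths[1], cfg$head_widths[2])
    params$fc_out <- nn_dense_init(cfg$head_widths[2], cfg$n_classes)
  })
  structure(list(params = params, config = cfg, structure = struct,
                 feature_channels = length(params$final_bn$gamma),
                 seed = seed, trained = FALSE),
            class = "densenet")
}

densenet_forward <- function(net, X, B, H, W, training = FALSE,
                             with_cache = FALSE) {
  cfg <- net$config
  p <- net$params
  ca <- list(bn_updates = list())
  # stem: conv stride 2, then 2x2 max pool
  st <- nn_conv_fw(X, B, H, W, p$stem, 3L, stride = 2L, pad = 1L)
  a0 <- nn_relu_fw(st$out)
  pool0 <- maxpool2_fwd(a0, B, st$H, st$W)
  if (with_cache) ca$stem <- list(f = st, pre = st$out, idx = pool0$idx,
                                  H = st$H, W = st$W)
  cur <- pool0$out; curH <- st$H %/% 2L; curW <- st$W %/% 2L
  for (b in 1:4) {
    for (l in seq_len(cfg$layers_per_block[b])) {
      id <- paste0("b", b, "l", l)
      bn1 <- nn_bn_fw(cur, p[[paste0(id, "_bn1")]], training)
      r1 <- nn_relu_fw(bn1$out)
      cv1 <- nn_conv_fw(r1, B, curH, curW, p[[paste0(id, "_cv1")]], 1L)
      bn2 <- nn_bn_fw(cv1$out, p[[paste0(id, "_bn2")]], training)
      r2 <- nn_relu_fw(bn2$out)
      cv2 <- nn_conv_fw(r2, B, curH, curW, p[[paste0(id, "_cv2")]], 3L)
      newcur <- cbind(cur, cv2$out)
      if (with_cache)
        ca[[id]] <- list(bn1 = bn1, r1pre = bn1$out, cv1 = cv1, bn2 = bn2,
                         r2pre = bn2$out, cv2 = cv2, in_ch = ncol(cur))
      ca$bn_updates[[paste0(id, "_bn1")]] <- list(rm = bn1$rm, rv = bn1$rv)
      ca$bn_updates[[paste0(id, "_bn2")]] <- list(rm = bn2$rm, rv = bn2$rv)
      cur <- newcur
    }
    if (b < 4) {
      tid <- paste0("t", b)
      bn <- nn_bn_fw(cur, p[[paste0(tid, "_bn")]], training)
      r <- nn_relu_fw(bn$out)
      cv <- nn_conv_fw(r, B, curH, curW, p[[paste0(tid, "_cv")]], 1L)
      ap <- avgpool2_fwd(cv$out, B, curH, curW)
      if (with_cache)
        ca[[tid]] <- list(bn = bn, rpre = bn$out, cv = cv, H = curH, W = curW)
      ca$bn_updates[[paste0(tid, "_bn")]] <- list(rm = bn$rm, rv = bn$rv)
      cur <- ap; curH <- curH %/% 2L; curW <- curW %/% 2L
    }
  }
  fbn <- nn_bn_fw(cur, p$final_bn, training)
  fr <- nn_relu_fw(fbn$out)
  ca$bn_updates$final_bn <- list(rm = fbn$rm, rv = fbn$rv)
  # global average pooling -> B x C
  npx <- curH * curW
  pooled <- rowsum(fr, rep(seq_len(B), each = npx), reorder = FALSE) / npx
  dimnames(pooled) <- NULL
  h1 <- sweep(pooled %*% p$fc1$W, 2, p$fc1$b, `+`)
  a1 <- h1 * (h1 > 0)
  d1 <- a1
  m1 <- NULL
  if (training && cfg$dropout > 0) {
    m1 <- matrix(runif(length(a1)) > cfg$dropout, nrow(a1)) / (1 - cfg$dropout)
    d1 <- a1 * m1
  }
  h2 <- sweep(d1 %*% p$fc2$W, 2, p$fc2$b, `+`)
  a2 <- h2 * (h2 > 0)
  d2 <- a2
  m2 <- NULL
  if (training && cfg$dropout > 0) {
    m2 <- matrix(runif(length(a2)) > cfg$dropout, nrow(a2)) / (1 - cfg$dropout)
    d2 <- a2 * m2
  }
  tz <- tanh(d2)
  logits <- sweep(tz %*% p$fc_out$W, 2, p$fc_out$b, `+`)
  prob <- nn_softmax(logits)
  if (with_cache)
    ca$head <- list(fbn = fbn, frpre = fbn$out, fr = fr, pooled = pooled,
                    h1 = h1, m1 = m1, d1 = d1, h2 = h2, m2 = m2, d2 = d2,
                    tz = tz, npx = curH * curW, H = curH, W = curW)
  list(prob = prob, cache = if (with_cache) ca else NULL,
       bn_updates = ca$bn_updates)
}

densenet_backward <- function(net, ca, dlogits) {
  cfg <- net$config
  p <- net$params
  g <- list()
  hd <- ca$head
  g$fc_out <- list(dW = crossprod(hd$tz, dlogits), db = colSums(dlogits))
  dtz <- dlogits %*% t(p$fc_out$W)
  dd2 <- dtz * (1 - hd$tz^2)
  da2 <- if (is.null(hd$m2)) dd2 else dd2 * hd$m2
  dh2 <- da2 * (hd$h2 > 0)
  g$fc2 <- list(dW = crossprod(hd$d1, dh2), db = colSums(dh2))
  dd1 <- dh2 %*% t(p$fc2$W)
  da1 <- if (is.null(hd$m1)) dd1 else dd1 * hd$m1
  dh1 <- da1 * (hd$h1 > 0)
  g$fc1 <- list(dW = crossprod(hd$pooled, dh1), db = colSums(dh1))
  dpooled <- dh1 %*% t(p$fc1$W)
  B <- nrow(dpooled)
  dfr <- dpooled[rep(seq_len(B), each = hd$npx), , drop = FALSE] / hd$npx
  dfbn <- nn_relu_bw(dfr, hd$frpre)
  bfbn <- nn_bn_bw(dfbn, p$final_bn, hd$fbn$cache)
  g$final_bn <- list(dgamma = bfbn$dgamma, dbeta = bfbn$dbeta)
  cur <- bfbn$dx
  for (b in 4:1) {
    if (b < 4) {
      tid <- paste0("t", b)
      cc <- ca[[tid]]
      dap <- avgpool2_bwd(cur, B, cc$H, cc$W)
      bcv <- nn_conv_bw(dap, p[[paste0(tid, "_cv")]], cc$cv$cache)
      g[[paste0(tid, "_cv")]] <- list(dW = bcv$dW, db = bcv$db)
      dr <- nn_relu_bw(bcv$dx, cc$rpre)
      bbn <- nn_bn_bw(dr, p[[paste0(tid, "_bn")]], cc$bn$cache)
      g[[paste0(tid, "_bn")]] <- list(dgamma = bbn$dgamma, dbeta = bbn$dbeta)
      cur <- bbn$dx
    }
    for (l in rev(seq_len(cfg$layers_per_block[b]))) {
      id <- paste0("b", b, "l", l)
      cc <- ca[[id]]
      nin <- cc$in_ch
      dprev <- cur[, seq_len(nin), drop = FALSE]
      dnew <- cur[, -seq_len(nin), drop = FALSE]
      bcv2 <- nn_conv_bw(dnew, p[[paste0(id, "_cv2")]], cc$cv2$cache)
      g[[paste0(id, "_cv2")]] <- list(dW = bcv2$dW, db = bcv2$db)
      dr2 <- nn_relu_bw(bcv2$dx, cc$r2pre)
      bbn2 <- nn_bn_bw(dr2, p[[paste0(id, "_bn2")]], cc$bn2$cache)
      g[[paste0(id, "_bn2")]] <- list(dgamma = bbn2$dgamma, dbeta = bbn2$dbeta)
      bcv1 <- nn_conv_bw(bbn2$dx, p[[paste0(id, "_cv1")]], cc$cv1$cache)
      g[[paste0(id, "_cv1")]] <- list(dW = bcv1$dW, db = bcv1$db)
      dr1 <- nn_relu_bw(bcv1$dx, cc$r1pre)
      bbn1 <- nn_bn_bw(dr1, p[[paste0(id, "_bn1")]], cc$bn1$cache)
      g[[paste0(id, "_bn1")]] <- list(dgamma = bbn1$dgamma, dbeta = bbn1$dbeta)
      cur <- dprev + bbn1$dx
    }
  }
  st <- ca$stem
  dpool <- maxpool2_bwd(cur, st$idx, as.numeric(B) * st$H * st$W)
  dst <- nn_relu_bw(dpool, st$pre)
  bst <- nn_conv_bw(dst, p$stem, st$f$cache)
  g$stem <- list(dW = bst$dW, db = bst$db)
  g
}

apply_bn_updates <- function(net, upd) {
  for (nm in names(upd)) {
    net$params[[nm]]$rm <- upd[[nm]]$rm
    net$params[[nm]]$rv <- upd[[nm]]$rv
  }
  net
}

#' Training configuration for the grading classifier
#'
#' The study's training recipe: Adam at learning rate 0.001, dropout 0.2,
#' Kullback-Leibler divergence loss on the softmax output, batch size 10,
#' 80 epochs, and a stratified 50/50 train/validation split.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Images per optimisation step.
#' @param epochs Training epochs.
#' @param val_fraction Validation share of the stratified split.
#' @param enhance Route images through [enhance_fundus()] first?
#' @param seed Integer seed (split, init, shuffling, dropout).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 10L,
                         epochs = 80L, val_fraction = 0.5, enhance = TRUE,
                         seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            val_fraction > 0, val_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), val_fraction = val_fraction,
                 enhance = isTRUE(enhance), seed = as.integer(seed)),
            class = "train_config")
}

load_training_images <- function(manifest, cfg, tcfg, regions = NULL) {
  sz <- cfg$input_size
  ecfg <- enhancement_config()
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_image(manifest$image[i])
    if (!all(dim(img)[1:2] == sz)) img <- resize_image(img, sz, sz)
    if (tcfg$enhance) img <- clip01(enhance_fundus(img, ecfg))
    fm <- img_to_fm(img)
    if (!is.null(regions)) {
      r <- regions[[i]]
      if (!all(dim(r) == sz)) r <- resize_image(r, sz, sz, "nearest")
      fm <- cbind(fm, as.numeric(as.vector(r) > 0))
    }
    fm
  })
}

#' Train the grading classifier
#'
#' Stratified seeded 50/50 train/validation split over the manifest, Adam
#' on the KL-divergence loss against one-hot grades, per-epoch loss and
#' accuracy curves, and a checkpoint of the best-validation-accuracy
#' weights. Images are routed through the enhancement stage first (pipeline
#' convention) and optionally conditioned on instance-segmentation output as
#' a fourth binary input plane.
#'
#' @param net A [build_densenet()] object.
#' @param manifest Dataset manifest tibble (columns image, grade).
#' @param tcfg A [train_config()].
#' @param regions Optional list of instance label maps aligned with the
#'   manifest rows (requires a 4-channel network).
#' @return An `hr_classifier` object: trained network, `curves` tibble
#'   (epoch, train_loss, val_loss, train_acc, val_acc), split indices.
#' @export
train_classifier <- function(net, manifest, tcfg = train_config(),
                             regions = NULL) {
  stopifnot(inherits(net, "densenet"), inherits(tcfg, "train_config"))
  cfg <- net$config
  n_ch_expect <- cfg$in_channels
  if (!is.null(regions) && n_ch_expect < 4L)
    stop("region conditioning needs a 4-channel network", call. = FALSE)
  grades <- manifest$grade
  if (length(unique(grades)) < cfg$n_classes)
    stop("every grade must be present in the manifest", call. = FALSE)
  xs <- load_training_images(manifest, cfg, tcfg, regions)
  if (ncol(xs[[1]]) != n_ch_expect)
    stop("input channel count does not match the network", call. = FALSE)
  sz <- cfg$input_size
  n <- nrow(manifest)
  split <- with_seed(tcfg$seed, {
    val <- unlist(lapply(split(seq_len(n), grades), function(ix)
      sample(ix, round(length(ix) * tcfg$val_fraction))))
    sort(val)
  })
  train_ix <- setdiff(seq_len(n), split)
  if (length(unique(grades[train_ix])) < cfg$n_classes)
    stop("a grade is absent from the training split", call. = FALSE)
  onehot <- matrix(0, n, cfg$n_classes)
  onehot[cbind(seq_len(n), grades + 1L)] <- 1

  flat <- flatten_params(net$params)
  st <- adam_init(flat)
  best <- list(acc = -1, params = NULL)
  curves <- vector("list", tcfg$epochs)
  eval_split <- function(ix) {
    probs <- matrix(0, length(ix), cfg$n_classes)
    bs <- 20L
    for (s in seq(1, length(ix), by = bs)) {
      sel <- ix[s:min(s + bs - 1L, length(ix))]
      fwd <- densenet_forward(net, stack_batch(xs[sel]), length(sel), sz, sz,
                              training = FALSE)
      probs[match(sel, ix), ] <- fwd$prob
    }
    list(loss = kld_loss(onehot[ix, , drop = FALSE], probs),
         acc = mean(max.col(probs) == grades[ix] + 1L))
  }
  with_seed(tcfg$seed + 1L, {
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample(train_ix)
      ep_loss <- 0; ep_hits <- 0
      for (s in seq(1, length(ord), by = tcfg$batch_size)) {
        sel <- ord[s:min(s + tcfg$batch_size - 1L, length(ord))]
        net$params <- unflatten_params(flat, net$params)
        fwd <- densenet_forward(net, stack_batch(xs[sel]), length(sel),
                                sz, sz, training = TRUE, with_cache = TRUE)
        net <- apply_bn_updates(net, fwd$bn_updates)
        tgt <- onehot[sel, , drop = FALSE]
        ep_loss <- ep_loss + kld_loss(tgt, fwd$prob) * length(sel)
        ep_hits <- ep_hits + sum(max.col(fwd$prob) == grades[sel] + 1L)
        dlogits <- (fwd$prob - tgt) / length(sel)
        g <- densenet_backward(net, fwd$cache, dlogits)
        upd <- adam_step(flat, flatten_params(g, grad = TRUE), st,
                         tcfg$learning_rate)
        flat <- upd$params; st <- upd$st
      }
      net$params <- unflatten_params(flat, net$params)
      va <- eval_split(split)
      if (va$acc > best$acc) best <- list(acc = va$acc, params = net$params)
      # train metrics are the running batch averages of the epoch
      curves[[ep]] <- tibble::tibble(epoch = ep,
                                     train_loss = ep_loss / length(ord),
                                     val_loss = va$loss,
                                     train_acc = ep_hits / length(ord),
                                     val_acc = va$acc)
    }
  })
  net$params <- best$params
  net$trained <- TRUE
  structure(list(net = net, curves = dplyr::bind_rows(curves),
                 val_indices = split, train_indices = train_ix,
                 tcfg = tcfg, best_val_acc = best$acc),
            class = "hr_classifier")
}

#' Predict the hypertensive-retinopathy grade of one image
#'
#' @param model An `hr_classifier` from [train_classifier()] (or a trained
#'   `densenet`).
#' @param image H x W x 3 array in [0, 1].
#' @param regions Optional `instance_labels` (or binary matrix); rendered as
#'   a binary lesion-presence plane concatenated as a fourth input channel.
#' @param enhance Route through [enhance_fundus()] first (default: the
#'   training convention).
#' @return A `grade_prediction`: `probabilities` (5-vector summing to 1) and
#'   `grade` (argmax, 0-4). Inference is deterministic (dropout off).
#' @export
predict_grade <- function(model, image, regions = NULL, enhance = NULL) {
  net <- if (inherits(model, "hr_classifier")) model$net else model
  stopifnot(inherits(net, "densenet"))
  if (!isTRUE(net$trained))
    stop("network is untrained; call train_classifier() first", call. = FALSE)
  cfg <- net$config
  sz <- cfg$input_size
  if (is.null(enhance))
    enhance <- if (inherits(model, "hr_classifier")) model$tcfg$enhance else TRUE
  img <- image
  if (!all(dim(img)[1:2] == sz)) img <- resize_image(img, sz, sz)
  if (enhance) img <- clip01(enhance_fundus(img))
  fm <- img_to_fm(img)
  if (!is.null(regions)) {
    r <- if (inherits(regions, "instance_labels")) regions$labels else regions
    if (!all(dim(r) == sz)) r <- resize_image(r, sz, sz, "nearest")
    fm <- cbind(fm, as.numeric(as.vector(r) > 0))
  }
  if (ncol(fm) != cfg$in_channels)
    stop("input channel count does not match the network", call. = FALSE)
  prob <- densenet_forward(net, fm, 1L, sz, sz, training = FALSE)$prob[1, ]
  structure(list(probabilities = as.numeric(prob),
                 grade = which.max(prob) - 1L),
            class = "grade_prediction")
}

#' @export
print.grade_prediction <- function(x, ...) {
  cat(sprintf("<grade_prediction> grade %d (p = %s)\n", x$grade,
              paste(sprintf("%.3f", x$probabilities), collapse = " ")))
  invisible(x)
}
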