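#' Build an encoder-decoder mask network
#'
#' A symmetric U-Net: each encoder level applies two 3 x 3 convolutions
#' (ReLU) and halves the resolution by max pooling; the decoder mirrors it
#' with nearest-neighbour upsampling and skip-connection concatenation, so
#' the sigmoid output mask has exactly the input's spatial size. Default
#' working resolution is 256 x 256.
#'
#' @param input_size Square input side; must be divisible by 2^depth.
#' @param depth Number of pooling levels.
#' @param base_channels Channels of the first encoder level (doubled per
#'   level).
#' @param in_channels Input planes.
#' @param seed Integer seed for initialisation.
#' @return A `unet` object.
#' @export
build_unet <- function(input_size = 256L, depth = 4L, base_channels = 16L,
                       in_channels = 3L, seed = 1L) {
  if (input_size %% (2^depth) != 0)
    stop("input_size must be divisible by 2^depth", call. = FALSE)
  widths <- base_channels * 2^(0:depth)
  params <- with_seed(seed, {
    p <- list()
    cin <- in_channels
    for (i in seq_len(depth)) {
      p[[paste0("e", i, "c1")]] <- nn_conv_init(cin, widths[i], 3L)
      p[[paste0("e", i, "c2")]] <- nn_conv_init(widths[i], widths[i], 3L)
      cin <- widths[i]
    }
    p$botc1 <- nn_conv_init(widths[depth], widths[depth + 1], 3L)
    p$botc2 <- nn_conv_init(widths[depth + 1], widths[depth + 1], 3L)
    for (i in rev(seq_len(depth))) {
      cin_up <- if (i == depth) widths[depth + 1] else widths[i + 1]
      p[[paste0("d", i, "c1")]] <- nn_conv_init(cin_up + widths[i], widths[i], 3L)
      p[[paste0("d", i, "c2")]] <- nn_conv_init(widths[i], widths[i], 3L)
    }
    p$out <- nn_conv_init(widths[1], 1L, 1L)
    p
  })
  structure(list(params = params, input_size = as.integer(input_size),
                 depth = as.integer(depth), base_channels = base_channels,
                 in_channels = in_channels, seed = seed, trained = FALSE),
            class = "unet")
}

unet_forward <- function(net, X, B, H, W, with_cache = FALSE) {
  p <- net$params
  ca <- list()
  skips <- list()
  cur <- X; curH <- H; curW <- W
  for (i in seq_len(net$depth)) {
    f1 <- nn_conv_fw(cur, B, curH, curW, p[[paste0("e", i, "c1")]], 3L)
    a1 <- nn_relu_fw(f1$out)
    f2 <- nn_conv_fw(a1, B, curH, curW, p[[paste0("e", i, "c2")]], 3L)
    a2 <- nn_relu_fw(f2$out)
    skips[[i]] <- a2
    pool <- maxpool2_fwd(a2, B, curH, curW)
    if (with_cache)
      ca[[paste0("e", i)]] <- list(f1 = f1, f2 = f2, pre1 = f1$out,
                                   pre2 = f2$out, idx = pool$idx,
                                   H = curH, W = curW)
    cur <- pool$out; curH <- curH %/% 2L; curW <- curW %/% 2L
  }
  fb1 <- nn_conv_fw(cur, B, curH, curW, p$botc1, 3L)
  ab1 <- nn_relu_fw(fb1$out)
  fb2 <- nn_conv_fw(ab1, B, curH, curW, p$botc2, 3L)
  ab2 <- nn_relu_fw(fb2$out)
  if (with_cache) ca$bot <- list(f1 = fb1, f2 = fb2, pre1 = fb1$out,
                                 pre2 = fb2$out, H = curH, W = curW)
  cur <- ab2
  for (i in rev(seq_len(net$depth))) {
    up <- upsample2_fwd(cur, B, curH, curW)
    curH <- 2L * curH; curW <- 2L * curW
    merged <- cbind(up, skips[[i]])
    f1 <- nn_conv_fw(merged, B, curH, curW, p[[paste0("d", i, "c1")]], 3L)
    a1 <- nn_relu_fw(f1$out)
    f2 <- nn_conv_fw(a1, B, curH, curW, p[[paste0("d", i, "c2")]], 3L)
    a2 <- nn_relu_fw(f2$out)
    if (with_cache)
      ca[[paste0("d", i)]] <- list(f1 = f1, f2 = f2, pre1 = f1$out,
                                   pre2 = f2$out, H = curH, W = curW,
                                   up_channels = ncol(up))
    cur <- a2
  }
  fo <- nn_conv_fw(cur, B, curH, curW, p$out, 1L)
  prob <- nn_sigmoid_fw(fo$out)
  if (with_cache) ca$out <- list(f = fo, prob = prob)
  list(prob = prob, cache = if (with_cache) ca else NULL)
}

unet_backward <- function(net, ca, dprob, B) {
  p <- net$params
  g <- list()
  skip_grads <- list()
  dz <- nn_sigmoid_bw(dprob, ca$out$prob)
  bo <- nn_conv_bw(dz, p$out, ca$out$f$cache)
  g$out <- list(dW = bo$dW, db = bo$db)
  cur <- bo$dx
  for (i in seq_len(net$depth)) {  # decoder levels, shallowest first
    cc <- ca[[paste0("d", i)]]
    d2 <- nn_relu_bw(cur, cc$pre2)
    b2 <- nn_conv_bw(d2, p[[paste0("d", i, "c2")]], cc$f2$cache)
    d1 <- nn_relu_bw(b2$dx, cc$pre1)
    b1 <- nn_conv_bw(d1, p[[paste0("d", i, "c1")]], cc$f1$cache)
    g[[paste0("d", i, "c1")]] <- list(dW = b1$dW, db = b1$db)
    g[[paste0("d", i, "c2")]] <- list(dW = b2$dW, db = b2$db)
    nup <- cc$up_channels
    skip_grads[[i]] <- b1$dx[, -seq_len(nup), drop = FALSE]
    cur <- upsample2_bwd(b1$dx[, seq_len(nup), drop = FALSE], B,
                         cc$H %/% 2L, cc$W %/% 2L)
  }
  cc <- ca$bot
  d2 <- nn_relu_bw(cur, cc$pre2)
  b2 <- nn_conv_bw(d2, p$botc2, cc$f2$cache)
  d1 <- nn_relu_bw(b2$dx, cc$pre1)
  b1 <- nn_conv_bw(d1, p$botc1, cc$f1$cache)
  g$botc1 <- list(dW = b1$dW, db = b1$db)
  g$botc2 <- list(dW = b2$dW, db = b2$db)
  cur <- b1$dx
  for (i in rev(seq_len(net$depth))) {  # encoder levels, deepest first
    cc <- ca[[paste0("e", i)]]
    dpool <- maxpool2_bwd(cur, cc$idx, as.numeric(B) * cc$H * cc$W)
    dtot <- dpool + skip_grads[[i]]
    d2 <- nn_relu_bw(dtot, cc$pre2)
    b2 <- nn_conv_bw(d2, p[[paste0("e", i, "c2")]], cc$f2$cache)
    d1 <- nn_relu_bw(b2$dx, cc$pre1)
    b1 <- nn_conv_bw(d1, p[[paste0("e", i, "c1")]], cc$f1$cache)
    g[[paste0("e", i, "c1")]] <- list(dW = b1$dW, db = b1$db)
    g[[paste0("e", i, "c2")]] <- list(dW = b2$dW, db = b2$db)
    cur <- b1$dx
  }
  g
}

# Dice + binary cross-entropy on sigmoid probabilities; returns loss and the
# gradient w.r.t. the probabilities.
dice_bce_loss <- function(prob, target, eps = 1e-6) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  n <- length(p)
  bce <- -mean(target * log(p) + (1 - target) * log(1 - p))
  inter <- sum(p * target)
  denom <- sum(p) + sum(target) + eps
  dice <- 1 - 2 * inter / denom
  dbce <- (p - target) / (p * (1 - p)) / n
  ddice <- -2 * (target * denom - inter) / denom^2
  list(loss = bce + dice, grad = dbce + ddice,
       dice = 2 * inter / denom)
}

#' Train the mask network
#'
#' Adam on a Dice + binary cross-entropy loss over (image, binary mask)
#' pairs. Images larger than the network's working resolution are resized
#' down (bilinear; masks nearest-neighbour).
#'
#' @param net A [build_unet()] object.
#' @param images List of H x W x C arrays.
#' @param masks List of aligned binary masks (0/1 matrices).
#' @param steps Optimisation steps.
#' @param batch_size Images per step.
#' @param lr Adam learning rate.
#' @param seed Integer seed (batch order).
#' @return The trained `unet`, with a `history` tibble of per-step loss and
#'   training Dice.
#' @export
train_unet <- function(net, images, masks, steps = 200L, batch_size = 2L,
                       lr = 1e-3, seed = 1L) {
  stopifnot(inherits(net, "unet"))
  sz <- net$input_size
  xs <- lapply(images, function(im) {
    if (!all(dim(im)[1:2] == sz)) im <- resize_image(im, sz, sz)
    img_to_fm(im)
  })
  ys <- lapply(masks, function(m) {
    if (!all(dim(m) == sz)) m <- resize_image(m, sz, sz, "nearest")
    as.numeric(as.vector(m) > 0)
  })
  flat <- flatten_params(net$params)
  st <- adam_init(flat)
  hist <- vector("list", steps)
  npx <- sz * sz
  with_seed(seed, {
    for (s in seq_len(steps)) {
      sel <- sample.int(length(xs), min(batch_size, length(xs)))
      B <- length(sel)
      net$params <- unflatten_params(flat, net$params)
      fwd <- unet_forward(net, stack_batch(xs[sel]), B, sz, sz,
                          with_cache = TRUE)
      dprob <- numeric(B * npx)
      loss <- 0; dice <- 0
      for (j in seq_len(B)) {
        rows <- ((j - 1L) * npx + 1L):(j * npx)
        l <- dice_bce_loss(fwd$prob[rows, 1], ys[[sel[j]]])
        loss <- loss + l$loss / B
        dice <- dice + l$dice / B
        dprob[rows] <- l$grad / B
      }
      g <- unet_backward(net, fwd$cache, matrix(dprob, ncol = 1), B)
      upd <- adam_step(flat, flatten_params(g, grad = TRUE), st, lr)
      flat <- upd$params; st <- upd$st
      hist[[s]] <- tibble::tibble(step = s, loss = loss, dice = dice)
    }
  })
  net$params <- unflatten_params(flat, net$params)
  net$trained <- TRUE
  net$history <- dplyr::bind_rows(hist)
  net
}

# flat named list <-> nested {layer}${W,b} structure shared by unet/densenet
flatten_params <- function(p, grad = FALSE) {
  out <- list()
  for (nm in names(p)) {
    if (grad) {
      if (!is.null(p[[nm]]$dW)) {
        out[[paste0(nm, ".W")]] <- p[[nm]]$dW
        out[[paste0(nm, ".b")]] <- p[[nm]]$db
      }
      if (!is.null(p[[nm]]$dgamma)) {
        out[[paste0(nm, ".gamma")]] <- p[[nm]]$dgamma
        out[[paste0(nm, ".beta")]] <- p[[nm]]$dbeta
      }
    } else {
      for (f in intersect(names(p[[nm]]), c("W", "b", "gamma", "beta")))
        out[[paste0(nm, ".", f)]] <- p[[nm]][[f]]
    }
  }
  out
}

unflatten_params <- function(flat, proto) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    proto[[parts[1]]][[parts[2]]] <- flat[[nm]]
  }
  proto
}

#' Predict a probability mask
#'
#' @param net A trained [build_unet()] object.
#' @param image H x W x C array; resized to the network's working resolution
#'   if needed, and the output upsampled back.
#' @return H x W matrix of probabilities in [0, 1].
#' @export
predict_prob_mask <- function(net, image) {
  stopifnot(inherits(net, "unet"))
  d0 <- dim(image)[1:2]
  sz <- net$input_size
  im <- if (!all(d0 == sz)) resize_image(image, sz, sz) else image
  pr <- unet_forward(net, img_to_fm(im), 1L, sz, sz)$prob
  m <- matrix(pr[, 1], sz, sz)
  if (!all(d0 == sz)) m <- resize_image(m, d0[1], d0[2])
  clip01(m)
}
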