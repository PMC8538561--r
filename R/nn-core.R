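# Minimal conv-net engine.
#
# A batch of B feature maps is ONE (B*H*W) x C matrix: image i occupies the
# row block [i*H*W, (i+1)*H*W), each block the column-major vectorisation of
# an H x W plane. Index shuffling (im2col/col2im, pooling, upsampling) is in
# C++; all matrix algebra goes through BLAS. Parameters live in flat named
# lists so a single Adam implementation serves every architecture.
# Correctness is pinned by numeric gradient checks in the test suite.

nn_conv_init <- function(cin, cout, k) {
  sd <- sqrt(2 / (cin * k * k))
  list(W = matrix(rnorm(cin * k * k * cout, 0, sd), cin * k * k, cout),
       b = rep(0, cout))
}

nn_dense_init <- function(din, dout) {
  sd <- sqrt(2 / din)
  list(W = matrix(rnorm(din * dout, 0, sd), din, dout), b = rep(0, dout))
}

nn_bn_init <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C), rm = rep(0, C), rv = rep(1, C))
}

# -- convolution -------------------------------------------------------------

nn_conv_fw <- function(X, B, H, W, prm, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  cols <- im2col_chw(X, B, H, W, k, stride, pad)
  out <- cols %*% prm$W
  out <- sweep(out, 2, prm$b, `+`)
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  list(out = out, H = Ho, W = Wo,
       cache = list(cols = cols, B = B, H = H, W = W, k = k, stride = stride,
                    pad = pad, cin = ncol(X)))
}

nn_conv_bw <- function(dY, prm, cache) {
  dW <- crossprod(cache$cols, dY)
  db <- colSums(dY)
  dcols <- dY %*% t(prm$W)
  dX <- col2im_chw(dcols, cache$B, cache$H, cache$W, cache$cin, cache$k,
                   cache$stride, cache$pad)
  list(dx = dX, dW = dW, db = db)
}

# -- batch normalisation (statistics over batch x spatial) ------------------

nn_bn_fw <- function(X, prm, training, momentum = 0.9, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    v <- colMeans(xc^2)
    rm <- momentum * prm$rm + (1 - momentum) * mu
    rv <- momentum * prm$rv + (1 - momentum) * v
  } else {
    mu <- prm$rm; v <- prm$rv
    xc <- sweep(X, 2, mu)
    rm <- prm$rm; rv <- prm$rv
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, ivar, `*`)
  out <- sweep(sweep(xhat, 2, prm$gamma, `*`), 2, prm$beta, `+`)
  list(out = out, rm = rm, rv = rv,
       cache = list(xhat = xhat, ivar = ivar, training = training))
}

nn_bn_bw <- function(dY, prm, cache) {
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  N <- nrow(dY)
  if (cache$training) {
    dxhat <- sweep(dY, 2, prm$gamma, `*`)
    t1 <- sweep(dxhat, 2, colSums(dxhat) / N)
    t2 <- sweep(cache$xhat, 2, colSums(dxhat * cache$xhat) / N, `*`)
    dX <- sweep(t1 - t2, 2, cache$ivar, `*`)
  } else {
    dX <- sweep(sweep(dY, 2, prm$gamma, `*`), 2, cache$ivar, `*`)
  }
  list(dx = dX, dgamma = dgamma, dbeta = dbeta)
}

# -- activations ------------------------------------------------------------

nn_relu_fw <- function(x) x * (x > 0)
nn_relu_bw <- function(d, x) d * (x > 0)
nn_sigmoid_fw <- function(x) 1 / (1 + exp(-x))
nn_sigmoid_bw <- function(d, s) d * s * (1 - s)

# -- softmax / losses --------------------------------------------------------

nn_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Kullback-Leibler divergence loss
#'
#' Mean over rows of `sum_i t_i * log(t_i / p_i)` for target and predicted
#' probability vectors; equals cross-entropy minus the target entropy, hence
#' zero iff the distributions coincide and non-negative otherwise (Gibbs'
#' inequality). Predictions are clipped below at 1e-7 before the log.
#'
#' @param target,predicted Probability vectors or row-wise probability
#'   matrices on the simplex (rows sum to 1 within 1e-6).
#' @return Non-negative scalar, in nats.
#' @export
kld_loss <- function(target, predicted) {
  t <- if (is.matrix(target)) target else matrix(target, 1)
  p <- if (is.matrix(predicted)) predicted else matrix(predicted, 1)
  if (!all(dim(t) == dim(p)))
    stop("target and predicted must have identical shapes", call. = FALSE)
  check_simplex <- function(m, what) {
    if (anyNA(m) || min(m) < -1e-9 || any(abs(rowSums(m) - 1) > 1e-6))
      stop(sprintf("%s rows must be probability vectors summing to 1", what),
           call. = FALSE)
  }
  check_simplex(t, "target"); check_simplex(p, "predicted")
  p <- pmax(p, 1e-7)
  tl <- ifelse(t > 0, t * (log(pmax(t, 1e-300)) - log(p)), 0)
  mean(rowSums(tl))
}

# -- Adam over a flat named list of parameter tensors ------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, st = st)
}

# image array (H x W x C) <-> feature-map matrix
img_to_fm <- function(img) {
  if (is.matrix(img)) return(matrix(as.vector(img), ncol = 1))
  d <- dim(img)
  matrix(img, d[1] * d[2], d[3])
}
fm_to_img <- function(fm, H, W) array(fm, c(H, W, ncol(fm)))

# stack a list of per-image feature maps into the batch representation
stack_batch <- function(xs) do.call(rbind, xs)
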