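# The conv engine is pinned by (a) a naive direct-convolution oracle and
# (b) numeric gradient checks through every layer type.

naive_conv <- function(X, H, W, Wt, b, k, stride = 1, pad = (k - 1) %/% 2) {
  cin <- ncol(X); Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  out <- matrix(0, Ho * Wo, ncol(Wt))
  A <- array(X, c(H, W, cin))
  for (yo in 1:Ho) for (xo in 1:Wo) {
    v <- numeric(cin * k * k)
    for (c in 1:cin) for (kx in 1:k) for (ky in 1:k) {
      y <- (yo - 1) * stride + ky - pad
      x <- (xo - 1) * stride + kx - pad
      v[(c - 1) * k * k + (kx - 1) * k + ky] <-
        if (y >= 1 && y <= H && x >= 1 && x <= W) A[y, x, c] else 0
    }
    out[yo + (xo - 1) * Ho, ] <- v %*% Wt + b
  }
  out
}

test_that("batched im2col convolution matches direct convolution", {
  set.seed(51)
  for (cfg in list(c(6, 5, 3, 1), c(8, 8, 3, 2), c(7, 9, 1, 1), c(6, 6, 5, 1))) {
    H <- cfg[1]; W <- cfg[2]; k <- cfg[3]; s <- cfg[4]
    X1 <- matrix(rnorm(H * W * 2), H * W, 2)
    X2 <- matrix(rnorm(H * W * 2), H * W, 2)
    prm <- fundushr:::nn_conv_init(2L, 3L, k)
    pad <- (k - 1) %/% 2
    fw <- fundushr:::nn_conv_fw(rbind(X1, X2), 2L, H, W, prm, as.integer(k),
                                stride = as.integer(s), pad = as.integer(pad))
    oracle <- rbind(naive_conv(X1, H, W, prm$W, prm$b, k, s, pad),
                    naive_conv(X2, H, W, prm$W, prm$b, k, s, pad))
    expect_lt(max(abs(fw$out - oracle)), 1e-12)
  }
})

test_that("col2im is the exact adjoint of im2col", {
  set.seed(52)
  X <- matrix(rnorm(2 * 8 * 8 * 4), 2 * 64, 4)
  A <- fundushr:::im2col_chw(X, 2L, 8L, 8L, 3L, 1L, 1L)
  Y <- matrix(rnorm(length(A)), nrow(A))
  lhs <- sum(A * Y)
  rhs <- sum(X * fundushr:::col2im_chw(Y, 2L, 8L, 8L, 4L, 3L, 1L, 1L))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("pooling and upsampling are exact adjoint pairs", {
  set.seed(53)
  X <- matrix(rnorm(2 * 64 * 3), 2 * 64, 3)
  mp <- fundushr:::maxpool2_fwd(X, 2L, 8L, 8L)
  dY <- matrix(rnorm(length(mp$out)), nrow(mp$out))
  dX <- fundushr:::maxpool2_bwd(dY, mp$idx, nrow(X))
  expect_equal(sum(mp$out * dY), sum(X * dX), tolerance = 1e-10)
  ap <- fundushr:::avgpool2_fwd(X, 2L, 8L, 8L)
  dXa <- fundushr:::avgpool2_bwd(dY, 2L, 8L, 8L)
  expect_equal(sum(ap * dY), sum(X * dXa), tolerance = 1e-10)
  up <- fundushr:::upsample2_fwd(X, 2L, 8L, 8L)
  dYu <- matrix(rnorm(length(up)), nrow(up))
  dXu <- fundushr:::upsample2_bwd(dYu, 2L, 8L, 8L)
  expect_equal(sum(up * dYu), sum(X * dXu), tolerance = 1e-10)
})

test_that("batch-norm backward matches numeric gradients", {
  set.seed(54)
  C <- 3; X <- matrix(rnorm(40 * C), 40, C)
  prm <- fundushr:::nn_bn_init(C)
  prm$gamma <- runif(C, 0.5, 1.5); prm$beta <- rnorm(C)
  loss <- function(Xi) sum(fundushr:::nn_bn_fw(Xi, prm, TRUE)$out^3)
  f <- fundushr:::nn_bn_fw(X, prm, TRUE)
  bw <- fundushr:::nn_bn_bw(3 * f$out^2, prm, f$cache)
  eps <- 1e-6
  for (rep in 1:8) {
    ii <- sample(length(X), 1)
    X2 <- X; X2[ii] <- X2[ii] + eps
    num <- (loss(X2) - loss(X)) / eps
    expect_equal(bw$dx[ii], num, tolerance = 1e-3)
  }
})

test_that("whole-network gradients match finite differences", {
  cfg <- densenet_config(growth_rate = 2L, initial_channels = 4L,
                         layers_per_block = c(1L, 1L, 1L, 1L),
                         head_widths = c(6L, 4L), input_size = 32L,
                         dropout = 0)
  net <- build_densenet(cfg, seed = 2)
  set.seed(55)
  B <- 2L; X <- matrix(runif(B * 32 * 32 * 3), B * 1024, 3)
  Tm <- matrix(0, B, 5); Tm[cbind(1:B, c(2, 4))] <- 1
  loss_of <- function(params) {
    net$params <- params
    fw <- fundushr:::densenet_forward(net, X, B, 32L, 32L, training = TRUE)
    kld_loss(Tm, fw$prob)
  }
  fw <- fundushr:::densenet_forward(net, X, B, 32L, 32L, training = TRUE,
                                    with_cache = TRUE)
  g <- fundushr:::densenet_backward(net, fw$cache, (fw$prob - Tm) / B)
  gf <- fundushr:::flatten_params(g, grad = TRUE)
  pf <- fundushr:::flatten_params(net$params)
  eps <- 1e-6
  base <- loss_of(net$params)
  for (nm in sample(names(gf), 10)) {
    ii <- sample(length(gf[[nm]]), 1)
    flat2 <- pf; flat2[[nm]][ii] <- flat2[[nm]][ii] + eps
    num <- (loss_of(fundushr:::unflatten_params(flat2, net$params)) - base) / eps
    ana <- gf[[nm]][ii]
    expect_lt(abs(num - ana) / max(1e-4, abs(num), abs(ana)), 2e-2)
  }
})
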