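# The bundled network engine is the package's own primitive, so its
# convolution kernels and end-to-end gradients are checked against
# independent oracles (direct nested-loop convolution; central finite
# differences).

naive_conv <- function(x, w, b, stride, pad) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; N <- dim(x)[4]
  k <- dim(w)[1]; nf <- dim(w)[4]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  y <- array(0, c(Ho, Wo, nf, N))
  for (n in 1:N) for (f in 1:nf) for (i in 1:Ho) for (j in 1:Wo) {
    acc <- b[f]
    for (c in 1:C) for (ki in 1:k) for (kj in 1:k) {
      hi <- (i - 1) * stride + ki - pad
      wj <- (j - 1) * stride + kj - pad
      if (hi >= 1 && hi <= H && wj >= 1 && wj <= W) {
        acc <- acc + x[hi, wj, c, n] * w[ki, kj, c, f]
      }
    }
    y[i, j, f, n] <- acc
  }
  y
}

test_that("convolution forward matches a direct nested-loop oracle", {
  set.seed(1)
  x <- array(rnorm(7 * 6 * 2 * 3), c(7, 6, 2, 3))
  w <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  b <- rnorm(4)
  expect_lt(max(abs(echodl:::nn_conv_fwd(x, w, b, 1L, 1L) -
                      naive_conv(x, w, b, 1, 1))), 1e-12)
  x2 <- array(rnorm(9 * 8 * 2 * 2), c(9, 8, 2, 2))
  expect_lt(max(abs(echodl:::nn_conv_fwd(x2, w, b, 2L, 1L) -
                      naive_conv(x2, w, b, 2, 1))), 1e-12)
})

test_that("2x2 pooling matches a hand computation and floors odd dims", {
  x <- array(0, c(3, 4, 1, 1))
  x[, , 1, 1] <- matrix(c(1, 2, 3, 4,
                          5, 6, 7, 8,
                          9, 10, 11, 12), 3, 4, byrow = TRUE)
  mx <- echodl:::nn_pool_fwd(x, 0L)$y
  av <- echodl:::nn_pool_fwd(x, 1L)$y
  expect_equal(dim(mx), c(1L, 2L, 1L, 1L))
  expect_equal(as.vector(mx), c(6, 8))
  expect_equal(as.vector(av), c(3.5, 5.5))
})

test_that("batch norm standardises each channel in training mode", {
  set.seed(2)
  l <- echodl:::nn_bn(3L)
  x <- array(rnorm(6 * 5 * 3 * 4, mean = 2, sd = 3), c(6, 5, 3, 4))
  y <- echodl:::layer_forward(l, x, training = TRUE)
  for (c in 1:3) {
    expect_lt(abs(mean(y[, , c, ])), 1e-8)
    expect_lt(abs(mean(y[, , c, ]^2) - 1), 1e-3)
  }
})

test_that("end-to-end CNN gradients agree with central finite differences", {
  cfg <- cnn_config(8, 8, list(list(n_convs = 1L, filters = 3L, filter_size = 3L),
                               list(n_convs = 1L, filters = 4L, filter_size = 3L)),
                    pooling = "max", fc_sizes = 5L, dropout_rate = 0,
                    l2_strength = 0, n_classes = 3L)
  m <- build_cnn(cfg, seed = 42)
  set.seed(43)
  xb <- array(runif(8 * 8 * 1 * 4), c(8, 8, 1, 4))
  yb <- c(0L, 1L, 2L, 1L)
  loss <- function() {
    logits <- echodl:::cnn_forward(m, xb, training = TRUE)
    echodl:::softmax_ce(echodl:::softmax_cols(logits), yb)$loss
  }
  logits <- echodl:::cnn_forward(m, xb, training = TRUE)
  ce <- echodl:::softmax_ce(echodl:::softmax_cols(logits), yb)
  echodl:::cnn_backward(m, ce$dlogits)
  layers <- echodl:::cnn_layers(m)
  for (li in c(1, 2, 5, 8)) {
    l <- layers[[li]]
    if (length(l$params) == 0) next
    for (p in l$params) {
      i <- sample(length(l[[p]]), 1)
      eps <- 1e-6
      orig <- l[[p]][i]
      l[[p]][i] <- orig + eps; lp <- loss()
      l[[p]][i] <- orig - eps; lm <- loss()
      l[[p]][i] <- orig
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - l$g[[p]][i]) / max(1e-6, abs(num) + abs(l$g[[p]][i])),
                1e-3)
    }
  }
})

test_that("transposed convolution is the exact adjoint of convolution", {
  # <conv(x), y> == <x, convT(y)> for matching weights
  set.seed(3)
  w <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))  # conv: 2 ch -> 3 ch
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  y <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  cx <- echodl:::nn_conv_fwd(x, w, numeric(3), 2L, 1L)        # (4,4,3,2)
  ty <- echodl:::nn_conv_bwd_data(y, w, 2L, 1L, 8L, 8L)       # (8,8,2,2)
  expect_equal(sum(cx * y), sum(x * ty), tolerance = 1e-10)
})
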