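# Layer primitives for the bundled CPU network engine.
#
# Activations are stored column-major as array(H, W, C, N) for spatial layers
# and matrix(units, N) for dense layers. Each layer is a mutable environment
# holding its parameters, gradients (in $g) and Adam state (in $adam); the
# forward pass caches whatever the backward pass needs. All randomness
# (weight init, dropout masks) is drawn from R's RNG so that set.seed() makes
# whole training runs reproducible on one thread.

new_layer <- function(type, class) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$params <- character(0)
  l$trainable <- TRUE
  l$g <- list()
  l$adam <- list()
  class(l) <- c(class, "nn_layer")
  l
}

#' @noRd
nn_conv <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L) {
  l <- new_layer("conv", "nn_conv")
  l$k <- as.integer(k); l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  l$in_ch <- in_ch; l$out_ch <- out_ch
  sd <- sqrt(2 / (k * k * in_ch))  # He init for ReLU-family trunks
  l$W <- array(stats::rnorm(k * k * in_ch * out_ch, 0, sd), c(k, k, in_ch, out_ch))
  l$b <- numeric(out_ch)
  l$params <- c("W", "b")
  l
}

# Transposed convolution (stride-2 learnable upsampling). Weights follow the
# underlying convolution's layout (k, k, out_ch, in_ch), so forward is the
# convolution's backward-data pass and vice versa.
#' @noRd
nn_convT <- function(in_ch, out_ch, k = 4L, stride = 2L, pad = 1L) {
  l <- new_layer("convT", "nn_convT")
  l$k <- as.integer(k); l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  l$in_ch <- in_ch; l$out_ch <- out_ch
  sd <- sqrt(2 / (k * k * in_ch))
  l$W <- array(stats::rnorm(k * k * out_ch * in_ch, 0, sd), c(k, k, out_ch, in_ch))
  l$b <- numeric(out_ch)
  l$params <- c("W", "b")
  l
}

#' @noRd
nn_bn <- function(ch, spatial = TRUE, momentum = 0.9, eps = 1e-5) {
  l <- new_layer("bn", "nn_bn")
  l$spatial <- spatial; l$momentum <- momentum; l$eps <- eps
  l$gamma <- rep(1, ch); l$beta <- numeric(ch)
  l$run_mean <- numeric(ch); l$run_var <- rep(1, ch)
  l$params <- c("gamma", "beta")
  l
}

#' @noRd
nn_act <- function(kind = c("relu", "leaky", "tanh"), slope = 0.2) {
  l <- new_layer("act", "nn_act")
  l$kind <- match.arg(kind); l$slope <- slope
  l
}

#' @noRd
nn_pool <- function(mode = c("max", "average")) {
  l <- new_layer("pool", "nn_pool")
  l$mode <- match.arg(mode)
  l
}

#' @noRd
nn_dropout <- function(rate) {
  l <- new_layer("dropout", "nn_dropout")
  l$rate <- rate
  l
}

#' @noRd
nn_flatten <- function() new_layer("flatten", "nn_flatten")

#' @noRd
nn_dense <- function(in_dim, out_dim, l2 = 0, init = c("he", "xavier")) {
  l <- new_layer("dense", "nn_dense")
  init <- match.arg(init)
  if (init == "he") {
    l$W <- matrix(stats::rnorm(out_dim * in_dim, 0, sqrt(2 / in_dim)), out_dim, in_dim)
  } else {
    lim <- sqrt(6 / (in_dim + out_dim))
    l$W <- matrix(stats::runif(out_dim * in_dim, -lim, lim), out_dim, in_dim)
  }
  l$b <- numeric(out_dim)
  l$l2 <- l2
  l$params <- c("W", "b")
  l
}

layer_forward <- function(l, x, training = FALSE) {
  switch(l$type,
    conv = {
      l$x <- x
      nn_conv_fwd(x, l$W, l$b, l$stride, l$pad)
    },
    convT = {
      l$x <- x
      d <- dim(x)
      ho <- l$stride * (d[1] - 1L) - 2L * l$pad + l$k
      wo <- l$stride * (d[2] - 1L) - 2L * l$pad + l$k
      y <- nn_conv_bwd_data(x, l$W, l$stride, l$pad, ho, wo)
      sweep(y, 3, l$b, "+")
    },
    bn = bn_forward(l, x, training),
    act = {
      l$x <- x
      switch(l$kind,
        relu = pmax(x, 0),
        leaky = {
          y <- x
          neg <- x < 0
          y[neg] <- l$slope * x[neg]
          y
        },
        tanh = {
          l$y <- tanh(x)
          l$y
        }
      )
    },
    pool = {
      d <- dim(x)
      l$in_h <- d[1]; l$in_w <- d[2]
      r <- nn_pool_fwd(x, if (l$mode == "max") 0L else 1L)
      if (l$mode == "max") l$idx <- r$idx
      r$y
    },
    dropout = {
      if (!training || l$rate <= 0) {
        l$mask <- NULL
        return(x)
      }
      keep <- 1 - l$rate
      l$mask <- (stats::runif(length(x)) < keep) / keep
      dim(l$mask) <- dim(x)
      x * l$mask
    },
    flatten = {
      l$in_dim <- dim(x)
      y <- x
      dim(y) <- c(prod(l$in_dim[-length(l$in_dim)]), l$in_dim[length(l$in_dim)])
      y
    },
    dense = {
      l$x <- x
      l$W %*% x + l$b
    },
    stop("unknown layer type: ", l$type)
  )
}

layer_backward <- function(l, dy) {
  switch(l$type,
    conv = {
      gw <- nn_conv_bwd_w(l$x, dy, l$k, l$stride, l$pad)
      l$g <- list(W = gw$dW, b = gw$db)
      d <- dim(l$x)
      nn_conv_bwd_data(dy, l$W, l$stride, l$pad, d[1], d[2])
    },
    convT = {
      # forward was the conv backward-data map, so gradients swap roles
      r <- nn_convT_bwd(dy, l$W, l$x, l$stride, l$pad)
      l$g <- list(W = r$dW, b = r$db)
      r$dx
    },
    bn = bn_backward(l, dy),
    act = switch(l$kind,
      relu = dy * (l$x > 0),
      leaky = {
        g <- dy
        neg <- l$x < 0
        g[neg] <- l$slope * dy[neg]
        g
      },
      tanh = dy * (1 - l$y^2)
    ),
    pool = nn_pool_bwd(dy, if (l$mode == "max") l$idx else NULL,
                       l$in_h, l$in_w, if (l$mode == "max") 0L else 1L),
    dropout = if (is.null(l$mask)) dy else dy * l$mask,
    flatten = {
      dx <- dy
      dim(dx) <- l$in_dim
      dx
    },
    dense = {
      dW <- dy %*% t(l$x)
      if (l$l2 > 0) dW <- dW + l$l2 * l$W
      l$g <- list(W = dW, b = rowSums(dy))
      t(l$W) %*% dy
    },
    stop("unknown layer type: ", l$type)
  )
}

bn_forward <- function(l, x, training) {
  if (l$spatial) {
    nch <- length(l$gamma)
    if (training) {
      st <- nn_bn_stats(x)
      m <- st$mean; v <- st$var
      if (!isTRUE(l$freeze_stats)) {
        l$run_mean <- l$momentum * l$run_mean + (1 - l$momentum) * m
        l$run_var <- l$momentum * l$run_var + (1 - l$momentum) * v
      }
      istd <- 1 / sqrt(v + l$eps)
      xh <- nn_bn_apply(x, m, istd, numeric(nch))
      l$xh <- xh; l$istd <- istd
      nn_bn_apply(xh, numeric(nch), l$gamma, l$beta)
    } else {
      istd <- 1 / sqrt(l$run_var + l$eps)
      nn_bn_apply(x, l$run_mean, l$gamma * istd, l$beta)
    }
  } else {
    if (training) {
      m <- rowMeans(x)
      v <- rowMeans(sweep(x, 1, m)^2)
      if (!isTRUE(l$freeze_stats)) {
        l$run_mean <- l$momentum * l$run_mean + (1 - l$momentum) * m
        l$run_var <- l$momentum * l$run_var + (1 - l$momentum) * v
      }
    } else {
      m <- l$run_mean; v <- l$run_var
    }
    istd <- 1 / sqrt(v + l$eps)
    xh <- sweep(x, 1, m) * istd
    if (training) { l$xh <- xh; l$istd <- istd }
    xh * l$gamma + l$beta
  }
}

bn_backward <- function(l, dy) {
  if (l$spatial) {
    st <- nn_bn_bwd_stats(dy, l$xh)
    cnt <- length(dy) / length(l$gamma)
    dgamma <- st$sum_dyxh
    dbeta <- st$sum_dy
    dx <- nn_bn_bwd_apply(dy, l$xh, st$sum_dy / cnt, st$sum_dyxh / cnt,
                          l$gamma * l$istd)
  } else {
    dgamma <- rowSums(dy * l$xh)
    dbeta <- rowSums(dy)
    m_dy <- rowMeans(dy)
    m_dyxh <- rowMeans(dy * l$xh)
    dx <- (sweep(dy, 1, m_dy) - l$xh * m_dyxh) * (l$gamma * l$istd)
  }
  l$g <- list(gamma = dgamma, beta = dbeta)
  dx
}
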