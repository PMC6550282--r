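# Sequential network container, Adam optimiser, loss heads and parameter
# snapshot/restore for the bundled CPU engine.

nn_sequential <- function(layers) {
  structure(list(layers = layers), class = "nn_network")
}

net_forward <- function(net, x, training = FALSE) {
  for (l in net$layers) x <- layer_forward(l, x, training)
  x
}

net_backward <- function(net, dy) {
  for (l in rev(net$layers)) dy <- layer_backward(l, dy)
  dy
}

# One Adam update over every trainable layer. `t` is the 1-based global step
# used for bias correction.
adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) {
    if (!l$trainable || length(l$params) == 0) next
    for (p in l$params) {
      g <- l$g[[p]]
      if (is.null(g)) next
      st <- l$adam[[p]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      l[[p]] <- l[[p]] - lr * mh / (sqrt(vh) + eps)
      l$adam[[p]] <- st
    }
  }
  invisible(NULL)
}

# Deep copy of all parameters and batch-norm running statistics.
snapshot_params <- function(layers) {
  lapply(layers, function(l) {
    s <- lapply(l$params, function(p) l[[p]])
    names(s) <- l$params
    if (l$type == "bn") {
      s$run_mean <- l$run_mean
      s$run_var <- l$run_var
    }
    s
  })
}

restore_params <- function(layers, snap) {
  for (i in seq_along(layers)) {
    for (p in names(snap[[i]])) layers[[i]][[p]] <- snap[[i]][[p]]
  }
  invisible(NULL)
}

# Clone a layer (fresh environment, copied parameters, reset optimiser state).
clone_layer <- function(l) {
  l2 <- new.env(parent = emptyenv())
  for (nm in ls(l, all.names = TRUE)) {
    if (nm %in% c("adam", "g")) next
    v <- get(nm, envir = l)
    if (!is.environment(v)) assign(nm, v, envir = l2)
  }
  l2$g <- list()
  l2$adam <- list()
  class(l2) <- class(l)
  l2
}

LOG_EPS <- 1e-7

clamp_prob <- function(p) pmin(pmax(p, LOG_EPS), 1 - LOG_EPS)

# column-wise softmax of a (K x N) logit matrix
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Multiclass cross-entropy on (K x N) probabilities with 0-based labels.
# Returns loss (mean nats) and the gradient w.r.t. the logits.
softmax_ce <- function(probs, labels) {
  n <- ncol(probs)
  idx <- cbind(as.integer(labels) + 1L, seq_len(n))
  loss <- -mean(log(clamp_prob(probs[idx])))
  onehot <- matrix(0, nrow(probs), n)
  onehot[idx] <- 1
  list(loss = loss, dlogits = (probs - onehot) / n)
}
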