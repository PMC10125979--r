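# Minimal CNN layer framework with manual backpropagation.
#
# Activations are 4D arrays (H, W, C, N); the batch loop over N happens at
# the conv layers, which call the Rcpp im2col kernels. Each layer exposes a
# forward pass returning (y, cache) and a backward pass returning
# (dx, grads); a network is an ordered layer list and keeps no hidden state,
# so the same network can be run several times inside one training step
# (each forward returns its own tape).

rnorm_arr <- function(dims, sd = 0.02) {
  if (sd == 0) return(array(0, dim = dims))
  array(stats::rnorm(prod(dims), 0, sd), dim = dims)
}

layer_conv <- function(k, in_c, out_c, stride = 1L, pad = 0L,
                       pad_mode = c("zero", "reflect"), init_sd = 0.02) {
  pad_mode <- match.arg(pad_mode)
  list(type = "conv", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), pad_mode = if (pad_mode == "zero") 0L else 1L,
       W = rnorm_arr(c(k * k * in_c, out_c), init_sd), b = numeric(out_c))
}

layer_upconv <- function(k, in_c, out_c) {
  # fractionally-strided (transposed) convolution: zero-stuff 2x, then conv
  list(type = "upconv", k = as.integer(k),
       W = rnorm_arr(c(k * k * in_c, out_c)), b = numeric(out_c))
}

layer_inorm <- function(channels, eps = 1e-5) {
  list(type = "inorm", gamma = rep(1, channels), beta = numeric(channels),
       eps = eps)
}

layer_act <- function(type, alpha = 0.2) list(type = type, alpha = alpha)

layer_resblock <- function(channels) {
  list(type = "resblock", layers = list(
    layer_conv(3, channels, channels, 1, 1, "reflect"),
    layer_inorm(channels),
    layer_act("relu"),
    layer_conv(3, channels, channels, 1, 1, "reflect"),
    layer_inorm(channels)))
}

slice4 <- function(x, n) {
  d <- dim(x)
  array(x[, , , n], dim = d[1:3])
}

zero_stuff <- function(x) {
  d <- dim(x)
  out <- array(0, dim = c(2 * d[1], 2 * d[2], d[3], d[4]))
  out[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), , ] <- x
  out
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      y <- conv2d_forward_batch_cpp(x, layer$W, layer$b, layer$k,
                                    layer$stride, layer$pad, layer$pad_mode)
      list(y = y, cache = x)
    },
    upconv = {
      zs <- zero_stuff(x)
      y <- conv2d_forward_batch_cpp(zs, layer$W, layer$b, layer$k, 1L, 1L, 0L)
      list(y = y, cache = zs)
    },
    inorm = {
      d <- dim(x)
      hw <- d[1] * d[2]; cn <- d[3] * d[4]
      r <- inorm_forward_cpp(matrix(x, hw, cn), rep(layer$gamma, d[4]),
                             rep(layer$beta, d[4]), layer$eps)
      list(y = array(r$y, dim = d),
           cache = list(xhat = r$xhat, sd = as.numeric(r$sd), d = d))
    },
    relu = {
      pos <- x > 0
      list(y = x * pos, cache = pos)
    },
    lrelu = {
      pos <- x > 0
      list(y = x * (pos + layer$alpha * !pos), cache = pos)
    },
    tanh = {
      y <- tanh(x)
      list(y = y, cache = y)
    },
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(y = y, cache = y)
    },
    resblock = {
      r <- net_forward(layer, x)
      list(y = x + r$out, cache = r$tape)
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      g <- conv2d_backward_batch_cpp(cache, layer$W, dy, layer$k,
                                     layer$stride, layer$pad, layer$pad_mode)
      list(dx = g$dx, grads = list(W = g$dw, b = as.numeric(g$db)))
    },
    upconv = {
      d <- dim(cache)
      g <- conv2d_backward_batch_cpp(cache, layer$W, dy, layer$k, 1L, 1L, 0L)
      dx <- g$dx[seq(1, d[1], 2), seq(1, d[2], 2), , , drop = FALSE]
      list(dx = dx, grads = list(W = g$dw, b = as.numeric(g$db)))
    },
    inorm = {
      d <- cache$d
      hw <- d[1] * d[2]; cn <- d[3] * d[4]
      r <- inorm_backward_cpp(matrix(dy, hw, cn), cache$xhat, cache$sd,
                              rep(layer$gamma, d[4]))
      list(dx = array(r$dx, dim = d),
           grads = list(gamma = rowSums(matrix(as.numeric(r$dgamma), d[3], d[4])),
                        beta = rowSums(matrix(as.numeric(r$dbeta), d[3], d[4]))))
    },
    relu = list(dx = dy * cache, grads = NULL),
    lrelu = list(dx = dy * (cache + layer$alpha * !cache), grads = NULL),
    tanh = list(dx = dy * (1 - cache^2), grads = NULL),
    sigmoid = list(dx = dy * cache * (1 - cache), grads = NULL),
    resblock = {
      r <- net_backward(layer, cache, dy)
      list(dx = dy + r$dx, grads = r$grads)
    },
    stop("unknown layer type: ", layer$type))
}

# A "gated" network adds a bounded residual head on top of the layer trunk:
#   y = x + 0.5 * (1 - x^2) * tanh(u),   u = trunk(x)
# For any |x| <= 1 and any u this stays in [-1, 1] (|x| + 0.5(1 - x^2) <= 1),
# fixes the endpoints (air stays air), and with a zero-initialized trunk
# output layer the network starts as the exact identity map.
net_forward <- function(net, x) {
  tape <- vector("list", length(net$layers))
  x0 <- x
  for (i in seq_along(net$layers)) {
    r <- layer_forward(net$layers[[i]], x)
    tape[[i]] <- r$cache
    x <- r$y
  }
  if (isTRUE(net$gated)) {
    t <- tanh(x)
    y <- x0 + 0.5 * (1 - x0^2) * t
    return(list(out = y, tape = list(layers = tape, x0 = x0, t = t)))
  }
  list(out = x, tape = tape)
}

net_backward <- function(net, tape, dy) {
  if (isTRUE(net$gated)) {
    x0 <- tape$x0; t <- tape$t
    du <- dy * 0.5 * (1 - x0^2) * (1 - t^2)
    inner <- net_backward_layers(net, tape$layers, du)
    return(list(dx = inner$dx + dy * (1 - x0 * t), grads = inner$grads))
  }
  net_backward_layers(net, tape, dy)
}

net_backward_layers <- function(net, tape, dy) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    r <- layer_backward(net$layers[[i]], tape[[i]], dy)
    grads[i] <- list(r$grads)  # keep NULL slots for parameter-free layers
    dy <- r$dx
  }
  list(dx = dy, grads = grads)
}

net_predict <- function(net, x) net_forward(net, x)$out

# --- parameter bookkeeping ------------------------------------------------

param_names <- function(layer) {
  switch(layer$type,
         conv = c("W", "b"), upconv = c("W", "b"),
         inorm = c("gamma", "beta"), NULL)
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (i in seq_along(a)) {
    if (is.list(a[[i]]) && !is.null(a[[i]])) a[[i]] <- grads_add(a[[i]], b[[i]])
    else if (!is.null(b[[i]])) a[[i]] <- a[[i]] + b[[i]]
  }
  a
}

adam_init_layers <- function(layers) {
  lapply(layers, function(layer) {
    if (layer$type == "resblock") return(adam_init_layers(layer$layers))
    pn <- param_names(layer)
    if (is.null(pn)) return(NULL)
    st <- lapply(pn, function(p) list(m = layer[[p]] * 0, v = layer[[p]] * 0))
    names(st) <- pn
    st
  })
}

adam_init <- function(net) list(t = 0L, layers = adam_init_layers(net$layers))

adam_update_layers <- function(layers, grads, state, lr, beta1, beta2, eps, t) {
  for (i in seq_along(layers)) {
    layer <- layers[[i]]
    if (layer$type == "resblock") {
      r <- adam_update_layers(layer$layers, grads[[i]], state[[i]],
                              lr, beta1, beta2, eps, t)
      layer$layers <- r$layers
      state[[i]] <- r$state
      layers[[i]] <- layer
      next
    }
    pn <- param_names(layer)
    if (is.null(pn) || is.null(grads[[i]])) next
    for (p in pn) {
      g <- grads[[i]][[p]]
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layer[[p]] <- layer[[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
    layers[[i]] <- layer
  }
  list(layers = layers, state = state)
}

adam_step <- function(net, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  r <- adam_update_layers(net$layers, grads, state$layers, lr, beta1, beta2,
                          eps, state$t)
  net$layers <- r$layers
  state$layers <- r$state
  list(net = net, state = state)
}
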