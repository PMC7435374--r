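# Internal conv-net engine.
#
# Tensors are plain R arrays with dim = c(H, W, C, N); the heavy convolution
# kernels live in src/nn.cpp. A "net" is a list of layer lists; each layer
# carries its own parameters. All of this is internal plumbing behind the
# user-facing network constructors in networks.R.

nn_conv_layer <- function(in_ch, out_ch, k, stride = 1L,
                          pad = (k - 1L) %/% 2L, init_sd = 0.02) {
  list(type = "conv",
       w = array(stats::rnorm(k * k * in_ch * out_ch, 0, init_sd),
                 c(k, k, in_ch, out_ch)),
       b = numeric(out_ch),
       stride = as.integer(stride), pad = as.integer(pad))
}

nn_convt_layer <- function(in_ch, out_ch, k, stride = 2L, pad = 1L,
                           opad = 1L, init_sd = 0.02) {
  list(type = "convt",
       w = array(stats::rnorm(k * k * out_ch * in_ch, 0, init_sd),
                 c(k, k, out_ch, in_ch)),
       b = numeric(out_ch),
       stride = as.integer(stride), pad = as.integer(pad),
       opad = as.integer(opad))
}

nn_inorm_layer <- function() list(type = "inorm")
nn_relu_layer <- function() list(type = "relu")
nn_lrelu_layer <- function(slope = 0.2) list(type = "lrelu", slope = slope)
nn_sigmoid_layer <- function() list(type = "sigmoid")
nn_maxpool_layer <- function() list(type = "maxpool")

# residual block: x + IN(conv(ReLU(IN(conv(x)))))
nn_res_layer <- function(ch, k = 3L, init_sd = 0.02) {
  list(type = "res",
       body = list(nn_conv_layer(ch, ch, k, init_sd = init_sd),
                   nn_inorm_layer(), nn_relu_layer(),
                   nn_conv_layer(ch, ch, k, init_sd = init_sd),
                   nn_inorm_layer()))
}

nn_as_batch <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 4L)
  x
}

nn_inorm_fwd <- function(x) {
  d <- dim(x); hw <- d[1L] * d[2L]
  m <- matrix(x, hw)
  mu <- colMeans(m)
  xc <- m - rep(mu, each = hw)
  sdv <- sqrt(colMeans(xc^2) + 1e-5)
  y <- xc / rep(sdv, each = hw)
  list(out = array(y, d), cache = list(y = y, sdv = sdv, d = d))
}

nn_inorm_bwd <- function(cache, g) {
  d <- cache$d; hw <- d[1L] * d[2L]
  gm <- matrix(g, hw)
  y <- cache$y
  gc_ <- gm - rep(colMeans(gm), each = hw) - y * rep(colMeans(gm * y), each = hw)
  array(gc_ / rep(cache$sdv, each = hw), d)
}

nn_maxpool_fwd <- function(x) {
  d <- dim(x)
  He <- (d[1L] %/% 2L) * 2L; We <- (d[2L] %/% 2L) * 2L
  i1 <- seq(1L, He, 2L); i2 <- seq(2L, He, 2L)
  j1 <- seq(1L, We, 2L); j2 <- seq(2L, We, 2L)
  a <- x[i1, j1, , , drop = FALSE]; b <- x[i2, j1, , , drop = FALSE]
  cc <- x[i1, j2, , , drop = FALSE]; dd <- x[i2, j2, , , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  list(out = out, cache = list(d = d, a = a, b = b, cc = cc, dd = dd, out = out))
}

nn_maxpool_bwd <- function(cache, g) {
  d <- cache$d
  gx <- array(0, d)
  He <- (d[1L] %/% 2L) * 2L; We <- (d[2L] %/% 2L) * 2L
  i1 <- seq(1L, He, 2L); i2 <- seq(2L, He, 2L)
  j1 <- seq(1L, We, 2L); j2 <- seq(2L, We, 2L)
  taken <- cache$a == cache$out
  gx[i1, j1, , ] <- g * taken
  rem <- !taken
  m <- (cache$b == cache$out) & rem
  gx[i2, j1, , ] <- g * m; rem <- rem & !m
  m <- (cache$cc == cache$out) & rem
  gx[i1, j2, , ] <- g * m; rem <- rem & !m
  m <- (cache$dd == cache$out) & rem
  gx[i2, j2, , ] <- g * m
  gx
}

nn_layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = list(out = .nn_conv_fwd(x, layer$w, layer$b, layer$stride, layer$pad),
                cache = x),
    convt = list(out = .nn_convt_fwd(x, layer$w, layer$b, layer$stride,
                                     layer$pad, layer$opad),
                 cache = x),
    inorm = nn_inorm_fwd(x),
    relu = {
      mask <- x > 0
      out <- x; out[!mask] <- 0
      list(out = out, cache = mask)
    },
    lrelu = {
      mask <- x > 0
      out <- x; out[!mask] <- layer$slope * x[!mask]
      list(out = out, cache = mask)
    },
    sigmoid = {
      out <- 1 / (1 + exp(-x))
      list(out = out, cache = out)
    },
    maxpool = nn_maxpool_fwd(x),
    res = {
      h <- nn_net_forward(layer$body, x)
      list(out = x + h$out, cache = h$caches)
    },
    stop("unknown layer type: ", layer$type)
  )
}

nn_layer_backward <- function(layer, cache, g) {
  switch(layer$type,
    conv = {
      r <- .nn_conv_bwd(cache, layer$w, g, layer$stride, layer$pad)
      list(gx = r$gx, grad = list(w = r$gw, b = r$gb))
    },
    convt = {
      r <- .nn_convt_bwd(cache, layer$w, g, layer$stride, layer$pad, layer$opad)
      list(gx = r$gx, grad = list(w = r$gw, b = r$gb))
    },
    inorm = list(gx = nn_inorm_bwd(cache, g), grad = NULL),
    relu = list(gx = g * cache, grad = NULL),
    lrelu = {
      gx <- g
      gx[!cache] <- layer$slope * g[!cache]
      list(gx = gx, grad = NULL)
    },
    sigmoid = list(gx = g * cache * (1 - cache), grad = NULL),
    maxpool = list(gx = nn_maxpool_bwd(cache, g), grad = NULL),
    res = {
      bw <- nn_net_backward(layer$body, cache, g)
      list(gx = bw$gx + g, grad = bw$grads)
    },
    stop("unknown layer type: ", layer$type)
  )
}

nn_net_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- nn_layer_forward(layers[[i]], x)
    caches[[i]] <- r$cache
    x <- r$out
  }
  list(out = x, caches = caches)
}

nn_net_backward <- function(layers, caches, g) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- nn_layer_backward(layers[[i]], caches[[i]], g)
    grads[i] <- list(r$grad)   # keep NULL slots for param-free layers
    g <- r$gx
  }
  list(gx = g, grads = grads)
}

# forward without keeping caches (inference)
nn_net_apply <- function(layers, x) {
  for (layer in layers) x <- nn_layer_forward(layer, x)$out
  x
}

nn_has_params <- function(layer) layer$type %in% c("conv", "convt")

nn_adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (nn_has_params(l)) {
      list(mw = array(0, dim(l$w)), vw = array(0, dim(l$w)),
           mb = numeric(length(l$b)), vb = numeric(length(l$b)))
    } else if (l$type == "res") {
      nn_adam_init(l$body)
    } else NULL
  })
}

nn_adam_step <- function(layers, grads, state, lr, b1 = 0.5, b2 = 0.999,
                         eps = 1e-8, t = 1L) {
  corr <- lr * sqrt(1 - b2^t) / (1 - b1^t)
  for (i in seq_along(layers)) {
    l <- layers[[i]]; g <- grads[[i]]; s <- state[[i]]
    if (is.null(g)) next
    if (nn_has_params(l)) {
      s$mw <- b1 * s$mw + (1 - b1) * g$w
      s$vw <- b2 * s$vw + (1 - b2) * g$w^2
      l$w <- l$w - corr * s$mw / (sqrt(s$vw) + eps)
      s$mb <- b1 * s$mb + (1 - b1) * g$b
      s$vb <- b2 * s$vb + (1 - b2) * g$b^2
      l$b <- l$b - corr * s$mb / (sqrt(s$vb) + eps)
      layers[[i]] <- l; state[[i]] <- s
    } else if (l$type == "res") {
      r <- nn_adam_step(l$body, g, s, lr, b1, b2, eps, t)
      l$body <- r$layers
      layers[[i]] <- l; state[[i]] <- r$state
    }
  }
  list(layers = layers, state = state)
}

nn_param_count <- function(layers) {
  sum(vapply(layers, function(l) {
    if (nn_has_params(l)) length(l$w) + length(l$b)
    else if (l$type == "res") nn_param_count(l$body)
    else 0L
  }, numeric(1)))
}
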