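# Internal neural-network machinery: sequential layer stacks over H x W x C
# activation arrays, with hand-written backward passes and an Adam
# optimizer. Convolution and max-pooling inner loops live in src/conv.cpp.
#
# A layer is a plain list with a `type` and its parameters:
#   conv     : W ((k*k*cin) x cout matrix), b, k, cin, cout
#   instnorm : gamma, beta (length-C), eps
#   relu / lrelu (alpha) : activations
#   maxpool / avgpool / upnearest : 2x resolution changes
#   resblock : layers (inner stack); output = input + stack(input)
# Gradients mirror the layer list: one entry per layer holding numeric
# arrays named like the parameters (NULL for parameter-free layers).

as_chw <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

he_init <- function(k, cin, cout, zero = FALSE) {
  if (zero) return(matrix(0, k * k * cin, cout))
  matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
         k * k * cin, cout)
}

layer_conv <- function(k, cin, cout, zero_init = FALSE) {
  list(type = "conv", k = as.integer(k), cin = cin, cout = cout,
       W = he_init(k, cin, cout, zero_init), b = numeric(cout))
}

layer_instnorm <- function(c, eps = 1e-5) {
  list(type = "instnorm", gamma = rep(1, c), beta = numeric(c), eps = eps)
}

layer_relu <- function() list(type = "relu")
layer_lrelu <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha)
layer_maxpool <- function() list(type = "maxpool")
layer_avgpool <- function() list(type = "avgpool")
layer_upnearest <- function() list(type = "upnearest")
layer_resblock <- function(layers) list(type = "resblock", layers = layers)

upnearest_fwd <- function(x) {
  x[rep(seq_len(dim(x)[1]), each = 2L),
    rep(seq_len(dim(x)[2]), each = 2L), , drop = FALSE]
}

upnearest_bwd <- function(dy) {
  io <- seq(1L, dim(dy)[1], by = 2L)
  jo <- seq(1L, dim(dy)[2], by = 2L)
  dy[io, jo, , drop = FALSE] + dy[io + 1L, jo, , drop = FALSE] +
    dy[io, jo + 1L, , drop = FALSE] + dy[io + 1L, jo + 1L, , drop = FALSE]
}

avgpool_fwd <- function(x) {
  upnearest_bwd(x) / 4
}

avgpool_bwd <- function(dy) {
  upnearest_fwd(dy) / 4
}

layer_fwd <- function(layer, x) {
  switch(layer$type,
    conv = {
      y <- conv2d_fwd(x, layer$W, layer$b, layer$k)
      list(y = y, cache = list(x = x))
    },
    instnorm = {
      dims <- dim(x)
      n <- dims[1] * dims[2]
      xm <- matrix(x, n, dims[3])
      mu <- colMeans(xm)
      v <- colMeans(xm^2) - mu^2
      inv <- 1 / sqrt(v + layer$eps)
      xhat <- (xm - rep(mu, each = n)) * rep(inv, each = n)
      y <- xhat * rep(layer$gamma, each = n) + rep(layer$beta, each = n)
      list(y = array(y, dims), cache = list(xhat = xhat, inv = inv, n = n))
    },
    relu = {
      mask <- x > 0
      list(y = x * mask, cache = list(mask = mask))
    },
    lrelu = {
      mask <- x > 0
      list(y = x * mask + layer$alpha * (x * !mask),
           cache = list(mask = mask))
    },
    maxpool = {
      r <- maxpool2_fwd(x)
      list(y = r$y, cache = list(idx = r$idx, H = dim(x)[1], W = dim(x)[2]))
    },
    avgpool = list(y = avgpool_fwd(x), cache = NULL),
    upnearest = list(y = upnearest_fwd(x), cache = NULL),
    resblock = {
      r <- net_fwd(layer$layers, x)
      list(y = x + r$y, cache = list(inner = r$caches))
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_bwd <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      r <- conv2d_bwd(cache$x, layer$W, dy, layer$k)
      list(dx = r$dx, grad = list(W = r$dw, b = as.numeric(r$db)))
    },
    instnorm = {
      dims <- dim(dy)
      n <- cache$n
      dym <- matrix(dy, n, dims[3])
      dgamma <- colSums(dym * cache$xhat)
      dbeta <- colSums(dym)
      dxhat <- dym * rep(layer$gamma, each = n)
      dx <- (dxhat - rep(colMeans(dxhat), each = n) -
               cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n)) *
        rep(cache$inv, each = n)
      list(dx = array(dx, dims), grad = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dy * cache$mask, grad = NULL),
    lrelu = list(dx = dy * cache$mask + layer$alpha * (dy * !cache$mask),
                 grad = NULL),
    maxpool = list(dx = maxpool2_bwd(dy, cache$idx, cache$H, cache$W),
                   grad = NULL),
    avgpool = list(dx = avgpool_bwd(dy), grad = NULL),
    upnearest = list(dx = upnearest_bwd(dy), grad = NULL),
    resblock = {
      r <- net_bwd(layer$layers, cache$inner, dy)
      list(dx = dy + r$dx, grad = list(layers = r$grads))
    }
  )
}

net_fwd <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_fwd(layers[[i]], x)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, caches = caches)
}

net_bwd <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_bwd(layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[i] <- list(r$grad)   # keep NULL slots for parameter-free layers
  }
  list(dx = dy, grads = grads)
}

# --- generic nested-list (tree) arithmetic over gradient structures -------

tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  stats::setNames(lapply(seq_along(a), function(i) tree_add(a[[i]], b[[i]])),
                  names(a))
}

tree_scale <- function(a, s) {
  if (is.null(a)) return(NULL)
  if (is.numeric(a)) return(a * s)
  lapply(a, tree_scale, s = s)
}

# --- Adam -----------------------------------------------------------------

adam_state_new <- function() {
  list(t = 0L, m = NULL, v = NULL)
}

# Walks the layer tree updating every parameter leaf named in `grad`.
# `params` is a layer list (possibly nested through resblocks); grads as
# produced by net_bwd. Returns list(params, state).
adam_update_layers <- function(layers, grads, state, lr,
                               beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  if (is.null(state$m)) {
    state$m <- tree_scale(grads, 0)
    state$v <- tree_scale(grads, 0)
  }
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  rec <- function(layer, g, m, v) {
    if (is.null(g)) return(list(layer = layer, m = m, v = v))
    for (nm in names(g)) {
      if (nm == "layers") {
        for (i in seq_along(g$layers)) {
          r <- rec(layer$layers[[i]], g$layers[[i]], m$layers[[i]],
                   v$layers[[i]])
          layer$layers[[i]] <- r$layer
          m$layers[i] <- list(r$m)
          v$layers[i] <- list(r$v)
        }
      } else {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
        layer[[nm]] <- layer[[nm]] -
          lr * (m[[nm]] / corr1) / (sqrt(v[[nm]] / corr2) + eps)
      }
    }
    list(layer = layer, m = m, v = v)
  }
  for (i in seq_along(layers)) {
    r <- rec(layers[[i]], grads[[i]], state$m[[i]], state$v[[i]])
    layers[[i]] <- r$layer
    state$m[i] <- list(r$m)
    state$v[i] <- list(r$v)
  }
  list(layers = layers, state = state)
}

# Piecewise learning-rate schedule: constant, then linear decay to zero.
lr_schedule <- function(epoch, lr, epochs_constant, epochs_decay) {
  if (epoch <= epochs_constant) return(lr)
  frac <- (epoch - epochs_constant) / max(epochs_decay, 1L)
  lr * max(0, 1 - frac)
}
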