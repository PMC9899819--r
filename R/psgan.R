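#' Configuration for the re-enhancing GAN
#'
#' A bi-directional unpaired-translation GAN: two residual generators
#' (`G_XY`: low- to high-contrast, `G_YX`: the reverse) and two patch
#' discriminators. Generators predict a residual added to the input and
#' clamped to `[0, 1]`, with the final convolution zero-initialized so an
#' untrained generator is the identity map. Defaults follow the stage's
#' training protocol: Adam, batch 1, initial learning rate `2e-4` constant
#' for `epochs_constant` epochs then decayed linearly to zero over
#' `epochs_decay` (default 100 + 100), least-squares adversarial loss,
#' `lambda_cyc = 10`, `lambda_idt = 5`, and a seeded 50-image replay buffer
#' for discriminator updates.
#'
#' @param base_channels Generator/discriminator width.
#' @param n_resblocks Residual blocks in each generator.
#' @param batch_size Images per update (the trainer uses 1).
#' @param lr Initial learning rate.
#' @param epochs_constant,epochs_decay Schedule phase lengths.
#' @param image_size Training image side length (images are expected at
#'   this size; must be divisible by 4 for the discriminators and by
#'   `2^max(feature tap)` for the extractor).
#' @param seed Seed for initialization, data order and the replay buffer.
#' @param weights An [enhance_weights()] object.
#' @param lambda_cyc,lambda_idt Baseline term weights.
#' @param buffer_size Replay buffer capacity.
#' @param profile `"tiny"` shorthand: 8 channels, 2 residual blocks,
#'   64-pixel images, 5 + 5 epochs.
#' @return A validated `psgan_config` list.
#' @export
psgan_config <- function(base_channels = 32L, n_resblocks = 4L,
                         batch_size = 1L, lr = 2e-4,
                         epochs_constant = 100L, epochs_decay = 100L,
                         image_size = 400L, seed = 1L,
                         weights = enhance_weights(),
                         lambda_cyc = 10, lambda_idt = 5,
                         buffer_size = 50L, profile = NULL) {
  if (!is.null(profile) && profile == "tiny") {
    # CPU-scale profile; explicitly passed arguments still win
    if (missing(base_channels)) base_channels <- 8L
    if (missing(n_resblocks)) n_resblocks <- 2L
    if (missing(image_size)) image_size <- 64L
    if (missing(epochs_constant)) epochs_constant <- 5L
    if (missing(epochs_decay)) epochs_decay <- 5L
    if (missing(lr)) lr <- 2e-3
  }
  check_count(base_channels, "base_channels", min = 2L)
  check_count(n_resblocks, "n_resblocks", min = 1L)
  check_count(batch_size, "batch_size")
  check_scalar(lr, "lr", 0, strict_lo = TRUE)
  check_count(image_size, "image_size", min = 16L)
  if (image_size %% 4 != 0) {
    stop_invalid("image_size must be divisible by 4")
  }
  if (!inherits(weights, "enhance_weights")) {
    stop_invalid("weights must come from enhance_weights()")
  }
  structure(list(base_channels = as.integer(base_channels),
                 n_resblocks = as.integer(n_resblocks),
                 batch_size = as.integer(batch_size), lr = lr,
                 epochs_constant = as.integer(epochs_constant),
                 epochs_decay = as.integer(epochs_decay),
                 image_size = as.integer(image_size),
                 seed = as.integer(seed), weights = weights,
                 lambda_cyc = lambda_cyc, lambda_idt = lambda_idt,
                 buffer_size = as.integer(buffer_size)),
            class = "psgan_config")
}

build_generator <- function(base, n_res) {
  resblocks <- lapply(seq_len(n_res), function(i) {
    layer_resblock(list(layer_conv(3L, base, base), layer_instnorm(base),
                        layer_relu(),
                        layer_conv(3L, base, base), layer_instnorm(base)))
  })
  net <- c(list(layer_conv(3L, 1L, base), layer_instnorm(base),
                layer_relu()),
           resblocks,
           list(layer_conv(3L, base, 1L, zero_init = TRUE)))
  structure(list(net = net), class = "octa_generator")
}

build_discriminator <- function(base) {
  list(layer_conv(3L, 1L, base), layer_lrelu(), layer_maxpool(),
       layer_conv(3L, base, 2L * base), layer_instnorm(2L * base),
       layer_lrelu(), layer_maxpool(),
       layer_conv(3L, 2L * base, 2L * base), layer_instnorm(2L * base),
       layer_lrelu(),
       layer_conv(1L, 2L * base, 1L))
}

#' Build the four re-enhancing networks
#'
#' @param config A [psgan_config()] object.
#' @return A `psgan_models` list with generators `g_xy`, `g_yx` and
#'   discriminators `d_x`, `d_y`, deterministically initialized from
#'   `config$seed`.
#' @export
build_psgan <- function(config = psgan_config()) {
  if (!inherits(config, "psgan_config")) {
    stop_invalid("config must come from psgan_config()")
  }
  with_seed(config$seed, {
    structure(list(
      g_xy = build_generator(config$base_channels, config$n_resblocks),
      g_yx = build_generator(config$base_channels, config$n_resblocks),
      d_x = build_discriminator(config$base_channels),
      d_y = build_discriminator(config$base_channels),
      config = config), class = "psgan_models")
  })
}

# Forward pass of a residual generator with caches:
# y = clamp01(x + net(x)); the clamp passes gradient on the open interval.
generator_fwd <- function(g, x) {
  r <- net_fwd(g$net, as_chw(x))
  t <- x + r$y[, , 1L]
  list(y = clip01(t), cache = list(net = r$caches, mask = t > 0 & t < 1))
}

generator_apply <- function(g, x) generator_fwd(g, x)$y

# Backward: returns grads for the generator and the gradient with respect
# to the input image (identity branch + network branch).
generator_bwd <- function(g, cache, dy) {
  dm <- dy * cache$mask
  r <- net_bwd(g$net, cache$net, as_chw(dm))
  list(dx = dm + r$dx[, , 1L], grads = r$grads)
}

disc_fwd <- function(d, x) {
  r <- net_fwd(d, as_chw(x))
  list(y = r$y[, , 1L], cache = r$caches)
}

disc_apply <- function(d, x) disc_fwd(d, x)$y

disc_bwd <- function(d, cache, dscore) {
  r <- net_bwd(d, cache, as_chw(dscore))
  list(dx = r$dx[, , 1L], grads = r$grads)
}

#' Enhance an image with a trained forward generator
#'
#' Deterministic at inference; output lies in `[0, 1]` and keeps the input
#' size (the generators are fully convolutional with stride 1).
#'
#' @param g_xy A generator from [build_psgan()] / [train_psgan()].
#' @param image Input image in `[0, 1]`.
#' @return Enhanced image of the same size.
#' @export
enhance <- function(g_xy, image) {
  if (!inherits(g_xy, "octa_generator")) {
    stop_invalid("g_xy must be an octa_generator")
  }
  check_image(image, "image")
  generator_apply(g_xy, image)
}

# Seeded replay buffer (capacity `size`): with probability 0.5 the incoming
# fake is swapped for a stored one, decorrelating discriminator updates.
buffer_new <- function(size) {
  list(size = size, images = list())
}

buffer_query <- function(buf, img) {
  if (length(buf$images) < buf$size) {
    buf$images[[length(buf$images) + 1L]] <- img
    return(list(buf = buf, img = img))
  }
  if (runif(1) < 0.5) {
    i <- sample.int(buf$size, 1)
    out <- buf$images[[i]]
    buf$images[[i]] <- img
    list(buf = buf, img = out)
  } else {
    list(buf = buf, img = img)
  }
}

#' Train the re-enhancing GAN
#'
#' Alternates generator updates (full objective: adversarial +
#' cycle-consistency + identity + cyclic perceptual + structure) and
#' discriminator updates (least-squares real/fake objective with a replay
#' buffer), one image pair per step, fully seeded.
#'
#' @param x_images List of low-contrast domain-X images (matrices, all at
#'   `config$image_size`).
#' @param y_images List of high-contrast domain-Y images.
#' @param config A [psgan_config()] object.
#' @param extractor A [feature_extractor()]; defaults to a seeded random
#'   extractor matching `config$weights$feature_layers`.
#' @param epochs Number of epochs (default: full schedule).
#' @param verbose Print per-epoch progress.
#' @return A list with the trained `models` (a `psgan_models` list) and a
#'   per-epoch `history` data frame of every loss term.
#' @export
train_psgan <- function(x_images, y_images, config = psgan_config(),
                        extractor = NULL,
                        epochs = config$epochs_constant + config$epochs_decay,
                        verbose = FALSE) {
  if (length(x_images) == 0L || length(y_images) == 0L) {
    stop_invalid("both image pools must be non-empty")
  }
  sz <- config$image_size
  for (im in c(x_images, y_images)) {
    if (nrow(im) != sz || ncol(im) != sz) {
      stop_invalid("all training images must be ", sz, "x", sz)
    }
  }
  if (is.null(extractor)) {
    extractor <- feature_extractor(seed = config$seed + 7L,
                                   taps = config$weights$feature_layers)
  }
  w <- config$weights
  models <- build_psgan(config)
  states <- list(g_xy = adam_state_new(), g_yx = adam_state_new(),
                 d_x = adam_state_new(), d_y = adam_state_new())
  buf_x <- buffer_new(config$buffer_size)
  buf_y <- buffer_new(config$buffer_size)
  n_iter <- min(length(x_images), length(y_images))
  ep_seeds <- derive_seeds(config$seed + 3L, epochs)
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    lr <- lr_schedule(ep, config$lr, config$epochs_constant,
                      config$epochs_decay)
    ord <- with_seed(ep_seeds[ep], list(
      x = sample(length(x_images), n_iter),
      y = sample(length(y_images), n_iter),
      rng = sample.int(.Machine$integer.max - 1L, 1)))
    acc <- c(adv = 0, cycle = 0, identity = 0, perceptual = 0,
             structure = 0, d_x = 0, d_y = 0)
    step_out <- with_seed(ord$rng, {
      for (it in seq_len(n_iter)) {
        x <- x_images[[ord$x[it]]]
        y <- y_images[[ord$y[it]]]
        st <- psgan_step(models, states, buf_x, buf_y, x, y, extractor,
                         config, lr)
        models <- st$models; states <- st$states
        buf_x <- st$buf_x; buf_y <- st$buf_y
        if (any(!is.finite(st$terms))) {
          stop("non-finite loss at epoch ", ep, ", iteration ", it)
        }
        acc <- acc + st$terms
      }
      list(models = models, states = states, buf_x = buf_x, buf_y = buf_y,
           acc = acc)
    })
    models <- step_out$models; states <- step_out$states
    buf_x <- step_out$buf_x; buf_y <- step_out$buf_y
    acc <- step_out$acc / n_iter
    history[[ep]] <- data.frame(epoch = ep, t(acc), lr = lr)
    if (verbose) {
      message(sprintf("epoch %d/%d adv %.4f cyc %.4f Lp %.4f Ls %.4f",
                      ep, epochs, acc[["adv"]], acc[["cycle"]],
                      acc[["perceptual"]], acc[["structure"]]))
    }
  }
  list(models = models, history = do.call(rbind, history))
}

# One alternating update on a single (x, y) pair.
psgan_step <- function(models, states, buf_x, buf_y, x, y, extractor,
                       config, lr) {
  w <- config$weights
  np <- length(x)
  # ---- generator forward passes (cached) ----
  f_fy <- generator_fwd(models$g_xy, x);  fy <- f_fy$y
  f_fx <- generator_fwd(models$g_yx, y);  fx <- f_fx$y
  f_rx <- generator_fwd(models$g_yx, fy); rx <- f_rx$y
  f_ry <- generator_fwd(models$g_xy, fx); ry <- f_ry$y
  f_iy <- generator_fwd(models$g_xy, y);  iy <- f_iy$y
  f_ix <- generator_fwd(models$g_yx, x);  ix <- f_ix$y
  # ---- adversarial scores on fakes ----
  dy_fy <- disc_fwd(models$d_y, fy)
  dx_fx <- disc_fwd(models$d_x, fx)
  adv <- mse_to(dy_fy$y, 1) + mse_to(dx_fx$y, 1)
  cyc <- mae(rx, x) + mae(ry, y)
  idt <- mae(iy, y) + mae(ix, x)
  # perceptual features
  e_x <- extractor_fwd(extractor, x)
  e_y <- extractor_fwd(extractor, y)
  e_rx <- extractor_fwd(extractor, rx)
  e_ry <- extractor_fwd(extractor, ry)
  lp <- sum(vapply(seq_along(e_x$features), function(l) {
    sum((e_x$features[[l]] - e_rx$features[[l]])^2) +
      sum((e_y$features[[l]] - e_ry$features[[l]])^2)
  }, numeric(1)))
  ls_xy <- structure_loss(x, fy, w)
  ls_yx <- structure_loss(y, fx, w)
  # ---- generator gradients ----
  # cycle + perceptual gradients on the reconstructions
  d_rx <- config$lambda_cyc * sign(rx - x) / np
  d_ry <- config$lambda_cyc * sign(ry - y) / np
  if (w$xi > 0) {
    d_rx <- d_rx + w$xi * extractor_bwd(extractor, e_rx$caches,
      lapply(seq_along(e_x$features), function(l)
        2 * (e_rx$features[[l]] - e_x$features[[l]])))
    d_ry <- d_ry + w$xi * extractor_bwd(extractor, e_ry$caches,
      lapply(seq_along(e_y$features), function(l)
        2 * (e_ry$features[[l]] - e_y$features[[l]])))
  }
  b_rx <- generator_bwd(models$g_yx, f_rx$cache, d_rx)   # through G_YX
  b_ry <- generator_bwd(models$g_xy, f_ry$cache, d_ry)   # through G_XY
  # adversarial gradient through the (frozen) discriminators
  d_fy <- disc_bwd(models$d_y, dy_fy$cache,
                   2 * (dy_fy$y - 1) / length(dy_fy$y))$dx
  d_fx <- disc_bwd(models$d_x, dx_fx$cache,
                   2 * (dx_fx$y - 1) / length(dx_fx$y))$dx
  if (w$rho1 > 0) d_fy <- d_fy + w$rho1 * structure_loss_grad(x, fy, w)
  if (w$rho2 > 0) d_fx <- d_fx + w$rho2 * structure_loss_grad(y, fx, w)
  d_fy <- d_fy + b_rx$dx
  d_fx <- d_fx + b_ry$dx
  b_fy <- generator_bwd(models$g_xy, f_fy$cache, d_fy)
  b_fx <- generator_bwd(models$g_yx, f_fx$cache, d_fx)
  # identity terms
  b_iy <- generator_bwd(models$g_xy, f_iy$cache,
                        config$lambda_idt * sign(iy - y) / np)
  b_ix <- generator_bwd(models$g_yx, f_ix$cache,
                        config$lambda_idt * sign(ix - x) / np)
  g_xy_grads <- tree_add(tree_add(b_fy$grads, b_ry$grads), b_iy$grads)
  g_yx_grads <- tree_add(tree_add(b_fx$grads, b_rx$grads), b_ix$grads)
  r1 <- adam_update_layers(models$g_xy$net, g_xy_grads, states$g_xy, lr)
  models$g_xy$net <- r1$layers; states$g_xy <- r1$state
  r2 <- adam_update_layers(models$g_yx$net, g_yx_grads, states$g_yx, lr)
  models$g_yx$net <- r2$layers; states$g_yx <- r2$state
  # ---- discriminator updates (replay buffer fakes, detached) ----
  qy <- buffer_query(buf_y, fy); buf_y <- qy$buf
  qx <- buffer_query(buf_x, fx); buf_x <- qx$buf
  upd_d <- function(d, state, real, fake) {
    fr <- disc_fwd(d, real)
    gr <- disc_bwd(d, fr$cache, (fr$y - 1) / length(fr$y))$grads
    ff <- disc_fwd(d, fake)
    gf <- disc_bwd(d, ff$cache, ff$y / length(ff$y))$grads
    loss <- 0.5 * (mse_to(fr$y, 1) + mse_to(ff$y, 0))
    r <- adam_update_layers(d, tree_add(gr, gf), state, lr)
    list(d = r$layers, state = r$state, loss = loss)
  }
  ud_y <- upd_d(models$d_y, states$d_y, y, qy$img)
  models$d_y <- ud_y$d; states$d_y <- ud_y$state
  ud_x <- upd_d(models$d_x, states$d_x, x, qx$img)
  models$d_x <- ud_x$d; states$d_x <- ud_x$state
  list(models = models, states = states, buf_x = buf_x, buf_y = buf_y,
       terms = c(adv = adv, cycle = cyc, identity = idt, perceptual = lp,
                 structure = ls_xy + ls_yx, d_x = ud_x$loss,
                 d_y = ud_y$loss))
}
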