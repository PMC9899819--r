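#' Configuration for the stripe-removal network
#'
#' A U-shaped encoder-decoder that maps a corrupted image to its
#' stripe-noise map. `depth` counts resolution levels including the
#' bottleneck (so the input size must be divisible by `2^(depth - 1)`), and
#' channel counts double per level starting from `base_channels`. Blocks use
#' two 3x3 convolutions with instance normalization, leaky-ReLU activations
#' in the encoder and ReLU in the decoder, 2x max-pool downsampling and
#' nearest-upsample + convolution upsampling with symmetric skip
#' concatenation; the head is a 1x1 convolution with a final ReLU so the
#' predicted noise map is non-negative. The default training schedule is
#' Adam (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`), batch 16, initial
#' learning rate `2e-4` held constant then decayed linearly to zero so the
#' decay concludes at the final epoch (default 150 + 150 = 300).
#'
#' @param depth Number of resolution levels (`>= 2`).
#' @param base_channels Channels at the top level (`>= 4`).
#' @param batch_size Mini-batch size.
#' @param lr Initial learning rate.
#' @param epochs_constant,epochs_decay Schedule phase lengths in epochs.
#' @param seed Seed controlling initialization and data order.
#' @param loss A [destripe_weights()] object.
#' @param atv_variant,squared Loss variants, see [destripe_loss()].
#' @param profile Optional shorthand: `"tiny"` sets `depth = 2`,
#'   `base_channels = 8` and a short 10 + 10 epoch schedule for CPU-scale
#'   runs.
#' @return A validated `srnet_config` list.
#' @export
srnet_config <- function(depth = 4L, base_channels = 32L, batch_size = 16L,
                         lr = 2e-4, epochs_constant = 150L,
                         epochs_decay = 150L, seed = 1L,
                         loss = destripe_weights(),
                         atv_variant = "scalar", squared = FALSE,
                         profile = NULL) {
  if (!is.null(profile) && profile == "tiny") {
    # CPU-scale profile; explicitly passed arguments still win
    if (missing(depth)) depth <- 2L
    if (missing(base_channels)) base_channels <- 8L
    if (missing(epochs_constant)) epochs_constant <- 10L
    if (missing(epochs_decay)) epochs_decay <- 10L
    # short schedules get a proportionally larger step size so the total
    # parameter movement matches the long default schedule; the gradient-map
    # edge term is used because the scalar form cannot localize edges and
    # its constant-magnitude subgradient destabilizes short runs
    if (missing(lr)) lr <- 2e-3
    if (missing(atv_variant)) atv_variant <- "map"
  }
  check_count(depth, "depth", min = 2L)
  check_count(base_channels, "base_channels", min = 4L)
  check_count(batch_size, "batch_size")
  check_scalar(lr, "lr", 0, strict_lo = TRUE)
  check_count(epochs_constant, "epochs_constant", min = 0L)
  check_count(epochs_decay, "epochs_decay", min = 0L)
  if (!inherits(loss, "destripe_weights")) {
    stop_invalid("loss must come from destripe_weights()")
  }
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 batch_size = as.integer(batch_size), lr = lr,
                 epochs_constant = as.integer(epochs_constant),
                 epochs_decay = as.integer(epochs_decay),
                 seed = as.integer(seed), loss = loss,
                 atv_variant = atv_variant, squared = squared),
            class = "srnet_config")
}

conv_in_act <- function(k, cin, cout, act) {
  c(list(layer_conv(k, cin, cout), layer_instnorm(cout)),
    if (act == "lrelu") list(layer_lrelu()) else list(layer_relu()))
}

#' Build a stripe-removal network
#'
#' Parameter initialization is deterministic under `config$seed`.
#'
#' @param config An [srnet_config()] object.
#' @return An `srnet` model object (untrained).
#' @export
build_srnet <- function(config = srnet_config()) {
  if (!inherits(config, "srnet_config")) {
    stop_invalid("config must come from srnet_config()")
  }
  d <- config$depth
  ch <- config$base_channels * 2^(seq_len(d) - 1L)
  with_seed(config$seed, {
    enc <- lapply(seq_len(d - 1L), function(i) {
      cin <- if (i == 1L) 1L else ch[i - 1L]
      c(conv_in_act(3L, cin, ch[i], "lrelu"),
        conv_in_act(3L, ch[i], ch[i], "lrelu"))
    })
    bottleneck <- c(conv_in_act(3L, ch[d - 1L], ch[d], "lrelu"),
                    conv_in_act(3L, ch[d], ch[d], "lrelu"))
    dec <- lapply(rev(seq_len(d - 1L)), function(i) {
      list(up = c(list(layer_upnearest()),
                  conv_in_act(3L, ch[i + 1L], ch[i], "relu")),
           post = c(conv_in_act(3L, 2L * ch[i], ch[i], "relu"),
                    conv_in_act(3L, ch[i], ch[i], "relu")))
    })
    # near-zero head: the untrained model predicts an almost-empty noise
    # map, so de-striping starts from the identity rather than from random
    # large noise estimates (the small positive bias keeps the final ReLU
    # out of its dead zone)
    head_conv <- layer_conv(1L, ch[1L], 1L, zero_init = TRUE)
    head_conv$b <- 0.01
    head <- list(head_conv, layer_relu())
    structure(list(config = config, enc = enc, bottleneck = bottleneck,
                   dec = dec, head = head),
              class = "srnet")
  })
}

check_srnet_size <- function(model, x) {
  div <- 2^(model$config$depth - 1L)
  if (nrow(x) %% div != 0 || ncol(x) %% div != 0) {
    stop_invalid("input size ", nrow(x), "x", ncol(x),
                 " must be divisible by ", div,
                 " for depth ", model$config$depth)
  }
}

srnet_fwd <- function(model, x) {
  check_srnet_size(model, x)
  a <- as_chw(x)
  d <- model$config$depth
  skips <- vector("list", d - 1L)
  enc_caches <- vector("list", d - 1L)
  pool_caches <- vector("list", d - 1L)
  for (i in seq_len(d - 1L)) {
    r <- net_fwd(model$enc[[i]], a)
    skips[[i]] <- r$y
    enc_caches[[i]] <- r$caches
    p <- layer_fwd(layer_maxpool(), r$y)
    a <- p$y
    pool_caches[[i]] <- p$cache
  }
  bot <- net_fwd(model$bottleneck, a)
  a <- bot$y
  dec_caches <- vector("list", d - 1L)
  for (j in seq_len(d - 1L)) {
    lev <- d - j                       # decoder level (matches skips[[lev]])
    up <- net_fwd(model$dec[[j]]$up, a)
    cat_in <- array(c(skips[[lev]], up$y),
                    c(dim(up$y)[1:2], dim(skips[[lev]])[3] + dim(up$y)[3]))
    post <- net_fwd(model$dec[[j]]$post, cat_in)
    a <- post$y
    dec_caches[[j]] <- list(up = up$caches, post = post$caches,
                            n_skip = dim(skips[[lev]])[3])
  }
  hd <- net_fwd(model$head, a)
  list(n_out = hd$y[, , 1L],
       cache = list(enc = enc_caches, pool = pool_caches, bot = bot$caches,
                    dec = dec_caches, head = hd$caches))
}

srnet_bwd <- function(model, cache, d_nout) {
  d <- model$config$depth
  dy <- as_chw(d_nout)
  grads <- list(enc = vector("list", d - 1L), bottleneck = NULL,
                dec = vector("list", d - 1L), head = NULL)
  r <- net_bwd(model$head, cache$head, dy)
  grads$head <- r$grads
  dy <- r$dx
  d_skip <- vector("list", d - 1L)
  for (j in rev(seq_len(d - 1L))) {
    lev <- d - j
    n_skip <- cache$dec[[j]]$n_skip
    post <- net_bwd(model$dec[[j]]$post, cache$dec[[j]]$post, dy)
    d_cat <- post$dx
    d_skip[[lev]] <- d_cat[, , seq_len(n_skip), drop = FALSE]
    d_up <- d_cat[, , -seq_len(n_skip), drop = FALSE]
    up <- net_bwd(model$dec[[j]]$up, cache$dec[[j]]$up, d_up)
    grads$dec[[j]] <- list(up = up$grads, post = post$grads)
    dy <- up$dx
  }
  bot <- net_bwd(model$bottleneck, cache$bot, dy)
  grads$bottleneck <- bot$grads
  dy <- bot$dx
  for (i in rev(seq_len(d - 1L))) {
    d_enc <- layer_bwd(layer_maxpool(), cache$pool[[i]], dy)$dx +
      d_skip[[i]]
    r <- net_bwd(model$enc[[i]], cache$enc[[i]], d_enc)
    grads$enc[[i]] <- r$grads
    dy <- r$dx
  }
  grads
}

srnet_grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  list(enc = Map(tree_add, a$enc, b$enc),
       bottleneck = tree_add(a$bottleneck, b$bottleneck),
       dec = Map(function(x, y) list(up = tree_add(x$up, y$up),
                                     post = tree_add(x$post, y$post)),
                 a$dec, b$dec),
       head = tree_add(a$head, b$head))
}

srnet_adam_step <- function(model, grads, states, lr) {
  d <- model$config$depth
  for (i in seq_len(d - 1L)) {
    r <- adam_update_layers(model$enc[[i]], grads$enc[[i]],
                            states$enc[[i]], lr)
    model$enc[[i]] <- r$layers; states$enc[[i]] <- r$state
    ru <- adam_update_layers(model$dec[[i]]$up, grads$dec[[i]]$up,
                             states$dec_up[[i]], lr)
    model$dec[[i]]$up <- ru$layers; states$dec_up[[i]] <- ru$state
    rp <- adam_update_layers(model$dec[[i]]$post, grads$dec[[i]]$post,
                             states$dec_post[[i]], lr)
    model$dec[[i]]$post <- rp$layers; states$dec_post[[i]] <- rp$state
  }
  rb <- adam_update_layers(model$bottleneck, grads$bottleneck,
                           states$bottleneck, lr)
  model$bottleneck <- rb$layers; states$bottleneck <- rb$state
  rh <- adam_update_layers(model$head, grads$head, states$head, lr)
  model$head <- rh$layers; states$head <- rh$state
  list(model = model, states = states)
}

#' Compose the clean image from input and predicted noise
#'
#' The residual rule `c_out = max(i_in - n_out, 0)`: the clean image is the
#' input minus the predicted stripe map, floored at zero.
#'
#' @param i_in Input image.
#' @param n_out Predicted noise map of the same shape.
#' @return The composed clean image.
#' @export
compose_clean <- function(i_in, n_out) {
  check_matrix(i_in, "i_in"); check_matrix(n_out, "n_out")
  check_same_shape(i_in, n_out, "i_in", "n_out")
  pmax(i_in - n_out, 0)
}

#' De-stripe an image with a (trained) stripe-removal network
#'
#' Deterministic at inference: the same input always yields the same output.
#'
#' @param model An `srnet` model.
#' @param i_in Input image, sized compatibly with the model depth.
#' @return A list with the predicted non-negative noise map `n_out` and the
#'   composed clean image `c_out`.
#' @export
destripe <- function(model, i_in) {
  if (!inherits(model, "srnet")) stop_invalid("model must be an srnet")
  check_matrix(i_in, "i_in")
  n_out <- srnet_fwd(model, i_in)$n_out
  list(n_out = n_out, c_out = compose_clean(i_in, n_out))
}

#' Train the stripe-removal network
#'
#' Optimizes the composite de-striping loss over the manifest's train split
#' with Adam and the constant-then-linear-decay learning-rate schedule.
#' Fully seeded: initialization and per-epoch data order derive from
#' `config$seed`.
#'
#' @param manifest Dataset manifest from [make_dataset()] or
#'   [load_manifest()].
#' @param config An [srnet_config()] object.
#' @param epochs Number of epochs to run (default: full schedule length).
#' @param validate Compute mean PSNR/SSIM of destriped vs clean on the test
#'   split after each epoch.
#' @param verbose Print per-epoch progress.
#' @return A list with the trained `model` and a per-epoch `history` data
#'   frame (total loss, unweighted components, learning rate, and optional
#'   validation metrics).
#' @export
train_srnet <- function(manifest, config = srnet_config(),
                        epochs = config$epochs_constant + config$epochs_decay,
                        validate = FALSE, verbose = FALSE) {
  train_rows <- which(manifest$split == "train")
  if (length(train_rows) == 0L) stop_invalid("manifest has no train split")
  data <- lapply(train_rows, function(r) {
    tri <- load_triplet(manifest, r)
    tri$a_ref <- stripe_degrade(tri$noise, config$loss$lam)
    tri
  })
  val <- NULL
  if (validate) {
    val <- lapply(which(manifest$split == "test"),
                  function(r) load_triplet(manifest, r))
  }
  model <- build_srnet(config)
  states <- list(
    enc = replicate(config$depth - 1L, adam_state_new(), simplify = FALSE),
    dec_up = replicate(config$depth - 1L, adam_state_new(), simplify = FALSE),
    dec_post = replicate(config$depth - 1L, adam_state_new(),
                         simplify = FALSE),
    bottleneck = adam_state_new(), head = adam_state_new())
  order_seeds <- derive_seeds(config$seed + 1L, epochs)
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    lr <- lr_schedule(ep, config$lr, config$epochs_constant,
                      config$epochs_decay)
    idx <- with_seed(order_seeds[ep], sample(length(data)))
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    ep_terms <- c(recon = 0, stripe = 0, atv = 0)
    ep_loss <- 0
    for (batch in batches) {
      grads <- NULL
      for (r in batch) {
        tri <- data[[r]]
        fwd <- srnet_fwd(model, tri$corrupted)
        n_out <- fwd$n_out
        c_out <- compose_clean(tri$corrupted, n_out)
        loss <- destripe_loss(tri$corrupted, n_out, c_out, tri$noise,
                              tri$clean, config$loss,
                              atv_variant = config$atv_variant,
                              squared = config$squared)
        if (!is.finite(loss)) {
          stop("non-finite loss at epoch ", ep, ", sample id ", tri$id)
        }
        g <- destripe_loss_grads(tri$corrupted, n_out, c_out, tri$noise,
                                 tri$clean, config$loss,
                                 atv_variant = config$atv_variant,
                                 squared = config$squared,
                                 a_ref = tri$a_ref)
        # chain the clean-branch gradient through c_out = max(i - n, 0)
        d_n <- g$d_n_out - g$d_c_out * (tri$corrupted - n_out > 0)
        sample_grads <- srnet_bwd(model, fwd$cache, d_n)
        grads <- srnet_grads_add(grads, sample_grads)
        ep_loss <- ep_loss + as.numeric(loss)
        ep_terms <- ep_terms + attr(loss, "terms")
      }
      scale <- 1 / length(batch)
      grads <- list(enc = lapply(grads$enc, tree_scale, s = scale),
                    bottleneck = tree_scale(grads$bottleneck, scale),
                    dec = lapply(grads$dec, function(g)
                      list(up = tree_scale(g$up, scale),
                           post = tree_scale(g$post, scale))),
                    head = tree_scale(grads$head, scale))
      upd <- srnet_adam_step(model, grads, states, lr)
      model <- upd$model
      states <- upd$states
    }
    rec <- data.frame(epoch = ep, loss = ep_loss / length(data),
                      recon = ep_terms[["recon"]] / length(data),
                      stripe = ep_terms[["stripe"]] / length(data),
                      atv = ep_terms[["atv"]] / length(data), lr = lr)
    if (validate && length(val) > 0L) {
      ps <- vapply(val, function(tri) {
        out <- destripe(model, tri$corrupted)
        c(psnr(tri$clean, out$c_out), ssim(tri$clean, out$c_out))
      }, numeric(2))
      rec$val_psnr <- mean(ps[1, ])
      rec$val_ssim <- mean(ps[2, ])
    }
    history[[ep]] <- rec
    if (verbose) {
      message(sprintf("epoch %d/%d loss %.5f lr %.2e", ep, epochs,
                      rec$loss, lr))
    }
  }
  list(model = model, history = do.call(rbind, history))
}

#' Save / load a stripe-removal model
#'
#' Checkpoints are R serialized objects with a JSON sidecar recording the
#' configuration for provenance.
#'
#' @param model An `srnet` or `psgan_models` object.
#' @param path Checkpoint path (`.rds`).
#' @return `path` (save) or the model object (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  cfg <- if (inherits(model, "srnet")) model$config else model$config
  jsonlite::write_json(list(class = class(model)[1], config = unclass(cfg)),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       force = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  readRDS(path)
}
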