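# Backprop correctness of the network machinery: every analytic gradient is
# checked against central finite differences on small random inputs.

oc <- asNamespace("octaclean")

test_that("convolution layer gradients match finite differences", {
  withr::with_seed(11, {
    x <- array(runif(10 * 10 * 3), c(10, 10, 3))
    layer <- oc$layer_conv(3L, 3L, 4L)
    dy <- array(rnorm(10 * 10 * 4), c(10, 10, 4))
  })
  f <- oc$layer_fwd(layer, x)
  b <- oc$layer_bwd(layer, f$cache, dy)
  # weights
  fdW <- fd_grad(function(w) {
    l2 <- layer; l2$W <- matrix(w, nrow(layer$W))
    sum(oc$layer_fwd(l2, x)$y * dy)
  }, as.numeric(layer$W))
  expect_lt(max_rel_err(as.numeric(b$grad$W), fdW), 1e-6)
  # bias
  fdb <- fd_grad(function(bb) {
    l2 <- layer; l2$b <- bb
    sum(oc$layer_fwd(l2, x)$y * dy)
  }, layer$b)
  expect_lt(max_rel_err(b$grad$b, fdb), 1e-6)
  # input (sampled entries)
  idx <- withr::with_seed(1, sample(length(x), 20))
  fdx <- sapply(idx, function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + 1e-6; xm[i] <- xm[i] - 1e-6
    (sum(oc$layer_fwd(layer, xp)$y * dy) -
       sum(oc$layer_fwd(layer, xm)$y * dy)) / 2e-6
  })
  expect_lt(max_rel_err(b$dx[idx], fdx), 1e-5)
})

test_that("instance norm, pooling and upsampling gradients are exact", {
  withr::with_seed(12, {
    x <- array(runif(8 * 8 * 2), c(8, 8, 2))
    dy <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  })
  layer <- oc$layer_instnorm(2L)
  layer$gamma <- c(1.3, 0.7); layer$beta <- c(0.1, -0.2)
  f <- oc$layer_fwd(layer, x)
  b <- oc$layer_bwd(layer, f$cache, dy)
  idx <- 1:20
  fdx <- sapply(idx, function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + 1e-6; xm[i] <- xm[i] - 1e-6
    (sum(oc$layer_fwd(layer, xp)$y * dy) -
       sum(oc$layer_fwd(layer, xm)$y * dy)) / 2e-6
  })
  expect_lt(max_rel_err(b$dx[idx], fdx), 1e-4)
  # pooling pair: upsample backward is the adjoint of forward
  dy2 <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  up <- oc$upnearest_fwd(x)
  expect_equal(sum(up * dy2), sum(x * oc$upnearest_bwd(dy2)),
               tolerance = 1e-10)
  av <- oc$avgpool_fwd(x)
  dy3 <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  expect_equal(sum(av * dy3), sum(x * oc$avgpool_bwd(dy3)),
               tolerance = 1e-10)
})

test_that("U-shaped network backprop matches finite differences end to end", {
  cfg <- srnet_config(depth = 2L, base_channels = 4L, seed = 3L)
  m <- build_srnet(cfg)
  x <- rand_image(13, 16)
  dno <- rand_image(14, 16, lo = -1, hi = 1)
  fwd <- oc$srnet_fwd(m, x)
  gr <- oc$srnet_bwd(m, fwd$cache, dno)
  val <- function(model) sum(oc$srnet_fwd(model, x)$n_out * dno)
  # deepest and shallowest parameters
  probe <- function(get, set, grads, k = 10L) {
    w <- get(m)
    idx <- seq_len(min(k, length(w)))
    fd <- sapply(idx, function(i) {
      mp <- set(m, i, w[i] + 1e-6); mm <- set(m, i, w[i] - 1e-6)
      (val(mp) - val(mm)) / 2e-6
    })
    max_rel_err(grads[idx], fd)
  }
  err_enc <- probe(function(m) m$enc[[1]][[1]]$W,
                   function(m, i, v) { m$enc[[1]][[1]]$W[i] <- v; m },
                   gr$enc[[1]][[1]]$W)
  err_bot <- probe(function(m) m$bottleneck[[4]]$W,
                   function(m, i, v) { m$bottleneck[[4]]$W[i] <- v; m },
                   gr$bottleneck[[4]]$W)
  err_gam <- probe(function(m) m$dec[[1]]$post[[2]]$gamma,
                   function(m, i, v) { m$dec[[1]]$post[[2]]$gamma[i] <- v; m },
                   gr$dec[[1]]$post[[2]]$gamma)
  expect_lt(err_enc, 1e-4)
  expect_lt(err_bot, 1e-4)
  expect_lt(err_gam, 1e-4)
})

test_that("generator and discriminator input gradients are correct", {
  models <- build_psgan(psgan_config(profile = "tiny", seed = 2L))
  x <- rand_image(15, 32, lo = 0.05, hi = 0.85)  # away from clamp kinks
  f <- oc$generator_fwd(models$g_xy, x)
  expect_identical(f$y, x)   # zero-initialized residual head: identity
  dy <- rand_image(16, 32, lo = -1, hi = 1)
  b <- oc$generator_bwd(models$g_xy, f$cache, dy)
  idx <- withr::with_seed(2, sample(length(x), 15))
  fdx <- sapply(idx, function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + 1e-6; xm[i] <- xm[i] - 1e-6
    (sum(oc$generator_fwd(models$g_xy, xp)$y * dy) -
       sum(oc$generator_fwd(models$g_xy, xm)$y * dy)) / 2e-6
  })
  expect_lt(max_rel_err(b$dx[idx], fdx), 1e-5)
  d <- oc$disc_fwd(models$d_y, x)
  expect_true(all(is.finite(d$y)))
  ds <- matrix(rnorm(length(d$y)), nrow(d$y))
  bd <- oc$disc_bwd(models$d_y, d$cache, ds)
  fdx <- sapply(idx, function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + 1e-6; xm[i] <- xm[i] - 1e-6
    (sum(oc$disc_apply(models$d_y, xp) * ds) -
       sum(oc$disc_apply(models$d_y, xm) * ds)) / 2e-6
  })
  expect_lt(max_rel_err(bd$dx[idx], fdx), 1e-4)
})

test_that("feature extractor is deterministic and backpropagates correctly", {
  ex <- feature_extractor(seed = 5L, taps = c(2L, 5L))
  x <- rand_image(17, 64)
  f1 <- extract_features(ex, x)
  expect_identical(f1, extract_features(ex, x))
  expect_identical(dim(f1[[1]]), c(16L, 16L, 8L))
  expect_identical(dim(f1[[2]]), c(2L, 2L, 8L))
  e <- oc$extractor_fwd(ex, x)
  dxe <- oc$extractor_bwd(ex, e$caches, lapply(e$features, function(f) 2 * f))
  val <- function(xx) sum(sapply(extract_features(ex, xx),
                                 function(f) sum(f^2)))
  idx <- withr::with_seed(3, sample(length(x), 10))
  fdx <- sapply(idx, function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + 1e-5; xm[i] <- xm[i] - 1e-5
    (val(xp) - val(xm)) / 2e-5
  })
  expect_lt(max_rel_err(dxe[idx], fdx), 1e-4)
})

test_that("Adam decreases a simple convex objective and lr schedule decays", {
  layer <- list(oc$layer_conv(1L, 1L, 1L))
  layer[[1]]$W[1] <- 2; layer[[1]]$b[1] <- -1
  st <- oc$adam_state_new()
  x <- array(rand_image(18, 8), c(8, 8, 1))
  target <- x * 0.5
  loss0 <- NULL
  for (i in 1:200) {
    f <- oc$net_fwd(layer, x)
    r <- f$y - target
    if (is.null(loss0)) loss0 <- sum(r^2)
    b <- oc$net_bwd(layer, f$caches, 2 * r)
    upd <- oc$adam_update_layers(layer, b$grads, st, lr = 0.05)
    layer <- upd$layers; st <- upd$state
  }
  f <- oc$net_fwd(layer, x)
  expect_lt(sum((f$y - target)^2), loss0 * 1e-3)
  expect_equal(oc$lr_schedule(10, 1, 10, 10), 1)
  expect_equal(oc$lr_schedule(15, 1, 10, 10), 0.5)
  expect_equal(oc$lr_schedule(20, 1, 10, 10), 0)
})
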