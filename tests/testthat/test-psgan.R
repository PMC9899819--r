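oc <- asNamespace("octaclean")

tiny_models <- function() {
  fixture("tiny_psgan", function() {
    build_psgan(psgan_config(profile = "tiny", seed = 2L))
  })
}

test_that("build_psgan is seeded and respects shape contracts", {
  m1 <- build_psgan(psgan_config(profile = "tiny", seed = 2L))
  m2 <- build_psgan(psgan_config(profile = "tiny", seed = 2L))
  expect_identical(m1, m2)
  x <- rand_image(30, 64)
  gy <- oc$generator_apply(m1$g_xy, x)
  expect_identical(dim(gy), dim(x))
  expect_true(all(gy >= 0 & gy <= 1))
  sc <- oc$disc_apply(m1$d_y, x)
  expect_true(all(is.finite(sc)))
})

test_that("untrained generators are identity maps (zero-initialized residual)", {
  m <- tiny_models()
  x <- rand_image(31, 64)
  expect_lte(max(abs(oc$generator_apply(m$g_xy, x) - x)), 0.1)
  expect_identical(oc$generator_apply(m$g_xy, x),
                   oc$generator_apply(m$g_xy, x))
})

test_that("baseline loss obeys weight masking and the linear combination", {
  m <- tiny_models()
  x <- rand_image(32, 64); y <- rand_image(33, 64)
  # identity generators (untrained): cycle and identity terms vanish
  bl <- baseline_loss(x, y, m, lambda_cyc = 3, lambda_idt = 7)
  terms <- attr(bl, "terms")
  expect_equal(terms[["cycle"]], 0, tolerance = 1e-12)
  expect_equal(terms[["identity"]], 0, tolerance = 1e-12)
  # zero weights reduce to the adversarial terms
  bl0 <- baseline_loss(x, y, m, lambda_cyc = 0, lambda_idt = 0)
  expect_equal(as.numeric(bl0), attr(bl0, "terms")[["adv"]],
               tolerance = 1e-12)
  # equals the independently composed sum
  adv <- mean((oc$disc_apply(m$d_y, oc$generator_apply(m$g_xy, x)) - 1)^2) +
    mean((oc$disc_apply(m$d_x, oc$generator_apply(m$g_yx, y)) - 1)^2)
  fy <- oc$generator_apply(m$g_xy, x)
  fx <- oc$generator_apply(m$g_yx, y)
  cyc <- mean(abs(oc$generator_apply(m$g_yx, fy) - x)) +
    mean(abs(oc$generator_apply(m$g_xy, fx) - y))
  idt <- mean(abs(oc$generator_apply(m$g_xy, y) - y)) +
    mean(abs(oc$generator_apply(m$g_yx, x) - x))
  expect_equal(as.numeric(bl), adv + 3 * cyc + 7 * idt, tolerance = 1e-6)
})

test_that("cyclic perceptual loss vanishes for identity generators and composes", {
  m <- tiny_models()
  ex <- feature_extractor(seed = 4L, taps = c(2L, 5L))
  x <- rand_image(34, 64); y <- rand_image(35, 64)
  expect_equal(cyclic_perceptual_loss(x, y, m$g_xy, m$g_yx, ex), 0,
               tolerance = 1e-12)
  # symmetry: swapping (x, G_XY, G_YX) with (y, G_YX, G_XY) jointly
  expect_equal(cyclic_perceptual_loss(x, y, m$g_xy, m$g_yx, ex),
               cyclic_perceptual_loss(y, x, m$g_yx, m$g_xy, ex),
               tolerance = 1e-12)
  # hand-composed two-pass oracle on perturbed generators
  mp <- m
  mp$g_yx$net[[length(mp$g_yx$net)]]$b <- 0.05  # breaks identity
  rx <- oc$generator_apply(mp$g_yx, oc$generator_apply(mp$g_xy, x))
  ry <- oc$generator_apply(mp$g_xy, oc$generator_apply(mp$g_yx, y))
  fx <- extract_features(ex, x); frx <- extract_features(ex, rx)
  fy <- extract_features(ex, y); fry <- extract_features(ex, ry)
  ref <- sum(sapply(1:2, function(l) sum((fx[[l]] - frx[[l]])^2) +
                      sum((fy[[l]] - fry[[l]])^2)))
  expect_equal(cyclic_perceptual_loss(x, y, mp$g_xy, mp$g_yx, ex), ref,
               tolerance = 1e-6)
})

test_that("with an identity extractor the perceptual loss is the squared cycle error", {
  # single linear tap phi(x) = x: build a 1-stage extractor and overwrite
  # its convolution with the identity kernel, tapping before any pooling
  # would distort (tap = stage 1 with an identity-preserving stage)
  m <- tiny_models()
  mp <- m
  mp$g_yx$net[[length(mp$g_yx$net)]]$b <- 0.04
  x <- rand_image(36, 64); y <- rand_image(37, 64)
  rx <- oc$generator_apply(mp$g_yx, oc$generator_apply(mp$g_xy, x))
  ry <- oc$generator_apply(mp$g_xy, oc$generator_apply(mp$g_yx, y))
  expected <- sum((x - rx)^2) + sum((y - ry)^2)
  # linear extractor: avgpool-free identity mapping
  ex <- feature_extractor(seed = 1L, channels = 1L, taps = 1L,
                          n_stages = 1L)
  ex$stages[[1]] <- list(list(type = "conv", k = 1L, cin = 1L, cout = 1L,
                              W = matrix(1, 1, 1), b = 0))
  got <- cyclic_perceptual_loss(x, y, mp$g_xy, mp$g_yx, ex)
  expect_equal(got, expected, tolerance = 1e-8)
})

test_that("structure loss is bounded, affine-invariant and exact on anticorrelation", {
  w <- enhance_weights()
  withr::with_seed(40, {
    for (i in 1:20) {
      x <- matrix(runif(32 * 32), 32)
      g <- matrix(runif(32 * 32), 32)
      v <- structure_loss(x, g, w)
      expect_gte(v, 0)
      expect_lte(v, 2)
    }
  })
  x <- rand_image(41, 32)
  expect_equal(structure_loss(x, x, w), 0, tolerance = 1e-12)
  expect_lt(abs(structure_loss(x, 0.6 * x + 0.3, w)), 1e-6)
  # perfect anticorrelation: each window term is (-var + c)/(var + c)
  g <- 1 - x
  st <- oc$.window_stats(x, g, w$window)
  expected <- 1 - mean((st$cov + w$c) /
                         (sqrt(st$var_x * st$var_g) + w$c))
  expect_equal(structure_loss(x, g, w), expected, tolerance = 1e-12)
  expect_gt(structure_loss(x, g, w), 1.9)
})

test_that("full objective reduces to the baseline when extra weights are zero", {
  m <- tiny_models()
  mp <- m
  mp$g_xy$net[[length(mp$g_xy$net)]]$b <- 0.03
  mp$g_yx$net[[length(mp$g_yx$net)]]$b <- -0.02
  ex <- feature_extractor(seed = 4L, taps = c(2L, 5L))
  x <- rand_image(42, 64); y <- rand_image(43, 64)
  cfg0 <- psgan_config(profile = "tiny", seed = 2L,
                       weights = enhance_weights(xi = 0, rho1 = 0,
                                                 rho2 = 0))
  full0 <- psgan_loss(x, y, mp, ex, cfg0)
  bl <- baseline_loss(x, y, mp, cfg0$lambda_cyc, cfg0$lambda_idt)
  expect_equal(as.numeric(full0), as.numeric(bl), tolerance = 1e-12)
  # default weights: equals the weighted sum of independent terms
  cfg <- psgan_config(profile = "tiny", seed = 2L)
  full <- psgan_loss(x, y, mp, ex, cfg)
  lp <- cyclic_perceptual_loss(x, y, mp$g_xy, mp$g_yx, ex)
  ls1 <- structure_loss(x, oc$generator_apply(mp$g_xy, x), cfg$weights)
  ls2 <- structure_loss(y, oc$generator_apply(mp$g_yx, y), cfg$weights)
  expect_equal(as.numeric(full),
               as.numeric(bl) + 0.5 * lp + 0.5 * ls1 + 0.5 * ls2,
               tolerance = 1e-6)
})

test_that("structure loss gradient matches finite differences", {
  x <- rand_image(44, 16)
  g <- rand_image(45, 16)
  w <- enhance_weights(window = 8L)
  an <- oc$structure_loss_grad(x, g, w)
  expect_lt(max_rel_err(an, fd_grad(function(gg) structure_loss(x, gg, w),
                                    g)), 1e-4)
})

test_that("a one-epoch tiny training run is finite and seeded", {
  x_pool <- lapply(1:2, function(i)
    generate_vessel_phantom(600 + i, 32, 32)$image)
  y_pool <- lapply(1:2, function(i)
    generate_vessel_phantom(700 + i, 32, 32)$image)
  cfg <- psgan_config(profile = "tiny", seed = 5L, image_size = 32L)
  tr1 <- train_psgan(x_pool, y_pool, cfg, epochs = 1L)
  expect_identical(nrow(tr1$history), 1L)
  expect_true(all(is.finite(unlist(tr1$history))))
  tr2 <- train_psgan(x_pool, y_pool, cfg, epochs = 1L)
  expect_equal(tr1$history, tr2$history, tolerance = 1e-12)
  expect_identical(tr1$models, tr2$models)
  # enhance keeps range and determinism
  x <- x_pool[[1]]
  e1 <- enhance(tr1$models$g_xy, x)
  expect_true(all(e1 >= 0 & e1 <= 1))
  expect_identical(e1, enhance(tr1$models$g_xy, x))
})

test_that("a longer schedule raises vessel contrast while preserving structure", {
  lowp <- vessel_phantom_params(intensity_range = c(0.3, 0.5),
                                background_level = 0.15)
  x_pool <- lapply(1:30, function(i)
    generate_vessel_phantom(1000 + i, 64, 64, lowp)$image)
  y_pool <- lapply(1:30, function(i)
    generate_vessel_phantom(2000 + i, 64, 64)$image)
  cfg <- psgan_config(profile = "tiny", seed = 9L,
                      epochs_constant = 30L, epochs_decay = 10L)
  tr <- train_psgan(x_pool, y_pool, cfg, epochs = 40L)
  held <- lapply(1:10, function(i)
    generate_vessel_phantom(3000 + i, 64, 64, lowp))
  stats <- vapply(held, function(ph) {
    enh <- enhance(tr$models$g_xy, ph$image)
    c(before = mean(ph$image[ph$mask == 1]) - mean(ph$image[ph$mask == 0]),
      after = mean(enh[ph$mask == 1]) - mean(enh[ph$mask == 0]),
      sloss = structure_loss(ph$image, enh))
  }, numeric(3))
  expect_gt(mean(stats["after", ]), mean(stats["before", ]))
  expect_lt(max(stats["sloss", ]), 0.1)
})
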