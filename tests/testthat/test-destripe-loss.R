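oc <- asNamespace("octaclean")

test_that("reconstruction loss matches its closed forms and oracle", {
  i_in <- rand_image(1, 8)
  n <- rand_image(2, 8, lo = 0, hi = 0.3)
  expect_identical(reconstruction_loss(i_in, n, i_in - n), 0)
  # constant residual d on m x n grid -> |d| * sqrt(m*n) / 2
  d <- 0.17
  expect_equal(reconstruction_loss(i_in, n, i_in - n - d),
               0.5 * d * sqrt(64), tolerance = 1e-12)
  # brute-force elementwise oracle
  c_out <- rand_image(3, 8)
  r <- i_in - (n + c_out)
  expect_equal(reconstruction_loss(i_in, n, c_out),
               sqrt(sum(r^2)) / 2, tolerance = 1e-10)
  expect_error(reconstruction_loss(i_in, n, rand_image(1, 9)), "shape")
})

test_that("singular-value shrinkage follows max(s - lam, 0)", {
  expect_equal(shrink_singular_values(c(3, 1, 0.001), 0.5), c(2.5, 0.5, 0))
  s <- sort(runif(5), decreasing = TRUE)
  expect_identical(shrink_singular_values(s, 0), s)
  expect_identical(shrink_singular_values(c(0.3, 0.2), 0.5), c(0, 0))
  expect_error(shrink_singular_values(c(1, -0.1), 0.5), "non-negative")
})

test_that("stripe_degrade shrinks singular values exactly", {
  # rank-1: s * u v^T -> (s - lam) * u v^T
  u <- c(1, 0, 0, 0); v <- c(0, 1, 0, 0)
  n <- 2 * outer(u, v)
  expect_equal(stripe_degrade(n, 0.5), 1.5 * outer(u, v), tolerance = 1e-12)
  z <- matrix(0, 5, 5)
  expect_identical(stripe_degrade(z, 0.1), z)
  # nuclear-norm contraction
  for (seed in 1:5) {
    n <- rand_image(seed, 6)
    expect_lte(sum(svd(stripe_degrade(n, 0.05))$d), sum(svd(n)$d))
  }
})

test_that("stripe loss is zero at equality, symmetric, and composes", {
  a <- rand_image(4, 8); b <- rand_image(5, 8)
  expect_identical(stripe_loss(a, a, 0.01), 0)
  expect_equal(stripe_loss(a, b, 0.01), stripe_loss(b, a, 0.01),
               tolerance = 1e-12)
  ref <- sqrt(sum((stripe_degrade(a, 0.01) - stripe_degrade(b, 0.01))^2))
  expect_equal(stripe_loss(a, b, 0.01), ref, tolerance = 1e-8)
})

test_that("atv matches hand counts and its invariances", {
  expect_identical(atv(matrix(0.4, 8, 8)), 0)
  expect_identical(atv(matrix(c(0, 0, 1, 1), 2, 2)), 2)
  for (seed in 1:20) {
    c1 <- rand_image(seed, 16)
    k <- runif(1, -3, 3)
    expect_equal(atv(k * c1), abs(k) * atv(c1), tolerance = 1e-10)
    expect_equal(atv(c1 + 0.37), atv(c1), tolerance = 1e-10)
  }
})

test_that("atv loss vanishes on shifts and composes from the scalar", {
  a <- rand_image(6, 12); b <- rand_image(7, 12)
  expect_identical(atv_loss(a, a), 0)
  expect_equal(atv_loss(a, a + 0.2), 0, tolerance = 1e-12)
  expect_equal(atv_loss(a, b), abs(atv(a) - atv(b)), tolerance = 1e-12)
  expect_identical(atv_loss(a, a, variant = "map"), 0)
})

test_that("destripe loss is zero at perfect prediction and linear in terms", {
  n_ref <- rand_image(8, 8, lo = 0, hi = 0.4)
  c_ref <- rand_image(9, 8, lo = 0, hi = 0.6)
  i_in <- n_ref + c_ref
  w <- destripe_weights()
  expect_equal(as.numeric(destripe_loss(i_in, n_ref, c_ref, n_ref, c_ref,
                                        w)), 0, tolerance = 1e-12)
  # weights (1, 0, 0) reduce to the reconstruction term alone
  n_out <- rand_image(10, 8, lo = 0, hi = 0.4)
  c_out <- rand_image(11, 8)
  w100 <- destripe_weights(alpha = 1, beta = 0, gamma = 0)
  expect_equal(as.numeric(destripe_loss(i_in, n_out, c_out, n_ref, c_ref,
                                        w100)),
               reconstruction_loss(i_in, n_out, c_out), tolerance = 1e-12)
  # default weights equal the independently combined sum
  expected <- 0.5 * reconstruction_loss(i_in, n_out, c_out) +
    2 * stripe_loss(n_ref, n_out, 0.002) +
    1 * atv_loss(c_ref, c_out)
  expect_equal(as.numeric(destripe_loss(i_in, n_out, c_out, n_ref, c_ref,
                                        w)), expected, tolerance = 1e-8)
})

test_that("analytic gradients of each loss term match finite differences", {
  withr::with_seed(21, {
    i_in <- matrix(runif(64), 8)
    n_ref <- matrix(runif(64) * 0.4, 8)
    c_ref <- matrix(runif(64), 8)
    n_out <- matrix(runif(64) * 0.4, 8)
    c_out <- matrix(runif(64), 8)
  })
  g <- oc$reconstruction_loss_grad(i_in, n_out, c_out)
  expect_lt(max_rel_err(
    g, fd_grad(function(n) reconstruction_loss(i_in, n, c_out), n_out)),
    1e-4)
  # lam placed away from the singular values (non-smooth points)
  lam <- 0.05
  g <- oc$stripe_loss_grad(n_ref, n_out, lam)
  expect_lt(max_rel_err(
    g, fd_grad(function(n) stripe_loss(n_ref, n, lam), n_out)), 1e-4)
  # non-square shapes exercise the extra SVD-backward terms
  n_w <- cbind(n_out, n_out[, 1:3] * 0.7)
  n_wr <- cbind(n_ref, n_ref[, 1:3] * 0.9)
  g <- oc$stripe_loss_grad(n_wr, n_w, lam)
  expect_lt(max_rel_err(
    g, fd_grad(function(n) stripe_loss(n_wr, n, lam), n_w)), 1e-4)
  g <- oc$atv_loss_grad(c_ref, c_out)
  expect_lt(max_rel_err(
    g, fd_grad(function(cc) atv_loss(c_ref, cc), c_out)), 1e-4)
  g <- oc$atv_loss_grad(c_ref, c_out, "map")
  expect_lt(max_rel_err(
    g, fd_grad(function(cc) atv_loss(c_ref, cc, "map"), c_out)), 1e-4)
  # combined gradients
  w <- destripe_weights(lam = lam)
  g <- oc$destripe_loss_grads(i_in, n_out, c_out, n_ref, c_ref, w)
  expect_lt(max_rel_err(
    g$d_n_out,
    fd_grad(function(n) as.numeric(
      destripe_loss(i_in, n, c_out, n_ref, c_ref, w)), n_out)), 1e-4)
  expect_lt(max_rel_err(
    g$d_c_out,
    fd_grad(function(cc) as.numeric(
      destripe_loss(i_in, n_out, cc, n_ref, c_ref, w)), c_out)), 1e-4)
})

test_that("destripe loss is Lipschitz-continuous in the noise estimate", {
  n_ref <- rand_image(30, 8, lo = 0, hi = 0.4)
  c_ref <- rand_image(31, 8)
  i_in <- pmin(n_ref + c_ref, 1)
  n_out <- rand_image(32, 8, lo = 0, hi = 0.4)
  c_out <- rand_image(33, 8)
  w <- destripe_weights()
  base <- as.numeric(destripe_loss(i_in, n_out, c_out, n_ref, c_ref, w))
  for (eps in c(1e-3, 1e-4)) {
    pert <- n_out + eps * rand_image(34, 8, lo = -1, hi = 1)
    delta <- abs(as.numeric(
      destripe_loss(i_in, pert, c_out, n_ref, c_ref, w)) - base)
    # gradient norms are bounded by alpha/2 + beta here, so O(eps)
    expect_lt(delta, 50 * eps)
  }
})
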