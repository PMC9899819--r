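#' Weights and constants of the re-enhancing objective
#'
#' The enhancement objective adds to the baseline unpaired-translation
#' losses a cyclic perceptual term weighted by `xi` and two structure terms
#' weighted by `rho1` (forward generator) and `rho2` (backward generator).
#' The structure term is stabilized by a small constant `c` and evaluated
#' over non-overlapping square windows of side `window`.
#'
#' @param xi Weight of the cyclic perceptual loss (default 0.5).
#' @param rho1,rho2 Weights of the two structure losses (default 0.5 each).
#' @param c Positive stabilizer, default `0.03^2 / 2` on the `[0, 1]`
#'   intensity scale (the conventional SSIM structure-term constant).
#' @param window Window side length in pixels (`>= 2`).
#' @param feature_layers Extractor tap depths for the perceptual loss.
#' @return A validated `enhance_weights` list.
#' @export
enhance_weights <- function(xi = 0.5, rho1 = 0.5, rho2 = 0.5,
                            c = 0.03^2 / 2, window = 8L,
                            feature_layers = c(2L, 5L)) {
  check_scalar(xi, "xi", 0)
  check_scalar(rho1, "rho1", 0)
  check_scalar(rho2, "rho2", 0)
  check_scalar(c, "c", 0, strict_lo = TRUE)
  check_count(window, "window", min = 2L)
  structure(list(xi = xi, rho1 = rho1, rho2 = rho2, c = c,
                 window = as.integer(window),
                 feature_layers = as.integer(feature_layers)),
            class = "enhance_weights")
}

mae <- function(a, b) mean(abs(a - b))
mse_to <- function(s, t) mean((s - t)^2)

#' Baseline unpaired-translation loss
#'
#' Least-squares adversarial terms for both directions plus
#' cycle-consistency and identity L1 terms:
#' `adv + lambda_cyc * (|G_YX(G_XY(x)) - x|_1 + |G_XY(G_YX(y)) - y|_1) +
#'  lambda_idt * (|G_XY(y) - y|_1 + |G_YX(x) - x|_1)`
#' with L1 norms taken as pixel means. Defaults `lambda_cyc = 10`,
#' `lambda_idt = 5` are the canonical settings of the bi-directional
#' translation architecture this stage follows.
#'
#' @param x,y One image from each domain.
#' @param models A `psgan_models` list from [build_psgan()].
#' @param lambda_cyc,lambda_idt Term weights.
#' @return Total scalar with a `"terms"` attribute
#'   (`adv`, `cycle`, `identity`).
#' @export
baseline_loss <- function(x, y, models, lambda_cyc = 10, lambda_idt = 5) {
  check_matrix(x, "x"); check_matrix(y, "y")
  check_same_shape(x, y, "x", "y")
  fy <- generator_apply(models$g_xy, x)
  fx <- generator_apply(models$g_yx, y)
  adv <- mse_to(disc_apply(models$d_y, fy), 1) +
    mse_to(disc_apply(models$d_x, fx), 1)
  cyc <- mae(generator_apply(models$g_yx, fy), x) +
    mae(generator_apply(models$g_xy, fx), y)
  idt <- mae(generator_apply(models$g_xy, y), y) +
    mae(generator_apply(models$g_yx, x), x)
  terms <- c(adv = adv, cycle = cyc, identity = idt)
  structure(adv + lambda_cyc * cyc + lambda_idt * idt, terms = terms)
}

#' Cyclic perceptual loss
#'
#' Feature-level cycle consistency: squared Frobenius distances between the
#' extractor features of each image and of its round-trip reconstruction,
#' summed over the configured tap depths and both directions.
#'
#' @param x,y One image from each domain.
#' @param g_xy,g_yx The two generators.
#' @param extractor A [feature_extractor()].
#' @return Non-negative scalar.
#' @export
cyclic_perceptual_loss <- function(x, y, g_xy, g_yx, extractor) {
  rx <- generator_apply(g_yx, generator_apply(g_xy, x))
  ry <- generator_apply(g_xy, generator_apply(g_yx, y))
  fx <- extract_features(extractor, x)
  frx <- extract_features(extractor, rx)
  fy <- extract_features(extractor, y)
  fry <- extract_features(extractor, ry)
  sum(vapply(seq_along(fx), function(l) {
    sum((fx[[l]] - frx[[l]])^2) + sum((fy[[l]] - fry[[l]])^2)
  }, numeric(1)))
}

# Per-window structure statistics over non-overlapping w x w tiles; partial
# edge windows are dropped. Population (1/n) moments.
.window_stats <- function(x, gx, w) {
  h <- nrow(x) %/% w
  wn <- ncol(x) %/% w
  if (h < 1L || wn < 1L) stop_invalid("image smaller than one window")
  n <- w * w
  # block index for each retained pixel
  ii <- seq_len(h * w)
  jj <- seq_len(wn * w)
  blk <- matrix((rep((jj - 1L) %/% w, each = length(ii))) * h +
                  ((ii - 1L) %/% w) + 1L, length(ii), length(jj))
  xs <- x[ii, jj]; gs <- gx[ii, jj]
  f <- factor(blk, levels = seq_len(h * wn))
  mx <- as.vector(tapply(xs, f, mean))
  mg <- as.vector(tapply(gs, f, mean))
  sxx <- as.vector(tapply(xs * xs, f, mean)) - mx^2
  sgg <- as.vector(tapply(gs * gs, f, mean)) - mg^2
  sxg <- as.vector(tapply(xs * gs, f, mean)) - mx * mg
  list(mx = mx, mg = mg, var_x = pmax(sxx, 0), var_g = pmax(sgg, 0),
       cov = sxg, blk = blk, ii = ii, jj = jj, n = n)
}

#' Structure loss between an image and its enhancement
#'
#' `1 - (1/M) * sum_i (cov_i + c) / (sd_x_i * sd_gx_i + c)` over the `M`
#' non-overlapping windows: one minus the mean per-window SSIM structure
#' term. Zero for identical images and (up to the `c` stabilization) for
#' any positive affine rescaling; at most 2 when every window is perfectly
#' anti-correlated.
#'
#' @param x Input image.
#' @param gx Its enhanced version, same shape.
#' @param weights An [enhance_weights()] object (for `c` and `window`).
#' @return Scalar in `[0, 2]`.
#' @export
structure_loss <- function(x, gx, weights = enhance_weights()) {
  check_matrix(x, "x"); check_matrix(gx, "gx")
  check_same_shape(x, gx, "x", "gx")
  st <- .window_stats(x, gx, weights$window)
  terms <- (st$cov + weights$c) /
    (sqrt(st$var_x) * sqrt(st$var_g) + weights$c)
  1 - mean(terms)
}

# Gradient of structure_loss with respect to gx.
structure_loss_grad <- function(x, gx, weights = enhance_weights()) {
  st <- .window_stats(x, gx, weights$window)
  m <- length(st$mx)
  sx <- sqrt(st$var_x); sg <- sqrt(st$var_g)
  den <- sx * sg + weights$c
  num <- st$cov + weights$c
  xs <- x[st$ii, st$jj]; gs <- gx[st$ii, st$jj]
  blk <- as.vector(st$blk)
  # per-pixel pieces: dcov/dg = (x - mx)/n ; dsg/dg = (g - mg)/(n*sg)
  dcov <- (as.vector(xs) - st$mx[blk]) / st$n
  sg_blk <- sg[blk]
  dsg <- ifelse(sg_blk > 1e-12,
                (as.vector(gs) - st$mg[blk]) / (st$n * sg_blk), 0)
  dterm <- matrix((dcov * den[blk] - num[blk] * sx[blk] * dsg) / den[blk]^2,
                  nrow(xs), ncol(xs))
  g <- matrix(0, nrow(gx), ncol(gx))
  g[st$ii, st$jj] <- -dterm / m
  g
}

#' Full re-enhancing objective
#'
#' `baseline + xi * L_p + rho1 * L_s(x, G_XY(x)) + rho2 * L_s(y, G_YX(y))`.
#' Setting `xi = rho1 = rho2 = 0` recovers the baseline objective exactly
#' (the ablation axis of the enhancement stage).
#'
#' @param x,y One image from each domain.
#' @param models A `psgan_models` list.
#' @param extractor A [feature_extractor()].
#' @param config A [psgan_config()] object (for weights).
#' @return Total scalar with a `"terms"` attribute (`baseline`, `adv`,
#'   `cycle`, `identity`, `perceptual`, `structure_xy`, `structure_yx`).
#' @export
psgan_loss <- function(x, y, models, extractor, config = psgan_config()) {
  w <- config$weights
  bl <- baseline_loss(x, y, models, config$lambda_cyc, config$lambda_idt)
  lp <- cyclic_perceptual_loss(x, y, models$g_xy, models$g_yx, extractor)
  ls_xy <- structure_loss(x, generator_apply(models$g_xy, x), w)
  ls_yx <- structure_loss(y, generator_apply(models$g_yx, y), w)
  total <- as.numeric(bl) + w$xi * lp + w$rho1 * ls_xy + w$rho2 * ls_yx
  structure(total,
            terms = c(baseline = as.numeric(bl), attr(bl, "terms"),
                      perceptual = lp, structure_xy = ls_xy,
                      structure_yx = ls_yx))
}
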