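#' Weights of the composite de-striping objective
#'
#' The de-striping objective is
#' `L = alpha * L_recon + beta * L_stripe + gamma * L_atv`, where `L_recon`
#' ties the predicted noise/clean pair to the input, `L_stripe` compares the
#' low-rank stripe components of predicted and reference noise maps after
#' singular-value soft-thresholding with threshold `lam`, and `L_atv`
#' compares anisotropic total variation (edge sharpness). Defaults are the
#' training settings used throughout the package: `alpha = 0.5`, `beta = 2`,
#' `gamma = 1`, `lam = 0.002` on the `[0, 1]` intensity scale.
#'
#' @param alpha,beta,gamma Non-negative term weights.
#' @param lam Positive shrinkage threshold for the singular values.
#' @return A validated `destripe_weights` list.
#' @export
destripe_weights <- function(alpha = 0.5, beta = 2, gamma = 1, lam = 0.002) {
  check_scalar(alpha, "alpha", 0)
  check_scalar(beta, "beta", 0)
  check_scalar(gamma, "gamma", 0)
  check_scalar(lam, "lam", 0, strict_lo = TRUE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, lam = lam),
            class = "destripe_weights")
}

#' Reconstruction loss
#'
#' `0.5 * ||i_in - (n_out + c_out)||_F` (unsquared Frobenius norm of the
#' elementwise residual): the predicted noise and clean maps must jointly
#' reconstruct the input image.
#'
#' @param i_in,n_out,c_out Same-shape numeric matrices.
#' @param squared Use the squared-norm variant `0.5 * ||.||_F^2` (smoother
#'   gradients; the unsquared form is the default).
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(i_in, n_out, c_out, squared = FALSE) {
  check_matrix(i_in, "i_in"); check_matrix(n_out, "n_out")
  check_matrix(c_out, "c_out")
  check_same_shape(i_in, n_out, "i_in", "n_out")
  check_same_shape(i_in, c_out, "i_in", "c_out")
  r <- i_in - (n_out + c_out)
  if (squared) 0.5 * sum(r * r) else 0.5 * frob(r)
}

# Gradient of reconstruction_loss with respect to n_out (identical for
# c_out). Subgradient 0 at the zero-residual point.
reconstruction_loss_grad <- function(i_in, n_out, c_out, squared = FALSE) {
  r <- i_in - (n_out + c_out)
  if (squared) return(-r)
  nrm <- frob(r)
  if (nrm == 0) matrix(0, nrow(r), ncol(r)) else -r / (2 * nrm)
}

#' Soft-threshold a vector of singular values
#'
#' Applies `max(s_i - lam, 0)` elementwise; with the input sorted
#' non-increasing the output stays sorted non-increasing.
#'
#' @param s Non-negative singular values, sorted non-increasing.
#' @param lam Positive threshold.
#' @return Shrunk singular values.
#' @export
shrink_singular_values <- function(s, lam) {
  if (any(s < 0)) stop_invalid("singular values must be non-negative")
  check_scalar(lam, "lam", 0)
  pmax(s - lam, 0)
}

#' Stripe degradation: singular-value soft-thresholding
#'
#' Computes the SVD `N = U S V^T` and returns `U shrink(S) V^T`, the matrix
#' whose singular values are `max(sigma_i - lam, 0)`. This is the proximal
#' operator of `lam * ||.||_*` (nuclear norm) and isolates the dominant
#' low-rank stripe component of a noise map.
#'
#' @param n Real matrix.
#' @param lam Positive threshold.
#' @return Matrix of the same shape with shrunk singular values.
#' @export
stripe_degrade <- function(n, lam) {
  check_matrix(n, "n")
  check_scalar(lam, "lam", 0)
  sv <- svd(n)
  d <- shrink_singular_values(sv$d, lam)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(n), ncol(n)))
  sv$u[, keep, drop = FALSE] %*%
    (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Stripe loss
#'
#' `||stripe_degrade(n_ref, lam) - stripe_degrade(n_out, lam)||_F`: keeps
#' the low-rank stripe component of the predicted noise map consistent with
#' that of the reference stripe-noise image.
#'
#' @param n_ref,n_out Same-shape noise maps.
#' @param lam Positive shrinkage threshold.
#' @param squared Use the squared Frobenius norm instead of the plain norm.
#' @return Non-negative scalar.
#' @export
stripe_loss <- function(n_ref, n_out, lam, squared = FALSE) {
  check_matrix(n_ref, "n_ref"); check_matrix(n_out, "n_out")
  check_same_shape(n_ref, n_out, "n_ref", "n_out")
  r <- stripe_degrade(n_ref, lam) - stripe_degrade(n_out, lam)
  if (squared) sum(r * r) else frob(r)
}

# Gradient of stripe_loss with respect to n_out: full differentiation
# through the SVD of n_out. Uses the standard thin-SVD backward with
# F_ij = 1/(d_j^2 - d_i^2) (guarded near degenerate singular values); the
# soft-threshold subgradient at the kink sigma = lam is taken as 0.
stripe_loss_grad <- function(n_ref, n_out, lam, squared = FALSE,
                             a_ref = NULL) {
  if (is.null(a_ref)) a_ref <- stripe_degrade(n_ref, lam)
  m <- nrow(n_out); n <- ncol(n_out); k <- min(m, n)
  sv <- svd(n_out)
  u <- sv$u; v <- sv$v; d <- sv$d
  ds <- pmax(d - lam, 0)
  d_out <- u %*% (ds * t(v))
  r <- d_out - a_ref
  if (squared) {
    g <- 2 * r
  } else {
    nrm <- frob(r)
    if (nrm == 0) return(matrix(0, m, n))
    g <- r / nrm
  }
  # Adjoints of U, diag(S-hat), V of the reconstruction D = U Shat V^T
  gu <- g %*% v %*% diag(ds, k)                    # dL/dU
  gv <- t(g) %*% u %*% diag(ds, k)                 # dL/dV
  gd <- diag(t(u) %*% g %*% v) * as.numeric(d > lam)
  # SVD backward
  d2 <- d^2
  den <- outer(d2, d2, FUN = function(a, b) b - a)  # d_j^2 - d_i^2
  f <- ifelse(abs(den) < 1e-12, 0, 1 / den)
  diag(f) <- 0
  utgu <- t(u) %*% gu
  vtgv <- t(v) %*% gv
  j_mat <- (f * (utgu - t(utgu))) %*% diag(d, k) +
    diag(d, k) %*% (f * (vtgv - t(vtgv))) +
    diag(gd, k)
  dn <- u %*% j_mat %*% t(v)
  dinv <- ifelse(d > 1e-12, ds / d, 0)             # Shat S^{-1}, 0-guarded
  if (m > k) {
    p <- g %*% v %*% diag(dinv, k)                 # = gu S^{-1}
    dn <- dn + (p - u %*% (t(u) %*% p)) %*% t(v)
  }
  if (n > k) {
    q <- diag(dinv, k) %*% t(u) %*% g              # = S^{-1} gv^T
    dn <- dn + u %*% (q - (q %*% v) %*% t(v))
  }
  dn
}

#' Anisotropic total variation of an image
#'
#' Sum of the L1 norms of the horizontal and vertical forward differences
#' (no wrap-around at boundaries): a scalar edge-sharpness measure.
#'
#' @param c Numeric matrix, at least 2x2.
#' @return Non-negative scalar.
#' @export
atv <- function(c) {
  check_matrix(c, "c")
  if (nrow(c) < 2L || ncol(c) < 2L) stop_invalid("image must be at least 2x2")
  h <- c[, -1L, drop = FALSE] - c[, -ncol(c), drop = FALSE]
  v <- c[-1L, , drop = FALSE] - c[-nrow(c), , drop = FALSE]
  sum(abs(h)) + sum(abs(v))
}

# Subgradient of atv(c); sign(0) treated as 0.
atv_grad <- function(c) {
  g <- matrix(0, nrow(c), ncol(c))
  h <- sign(c[, -1L, drop = FALSE] - c[, -ncol(c), drop = FALSE])
  v <- sign(c[-1L, , drop = FALSE] - c[-nrow(c), , drop = FALSE])
  g[, -1L] <- g[, -1L, drop = FALSE] + h
  g[, -ncol(c)] <- g[, -ncol(c), drop = FALSE] - h
  g[-1L, ] <- g[-1L, , drop = FALSE] + v
  g[-nrow(c), ] <- g[-nrow(c), , drop = FALSE] - v
  g
}

#' Anisotropic-TV loss between a reference and a predicted clean image
#'
#' The default (`variant = "scalar"`) reads the edge constraint literally as
#' the absolute difference of the two scalar ATV values,
#' `|atv(c_ref) - atv(c_out)|`. The `"map"` variant instead compares the
#' absolute horizontal and vertical gradient maps elementwise (one Frobenius
#' norm over both stacked difference maps), which can localize edges.
#'
#' @param c_ref,c_out Same-shape images.
#' @param variant `"scalar"` (default) or `"map"`.
#' @return Non-negative scalar.
#' @export
atv_loss <- function(c_ref, c_out, variant = c("scalar", "map")) {
  variant <- match.arg(variant)
  check_matrix(c_ref, "c_ref"); check_matrix(c_out, "c_out")
  check_same_shape(c_ref, c_out, "c_ref", "c_out")
  if (variant == "scalar") {
    abs(atv(c_ref) - atv(c_out))
  } else {
    dh <- abs(.fdiff_h(c_ref)) - abs(.fdiff_h(c_out))
    dv <- abs(.fdiff_v(c_ref)) - abs(.fdiff_v(c_out))
    sqrt(sum(dh * dh) + sum(dv * dv))
  }
}

.fdiff_h <- function(x) x[, -1L, drop = FALSE] - x[, -ncol(x), drop = FALSE]
.fdiff_v <- function(x) x[-1L, , drop = FALSE] - x[-nrow(x), , drop = FALSE]

# Subgradient of atv_loss with respect to c_out.
atv_loss_grad <- function(c_ref, c_out, variant = "scalar") {
  if (variant == "scalar") {
    s <- sign(atv(c_ref) - atv(c_out))
    return(-s * atv_grad(c_out))
  }
  dh_ref <- abs(.fdiff_h(c_ref)); dv_ref <- abs(.fdiff_v(c_ref))
  h_out <- .fdiff_h(c_out); v_out <- .fdiff_v(c_out)
  val <- sqrt(sum((dh_ref - abs(h_out))^2) + sum((dv_ref - abs(v_out))^2))
  if (val == 0) return(matrix(0, nrow(c_out), ncol(c_out)))
  # d/d|h_out| of the norm, then chain through |.| and the difference op
  gh <- -(dh_ref - abs(h_out)) / val * sign(h_out)
  gv <- -(dv_ref - abs(v_out)) / val * sign(v_out)
  g <- matrix(0, nrow(c_out), ncol(c_out))
  g[, -1L] <- g[, -1L, drop = FALSE] + gh
  g[, -ncol(c_out)] <- g[, -ncol(c_out), drop = FALSE] - gh
  g[-1L, ] <- g[-1L, , drop = FALSE] + gv
  g[-nrow(c_out), ] <- g[-nrow(c_out), , drop = FALSE] - gv
  g
}

#' Composite de-striping loss
#'
#' `alpha * L_recon + beta * L_stripe + gamma * L_atv` over a prediction
#' (`n_out`, `c_out`) and its reference triplet. The returned scalar carries
#' a `"terms"` attribute with the three unweighted components.
#'
#' @param i_in Corrupted input image.
#' @param n_out,c_out Predicted noise and clean maps.
#' @param n_ref,c_ref Reference noise and clean maps.
#' @param weights A [destripe_weights()] object.
#' @param atv_variant Passed to [atv_loss()].
#' @param squared Use squared-norm variants of the reconstruction and stripe
#'   terms.
#' @return Non-negative scalar with attribute `terms`.
#' @export
destripe_loss <- function(i_in, n_out, c_out, n_ref, c_ref,
                          weights = destripe_weights(),
                          atv_variant = "scalar", squared = FALSE) {
  if (!inherits(weights, "destripe_weights")) {
    stop_invalid("weights must come from destripe_weights()")
  }
  terms <- c(
    recon = reconstruction_loss(i_in, n_out, c_out, squared = squared),
    stripe = stripe_loss(n_ref, n_out, weights$lam, squared = squared),
    atv = atv_loss(c_ref, c_out, variant = atv_variant)
  )
  total <- weights$alpha * terms[["recon"]] + weights$beta * terms[["stripe"]] +
    weights$gamma * terms[["atv"]]
  structure(total, terms = terms)
}

# Gradients of destripe_loss with respect to the two predictions. `a_ref`
# optionally carries a precomputed stripe_degrade(n_ref, lam).
destripe_loss_grads <- function(i_in, n_out, c_out, n_ref, c_ref,
                                weights = destripe_weights(),
                                atv_variant = "scalar", squared = FALSE,
                                a_ref = NULL) {
  g_rec <- reconstruction_loss_grad(i_in, n_out, c_out, squared = squared)
  d_n <- weights$alpha * g_rec
  if (weights$beta > 0) {
    d_n <- d_n + weights$beta *
      stripe_loss_grad(n_ref, n_out, weights$lam, squared = squared,
                       a_ref = a_ref)
  }
  d_c <- weights$alpha * g_rec
  if (weights$gamma > 0) {
    d_c <- d_c + weights$gamma * atv_loss_grad(c_ref, c_out, atv_variant)
  }
  list(d_n_out = d_n, d_c_out = d_c)
}
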