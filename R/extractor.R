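#' Deterministic convolutional feature extractor for the perceptual loss
#'
#' A fixed (non-trainable) stack of `n_stages` conv3x3 + ReLU + 2x average
#' pool stages with seeded random weights; features are tapped after the
#' configured pooling stages (default after the 2nd and 5th, the low- and
#' high-level tap depths of the perceptual loss). Random convolutional
#' features are a standard fully-offline stand-in for a pretrained
#' classification backbone in perceptual losses: the loss structure
#' (multi-depth feature comparison under squared Frobenius norms) is
#' unchanged, only the filters differ.
#'
#' @param seed Seed fixing the random filters.
#' @param channels Channels per stage.
#' @param taps Stage indices (after pooling) whose features are returned.
#' @param n_stages Total number of stages (`>= max(taps)`).
#' @return A `feature_extractor` object.
#' @export
feature_extractor <- function(seed = 99L, channels = 8L, taps = c(2L, 5L),
                              n_stages = max(taps)) {
  check_count(n_stages, "n_stages")
  if (any(taps < 1L) || any(taps > n_stages)) {
    stop_invalid("taps must lie within 1..n_stages")
  }
  with_seed(seed, {
    stages <- lapply(seq_len(n_stages), function(s) {
      cin <- if (s == 1L) 1L else channels
      list(layer_conv(3L, cin, channels), layer_relu(), layer_avgpool())
    })
    structure(list(stages = stages, taps = as.integer(taps),
                   channels = channels, seed = as.integer(seed)),
              class = "feature_extractor")
  })
}

# Forward pass; returns tapped features plus the caches needed to
# backpropagate a feature-space gradient to the input image.
extractor_fwd <- function(extractor, x) {
  a <- as_chw(x)
  feats <- vector("list", length(extractor$taps))
  caches <- vector("list", length(extractor$stages))
  for (s in seq_along(extractor$stages)) {
    r <- net_fwd(extractor$stages[[s]], a)
    a <- r$y
    caches[[s]] <- r$caches
    hit <- which(extractor$taps == s)
    if (length(hit)) feats[[hit]] <- a
  }
  list(features = feats, caches = caches)
}

#' Extract multi-depth features from an image
#'
#' @param extractor A [feature_extractor()].
#' @param image Input image matrix; each spatial dimension must be
#'   divisible by `2^max(taps)`.
#' @return A list of feature arrays, one per configured tap.
#' @export
extract_features <- function(extractor, image) {
  if (!inherits(extractor, "feature_extractor")) {
    stop_invalid("extractor must come from feature_extractor()")
  }
  check_matrix(image, "image")
  div <- 2^length(extractor$stages)
  if (nrow(image) %% div != 0 || ncol(image) %% div != 0) {
    stop_invalid("image size must be divisible by ", div,
                 " for ", length(extractor$stages), " extractor stages")
  }
  extractor_fwd(extractor, image)$features
}

# Backpropagate per-tap feature gradients to an image-space gradient.
# No parameter gradients: the extractor is frozen.
extractor_bwd <- function(extractor, caches, d_feats) {
  n <- length(extractor$stages)
  dy <- NULL
  for (s in rev(seq_len(n))) {
    hit <- which(extractor$taps == s)
    if (length(hit)) {
      dtap <- d_feats[[hit]]
      dy <- if (is.null(dy)) dtap else dy + dtap
    }
    if (!is.null(dy)) {
      dy <- net_bwd(extractor$stages[[s]], caches[[s]], dy)$dx
    }
  }
  dy[, , 1L]
}
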