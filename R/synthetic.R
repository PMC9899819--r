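#' Parameters for the vessel phantom generator
#'
#' Describes the clean, vessel-bearing phantoms that stand in for
#' high-contrast, noise-free *en face* angiograms: smooth curvilinear bright
#' vessels on a dark speckled background.
#'
#' @param n_vessels Number of vessels to draw (0 gives a pure background
#'   texture with an empty mask).
#' @param width_range Range of vessel thickness in pixels.
#' @param intensity_range Range of vessel brightness; must lie entirely above
#'   `background_level` (vessels are bright on dark).
#' @param background_level Mean background intensity in `[0, 1]`.
#' @param texture_sd Standard deviation of the Gaussian background speckle.
#' @param blur_sigma Gaussian blur (pixels) applied to the rendered vessel
#'   layer to soften edges.
#' @return A validated `vessel_phantom_params` list.
#' @export
vessel_phantom_params <- function(n_vessels = 8L,
                                  width_range = c(1.5, 4),
                                  intensity_range = c(0.55, 0.95),
                                  background_level = 0.12,
                                  texture_sd = 0.04,
                                  blur_sigma = 0.8) {
  check_count(n_vessels, "n_vessels", min = 0L)
  if (any(width_range <= 0)) stop_invalid("width_range must be positive")
  if (length(width_range) != 2L || width_range[1] > width_range[2]) {
    stop_invalid("width_range must be a non-empty range")
  }
  check_range(intensity_range, "intensity_range")
  check_scalar(background_level, "background_level", 0, 1)
  if (intensity_range[1] <= background_level) {
    stop_invalid("intensity_range must lie entirely above background_level")
  }
  check_scalar(texture_sd, "texture_sd", 0, 1)
  check_scalar(blur_sigma, "blur_sigma", 0, Inf)
  structure(list(n_vessels = as.integer(n_vessels),
                 width_range = width_range,
                 intensity_range = intensity_range,
                 background_level = background_level,
                 texture_sd = texture_sd,
                 blur_sigma = blur_sigma),
            class = "vessel_phantom_params")
}

#' Parameters for the stripe-noise field generator
#'
#' Stripe artifacts are additive bright bands of one orientation with
#' randomly drawn intensity, length, thickness and position; each band is a
#' rank-1 pattern, so a field of `k` stripes has matrix rank at most `k`.
#'
#' @param orientation `"horizontal"` (constant along a row, the B-scan
#'   direction) or `"vertical"`.
#' @param n_stripes_mean Expected stripe count per field (Poisson-drawn).
#' @param thickness_range Stripe thickness range in pixels.
#' @param amplitude_range Additive amplitude range, a sub-range of `(0, 1]`.
#' @param full_span_prob Probability that a stripe spans the full row/column.
#' @param min_fraction Minimum fractional length of a partial stripe.
#' @return A validated `stripe_field_params` list.
#' @export
stripe_field_params <- function(orientation = c("horizontal", "vertical"),
                                n_stripes_mean = 3,
                                thickness_range = c(1, 4),
                                amplitude_range = c(0.1, 0.5),
                                full_span_prob = 0.7,
                                min_fraction = 0.3) {
  orientation <- match.arg(orientation)
  check_scalar(n_stripes_mean, "n_stripes_mean", 0, Inf)
  if (length(thickness_range) != 2L || any(thickness_range < 1) ||
      thickness_range[1] > thickness_range[2]) {
    stop_invalid("thickness_range must be a non-empty range of pixels >= 1")
  }
  check_range(amplitude_range, "amplitude_range", lo = 0, hi = 1)
  if (amplitude_range[1] <= 0) {
    stop_invalid("amplitude_range must be strictly positive (additive bright stripes)")
  }
  check_scalar(full_span_prob, "full_span_prob", 0, 1)
  check_scalar(min_fraction, "min_fraction", 0, 1, strict_lo = TRUE)
  structure(list(orientation = orientation,
                 n_stripes_mean = n_stripes_mean,
                 thickness_range = thickness_range,
                 amplitude_range = amplitude_range,
                 full_span_prob = full_span_prob,
                 min_fraction = min_fraction),
            class = "stripe_field_params")
}

#' Generate a clean vessel phantom and its exact vessel mask
#'
#' Vessels are rendered as smooth spline curves through random waypoints,
#' dilated to a sampled thickness, composited brightly over a speckled dark
#' background and softened with a small Gaussian blur. The returned mask
#' marks the exact pre-blur vessel footprint.
#'
#' @param seed Integer seed; output is bit-identical for a fixed seed.
#' @param height,width Image size in pixels (both `>= 16`).
#' @param params A [vessel_phantom_params()] object.
#' @return A list with `image` (matrix in `[0, 1]`) and `mask`
#'   (0/1 matrix of vessel pixels).
#' @export
generate_vessel_phantom <- function(seed, height, width,
                                    params = vessel_phantom_params()) {
  check_count(height, "height", min = 16L)
  check_count(width, "width", min = 16L)
  if (!inherits(params, "vessel_phantom_params")) {
    stop_invalid("params must come from vessel_phantom_params()")
  }
  with_seed(seed, {
    bg <- matrix(params$background_level +
                   rnorm(height * width, sd = params$texture_sd),
                 height, width)
    vessel <- matrix(0, height, width)
    mask <- matrix(0L, height, width)
    for (v in seq_len(params$n_vessels)) {
      thick <- runif(1, params$width_range[1], params$width_range[2])
      inten <- runif(1, params$intensity_range[1], params$intensity_range[2])
      pts <- .vessel_curve(height, width)
      stamped <- .stamp_curve(height, width, pts, thick / 2)
      mask[stamped] <- 1L
      vessel[stamped] <- pmax(vessel[stamped], inten)
    }
    if (params$blur_sigma > 0 && params$n_vessels > 0) {
      vessel <- EBImage::gblur(vessel, sigma = params$blur_sigma)
    }
    list(image = clip01(bg + vessel), mask = mask)
  })
}

# A smooth random curve across the image: spline through random waypoints.
.vessel_curve <- function(height, width) {
  n_way <- sample(4:6, 1)
  # orient the parametrization along the longer random direction
  horiz <- runif(1) < 0.5
  if (horiz) {
    xs <- sort(runif(n_way, 1, width))
    xs[1] <- runif(1, 1, width * 0.25)
    xs[n_way] <- runif(1, width * 0.75, width)
    ys <- runif(n_way, 1, height)
    fit <- spline(xs, ys, n = 4L * max(height, width))
    cbind(fit$y, fit$x)              # (row, col)
  } else {
    ys <- sort(runif(n_way, 1, height))
    ys[1] <- runif(1, 1, height * 0.25)
    ys[n_way] <- runif(1, height * 0.75, height)
    xs <- runif(n_way, 1, width)
    fit <- spline(ys, xs, n = 4L * max(height, width))
    cbind(fit$x, fit$y)
  }
}

# Mark pixels within `radius` of any curve point; returns a logical matrix.
.stamp_curve <- function(height, width, pts, radius) {
  hit <- matrix(FALSE, height, width)
  r <- max(radius, 0.5)
  ri <- ceiling(r)
  for (p in seq_len(nrow(pts))) {
    ci <- round(pts[p, 1]); cj <- round(pts[p, 2])
    if (ci < 1 - ri || ci > height + ri || cj < 1 - ri || cj > width + ri) next
    ii <- max(1, ci - ri):min(height, ci + ri)
    jj <- max(1, cj - ri):min(width, cj + ri)
    d2 <- outer((ii - pts[p, 1])^2, (jj - pts[p, 2])^2, `+`)
    hit[ii, jj] <- hit[ii, jj] | (d2 <= r^2)
  }
  hit
}

#' Generate a low-rank stripe-noise field
#'
#' Draws a Poisson number of bands of the configured orientation; each band
#' has a constant amplitude over its support, smoothed by a 1-pixel Gaussian
#' along its short axis to avoid aliasing. Every band is a rank-1 pattern,
#' so the field's matrix rank never exceeds the number of stripes drawn.
#'
#' @param seed Integer seed.
#' @param height,width Field size in pixels.
#' @param params A [stripe_field_params()] object.
#' @return A non-negative `height x width` matrix, clipped to `[0, 1]`, with
#'   attribute `n_stripes` giving the realized stripe count.
#' @export
generate_stripe_field <- function(seed, height, width,
                                  params = stripe_field_params()) {
  check_count(height, "height", min = 16L)
  check_count(width, "width", min = 16L)
  if (!inherits(params, "stripe_field_params")) {
    stop_invalid("params must come from stripe_field_params()")
  }
  horiz <- params$orientation == "horizontal"
  n_axis <- if (horiz) height else width    # axis stripes stack along
  n_span <- if (horiz) width else height    # axis stripes run along
  with_seed(seed, {
    k <- rpois(1, params$n_stripes_mean)
    field <- matrix(0, height, width)
    if (k > 0) {
      for (s in seq_len(k)) {
        thick <- max(1L, round(runif(1, params$thickness_range[1],
                                     params$thickness_range[2])))
        amp <- runif(1, params$amplitude_range[1], params$amplitude_range[2])
        pos <- sample.int(n_axis, 1)
        band <- pmax(1L, pos - (thick - 1L) %/% 2L):
          pmin(n_axis, pos + thick %/% 2L)
        if (runif(1) < params$full_span_prob) {
          span <- seq_len(n_span)
        } else {
          len <- max(1L, round(runif(1, params$min_fraction, 1) * n_span))
          start <- sample.int(n_span - len + 1L, 1)
          span <- start:(start + len - 1L)
        }
        if (horiz) {
          field[band, span] <- field[band, span] + amp
        } else {
          field[span, band] <- field[span, band] + amp
        }
      }
      # 1-pixel Gaussian along the short axis: a linear map applied on the
      # stacking side, so each stripe stays a rank-1 pattern.
      g <- gauss1d_matrix(n_axis, sigma = 1)
      field <- if (horiz) g %*% field else field %*% t(g)
      field <- pmin(field, 1)
    }
    structure(field, n_stripes = k)
  })
}

#' Corrupt a clean image with graded stripe noise
#'
#' Adds `level` independently drawn stripe fields (the stripe noise level of
#' the synthesis protocol: level i means i fields summed onto one clean
#' image), clips the sum to `[0, 1]`, and stores the noise as
#' `corrupted - clean` so the additive decomposition `corrupted = clean +
#' noise` holds exactly after clipping.
#'
#' @param clean Clean image matrix in `[0, 1]`.
#' @param level Integer noise level `>= 1`.
#' @param seed Integer seed; the per-field seeds are derived from it.
#' @param params A [stripe_field_params()] object.
#' @return A `corruption_triplet` list: `clean`, `noise`, `corrupted`,
#'   `level`.
#' @export
corrupt_image <- function(clean, level, seed,
                          params = stripe_field_params()) {
  check_image(clean, "clean")
  check_count(level, "level", min = 1L)
  sub_seeds <- derive_seeds(seed, level)
  total <- clean
  for (j in seq_len(level)) {
    total <- total + generate_stripe_field(sub_seeds[j], nrow(clean),
                                           ncol(clean), params)
  }
  corrupted <- pmin(total, 1)
  structure(list(clean = clean,
                 noise = corrupted - clean,
                 corrupted = corrupted,
                 level = as.integer(level)),
            class = "corruption_triplet")
}

#' Generate a reproducible synthetic de-striping dataset on disk
#'
#' Renders `n_images` vessel phantoms, corrupts each at every requested
#' noise level, and writes clean/noise/corrupted images (16-bit TIFF),
#' vessel masks (8-bit PNG) and a plain-text manifest. The manifest records
#' every per-image seed, so the dataset is fully reproducible.
#'
#' @param n_images Number of phantoms.
#' @param levels Integer vector of noise levels (each `>= 1`).
#' @param seed Master seed.
#' @param out_dir Output directory (created if missing).
#' @param height,width Image size.
#' @param train_frac Fraction of phantoms assigned to the train split
#'   (assignment is per phantom so all levels of one phantom share a split).
#' @param phantom_params,stripe_params Generator parameter objects.
#' @return The manifest as a data frame (also written to
#'   `out_dir/manifest.tsv`), invisibly.
#' @export
make_dataset <- function(n_images, levels, seed, out_dir,
                         height = 64L, width = 64L, train_frac = 0.8,
                         phantom_params = vessel_phantom_params(),
                         stripe_params = stripe_field_params()) {
  check_count(n_images, "n_images", min = 1L)
  if (length(levels) < 1L || any(levels < 1) || any(levels != round(levels))) {
    stop_invalid("levels must be positive integers")
  }
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  seeds <- matrix(derive_seeds(seed, n_images * (length(levels) + 1L)),
                  nrow = n_images)
  n_train <- ceiling(train_frac * n_images)
  split <- with_seed(seed, sample(rep(c("train", "test"),
                                      c(n_train, n_images - n_train))))
  rows <- list()
  for (i in seq_len(n_images)) {
    ph_seed <- seeds[i, 1]
    ph <- generate_vessel_phantom(ph_seed, height, width, phantom_params)
    clean_file <- sprintf("clean_%04d.tif", i)
    mask_file <- sprintf("mask_%04d.png", i)
    write_image(ph$image, file.path(out_dir, clean_file), 16L)
    png::writePNG(ph$mask + 0, file.path(out_dir, mask_file))
    for (l in seq_along(levels)) {
      cr_seed <- seeds[i, l + 1L]
      tri <- corrupt_image(ph$image, levels[l], cr_seed, stripe_params)
      noise_file <- sprintf("noise_%04d_l%d.tif", i, levels[l])
      corr_file <- sprintf("corrupted_%04d_l%d.tif", i, levels[l])
      write_image(tri$noise, file.path(out_dir, noise_file), 16L)
      write_image(tri$corrupted, file.path(out_dir, corr_file), 16L)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%04d_l%d", i, levels[l]),
        phantom = i, level = levels[l], split = split[i],
        phantom_seed = ph_seed, corrupt_seed = cr_seed,
        clean = clean_file, noise = noise_file,
        corrupted = corr_file, mask = mask_file,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  attr(manifest, "dir") <- out_dir
  invisible(manifest)
}

#' Load a dataset manifest written by [make_dataset()]
#'
#' @param path Path to a `manifest.tsv` (or the directory holding one).
#' @return The manifest data frame with its directory attached.
#' @export
load_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.tsv")
  if (!file.exists(path)) stop_invalid("manifest not found: ", path)
  manifest <- read.delim(path, stringsAsFactors = FALSE)
  attr(manifest, "dir") <- dirname(normalizePath(path))
  manifest
}

# Read one manifest row back into an in-memory triplet. The reference noise
# is recomputed as corrupted - clean so the additive identity is exact at
# the file's quantization, matching what the training losses assume.
load_triplet <- function(manifest, row) {
  dir <- attr(manifest, "dir")
  r <- manifest[row, ]
  clean <- read_image(file.path(dir, r$clean))
  corrupted <- read_image(file.path(dir, r$corrupted))
  mask <- round(read_image(file.path(dir, r$mask)))
  list(clean = clean, noise = corrupted - clean, corrupted = corrupted,
       mask = mask, level = r$level, id = r$id)
}
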