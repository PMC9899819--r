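#' Peak signal-to-noise ratio
#'
#' `10 * log10(max_val^2 / MSE)` in dB. Identical images (zero MSE) return
#' `Inf` as a documented sentinel.
#'
#' @param reference,test Same-shape images.
#' @param max_val Peak signal value (1 for normalized images, 255 for
#'   8-bit data).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(reference, test, max_val = 1) {
  check_matrix(reference, "reference"); check_matrix(test, "test")
  check_same_shape(reference, test, "reference", "test")
  check_scalar(max_val, "max_val", 0, strict_lo = TRUE)
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_val^2 / mse)
}

#' Structural similarity index
#'
#' Mean local SSIM with the standard luminance/contrast/structure form:
#' Gaussian 11x11 window with `sigma = 1.5`, `K1 = 0.01`, `K2 = 0.03`,
#' valid-region filtering (no padded borders enter the mean).
#'
#' @param reference,test Same-shape images, at least as large as the
#'   window.
#' @param max_val Dynamic range of the data.
#' @param window Window side length (odd).
#' @param sigma Gaussian window standard deviation.
#' @param k1,k2 Stabilizer constants.
#' @return Scalar in `[-1, 1]`.
#' @export
ssim <- function(reference, test, max_val = 1, window = 11L, sigma = 1.5,
                 k1 = 0.01, k2 = 0.03) {
  check_matrix(reference, "reference"); check_matrix(test, "test")
  check_same_shape(reference, test, "reference", "test")
  if (nrow(reference) < window || ncol(reference) < window) {
    stop_invalid("images smaller than the ", window, "x", window, " window")
  }
  half <- (window - 1L) %/% 2L
  kern <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  filt_mat <- function(n) {
    m <- matrix(0, n - window + 1L, n)
    for (i in seq_len(nrow(m))) m[i, i:(i + window - 1L)] <- kern
    m
  }
  kv <- filt_mat(nrow(reference))
  kh <- filt_mat(ncol(reference))
  f <- function(img) kv %*% img %*% t(kh)
  mu_x <- f(reference); mu_y <- f(test)
  sxx <- f(reference^2) - mu_x^2
  syy <- f(test^2) - mu_y^2
  sxy <- f(reference * test) - mu_x * mu_y
  c1 <- (k1 * max_val)^2
  c2 <- (k2 * max_val)^2
  smap <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  mean(smap)
}

#' Pixelwise confusion counts between two binary masks
#'
#' @param predicted,truth Same-shape masks with values in `{0, 1}` (or
#'   logical).
#' @return A `confusion_counts` list `(tp, tn, fp, fn)` summing to the
#'   pixel count.
#' @export
confusion_counts <- function(predicted, truth) {
  p <- as.numeric(predicted); t <- as.numeric(truth)
  if (!all(p %in% c(0, 1)) || !all(t %in% c(0, 1))) {
    stop_invalid("masks must be binary (0/1)")
  }
  check_same_shape(predicted, truth, "predicted", "truth")
  structure(list(tp = sum(p == 1 & t == 1), tn = sum(p == 0 & t == 0),
                 fp = sum(p == 1 & t == 0), fn = sum(p == 0 & t == 1)),
            class = "confusion_counts")
}

.safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); returning NA")
    return(NA_real_)
  }
  num / den
}

#' Segmentation metrics from confusion counts
#'
#' `dice = 2TP / (2TP + FP + FN)`, `sensitivity = TP / (TP + FN)`,
#' `specificity = TN / (TN + FP)`, `gmean = sqrt(sen * spe)`. Zero
#' denominators yield `NA` with a warning (excluded from aggregates).
#'
#' @param counts A [confusion_counts()] object.
#' @return Scalar in `[0, 1]` (or `NA`).
#' @export
dice <- function(counts) {
  .safe_ratio(2 * counts$tp, 2 * counts$tp + counts$fp + counts$fn, "Dice")
}

#' @rdname dice
#' @export
sensitivity <- function(counts) {
  .safe_ratio(counts$tp, counts$tp + counts$fn, "sensitivity")
}

#' @rdname dice
#' @export
specificity <- function(counts) {
  .safe_ratio(counts$tn, counts$tn + counts$fp, "specificity")
}

#' @rdname dice
#' @export
gmean <- function(counts) {
  sqrt(sensitivity(counts) * specificity(counts))
}

#' Baseline global-threshold vessel segmenter
#'
#' A deliberately simple, deterministic stand-in for learned vessel
#' segmenters: optional Gaussian high-pass background subtraction followed
#' by a global threshold (Otsu or a quantile). A constant image yields an
#' empty mask with a warning.
#'
#' @param image Image in `[0, 1]`.
#' @param method `"otsu"` or `"percentile"`.
#' @param q Quantile for the percentile method.
#' @param highpass_sigma If non-`NULL`, subtract a Gaussian blur of this
#'   sigma before thresholding.
#' @return A 0/1 mask matrix.
#' @export
baseline_segment <- function(image, method = c("otsu", "percentile"),
                             q = 0.85, highpass_sigma = NULL) {
  method <- match.arg(method)
  check_image(image, "image")
  x <- image
  if (!is.null(highpass_sigma)) {
    x <- x - as.matrix(EBImage::gblur(x, sigma = highpass_sigma))
    x <- x - min(x)
    if (max(x) > 0) x <- x / max(x)
  }
  if (max(x) - min(x) < 1e-8) {
    warning("constant image; returning empty mask")
    return(matrix(0L, nrow(x), ncol(x)))
  }
  thr <- if (method == "otsu") {
    EBImage::otsu(x, range = c(0, 1))
  } else {
    as.numeric(stats::quantile(x, q))
  }
  mask <- matrix(0L, nrow(x), ncol(x))
  mask[x > thr] <- 1L
  mask
}

#' Evaluate processing conditions over a dataset manifest
#'
#' Computes, per image and condition (`corrupted`, `destriped`,
#' `enhanced`), the requested fidelity metrics against the clean reference
#' (PSNR, SSIM) and segmentation metrics (Dice, sensitivity, specificity,
#' G-mean) of the baseline segmenter against the vessel mask, then
#' aggregates mean and standard deviation per noise level and condition.
#' A `border` of pixels is excluded from mask comparison (edge effects of
#' the phantom renderer). Purely deterministic: re-running reproduces the
#' report.
#'
#' @param manifest Dataset manifest ([make_dataset()] / [load_manifest()]).
#' @param models Named list with optional `srnet` (needed for `destriped`
#'   and `enhanced`) and `g_xy` (needed for `enhanced`).
#' @param metrics Character vector among `psnr`, `ssim`, `dice`, `sen`,
#'   `spe`, `gmean`.
#' @param conditions Conditions to evaluate.
#' @param split Manifest split to use (default `test`; `"all"` uses every
#'   row).
#' @param segment_method,highpass_sigma Passed to [baseline_segment()].
#' @param border Mask border exclusion in pixels.
#' @return A `metric_report` list with `per_image` and `aggregate` data
#'   frames and a `provenance` record.
#' @export
evaluate <- function(manifest, models = list(),
                     metrics = c("psnr", "ssim", "dice", "sen", "spe",
                                 "gmean"),
                     conditions = c("corrupted", "destriped"),
                     split = "test", segment_method = "otsu",
                     highpass_sigma = NULL, border = 2L) {
  need_seg <- any(metrics %in% c("dice", "sen", "spe", "gmean"))
  if (any(conditions %in% c("destriped", "enhanced")) &&
      is.null(models$srnet)) {
    stop_invalid("condition 'destriped'/'enhanced' requires models$srnet")
  }
  if ("enhanced" %in% conditions && is.null(models$g_xy)) {
    stop_invalid("condition 'enhanced' requires models$g_xy")
  }
  rows <- if (identical(split, "all")) {
    seq_len(nrow(manifest))
  } else {
    which(manifest$split == split)
  }
  if (length(rows) == 0L) stop_invalid("no manifest rows in split ", split)
  crop <- function(m) {
    if (border > 0L) {
      m[(border + 1L):(nrow(m) - border), (border + 1L):(ncol(m) - border)]
    } else {
      m
    }
  }
  per <- list()
  for (r in rows) {
    tri <- load_triplet(manifest, r)
    imgs <- list(corrupted = tri$corrupted)
    if ("destriped" %in% conditions || "enhanced" %in% conditions) {
      ds <- destripe(models$srnet, tri$corrupted)
      imgs$destriped <- ds$c_out
      if ("enhanced" %in% conditions) {
        imgs$enhanced <- enhance(models$g_xy, ds$c_out)
      }
    }
    for (cond in conditions) {
      img <- imgs[[cond]]
      vals <- list(id = tri$id, level = tri$level, condition = cond)
      if ("psnr" %in% metrics) vals$psnr <- psnr(tri$clean, img)
      if ("ssim" %in% metrics) vals$ssim <- ssim(tri$clean, img)
      if (need_seg) {
        pred <- baseline_segment(img, method = segment_method,
                                 highpass_sigma = highpass_sigma)
        cc <- confusion_counts(crop(pred), crop(tri$mask))
        if ("dice" %in% metrics) vals$dice <- dice(cc)
        if ("sen" %in% metrics) vals$sen <- sensitivity(cc)
        if ("spe" %in% metrics) vals$spe <- specificity(cc)
        if ("gmean" %in% metrics) vals$gmean <- gmean(cc)
      }
      per[[length(per) + 1L]] <- as.data.frame(vals)
    }
  }
  per_image <- do.call(rbind, per)
  metric_cols <- setdiff(names(per_image), c("id", "level", "condition"))
  agg <- do.call(rbind, lapply(
    split(per_image, list(per_image$level, per_image$condition),
          drop = TRUE),
    function(g) {
      out <- data.frame(level = g$level[1], condition = g$condition[1],
                        n = nrow(g))
      for (m in metric_cols) {
        v <- g[[m]][is.finite(g[[m]])]
        out[[paste0(m, "_mean")]] <- mean(v)
        out[[paste0(m, "_sd")]] <- if (length(v) > 1) sd(v) else NA_real_
      }
      out
    }))
  rownames(agg) <- NULL
  structure(list(per_image = per_image, aggregate = agg,
                 provenance = list(split = split, border = border,
                                   segment_method = segment_method,
                                   n_images = length(rows))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Metric report (", x$provenance$n_images, " images, split ",
      x$provenance$split, ")\n", sep = "")
  print(x$aggregate, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a metric report to CSV and JSON
#'
#' @param report A `metric_report` from [evaluate()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$per_image, file.path(dir, "per_image.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(aggregate = report$aggregate, provenance = report$provenance),
    file.path(dir, "aggregate.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
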