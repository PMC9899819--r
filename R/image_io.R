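#' Read a grayscale image normalized to [0, 1]
#'
#' Reads a PNG or TIFF file and returns a numeric matrix with intensities in
#' `[0, 1]` (the underlying reader already normalizes by the container's
#' maximum value). RGB(A) files are converted to grayscale by the Rec. 601
#' luminance weights with a warning.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric `H x W` matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop_invalid("image file not found: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_invalid("unsupported image format '", ext, "' for ", path)
  )
  if (length(dim(x)) == 3L) {
    warning("reading multi-channel image as luminance grayscale: ", path)
    nch <- dim(x)[3]
    w <- if (nch >= 3) c(0.299, 0.587, 0.114) else rep(1 / nch, nch)
    x <- Reduce(`+`, lapply(seq_along(w), function(k) w[k] * x[, , k]))
  }
  storage.mode(x) <- "double"
  clip01(x)
}

#' Write a grayscale image with explicit quantization
#'
#' Quantizes with round-half-up to the requested bit depth; 16-bit output is
#' written as grayscale TIFF, 8-bit as grayscale PNG. A round trip through
#' [read_image()] is accurate to `1/(2^bit_depth - 1)`.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param path Output path; extension should match the bit depth
#'   (`.tif`/`.tiff` for 16-bit, `.png` for 8-bit).
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bit_depth = 16L) {
  check_matrix(image, "image")
  if (min(image) < 0 || max(image) > 1) {
    stop_invalid("image must be within [0, 1] before quantization")
  }
  if (!bit_depth %in% c(8L, 16L)) {
    stop_invalid("bit_depth must be 8 or 16")
  }
  levels <- 2^bit_depth - 1
  q <- floor(image * levels + 0.5) / levels
  ext <- tolower(tools::file_ext(path))
  if (bit_depth == 16L) {
    if (!ext %in% c("tif", "tiff")) {
      stop_invalid("16-bit images are written as TIFF; use a .tif path")
    }
    tiff::writeTIFF(q, path, bits.per.sample = 16L, compression = "none")
  } else {
    if (ext != "png") {
      stop_invalid("8-bit images are written as PNG; use a .png path")
    }
    png::writePNG(q, path)
  }
  invisible(path)
}
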