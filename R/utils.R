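# Internal validation and small helpers shared across modules.

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_invalid(name, " must be a numeric matrix")
  }
  if (!all(is.finite(x))) {
    stop_invalid(name, " contains non-finite values")
  }
  invisible(x)
}

check_image <- function(x, name = deparse(substitute(x)), min_size = 16L) {
  check_matrix(x, name)
  if (nrow(x) < min_size || ncol(x) < min_size) {
    stop_invalid(name, " must be at least ", min_size, "x", min_size,
                 " (got ", nrow(x), "x", ncol(x), ")")
  }
  if (min(x) < 0 || max(x) > 1) {
    stop_invalid(name, " must have intensities in [0, 1]")
  }
  invisible(x)
}

check_same_shape <- function(a, b, name_a = deparse(substitute(a)),
                             name_b = deparse(substitute(b))) {
  if (!identical(dim(a), dim(b))) {
    stop_invalid(name_a, " and ", name_b, " must share one shape (",
                 paste(dim(a), collapse = "x"), " vs ",
                 paste(dim(b), collapse = "x"), ")")
  }
  invisible(NULL)
}

check_range <- function(r, name, lo = 0, hi = 1) {
  if (length(r) != 2L || !is.numeric(r) || any(!is.finite(r)) || r[1] > r[2]) {
    stop_invalid(name, " must be a non-empty numeric range c(lo, hi)")
  }
  if (r[1] < lo || r[2] > hi) {
    stop_invalid(name, " must lie within [", lo, ", ", hi, "]")
  }
  invisible(r)
}

check_scalar <- function(x, name, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop_invalid(name, " must be a single finite number")
  }
  if (x < lo || (strict_lo && x <= lo) || x > hi) {
    stop_invalid(name, " out of range")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) ||
      x != round(x) || x < min) {
    stop_invalid(name, " must be an integer >= ", min)
  }
  invisible(as.integer(x))
}

clip01 <- function(x) {
  pmin(pmax(x, 0), 1)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Deterministic child seeds (kept below 2^31) derived from a parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

frob <- function(x) sqrt(sum(x * x))

# Banded matrix applying a truncated, renormalized 1-D Gaussian along an axis.
gauss1d_matrix <- function(n, sigma, radius = max(1L, ceiling(3 * sigma))) {
  kern <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  m <- matrix(0, n, n)
  for (d in seq(-radius, radius)) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1 & j <= n
    m[cbind(i[ok], j[ok])] <- kern[d + radius + 1]
  }
  m / rowSums(m)
}
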