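# Shared fixtures, built in code. Expensive artifacts (datasets, trained
# models) are cached per test session in a temp directory.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

rand_image <- function(seed, h = 16L, w = h, lo = 0, hi = 1) {
  withr::with_seed(seed, matrix(runif(h * w, lo, hi), h, w))
}

# finite-difference gradient of a scalar function of a matrix
fd_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), 1e-12)
}

# A small dataset on disk shared by srnet / evaluation tests.
small_dataset <- function() {
  fixture("small_dataset", function() {
    dir <- file.path(tempdir(), "octaclean-small-ds")
    make_dataset(10L, c(1L, 2L), seed = 77L, out_dir = dir)
  })
}
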