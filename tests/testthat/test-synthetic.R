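test_that("vessel phantom is deterministic, bounded, and vessel-bright", {
  ph <- generate_vessel_phantom(1, 64, 64)
  expect_true(all(ph$image >= 0 & ph$image <= 1))
  expect_gt(sum(ph$mask), 0)
  expect_identical(ph, generate_vessel_phantom(1, 64, 64))

  ph7 <- generate_vessel_phantom(7, 128, 128)
  expect_gt(mean(ph7$image[ph7$mask == 1]),
            mean(ph7$image[ph7$mask == 0]))
})

test_that("zero vessels give pure background and an empty mask", {
  p <- vessel_phantom_params(n_vessels = 0L)
  ph <- generate_vessel_phantom(1, 64, 64, p)
  expect_identical(sum(ph$mask), 0L)
  # background texture only: reproduce it directly from the same seed
  bg <- withr::with_seed(1L, matrix(0.12 + rnorm(64 * 64, sd = 0.04), 64))
  expect_equal(ph$image, pmin(pmax(bg, 0), 1))
})

test_that("phantom parameter validation names the offending field", {
  expect_error(vessel_phantom_params(intensity_range = c(0.05, 0.3),
                                     background_level = 0.12),
               "intensity_range")
  expect_error(vessel_phantom_params(width_range = c(2, 1)), "width_range")
  expect_error(generate_vessel_phantom(1, 8, 64), "height")
})

test_that("stripe fields are non-negative, deterministic and low rank", {
  p <- stripe_field_params(full_span_prob = 1)
  f <- generate_stripe_field(3, 64, 64, p)
  expect_gte(min(f), 0)
  expect_identical(f, generate_stripe_field(3, 64, 64, p))
  k <- attr(f, "n_stripes")
  expect_lte(sum(svd(f)$d > 1e-10), k)
  # rank <= stripes drawn holds for partial stripes too (rank-1 bands)
  for (seed in 11:20) {
    fp <- generate_stripe_field(seed, 48, 48,
                                stripe_field_params(full_span_prob = 0.3,
                                                    n_stripes_mean = 4))
    expect_lte(sum(svd(fp)$d > 1e-10), attr(fp, "n_stripes"))
  }
})

test_that("zero stripe mean forces an all-zero field", {
  f <- generate_stripe_field(5, 32, 32,
                             stripe_field_params(n_stripes_mean = 0))
  expect_identical(sum(f != 0), 0L)
})

test_that("stripe orientation controls band direction", {
  ph <- stripe_field_params(orientation = "horizontal", full_span_prob = 1,
                            n_stripes_mean = 2)
  pv <- stripe_field_params(orientation = "vertical", full_span_prob = 1,
                            n_stripes_mean = 2)
  fh <- generate_stripe_field(8, 32, 32, ph)
  fv <- generate_stripe_field(8, 32, 32, pv)
  if (attr(fh, "n_stripes") > 0) {
    expect_true(all(apply(fh, 1, function(r) diff(range(r)) == 0)))
  }
  if (attr(fv, "n_stripes") > 0) {
    expect_true(all(apply(fv, 2, function(cc) diff(range(cc)) == 0)))
  }
})

test_that("corruption triplets satisfy the exact additive identity", {
  ph <- generate_vessel_phantom(2, 64, 64)
  tri <- corrupt_image(ph$image, 1L, 5L)
  expect_identical(max(abs(tri$corrupted - tri$clean - tri$noise)), 0)
  expect_gte(min(tri$noise), 0)
  expect_lte(max(tri$corrupted), 1)
  expect_error(corrupt_image(ph$image, 0L, 5L), "level")
})

test_that("an all-zero clean image makes noise equal the corruption", {
  z <- matrix(0, 32, 32)
  tri <- corrupt_image(z, 2L, 5L)
  expect_identical(tri$noise, tri$corrupted)
})

test_that("corruption severity grows with the noise level", {
  # mean PSNR(clean, corrupted) non-increasing in level over 20 phantoms
  psnr_by_level <- sapply(1:4, function(lev) {
    mean(sapply(1:20, function(i) {
      ph <- generate_vessel_phantom(100 + i, 64, 64)
      tri <- corrupt_image(ph$image, lev, 500 + i)
      psnr(tri$clean, tri$corrupted)
    }))
  })
  expect_true(all(diff(psnr_by_level) < 0))
})

test_that("make_dataset writes a reproducible, round-trippable dataset", {
  dir1 <- file.path(tempdir(), "ds-a")
  dir2 <- file.path(tempdir(), "ds-b")
  unlink(c(dir1, dir2), recursive = TRUE)
  man1 <- make_dataset(4L, c(1L, 2L), seed = 3L, out_dir = dir1,
                       height = 32L, width = 32L)
  expect_identical(nrow(man1), 8L)
  expect_identical(as.integer(table(man1$level)), c(4L, 4L))
  # file round trip within 16-bit quantization of the regenerated arrays
  tri_mem <- corrupt_image(
    generate_vessel_phantom(man1$phantom_seed[1], 32, 32)$image,
    man1$level[1], man1$corrupt_seed[1])
  tri_file <- octaclean:::load_triplet(man1, 1)
  expect_lte(max(abs(tri_file$corrupted - tri_mem$corrupted)), 1 / 65535)
  expect_lte(max(abs(tri_file$clean - tri_mem$clean)), 1 / 65535)
  # identical rerun: same manifest, same file checksums
  man2 <- make_dataset(4L, c(1L, 2L), seed = 3L, out_dir = dir2,
                       height = 32L, width = 32L)
  attr(man2, "dir") <- attr(man1, "dir")
  expect_identical(man1, man2)
  sums1 <- tools::md5sum(sort(list.files(dir1, full.names = TRUE)))
  sums2 <- tools::md5sum(sort(list.files(dir2, full.names = TRUE)))
  expect_identical(unname(sums1), unname(sums2))
})
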