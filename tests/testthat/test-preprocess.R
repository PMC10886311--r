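test_that("TIFF round-trip is voxel-identical for 8- and 16-bit stacks", {
  for (bd in c(8L, 16L)) {
    s <- random_stack(c(5L, 12L, 10L), bit_depth = bd, seed = bd)
    f <- withr::local_tempfile(fileext = ".tif")
    write_stack(s, f)
    r <- read_stack(f)
    expect_identical(dim(r$voxels), dim(s$voxels))
    expect_equal(r$bit_depth, bd)
    expect_true(all(r$voxels == s$voxels))
  }
})

test_that("write_stack handles constant extremes and is byte-deterministic", {
  z <- image_stack(array(0, c(2L, 4L, 4L)), bit_depth = 8L)
  m <- image_stack(array(65535, c(2L, 4L, 4L)), bit_depth = 16L)
  f1 <- withr::local_tempfile(fileext = ".tif")
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_stack(z, f1)
  expect_true(all(read_stack(f1)$voxels == 0))
  write_stack(m, f1)
  expect_true(all(read_stack(f1)$voxels == 65535))
  s <- random_stack(seed = 3)
  write_stack(s, f1); write_stack(s, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("read_stack rejects multi-channel input", {
  f <- withr::local_tempfile(fileext = ".tif")
  rgb <- array(runif(4 * 4 * 3), c(4L, 4L, 3L))
  tiff::writeTIFF(rgb, f)
  expect_error(read_stack(f), "single-channel")
  expect_error(read_stack(file.path(tempdir(), "no-such-file.tif")),
               "cannot read")
})

test_that("median filter: constants pass through and lone spikes vanish", {
  const <- image_stack(array(7, c(5L, 5L, 5L)), bit_depth = 8L)
  expect_equal(median_filter_3d(const)$voxels, const$voxels)
  spike <- array(0, c(5L, 5L, 5L)); spike[3, 3, 3] <- 200
  out <- median_filter_3d(image_stack(spike, bit_depth = 8L))
  expect_true(all(out$voxels == 0))
})

test_that("median filter matches the brute-force window oracle", {
  for (seed in 1:3) {
    s <- random_stack(c(4L, 6L, 6L), seed = seed)
    for (radius in list(c(1L, 1L, 1L), c(0L, 1L, 2L))) {
      got <- median_filter_3d(s, radius)$voxels
      expect_equal(got, median3d_oracle(s$voxels, radius), tolerance = 1e-12)
    }
  }
  # property: agreement on small random stacks of varying shapes
  for (seed in 4:6) {
    d <- c(sample(2:8, 1), sample(2:8, 1), sample(2:8, 1))
    s <- random_stack(d, seed = seed)
    expect_equal(median_filter_3d(s, c(1L, 1L, 1L))$voxels,
                 median3d_oracle(s$voxels, c(1L, 1L, 1L)))
  }
})

test_that("FSCS maps a clean span linearly onto the full range", {
  v <- array(seq(100, 200, length.out = 64), c(4L, 4L, 4L))
  out <- fscs_normalize(image_stack(v, bit_depth = 16L), saturation_frac = 0)
  expect_equal(min(out$voxels), 0)
  expect_equal(max(out$voxels), 65535)
  expect_equal(out$voxels[1, 1, 1], 0)
  # every voxel maps linearly: (v - 100) / 100 * 65535, then rounds
  expect_equal(out$voxels, round((v - 100) / 100 * 65535))
})

test_that("FSCS on a constant stack warns and returns zeros", {
  s <- image_stack(array(123, c(2L, 4L, 4L)), bit_depth = 16L)
  expect_warning(out <- fscs_normalize(s), "constant")
  expect_true(all(out$voxels == 0))
})

test_that("FSCS clips ~ the requested fraction and hits exact endpoints", {
  set.seed(9)
  s <- image_stack(array(runif(64 * 64 * 12, 0, 65535), c(12L, 64L, 64L)),
                   bit_depth = 16L)
  out <- fscs_normalize(s, saturation_frac = 0.003)
  clipped <- mean(out$voxels == 0 | out$voxels == 65535)
  expect_gt(clipped, 0.002)
  expect_lt(clipped, 0.004)
  expect_equal(min(out$voxels), 0)
  expect_equal(max(out$voxels), 65535)
})

test_that("FSCS at saturation 0 is idempotent on a full-range stack", {
  set.seed(10)
  v <- array(sample(0:65535, 500, replace = TRUE), c(5L, 10L, 10L))
  v[1] <- 0; v[2] <- 65535
  s <- image_stack(v, bit_depth = 16L)
  once <- fscs_normalize(s, 0)
  twice <- fscs_normalize(once, 0)
  expect_equal(once$voxels, twice$voxels)
})

test_that("16-to-8-bit conversion follows round(i * 255 / 65535)", {
  v <- array(c(0, 65535, 32768, 256, 1000, 60000, 0, 0), c(2L, 2L, 2L))
  out <- convert_16_to_8(image_stack(v, bit_depth = 16L))
  expect_equal(out$bit_depth, 8L)
  expect_equal(out$voxels, round(v * 255 / 65535))
  expect_equal(out$voxels[1, 2, 1], 128)  # 32768 -> 128
  expect_error(convert_16_to_8(out), "16-bit")
})

test_that("split_frames and bind_frames are inverse and keep z order", {
  s <- random_stack(c(7L, 6L, 6L), seed = 11)
  fr <- split_frames(s)
  expect_length(fr, 7L)
  expect_equal(vapply(fr, function(f) attr(f, "z_index"), 1L), 1:7)
  expect_equal(bind_frames(fr)$voxels, s$voxels)
  one <- split_frames(fr[[3]])
  expect_equal(one[[1]]$voxels, fr[[3]]$voxels)
})

test_that("preprocessing chain preserves shape and only the bit conversion
           changes the value range", {
  s <- random_stack(c(4L, 16L, 16L), seed = 12)
  filt <- median_filter_3d(s)
  stretched <- fscs_normalize(filt)
  expect_identical(dim(stretched$voxels), dim(s$voxels))
  expect_equal(stretched$bit_depth, 16L)
  out <- preprocess_stack(s)
  expect_identical(dim(out$voxels), dim(s$voxels))
  expect_equal(out$bit_depth, 8L)
  expect_lte(max(out$voxels), 255)
})
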