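test_that("median filter removes isolated pixels and preserves structure", {
  u <- matrix(7L, 6, 6)
  expect_identical(median_filter_1px(u), u)

  z <- matrix(0L, 7, 7)
  z[4, 4] <- 255L
  expect_true(all(median_filter_1px(z) == 0L))

  # brute-force 3x3 median with replicate padding on a 5x5 checkerboard
  cb <- matrix(rep(c(0L, 255L), length.out = 25), 5, 5)
  oracle <- cb
  for (r in 1:5) for (cl in 1:5) {
    rr <- pmin(pmax(r + (-1:1), 1), 5)
    cc <- pmin(pmax(cl + (-1:1), 1), 5)
    oracle[r, cl] <- median(cb[rr, cc])
  }
  expect_identical(median_filter_1px(cb), oracle)
})

test_that("median filter never invents values and rejects tiny images", {
  set.seed(42)
  x <- matrix(sample(c(0L, 3L, 17L, 250L), 400, replace = TRUE), 20, 20)
  y <- median_filter_1px(x)
  expect_true(all(y %in% unique(as.integer(x))))
  expect_error(median_filter_1px(matrix(1L, 2, 5)), "3 x 3")
})

test_that("median filter applies per plane on stacks", {
  st <- array(0L, c(5, 5, 2))
  st[3, 3, 1] <- 200L
  st[, , 2] <- 9L
  out <- median_filter_1px(st)
  expect_true(all(out[, , 1] == 0L))
  expect_true(all(out[, , 2] == 9L))
})

test_that("intensity normalisation follows the background/max mapping", {
  expect_identical(normalize_image(matrix(10, 1, 1), 10, 210)[1], 0L)
  expect_identical(normalize_image(matrix(210, 1, 1), 10, 210)[1], 255L)
  # (110 - 10)/(210 - 10) * 255 = 127.5, rounded half-to-even
  expect_identical(normalize_image(matrix(110, 1, 1), 10, 210)[1], 128L)
  # clamping outside [background, max]
  out <- normalize_image(matrix(c(0, 500), 1, 2), 10, 210)
  expect_identical(as.integer(out), c(0L, 255L))
  expect_error(normalize_image(matrix(1, 2, 2), 50, 50), "invalid")
  expect_error(normalize_image(matrix(1, 2, 2), -1, 50), "invalid")
})

test_that("normalisation then alpha readout is monotone and maps the range onto [0,1]", {
  set.seed(7)
  f_raw <- sort(runif(50, 0, 300))
  img <- matrix(f_raw, 1)
  a <- alpha_from_image(normalize_image(img, 20, 280), pixel_size_nm = 50)
  expect_true(all(diff(as.numeric(a$alpha)) >= 0))
  expect_equal(as.numeric(alpha_from_image(
    normalize_image(matrix(c(20, 280), 1), 20, 280), 50)$alpha), c(0, 1))
})

test_that("alpha readout is pixel value over 255", {
  img <- matrix(c(0L, 64L, 128L, 255L), 2, 2)
  a <- alpha_from_image(img, pixel_size_nm = 50)
  expect_equal(as.numeric(a$alpha), c(0, 64, 128, 255) / 255)
  expect_equal(frame_alpha(alpha_map(matrix(128 / 255, 8, 8), 50)), 128 / 255)
  expect_error(alpha_from_image(matrix(300L, 2, 2), 50), "8-bit")
})

test_that("frame alpha summarises by median (or mean) over an optional mask", {
  m <- alpha_map(matrix(rep(c(0.1, 0.2, 0.3), each = 3), 3, 3), 50)
  expect_equal(frame_alpha(m), 0.2)
  expect_equal(frame_alpha(m, stat = "mean"), 0.2)
  mask <- matrix(FALSE, 3, 3); mask[, 3] <- TRUE
  expect_equal(frame_alpha(m, mask), 0.3)
  expect_error(frame_alpha(m, matrix(FALSE, 3, 3)), "no pixels")
  expect_error(frame_alpha(m, matrix(TRUE, 2, 2)), "shape")
})

test_that("line profiles sample the rasterised segment once per pixel", {
  m <- alpha_map(matrix(0.25, 20, 20), 50)
  lp <- line_profile_alpha(m, c(3, 3), c(17, 11))
  expect_true(all(lp$profile == 0.25))
  expect_equal(lp$alpha, 0.25)
  expect_false(any(duplicated(cbind(lp$rows, lp$cols))))

  # left half 0.1, right half 0.5: median follows the majority side
  half <- alpha_map(cbind(matrix(0.1, 10, 6), matrix(0.5, 10, 4)), 50)
  lp2 <- line_profile_alpha(half, c(5, 1), c(5, 10))
  expect_equal(lp2$alpha, 0.1)
  expect_error(line_profile_alpha(m, c(5, 5), c(5, 5)), "zero-length")
  expect_error(line_profile_alpha(m, c(0, 1), c(5, 5)), "inside")
})

test_that("homogenise conserves total ECS volume and is idempotent", {
  m <- alpha_map(matrix(c(0.1, 0.5), 10, 10), 50)
  h <- homogenize(m)
  expect_equal(unique(as.numeric(h$alpha)), 0.3)
  expect_equal(sum(h$alpha), sum(m$alpha))
  expect_equal(homogenize(h)$alpha, h$alpha)
})

test_that("alpha maps round-trip through float TIFF", {
  m <- make_blob_neuropil(0.25, 0.5, c(32, 32), 50, seed = 3)
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(path))
  write_alpha_tiff(m, path)
  back <- read_alpha_tiff(path, 50)
  expect_equal(back$alpha, m$alpha, tolerance = 1e-6)

  # integer image round trip (values are 8-bit fractions in the file)
  img <- matrix(as.integer(round(255 * m$alpha)), 32, 32)
  p2 <- tempfile(fileext = ".tif")
  on.exit(unlink(p2), add = TRUE)
  tiff::writeTIFF(img / 255, p2, bits.per.sample = 8L)
  ri <- read_image_tiff(p2, pixel_size_nm = 50)
  expect_identical(dim(ri), dim(img))
  expect_identical(as.integer(ri), as.integer(img))
})

test_that("alpha map constructor enforces its invariants", {
  expect_error(alpha_map(matrix(-0.1, 2, 2), 50), "\\[0, 1\\]")
  expect_error(alpha_map(matrix(1.1, 2, 2), 50), "\\[0, 1\\]")
  expect_error(alpha_map(matrix(0.5, 2, 2), -50), "positive")
  expect_error(alpha_map(array(0.5, c(2, 2, 2)), 50), "z_step_nm")
})
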