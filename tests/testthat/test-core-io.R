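test_that("gaussian kernels are unit-sum, isotropic, unimodal", {
  for (s in c(0.4, 1.1, 2.2, 5)) {
    k <- gaussian_kernel(s)
    expect_equal(sum(k), 1, tolerance = 1e-12)
    expect_true(nrow(k) %% 2 == 1)
    expect_equal(k, t(k))
    expect_equal(k, k[nrow(k):1, ncol(k):1])
    ctr <- (nrow(k) + 1) / 2
    expect_equal(max(k), k[ctr, ctr])
  }
  expect_error(gaussian_kernel(0), "positive")
  expect_error(gaussian_kernel(-1), "positive")
})

test_that("convolve2d is linear, preserves constants, and is a correlation", {
  f <- random_field(seed = 11)
  g <- random_field(seed = 12)
  k <- gaussian_kernel(1.3)
  expect_equal(convolve2d(2 * f + 3 * g, k),
               2 * convolve2d(f, k) + 3 * convolve2d(g, k),
               tolerance = 1e-10)
  # identity kernel
  expect_equal(convolve2d(f, matrix(1)), f)
  # constant field with a unit-sum kernel is a fixed point everywhere
  cf <- matrix(0.7, 24, 24)
  expect_equal(convolve2d(cf, k), cf, tolerance = 1e-12)
  # and scales by the kernel sum for a general kernel
  k2 <- matrix(1:9, 3, 3)
  expect_equal(convolve2d(cf, k2), cf * sum(k2), tolerance = 1e-10)
  # impulse response: correlation reproduces the point-reflected kernel
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  ka <- matrix(runif(25), 5, 5)
  out <- convolve2d(imp, ka)
  expect_equal(out[15:19, 15:19], ka[5:1, 5:1], tolerance = 1e-12)
  expect_error(convolve2d(f, matrix(1, 2, 3)), "odd")
})

test_that("images round-trip through PNG bit-exactly at 8 and 16 bits", {
  m <- random_field(24, 40, seed = 3)
  q8 <- round(m * 255) / 255
  f8 <- withr::local_tempfile(fileext = ".png")
  write_image(m, f8)
  expect_equal(greyscale(read_image(f8)), q8, tolerance = 1e-12)
  # writing the quantised image back reproduces the file contents
  f8b <- withr::local_tempfile(fileext = ".png")
  write_image(q8, f8b)
  expect_identical(readBin(f8b, "raw", 1e6), readBin(f8, "raw", 1e6))

  f16 <- withr::local_tempfile(fileext = ".png")
  write_image(m, f16, bits = 16)
  r16 <- t(EBImage::imageData(EBImage::readImage(f16)))
  expect_equal(r16, round(m * 65535) / 65535, tolerance = 1e-12)

  a <- withr::with_seed(5, array(stats::runif(24 * 24 * 3), c(24, 24, 3)))
  frgb <- withr::local_tempfile(fileext = ".png")
  write_image(rgb_image(a), frgb)
  expect_equal(read_image(frgb)$pixels, round(a * 255) / 255,
               tolerance = 1e-12)
})

test_that("greyscale PNG input is replicated to three channels", {
  m <- random_field(20, 20, seed = 9)
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(m, f)
  img <- read_image(f)
  expect_equal(img$pixels[, , 1], img$pixels[, , 2])
  expect_equal(img$pixels[, , 2], img$pixels[, , 3])
})

test_that("PPM files decode in both ASCII and binary form", {
  f <- withr::local_tempfile(fileext = ".ppm")
  vals <- withr::with_seed(2, sample(0:255, 16 * 16 * 3, replace = TRUE))
  writeLines(c("P3", "# comment", "16 16", "255",
               paste(vals, collapse = " ")), f)
  img <- read_image(f)
  expect_equal(img$height, 16)
  expect_equal(img$pixels[1, 1, ], vals[1:3] / 255)
  fb <- withr::local_tempfile(fileext = ".ppm")
  con <- file(fb, "wb")
  writeChar("P6\n16 16\n255\n", con, eos = NULL)
  writeBin(as.raw(vals), con)
  close(con)
  expect_equal(read_image(fb)$pixels, img$pixels)
})

test_that("unreadable or malformed image files raise I/O errors", {
  expect_error(read_image("no/such/file.png"), "not found")
  f <- withr::local_tempfile(fileext = ".png")
  writeBin(as.raw(1:10), f)  # truncated garbage
  expect_error(read_image(f), "unreadable")
})

test_that("rgb_image validates range, shape, and minimum size", {
  expect_error(rgb_image(array(2, c(20, 20, 3))), "\\[0, 1\\]")
  expect_error(rgb_image(array(0.5, c(8, 20, 3))), "16")
  expect_error(rgb_image(array(NaN, c(20, 20, 3))), "finite")
  img <- rgb_image(matrix(0.5, 20, 20))
  expect_equal(dim(img$pixels), c(20L, 20L, 3L))
})

test_that("boundary ground truth reads PNG masks and text matrices alike", {
  gt <- matrix(0, 20, 20); gt[5, ] <- 1
  d <- withr::local_tempdir()
  png::writePNG(gt, file.path(d, "gt_1.png"))
  write_boundary_mask(gt, file.path(d, "gt_2.txt"))
  b <- read_boundary_gt(file.path(d, "gt"))
  expect_length(b$maps, 2)
  expect_equal(b$maps[[1]], gt)
  expect_equal(b$maps[[2]], gt)
  expect_equal(b$consensus, gt)
  expect_error(boundary_gt(matrix(0.5, 4, 4)), "\\{0,1\\}")
})

test_that("model parameters validate and round-trip through YAML", {
  expect_error(model_params(w = 0.2), "\\[-1, 0\\]")
  expect_error(model_params(sigma = -1), "positive")
  expect_error(model_params(window_size = 10), "odd")
  expect_error(model_params(rho_dog = 0.4), "annular")
  expect_error(model_params(n_orient = 1), ">= 2")
  p <- model_params(w = -0.6, alpha = 0.5)
  f <- withr::local_tempfile(fileext = ".yaml")
  save_params(p, f)
  expect_equal(load_params(f), p)
  # CLI-style overrides win over the file
  expect_equal(load_params(f, alpha = 2)$alpha, 2)
  writeLines("bogus_key: 1", f)
  expect_error(load_params(f), "unknown config keys")
})
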