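test_that("load_image returns native-scale intensities for PNG and PGM", {
  m <- matrix(c(0, 128, 255, 64, 32, 16, 200, 100, 50), 3, 3)
  png_path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(m / 255, png_path)
  img <- load_image(png_path)
  expect_s3_class(img, "gray_image")
  expect_equal(as.matrix(img), m, tolerance = 1e-12, ignore_attr = TRUE)

  pgm_path <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(m, pgm_path)
  img2 <- load_image(pgm_path)
  expect_equal(as.matrix(img2), m, tolerance = 1e-9, ignore_attr = TRUE)

  # 256 x 256 8-bit: the acquisition geometry of the emulated study
  big <- matrix(sample(0:255, 256 * 256, replace = TRUE), 256, 256)
  big_path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(big / 255, big_path)
  loaded <- load_image(big_path)
  expect_identical(dim(as.matrix(loaded)), c(256L, 256L))
  expect_equal(range(as.matrix(loaded)), c(0, 255))
})

test_that("load_image rejects bad inputs with classed errors", {
  expect_error(load_image("no/such/file.png"), class = "hjorth2d_input_error")

  # too small: 2 x 5
  small_path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 2, 5), small_path)
  expect_error(load_image(small_path), class = "hjorth2d_dimension_error")

  # corrupt file
  bad <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(load_image(bad), class = "hjorth2d_input_error")

  # unsupported extension
  tif <- withr::local_tempfile(fileext = ".tif")
  file.create(tif)
  expect_error(load_image(tif), class = "hjorth2d_input_error")
})

test_that("RGB images load as planes and alpha is dropped with a warning", {
  arr <- array(runif(4 * 5 * 3), c(4, 5, 3))
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(arr, p)
  planes <- load_image(p)
  expect_s3_class(planes, "rgb_planes")
  expect_equal(planes$g, round(arr[, , 2] * 255), tolerance = 1e-9)

  arr4 <- array(runif(4 * 5 * 4), c(4, 5, 4))
  p4 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(arr4, p4)
  expect_warning(load_image(p4), "alpha")
})

test_that("to_grayscale applies BT.601 weights and stays within channel range", {
  c255 <- matrix(255, 4, 4); z <- matrix(0, 4, 4)
  # pure red plane: 0.299 * 255
  red <- to_grayscale(c255, z, z)
  expect_equal(as.matrix(red), matrix(76.245, 4, 4), tolerance = 1e-12,
               ignore_attr = TRUE)

  # gray input is a fixed point
  c7 <- matrix(7, 5, 5)
  expect_equal(as.matrix(to_grayscale(c7, c7, c7)), c7,
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(to_grayscale(matrix(0, 4, 4), matrix(0, 4, 5),
                            matrix(0, 4, 4)),
               class = "hjorth2d_dimension_error")

  # pixel-wise bounds property over random channels
  for (seed in 1:5) {
    set.seed(seed)
    r <- matrix(runif(36, 0, 255), 6, 6)
    g <- matrix(runif(36, 0, 255), 6, 6)
    b <- matrix(runif(36, 0, 255), 6, 6)
    gray <- as.matrix(to_grayscale(r, g, b))
    expect_true(all(gray >= pmin(r, g, b) - 1e-12))
    expect_true(all(gray <= pmax(r, g, b) + 1e-12))
  }
})

test_that("minmax_normalize maps to exact [0, 1], idempotently, affinely invariant", {
  img <- gray_image(matrix(c(0, 127.5, 255, 0, 255, 127.5, 255, 0, 127.5),
                           3, 3))
  norm <- minmax_normalize(img)
  expect_setequal(unique(as.vector(as.matrix(norm))), c(0, 0.5, 1))
  expect_identical(attr(norm, "provenance"), "normalized")

  # idempotence
  expect_equal(as.matrix(minmax_normalize(norm)), as.matrix(norm),
               tolerance = 1e-12)

  # scale/shift invariance and order preservation, random images
  for (seed in 1:8) {
    m <- as.matrix(random_image(seed, 10, 10))
    base <- as.matrix(minmax_normalize(gray_image(m)))
    for (ab in list(c(2, 0), c(0.3, 5), c(7, -100))) {
      shifted <- as.matrix(minmax_normalize(gray_image(ab[1] * m + ab[2])))
      expect_equal(shifted, base, tolerance = 1e-10)
    }
    expect_identical(order(as.vector(base)), order(as.vector(m)))
  }

  expect_error(minmax_normalize(gray_image(matrix(7, 4, 4))),
               class = "hjorth2d_degenerate_error")
})

test_that("smooth_image convolves with a unit-sum kernel", {
  # single bright pixel spreads into a 3x3 plateau of 1/9 * 9 = 1
  m <- matrix(0, 5, 5); m[3, 3] <- 9
  sm <- as.matrix(smooth_image(gray_image(m)))
  expect_equal(sm[2:4, 2:4], matrix(1, 3, 3), tolerance = 1e-12)
  expect_equal(sm[1, 1], 0)

  # constant image is preserved exactly under any spec
  cst <- gray_image(matrix(0.4, 6, 6))
  for (spec in list(smoothing_spec("box", 3),
                    smoothing_spec("gaussian", 5),
                    smoothing_spec("box", 5, border = "reflect"))) {
    expect_equal(as.matrix(smooth_image(cst, spec)), matrix(0.4, 6, 6),
                 tolerance = 1e-12)
  }

  # window = 1 is the identity
  img <- random_image(3, 8, 8)
  expect_identical(smooth_image(img, smoothing_spec("box", 1)), img)

  # window larger than the image
  expect_error(smooth_image(img, smoothing_spec("box", 9)),
               class = "hjorth2d_config_error")
  expect_error(smoothing_spec("box", 4), class = "hjorth2d_config_error")
})

test_that("smoothing matches a direct-convolution oracle on small images", {
  for (seed in 1:6) {
    nr <- sample(5:16, 1); nc <- sample(5:16, 1)
    m <- as.matrix(random_image(seed, nr, nc, max_val = 1))
    for (border in c("replicate", "reflect")) {
      for (spec in list(smoothing_spec("box", 3, border = border),
                        smoothing_spec("gaussian", 3, sigma = 0.7,
                                       border = border))) {
        got <- as.matrix(smooth_image(gray_image(m), spec))
        k <- hjorth2d:::smoothing_kernel(spec)
        want <- oracle_convolve(m, k, border)
        expect_equal(got, want, tolerance = 1e-12)
        # unit-sum kernel keeps the mean within 1e-10 relative
        expect_equal(mean(got), mean(want), tolerance = 1e-10)
      }
    }
  }
})
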