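test_that("bilinear resize preserves constants and is the identity at equal size", {
  const <- gray_image(matrix(100, 4, 4))
  out <- resize_image(const, c(224, 224))
  expect_equal(dim(out), c(224L, 224L))
  expect_true(all(abs(out$pixels - 100) < 1e-9))

  img <- rand_gray(224, 224, seed = 2)
  expect_identical(resize_image(img, c(224, 224))$pixels, img$pixels)
})

test_that("bilinear resize matches hand-evaluated interpolants on a 2x2 upscale", {
  img <- gray_image(matrix(c(0, 100, 100, 200), 2, 2))
  out <- resize_image(img, c(4, 4))$pixels
  # independent evaluation of the pixel-centre convention
  w1 <- function(n_in, n_out) {
    sapply(seq_len(n_in), function(k) {
      sapply(seq_len(n_out), function(i) {
        s <- min(max((i - 0.5) * n_in / n_out - 0.5, 0), n_in - 1)
        lo <- floor(s); fr <- s - lo
        (k - 1 == lo) * (1 - fr) + (k - 1 == min(lo + 1, n_in - 1)) * fr
      })
    })
  }
  expected <- w1(2, 4) %*% img$pixels %*% t(w1(2, 4))
  expect_equal(out, expected, tolerance = 1e-12)
  expect_equal(out[2, 2], 0 * 0.5625 + 100 * 0.1875 + 100 * 0.1875 + 200 * 0.0625)
})

test_that("contrast stretching maps the observed range onto the full range", {
  px <- matrix(c(50, 100, 150, 150), 2, 2)
  out <- contrast_stretch(gray_image(px))$pixels
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 2], 255)
  expect_equal(out[2, 1], 128)  # round(0.5 * 255)

  full <- rand_gray(8, 8, seed = 4)
  full$pixels[1] <- 0; full$pixels[2] <- 255
  expect_equal(contrast_stretch(full)$pixels, full$pixels)

  expect_warning(out0 <- contrast_stretch(gray_image(matrix(7, 3, 3))),
                 "constant")
  expect_true(all(out0$pixels == 0))
})

test_that("contrast stretching never inverts intensity order", {
  set.seed(11)
  for (rep in 1:10) {
    img <- rand_gray(8, 8)
    out <- contrast_stretch(img)$pixels
    o <- order(img$pixels)
    expect_true(all(diff(out[o]) >= 0))
  }
})

test_that("median filter suppresses salt noise and matches the brute-force oracle", {
  const <- gray_image(matrix(42, 6, 6))
  expect_equal(median_filter3(const)$pixels, const$pixels)

  salt <- matrix(0, 7, 7); salt[4, 4] <- 255
  expect_true(all(median_filter3(gray_image(salt))$pixels == 0))

  set.seed(21)
  for (rep in 1:50) {
    img <- rand_gray(8, 8)
    expect_identical(median_filter3(img)$pixels, oracle_median3(img$pixels))
  }
})

test_that("the preprocessing chain is deterministic", {
  img <- generate_phantom(phantom_params(), "abnormal", 3)$image
  a <- preprocess_image(img)
  b <- preprocess_image(img)
  expect_identical(a$pixels, b$pixels)
})
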