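test_that("the frame is Parseval: squared filter magnitudes sum to one", {
  sys <- build_shearlet_system(c(64, 64), 2)
  total <- Reduce(`+`, lapply(sys$filters, function(w) w^2))
  expect_lt(max(abs(total - 1)), 1e-10)
})

test_that("band count follows the shear-range formula and filters are admissible", {
  for (n in 1:3) {
    sys <- build_shearlet_system(c(64, 64), n)
    expected <- 1 + sum(2 * (2 * 2^seq_len(n) + 1))
    expect_equal(length(sys$filters), expected)
    expect_equal(sys$shears_per_scale, 2L * (2L * 2^seq_len(n) + 1L))
  }
  sys <- build_shearlet_system(c(64, 64), 2)
  for (w in sys$filters) {
    expect_true(all(Im(w) == 0) || is.numeric(w))
    expect_gte(min(w), 0)
  }
  expect_error(build_shearlet_system(c(8, 8), 1), "16")
  expect_error(build_shearlet_system(c(16, 16), 6), "too small")
})

test_that("identity gain reproduces the image exactly and constants are fixed points", {
  sys <- build_shearlet_system(c(64, 64), 2)
  img <- rand_gray(64, 64, seed = 8)
  out <- shearlet_enhance(img, sys, enhance_params(gain = 1))
  expect_equal(out$pixels, img$pixels)

  const <- gray_image(matrix(128, 64, 64))
  out2 <- shearlet_enhance(const, sys, enhance_params(gain = 3))
  expect_equal(out2$pixels, const$pixels)
})

test_that("amplifying fine scales sharpens a step edge", {
  px <- matrix(60, 64, 64); px[, 33:64] <- 180
  img <- gray_image(px)
  sys <- build_shearlet_system(c(64, 64), 2)
  enh <- shearlet_enhance(img, sys,
                          enhance_params(gain = 2, scales_amplified = 2,
                                         clip = FALSE))
  grad_in <- abs(px[, 33] - px[, 32])
  grad_out <- abs(enh[, 33] - enh[, 32])
  expect_true(mean(grad_out) > mean(grad_in))
})

test_that("enhancement dimensions are checked", {
  sys <- build_shearlet_system(c(64, 64), 2)
  expect_error(shearlet_enhance(rand_gray(32, 32), sys), "match")
})
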