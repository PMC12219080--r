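test_that("phantom generation is a pure function of (params, label, seed)", {
  p <- phantom_params()
  a <- generate_phantom(p, "abnormal", 7)
  b <- generate_phantom(p, "abnormal", 7)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$lesion_mask, b$truth$lesion_mask)
  expect_false(identical(a$image$pixels,
                         generate_phantom(p, "abnormal", 8)$image$pixels))
})

test_that("zero-contrast lesions degenerate to the normal class exactly", {
  p <- phantom_params(lesion_contrast = 0, spicule_count = 0, calc_count = 0)
  n <- generate_phantom(p, "normal", 12)
  a <- generate_phantom(p, "abnormal", 12)
  expect_identical(n$image$pixels, a$image$pixels)
  expect_null(n$truth$lesion_mask)
  expect_false(is.null(a$truth$lesion_mask))  # geometry still recorded
})

test_that("the default lesion is measurably brighter than its surround", {
  ph <- generate_phantom(phantom_params(), "abnormal", 0)
  px <- ph$image$pixels
  lm <- ph$truth$lesion_mask == 1
  ctr <- ph$truth$lesion_center; r <- ph$truth$lesion_radius
  rows <- matrix(seq_len(nrow(px)), nrow(px), ncol(px))
  cols <- matrix(seq_len(ncol(px)), nrow(px), ncol(px), byrow = TRUE)
  d <- sqrt((rows - 1 - ctr["row"])^2 + (cols - 1 - ctr["col"])^2)
  annulus <- d > r & d <= r * sqrt(2)  # same-area surround
  expect_gte(mean(px[lm]) - mean(px[annulus]), 0.5 * 60)
  # direction holds across seeds even where glandular texture interferes
  for (s in 1:6) {
    phs <- generate_phantom(phantom_params(), "abnormal", s)
    ds <- sqrt((rows - 1 - phs$truth$lesion_center["row"])^2 +
                 (cols - 1 - phs$truth$lesion_center["col"])^2)
    ann <- ds > phs$truth$lesion_radius & ds <= phs$truth$lesion_radius * sqrt(2)
    expect_gt(mean(phs$image$pixels[phs$truth$lesion_mask == 1]),
              mean(phs$image$pixels[ann]))
  }
})

test_that("datasets are balanced, reproducible, and carry truth manifests", {
  g <- generate_dataset(phantom_params(), n_per_class = 10, seed = 3)
  expect_equal(length(g$dataset), 20L)
  expect_equal(sum(g$dataset$labels == "normal"), 10L)
  expect_equal(nrow(g$manifest), 20L)
  expect_true(all(is.na(g$manifest$radius[g$manifest$label == "normal"])))
  expect_true(all(!is.na(g$manifest$radius[g$manifest$label == "abnormal"])))

  g2 <- generate_dataset(phantom_params(), n_per_class = 10, seed = 3)
  expect_identical(g$manifest, g2$manifest)
  expect_identical(g$dataset$images[[5]]$pixels, g2$dataset$images[[5]]$pixels)
  # per-image seeds make subsets reproducible independently of order
  solo <- generate_phantom(phantom_params(), g$manifest$label[5],
                           g$manifest$seed[5])
  expect_identical(solo$image$pixels, g$dataset$images[[5]]$pixels)
})

test_that("class separation in GLCM contrast grows with lesion contrast", {
  gaps <- c(contrast_gap(5), contrast_gap(20), contrast_gap(60))
  expect_true(all(diff(gaps) >= 0))
  expect_gt(gaps[3], 0)
})
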