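test_that("breast cropping keeps the largest component's bounding box", {
  px <- matrix(0, 40, 40)
  px[11:30, 6:25] <- 200
  res <- crop_breast_region(gray_image(px))
  expect_equal(unclass(res$box)[c("row_min", "row_max", "col_min", "col_max")],
               list(row_min = 10L, row_max = 30L, col_min = 5L, col_max = 25L))

  px2 <- matrix(0, 50, 50)
  px2[11:30, 11:30] <- 180      # 400 px blob
  px2[41:45, 41:45] <- 250      # 25 px blob
  res2 <- crop_breast_region(gray_image(px2))
  expect_equal(res2$box$row_max, 30L)
  expect_equal(res2$box$col_max, 30L)
  expect_true(all(res2$breast_mask[41:45, 41:45] == 0))

  expect_error(crop_breast_region(gray_image(matrix(0, 8, 8))), "foreground")
})

test_that("a corner-anchored pectoral wedge is detected and zeroed", {
  for (s in 1:3) {
    ph <- generate_phantom(phantom_params(pectoral = TRUE), "normal", s)
    res <- crop_breast_region(ph$image, remove_pectoral = TRUE)
    wedge <- ph$truth$pectoral_mask == 1L
    expect_gt(sum(wedge), 0)
    expect_true(all(res$pectoral_mask[wedge] == 1L | !wedge))
    # wedge pixels are gone from the cropped image
    full <- matrix(0, nrow(ph$image$pixels), ncol(ph$image$pixels))
    full[(res$box$row_min + 1):res$box$row_max,
         (res$box$col_min + 1):res$box$col_max] <- res$image$pixels
    expect_true(all(full[wedge] == 0))
  }
})

test_that("bimodal images threshold between the modes", {
  set.seed(3)
  vals <- sample(c(rep(40, 60), rep(200, 40)))
  img <- gray_image(matrix(vals, 10, 10))
  res <- improved_otsu_threshold(img, alpha = 0)
  expect_gte(res$threshold, 40)
  expect_lt(res$threshold, 200)
  expect_equal(mean(res$mask), 0.40)
  expect_error(improved_otsu_threshold(gray_image(matrix(9, 8, 8))),
               "degenerate")
})

test_that("variance weighting shifts the threshold without hurting lesion overlap", {
  ph <- generate_phantom(phantom_params(), "abnormal", 5)
  pre <- preprocess_image(ph$image)
  classical <- improved_otsu_threshold(pre, alpha = 0)
  weighted <- improved_otsu_threshold(pre, alpha = 1, window = 15)
  expect_false(weighted$threshold == classical$threshold)
  lesion <- ph$truth$lesion_mask == 1
  jac <- function(mask) sum(mask == 1 & lesion) / sum(mask == 1 | lesion)
  expect_gte(jac(weighted$mask), jac(classical$mask))
})

test_that("Canny behaves canonically on flat, step and disk images", {
  expect_true(all(canny_edges(gray_image(matrix(50, 32, 32))) == 0))

  px <- matrix(40, 32, 32); px[, 17:32] <- 210
  edges <- canny_edges(gray_image(px))
  hit_cols <- which(colSums(edges) > 0)
  expect_true(all(hit_cols >= 16 & hit_cols <= 18))
  expect_true(all(rowSums(edges[, hit_cols, drop = FALSE]) == 1))

  r <- 20
  rows <- matrix(1:96, 96, 96); cols <- t(rows)
  disk <- (rows - 48)^2 + (cols - 48)^2 <= r^2
  ring <- canny_edges(gray_image(disk * 200))
  count <- sum(ring)
  expect_lt(abs(count - 2 * pi * r) / (2 * pi * r), 0.15)
})

test_that("non-maximum suppression leaves no 2x2 solid blocks", {
  imgs <- list(generate_phantom(phantom_params(), "abnormal", 1)$image,
               generate_phantom(phantom_params(), "normal", 2)$image)
  for (img in imgs) {
    e <- canny_edges(img)
    expect_true(all(e %in% c(0L, 1L)))
    blocks <- e[-nrow(e), -ncol(e)] + e[-1, -ncol(e)] +
      e[-nrow(e), -1] + e[-1, -1]
    expect_lt(max(blocks), 4)
  }
})

test_that("ROI extraction combines masks and clips padding", {
  rows <- matrix(1:64, 64, 64); cols <- t(rows)
  disk <- ((rows - 30)^2 + (cols - 35)^2 <= 10^2) * 1L
  img <- gray_image(disk * 150)
  empty <- matrix(0L, 64, 64)
  res <- extract_roi(img, disk, empty, pad = 0)
  expect_equal(unclass(res$box)[1:4],
               list(row_min = 19L, row_max = 40L, col_min = 24L, col_max = 45L))

  res_pad <- extract_roi(img, disk, empty, pad = 1000)
  expect_equal(unclass(res_pad$box)[1:4],
               list(row_min = 0L, row_max = 64L, col_min = 0L, col_max = 64L))

  expect_error(extract_roi(img, empty, empty, 0), "empty")
})

test_that("phantom ROIs contain the true lesion box in at least 95 of 100 runs", {
  hits <- 0
  for (s in 1:100) {
    ph <- generate_phantom(phantom_params(), "abnormal", 1000 + s)
    pre <- preprocess_image(ph$image)
    ot <- improved_otsu_threshold(pre)
    ed <- canny_edges(pre)
    roi <- extract_roi(pre, ot$mask, ed, pad = 8)
    ctr <- ph$truth$lesion_center; r <- ph$truth$lesion_radius
    inside <- ctr["row"] - r >= roi$box$row_min &&
      ctr["row"] + r <= roi$box$row_max &&
      ctr["col"] - r >= roi$box$col_min &&
      ctr["col"] + r <= roi$box$col_max
    hits <- hits + inside
  }
  expect_gte(hits, 95)
})
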