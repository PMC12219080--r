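test_that("quantization bins follow the documented rule", {
  img <- gray_image(matrix(0:255, 16, 16))
  q <- quantize(img, 256)
  expect_equal(as.vector(q$levels), as.vector(img$pixels) + 1L)

  expect_true(all(quantize(gray_image(matrix(90, 5, 5)), 8)$levels == 1L))

  q4 <- quantize(img, 4)
  expect_equal(as.vector(table(q4$levels)), rep(64L, 4))
  expect_error(quantize(img, 1), "Ng")
})

test_that("GLCM counts hand-enumerable pair patterns", {
  q <- structure(list(levels = matrix(c(1L, 1L, 2L, 2L), 1, 4), Ng = 2L),
                 class = "quantized_image")
  M <- compute_glcm(q, 0, symmetric = FALSE)
  expect_equal(M$P[1, 1], 1 / 3)
  expect_equal(M$P[1, 2], 1 / 3)
  expect_equal(M$P[2, 2], 1 / 3)
  expect_equal(sum(M$P), 1)

  qc <- quantize(gray_image(matrix(77, 4, 4)), 8)
  Mc <- compute_glcm(qc, 90)
  expect_equal(Mc$P[1, 1], 1)

  expect_error(compute_glcm(structure(list(levels = matrix(1L, 1, 1), Ng = 2L),
                                      class = "quantized_image"), 0),
               "pairs")
})

test_that("GLCM normalisation and symmetry hold; rotation maps 0 deg to 90 deg", {
  set.seed(31)
  for (rep in 1:10) {
    q <- quantize(rand_gray(8, 8), 4)
    for (d in c(0, 45, 90, 135)) {
      M <- compute_glcm(q, d, symmetric = TRUE)
      expect_equal(sum(M$P), 1, tolerance = 1e-12)
      expect_equal(M$P, t(M$P))
    }
    # rotating the raster 90 deg counter-clockwise turns horizontal
    # neighbours into vertical ones
    rot <- q
    rot$levels <- t(q$levels)[ncol(q$levels):1, , drop = FALSE]
    M0 <- compute_glcm(rot, 0, symmetric = FALSE)$P
    M90 <- compute_glcm(q, 90, symmetric = FALSE)$P
    expect_true(isTRUE(all.equal(M0, M90)) || isTRUE(all.equal(M0, t(M90))))
  }
})

test_that("GLCM descriptors match closed forms and the naive oracle", {
  pm <- structure(list(P = matrix(c(1, 0, 0, 0), 2, 2), direction = 0,
                       distance = 1L, symmetric = TRUE), class = "glcm")
  f <- suppressWarnings(glcm_features(pm))
  expect_equal(unname(f[c("energy", "contrast", "entropy", "homogeneity",
                          "shade")]),
               c(1, 0, 0, 1, 0))
  expect_warning(glcm_features(pm), "constant")

  unif <- structure(list(P = matrix(0.25, 2, 2), direction = 0,
                         distance = 1L, symmetric = TRUE), class = "glcm")
  fu <- glcm_features(unif)
  expect_equal(unname(fu["energy"]), 0.25)
  expect_equal(unname(fu["entropy"]), 2)
  expect_equal(unname(fu["contrast"]), 0.5)

  set.seed(13)
  for (rep in 1:10) {
    M <- compute_glcm(quantize(rand_gray(8, 8), 6), sample(c(0, 45, 90, 135), 1))
    expect_equal(unname(glcm_features(M)), unname(oracle_glcm_features(M$P)),
                 tolerance = 1e-12)
  }
})

test_that("run-length matrices count hand-enumerable runs", {
  q <- structure(list(levels = matrix(c(5L, 5L, 5L, 2L), 1, 4), Ng = 5L),
                 class = "quantized_image")
  R <- compute_glrlm(q, 0)
  expect_equal(R$R[5, 3], 1L)
  expect_equal(R$R[2, 1], 1L)
  expect_equal(R$Nr, 2L)

  ck <- structure(list(levels = (outer(1:8, 1:8, "+") %% 2L) + 1L, Ng = 2L),
                  class = "quantized_image")
  Rck <- compute_glrlm(ck, 0)
  expect_true(all(Rck$R[, -1] == 0))
  expect_equal(Rck$Nr, 64L)
})

test_that("run-length pixel conservation holds and builders match the oracle", {
  set.seed(17)
  for (rep in 1:10) {
    q <- quantize(rand_gray(8, 8), 4)
    for (d in c(0, 45, 90, 135)) {
      R <- compute_glrlm(q, d)
      expect_equal(sum(sweep(R$R, 2, seq_len(R$Lmax), "*")), 64)
      orc <- oracle_glrlm(q$levels, 4, d)
      expect_equal(unname(R$R[, seq_len(ncol(orc))]), unname(orc))
    }
  }
})

test_that("run-length descriptors match closed forms and the naive oracle", {
  one_run <- structure(list(R = matrix(c(0, 0, 0, 1), 1, 4), direction = 0,
                            Nr = 1, Lmax = 4L), class = "glrlm")
  f <- glrlm_features(one_run)
  expect_equal(unname(f["sre"]), 1 / 16)
  expect_equal(unname(f["lre"]), 16)
  expect_equal(unname(f["gln"]), 1)

  ck <- structure(list(levels = (outer(1:8, 1:8, "+") %% 2L) + 1L, Ng = 2L),
                  class = "quantized_image")
  fck <- glrlm_features(compute_glrlm(ck, 0))
  expect_equal(unname(fck["sre"]), 1)
  expect_equal(unname(fck["lre"]), 1)

  set.seed(19)
  for (rep in 1:10) {
    R <- compute_glrlm(quantize(rand_gray(8, 8), 4), 45)
    expect_equal(unname(glrlm_features(R)),
                 unname(oracle_glrlm_features(R$R, R$Nr)), tolerance = 1e-12)
  }
})

test_that("first-order statistics match direct evaluation", {
  f <- suppressWarnings(first_order_features(gray_image(matrix(128, 5, 5))))
  expect_equal(unname(f), c(128, 0, 0, 1, 0))
  expect_warning(first_order_features(gray_image(matrix(128, 5, 5))),
                 "zero-variance")

  two <- gray_image(matrix(c(rep(0, 8), rep(255, 8)), 4, 4))
  f2 <- first_order_features(two)
  expect_equal(unname(f2["mean"]), 127.5)
  expect_equal(unname(f2["entropy"]), 1)
  expect_equal(unname(f2["uniformity"]), 0.5)
  expect_equal(unname(f2["smoothness"]), 1 - 1 / 1.25)

  set.seed(23)
  img <- rand_gray(12, 12)
  f3 <- first_order_features(img)
  z <- as.vector(img$pixels)
  mu <- mean(z); s2 <- mean((z - mu)^2)
  expect_equal(unname(f3["mean"]), mu, tolerance = 1e-10)
  expect_equal(unname(f3["skewness"]), mean((z - mu)^3) / s2^1.5,
               tolerance = 1e-10)
  expect_equal(unname(f3["smoothness"]), 1 - 1 / (1 + s2 / 255^2),
               tolerance = 1e-10)
})

test_that("the hybrid vector has the canonical 49-name layout and no NaNs", {
  expect_length(hybrid_feature_names(), 49L)
  img <- generate_phantom(phantom_params(), "abnormal", 5)$image
  fv <- assemble_hybrid(img)
  expect_named(fv, hybrid_feature_names())
  expect_false(anyNA(fv))
  expect_identical(fv, assemble_hybrid(img))

  const <- gray_image(matrix(60, 24, 24))
  fvc <- assemble_hybrid(const)
  expect_equal(unname(fvc["fo_mean"]), 60)
  expect_equal(unname(fvc["glcm_energy_d0"]), 1)
  expect_equal(unname(fvc["glcm_contrast_d0"]), 0)
  expect_equal(unname(fvc["glrlm_gln_d90"]), 24)  # 24 full-column runs
})
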