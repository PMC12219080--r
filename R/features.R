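#' Gray-level quantization
#'
#' Bins intensities into `Ng` levels using the region's own range:
#' `bin = 1 + floor((I - min) * Ng / (max - min + 1))`. Levels are 1-based so
#' that low-gray-level run emphasis (`1/i^2`) is well defined at the lowest
#' level. A constant region maps every pixel to bin 1.
#'
#' @param img A [gray_image()] (typically an ROI crop).
#' @param Ng Number of gray levels, >= 2. Default 32.
#' @return An object of class `quantized_image`: list with `levels` (integer
#'   matrix in `[1, Ng]`) and `Ng`.
#' @export
quantize <- function(img, Ng = 32) {
  assert_gray_image(img)
  Ng <- as.integer(Ng)
  if (Ng < 2L) stop("Ng must be >= 2", call. = FALSE)
  px <- img$pixels
  rng <- range(px)
  lev <- if (rng[1] == rng[2]) {
    matrix(1L, nrow(px), ncol(px))
  } else {
    matrix(pmin(1L + as.integer(floor((px - rng[1]) * Ng / (rng[2] - rng[1] + 1))),
                Ng),
           nrow(px), ncol(px))
  }
  structure(list(levels = lev, Ng = Ng), class = "quantized_image")
}

glcm_offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                     `90` = c(-1L, 0L), `135` = c(-1L, -1L))

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of level pairs at pixel distance 1 along one of the
#' four principal directions (offsets: 0 deg `(0,+1)`, 45 deg `(-1,+1)`,
#' 90 deg `(-1,0)`, 135 deg `(-1,-1)`), normalised to sum 1. Symmetric mode
#' (the default, standard Haralick practice) also counts each reversed pair.
#'
#' @param q A [quantize()]d image.
#' @param direction One of 0, 45, 90, 135 (degrees).
#' @param symmetric Count pairs in both orders. Default TRUE.
#' @return An object of class `glcm`: list with `P` (Ng x Ng, sums to 1),
#'   `direction`, `distance` (1) and `symmetric`.
#' @export
compute_glcm <- function(q, direction = 0, symmetric = TRUE) {
  stopifnot(inherits(q, "quantized_image"))
  off <- glcm_offsets[[as.character(direction)]]
  if (is.null(off)) stop("direction must be one of 0, 45, 90, 135", call. = FALSE)
  lev <- q$levels
  nr <- nrow(lev); nc <- ncol(lev)
  rows <- seq_len(nr); cols <- seq_len(nc)
  r1 <- rows[rows + off[1] >= 1L & rows + off[1] <= nr]
  c1 <- cols[cols + off[2] >= 1L & cols + off[2] <= nc]
  if (length(r1) == 0L || length(c1) == 0L) {
    stop("region smaller than the offset span: no pixel pairs", call. = FALSE)
  }
  a <- lev[r1, c1, drop = FALSE]
  b <- lev[r1 + off[1], c1 + off[2], drop = FALSE]
  counts <- tabulate((b - 1L) * q$Ng + a, nbins = q$Ng * q$Ng)
  P <- matrix(counts, q$Ng, q$Ng)
  if (symmetric) P <- P + t(P)
  structure(list(P = P / sum(P), direction = direction, distance = 1L,
                 symmetric = symmetric),
            class = "glcm")
}

#' Haralick-style GLCM descriptors
#'
#' Energy, contrast, entropy (base-2, with `0 log 0 = 0`), homogeneity,
#' correlation and cluster shade, computed from a normalised co-occurrence
#' matrix. Correlation of a constant texture (zero marginal spread) is
#' reported as 0 with a warning.
#'
#' @param M A [compute_glcm()] result.
#' @return Named numeric vector of the six descriptors.
#' @export
glcm_features <- function(M) {
  stopifnot(inherits(M, "glcm"))
  P <- M$P
  Ng <- nrow(P)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  adiff <- abs(i - j)
  energy <- sum(P^2)
  contrast <- sum(adiff^2 * P)
  pos <- P > 0
  entropy <- -sum(P[pos] * log2(P[pos]))
  homogeneity <- sum(P / (1 + adiff))
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  correlation <- if (sd_i == 0 || sd_j == 0) {
    warning("constant texture: GLCM correlation undefined, reporting 0",
            call. = FALSE)
    0
  } else {
    sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j)
  }
  shade <- sum((i + j - mu_i - mu_j)^3 * P)
  c(energy = energy, contrast = contrast, entropy = entropy,
    homogeneity = homogeneity, correlation = correlation, shade = shade)
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal quantised levels along every line of the
#' image in the given direction (0 deg rows, 90 deg columns, 45 deg
#' anti-diagonals running up-right, 135 deg diagonals running up-left).
#' Rows index gray level, columns index run length.
#'
#' @param q A [quantize()]d image.
#' @param direction One of 0, 45, 90, 135 (degrees).
#' @return An object of class `glrlm`: list with `R` (Ng x Lmax counts),
#'   `direction`, `Nr` (total number of runs) and `Lmax`.
#' @export
compute_glrlm <- function(q, direction = 0) {
  stopifnot(inherits(q, "quantized_image"))
  lev <- q$levels
  nr <- nrow(lev); nc <- ncol(lev)
  lines <- switch(as.character(direction),
    `0`   = split(as.vector(t(lev)), rep(seq_len(nr), each = nc)),
    `90`  = split(as.vector(lev), rep(seq_len(nc), each = nr)),
    `45`  = {  # up-right: constant row+col, walked from bottom-left
      key <- as.vector(row(lev) + col(lev))
      ord <- order(key, -as.vector(row(lev)))
      split(as.vector(lev)[ord], key[ord])
    },
    `135` = {  # up-left: constant row-col, walked from bottom-right
      key <- as.vector(row(lev) - col(lev))
      ord <- order(key, -as.vector(row(lev)))
      split(as.vector(lev)[ord], key[ord])
    },
    stop("direction must be one of 0, 45, 90, 135", call. = FALSE)
  )
  Lmax <- max(vapply(lines, length, 1L))
  R <- matrix(0L, q$Ng, Lmax)
  for (v in lines) {
    runs <- rle(v)
    for (k in seq_along(runs$lengths)) {
      R[runs$values[k], runs$lengths[k]] <- R[runs$values[k], runs$lengths[k]] + 1L
    }
  }
  structure(list(R = R, direction = direction, Nr = sum(R), Lmax = Lmax),
            class = "glrlm")
}

#' Galloway-style run-length descriptors
#'
#' Short/long run emphasis, low/high gray-level run emphasis, and gray-level
#' non-uniformity, all normalised by the total run count `Nr`.
#'
#' @param R A [compute_glrlm()] result.
#' @return Named numeric vector of the five descriptors.
#' @export
glrlm_features <- function(R) {
  stopifnot(inherits(R, "glrlm"))
  if (R$Nr < 1) stop("empty run-length matrix", call. = FALSE)
  m <- R$R
  i <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  j <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  c(sre  = sum(m / j^2) / R$Nr,
    lre  = sum(m * j^2) / R$Nr,
    lgre = sum(m / i^2) / R$Nr,
    hgre = sum(m * i^2) / R$Nr,
    gln  = sum(rowSums(m)^2) / R$Nr)
}

#' First-order histogram statistics
#'
#' Mean, skewness, entropy (base-2), uniformity and smoothness of the
#' intensity distribution over the selected pixels. Intensities are binned at
#' the integer gray levels `0..max_value`; smoothness is
#' `1 - 1/(1 + sigma_n^2)` with `sigma_n` the standard deviation of
#' intensities rescaled to `[0, 1]`. Skewness of a zero-variance region is
#' reported as 0 with a warning.
#'
#' @param img A [gray_image()].
#' @param mask Optional binary matrix selecting pixels (default: all).
#' @return Named numeric vector of the five descriptors.
#' @export
first_order_features <- function(img, mask = NULL) {
  assert_gray_image(img)
  z <- if (is.null(mask)) as.vector(img$pixels) else img$pixels[mask != 0]
  if (length(z) < 2L) stop("need at least 2 selected pixels", call. = FALSE)
  g <- pmin(pmax(round(z), 0), img$max_value)
  p <- tabulate(g + 1L, nbins = as.integer(img$max_value) + 1L)
  p <- p / sum(p)
  lv <- 0:as.integer(img$max_value)
  mu <- sum(lv * p)
  sig2 <- sum((lv - mu)^2 * p)
  skew <- if (sig2 == 0) {
    warning("zero-variance region: skewness undefined, reporting 0",
            call. = FALSE)
    0
  } else {
    sum((lv - mu)^3 * p) / sig2^1.5
  }
  pos <- p > 0
  entropy <- -sum(p[pos] * log2(p[pos]))
  uniformity <- sum(p^2)
  sig_n2 <- sig2 / img$max_value^2
  c(mean = mu, skewness = skew, entropy = entropy, uniformity = uniformity,
    smoothness = 1 - 1 / (1 + sig_n2))
}

#' Canonical hybrid feature-vector names
#'
#' @return Character vector of the 49 descriptor names, in canonical order:
#'   5 first-order, then 6 GLCM descriptors for each of the 4 directions,
#'   then 5 run-length descriptors for each of the 4 directions.
#' @export
hybrid_feature_names <- function() {
  dirs <- c(0, 45, 90, 135)
  c(paste0("fo_", c("mean", "skewness", "entropy", "uniformity", "smoothness")),
    as.vector(t(outer(dirs, c("energy", "contrast", "entropy", "homogeneity",
                              "correlation", "shade"),
                      function(d, f) paste0("glcm_", f, "_d", d)))),
    as.vector(t(outer(dirs, c("sre", "lre", "lgre", "hgre", "gln"),
                      function(d, f) paste0("glrlm_", f, "_d", d)))))
}

#' Assemble the hybrid feature vector
#'
#' Computes the canonical 49-element descriptor vector on an ROI crop:
#' first-order statistics on the raw intensities, then GLCM and GLRLM
#' descriptors on the `Ng`-level quantised crop, each over the four principal
#' directions.
#'
#' @param img A [gray_image()].
#' @param roi Optional [roi_box()]; default uses the whole image.
#' @param Ng Quantisation depth. Default 32.
#' @param symmetric Symmetric GLCM accumulation. Default TRUE.
#' @return Named numeric vector of length 49 (see [hybrid_feature_names()]).
#' @export
assemble_hybrid <- function(img, roi = NULL, Ng = 32, symmetric = TRUE) {
  assert_gray_image(img)
  crop <- if (is.null(roi)) img else crop_to_box(img, roi)
  q <- quantize(crop, Ng)
  fo <- suppressWarnings(first_order_features(crop))
  vals <- c(fo)
  for (d in c(0, 45, 90, 135)) {
    vals <- c(vals, suppressWarnings(glcm_features(compute_glcm(q, d, symmetric))))
  }
  for (d in c(0, 45, 90, 135)) {
    vals <- c(vals, glrlm_features(compute_glrlm(q, d)))
  }
  vals <- unname(vals)
  stats::setNames(vals, hybrid_feature_names())
}

#' Hybrid feature table for a dataset
#'
#' Runs the configured preprocessing + segmentation + feature pipeline over
#' every image and returns one tibble row per image.
#'
#' @param data A [mammo_dataset()].
#' @param config A [pipeline_config()] (or NULL for defaults).
#' @return Tibble with `id`, `label` and the 49 named feature columns.
#' @export
feature_table <- function(data, config = NULL) {
  config <- resolve_config(config)
  rows <- purrr::map2(data$images, seq_along(data$images), function(img, i) {
    fv <- pipeline_features(img, config)
    tibble::tibble(id = data$ids[i], label = data$labels[i], !!!as.list(fv))
  })
  dplyr::bind_rows(rows)
}
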