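#' ROI box
#'
#' Pixel-index bounding box, 0-based, half-open on the max side
#' (`row_min <= r < row_max`).
#'
#' @param row_min,row_max,col_min,col_max Integer bounds.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(row_min, row_max, col_min, col_max) {
  b <- list(row_min = as.integer(row_min), row_max = as.integer(row_max),
            col_min = as.integer(col_min), col_max = as.integer(col_max))
  if (b$row_min < 0L || b$col_min < 0L ||
      b$row_min >= b$row_max || b$col_min >= b$col_max) {
    stop("invalid roi_box bounds", call. = FALSE)
  }
  structure(b, class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box> rows [%d, %d), cols [%d, %d)\n",
              x$row_min, x$row_max, x$col_min, x$col_max))
  invisible(x)
}

crop_to_box <- function(img, box) {
  gray_image(img$pixels[(box$row_min + 1L):box$row_max,
                        (box$col_min + 1L):box$col_max, drop = FALSE],
             img$max_value)
}

mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no bounding box", call. = FALSE)
  roi_box(min(idx[, 1]) - 1L, max(idx[, 1]), min(idx[, 2]) - 1L, max(idx[, 2]))
}

# Shift a matrix by (dr, dc) with replicated borders.
shift_replicate <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  m[pmin(pmax(seq_len(nr) - dr, 1L), nr), pmin(pmax(seq_len(nc) - dc, 1L), nc)]
}

# 3x3 binary dilation / erosion via shifts (replicated borders).
dilate3 <- function(mask) {
  acc <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr || dc) acc <- acc | shift_replicate(mask, dr, dc)
  }
  acc
}
erode3 <- function(mask) {
  acc <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr || dc) acc <- acc & shift_replicate(mask, dr, dc)
  }
  acc
}

# Box-mean filter with replicated borders via an integral image.
box_mean <- function(m, window) {
  r <- window %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[pmin(pmax(seq_len(nr + 2L * r) - r, 1L), nr),
           pmin(pmax(seq_len(nc + 2L * r) - r, 1L), nc)]
  S <- rbind(0, apply(pad, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  i1 <- seq_len(nr); i2 <- i1 + 2L * r
  j1 <- seq_len(nc); j2 <- j1 + 2L * r
  (S[i2 + 1L, j2 + 1L, drop = FALSE] - S[i1, j2 + 1L, drop = FALSE] -
     S[i2 + 1L, j1, drop = FALSE] + S[i1, j1, drop = FALSE]) / window^2
}

#' Local intensity variance
#'
#' Mean of squares minus squared mean over a `window x window` neighbourhood,
#' borders replicated. Used to weight the improved-Otsu histogram.
#'
#' @param img A [gray_image()].
#' @param window Odd window size >= 3.
#' @return Numeric matrix of per-pixel variances.
#' @export
local_variance <- function(img, window = 15) {
  assert_gray_image(img)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop("window must be odd and >= 3", call. = FALSE)
  }
  mu <- box_mean(img$pixels, window)
  pmax(box_mean(img$pixels^2, window) - mu^2, 0)
}

# Exhaustive between-class-variance maximisation over a (possibly weighted)
# histogram on levels 0..max_value. Returns the smallest maximising threshold;
# the mask convention is foreground = intensity > t.
otsu_from_histogram <- function(h) {
  levels <- seq_along(h) - 1
  total <- sum(h)
  w0 <- cumsum(h)
  m0 <- cumsum(h * levels)
  mu_t <- m0[length(h)] / total
  om <- w0 / total
  valid <- om > 0 & om < 1
  if (!any(valid)) stop("degenerate histogram: single occupied level", call. = FALSE)
  sigma_b <- rep(-Inf, length(h))
  sigma_b[valid] <- (mu_t * om[valid] - m0[valid] / total)^2 /
    (om[valid] * (1 - om[valid]))
  levels[which.max(sigma_b)]
}

#' Improved (variance-weighted) Otsu thresholding
#'
#' Classical Otsu picks the global threshold maximising between-class variance
#' of the intensity histogram. The improved variant adapts to local image
#' statistics: each pixel contributes to the histogram with weight
#' `1 + alpha * v(x) / max(v)`, where `v` is the local variance over a
#' `window x window` neighbourhood, so high-texture pixels (lesion borders,
#' spiculations) pull the threshold toward separating them. `alpha = 0`
#' recovers classical Otsu exactly.
#'
#' @param img A [gray_image()].
#' @param alpha Non-negative local-variance weight. Default 1.
#' @param window Odd local-variance window. Default 15.
#' @return List with `threshold` (a gray level; foreground is `> threshold`)
#'   and `mask` (binary matrix).
#' @export
improved_otsu_threshold <- function(img, alpha = 1, window = 15) {
  assert_gray_image(img)
  if (alpha < 0) stop("alpha must be non-negative", call. = FALSE)
  g <- pmin(pmax(round(img$pixels), 0), img$max_value)
  if (alpha == 0) {
    w <- matrix(1, nrow(g), ncol(g))
  } else {
    v <- local_variance(img, window)
    vmax <- max(v)
    w <- 1 + if (vmax > 0) alpha * v / vmax else 0 * v
  }
  nlev <- as.integer(img$max_value) + 1L
  h <- as.vector(tapply(as.vector(w), factor(as.vector(g), levels = 0:(nlev - 1L)),
                        sum, default = 0))
  t_star <- otsu_from_histogram(h)
  list(threshold = t_star, mask = (g > t_star) * 1L)
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantised gradient direction, and dual-threshold hysteresis. The two
#' thresholds are fractions of the maximum gradient magnitude (defaults 0.1
#' and 0.3), so they adapt to image contrast.
#'
#' @param img A [gray_image()].
#' @param low_frac,high_frac Hysteresis thresholds as fractions of the peak
#'   gradient magnitude, `0 < low < high <= 1`.
#' @param sigma Gaussian smoothing width in pixels. Default 1.4.
#' @return Binary edge mask (matrix of 0/1).
#' @export
canny_edges <- function(img, low_frac = 0.1, high_frac = 0.3, sigma = 1.4) {
  assert_gray_image(img)
  if (!(low_frac > 0 && low_frac < high_frac && high_frac <= 1)) {
    stop("need 0 < low_frac < high_frac <= 1", call. = FALSE)
  }
  x <- gaussian_blur(img$pixels, sigma)
  gx <- sobel_conv(x, horizontal = TRUE)   # d/dcol
  gy <- sobel_conv(x, horizontal = FALSE)  # d/drow
  mag <- sqrt(gx^2 + gy^2)
  gmax <- max(mag)
  if (gmax == 0) return(matrix(0L, nrow(x), ncol(x)))

  # non-maximum suppression with linearly interpolated neighbour magnitudes
  # along the true gradient direction (avoids staircase double edges)
  nb <- function(dr, dc) shift_replicate(mag, -dr, -dc)
  N <- list(E = nb(0, 1), W = nb(0, -1), S = nb(1, 0), Nn = nb(-1, 0),
            SE = nb(1, 1), NW = nb(-1, -1), NE = nb(-1, 1), SW = nb(1, -1))
  s <- ifelse(gx < 0, -1, 1)  # normalise so the col component is >= 0
  gx_ <- gx * s; gy_ <- gy * s
  m1 <- matrix(0, nrow(x), ncol(x)); m2 <- m1
  c1 <- gy_ >= 0 & gx_ >= gy_            # 0..45 deg
  c2 <- gy_ > 0 & gy_ > gx_              # 45..90 deg
  c3 <- gy_ < 0 & gx_ >= -gy_            # -45..0 deg
  c4 <- gy_ < 0 & -gy_ > gx_             # -90..-45 deg
  t <- matrix(0, nrow(x), ncol(x))
  gabs <- pmax(abs(gx_), 1e-12)
  t[c1] <- (gy_ / gabs)[c1]
  t[c3] <- (-gy_ / gabs)[c3]
  vabs <- pmax(abs(gy_), 1e-12)
  t[c2] <- (gx_ / vabs)[c2]
  t[c4] <- (gx_ / vabs)[c4]
  m1[c1] <- ((1 - t) * N$E + t * N$SE)[c1]
  m2[c1] <- ((1 - t) * N$W + t * N$NW)[c1]
  m1[c2] <- ((1 - t) * N$S + t * N$SE)[c2]
  m2[c2] <- ((1 - t) * N$Nn + t * N$NW)[c2]
  m1[c3] <- ((1 - t) * N$E + t * N$NE)[c3]
  m2[c3] <- ((1 - t) * N$W + t * N$SW)[c3]
  m1[c4] <- ((1 - t) * N$Nn + t * N$NE)[c4]
  m2[c4] <- ((1 - t) * N$S + t * N$SW)[c4]
  nms <- mag * (mag >= m1 & mag > m2)
  nms <- thin_blocks(nms)

  strong <- nms >= high_frac * gmax
  weak <- nms >= low_frac * gmax
  cpp_hysteresis(weak * 1L, strong * 1L)
}

# Break any solid 2x2 response block by dropping its weakest pixel, so
# suppressed edges are everywhere at most one pixel wide across their normal.
thin_blocks <- function(nms) {
  repeat {
    on <- nms > 0
    blk <- which(on[-nrow(on), -ncol(on)] & on[-1, -ncol(on)] &
                   on[-nrow(on), -1] & on[-1, -1], arr.ind = TRUE)
    if (nrow(blk) == 0) return(nms)
    for (k in seq_len(nrow(blk))) {
      i <- blk[k, 1]; j <- blk[k, 2]
      cells <- rbind(c(i, j), c(i + 1, j), c(i, j + 1), c(i + 1, j + 1))
      vals <- nms[cells]
      if (all(vals > 0)) nms[cells[which.min(vals), , drop = FALSE]] <- 0
    }
  }
}

gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_axis <- function(n) {
    W <- matrix(0, n, n)
    for (o in -r:r) {
      j <- pmin(pmax(seq_len(n) + o, 1L), n)
      W[cbind(seq_len(n), j)] <- W[cbind(seq_len(n), j)] + k[o + r + 1L]
    }
    W
  }
  conv_axis(nrow(m)) %*% m %*% t(conv_axis(ncol(m)))
}

sobel_conv <- function(m, horizontal) {
  s1 <- c(1, 2, 1); s2 <- c(-1, 0, 1)
  acc <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    wgt <- if (horizontal) s1[dr + 2] * s2[dc + 2] else s2[dr + 2] * s1[dc + 2]
    if (wgt != 0) acc <- acc + wgt * shift_replicate(m, -dr, -dc)
  }
  acc
}

#' Crop the breast region
#'
#' Thresholds the image at `0.05 * max_value`, keeps the largest 8-connected
#' foreground component, optionally removes a pectoral-muscle wedge (a
#' high-intensity region anchored at a top image corner, covering 2-40% of
#' the component — mammogram pectoral shadows are corner-anchored bright
#' triangles), and returns the bounding-box crop of what remains.
#'
#' @param img A [gray_image()].
#' @param remove_pectoral Apply the corner-wedge heuristic. Default TRUE.
#' @return List with `image` (cropped [gray_image()]), `box` ([roi_box()]),
#'   `breast_mask` (full-size binary matrix after wedge removal) and
#'   `pectoral_mask` (full-size binary matrix, possibly all zero).
#' @export
crop_breast_region <- function(img, remove_pectoral = TRUE) {
  assert_gray_image(img)
  fg <- (img$pixels > 0.05 * img$max_value) * 1L
  if (!any(fg == 1L)) stop("empty foreground: nothing to crop", call. = FALSE)
  labels <- cpp_label8(fg)
  comp_id <- which.max(tabulate(labels[labels > 0L]))
  comp <- (labels == comp_id)
  pect <- matrix(0L, nrow(fg), ncol(fg))

  if (isTRUE(remove_pectoral)) {
    vals <- img$pixels[comp]
    thr <- mean(vals) + stats::sd(vals)
    bright <- (comp & img$pixels > thr) * 1L
    if (any(bright == 1L)) {
      blab <- cpp_label8(bright)
      nc <- ncol(bright)
      corner_labels <- unique(c(blab[1:min(3, nrow(bright)), 1:min(3, nc)],
                                blab[1:min(3, nrow(bright)), max(1, nc - 2):nc]))
      corner_labels <- setdiff(corner_labels, 0L)
      if (length(corner_labels)) {
        cand <- matrix(blab %in% corner_labels, nrow(bright), ncol(bright))
        frac <- sum(cand) / sum(comp)
        if (frac >= 0.02 && frac <= 0.40) {
          # fill each row from the anchored corner out to the furthest
          # detected wedge pixel (+2 px margin) so noisy stragglers go too
          left <- sum(cand[, 1:max(1, nc %/% 2)]) >= sum(cand) / 2
          for (r in which(rowSums(cand) > 0)) {
            cols <- which(cand[r, ] > 0)
            if (left) pect[r, 1:min(ncol(cand), max(cols) + 2L)] <- 1L
            else pect[r, max(1L, min(cols) - 2L):ncol(cand)] <- 1L
          }
          pect <- pect * comp
        }
      }
    }
  }

  keep <- comp & pect == 0L
  if (!any(keep)) stop("segmentation removed all foreground", call. = FALSE)
  box <- mask_bbox(keep)
  out <- img
  out$pixels[pect == 1L] <- 0
  list(image = crop_to_box(out, box), box = box,
       breast_mask = keep * 1L, pectoral_mask = pect)
}

#' Extract the region of interest
#'
#' Combines the statistical threshold mask with the gradient edge mask: their
#' union is morphologically closed (3x3), the largest 8-connected component is
#' taken, and its bounding box — expanded by `pad` and clipped to the image —
#' is returned together with the crop.
#'
#' @param img A [gray_image()].
#' @param mask Binary matrix from [improved_otsu_threshold()].
#' @param edges Binary matrix from [canny_edges()].
#' @param pad Padding in pixels around the detected box. Default 8.
#' @return List with `image` (the ROI crop) and `box` ([roi_box()]).
#' @export
extract_roi <- function(img, mask, edges, pad = 8) {
  assert_gray_image(img)
  if (!all(dim(mask) == dim(img$pixels)) || !all(dim(edges) == dim(img$pixels))) {
    stop("mask/edge dimensions must match the image", call. = FALSE)
  }
  u <- (mask != 0) | (edges != 0)
  if (!any(u)) stop("empty mask-edge union: no ROI", call. = FALSE)
  closed <- erode3(dilate3(u))
  if (!any(closed)) closed <- u  # closing can erase hairline structures
  labels <- cpp_label8(closed * 1L)
  comp <- labels == which.max(tabulate(labels[labels > 0L]))
  box <- mask_bbox(comp)
  box <- roi_box(max(0L, box$row_min - pad), min(nrow(u), box$row_max + pad),
                 max(0L, box$col_min - pad), min(ncol(u), box$col_max + pad))
  list(image = crop_to_box(img, box), box = box)
}
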