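#' Bilinear image resizing
#'
#' Separable bilinear interpolation with pixel-centre alignment: output pixel
#' centre `i + 0.5` (in units of the output grid) maps to source coordinate
#' `(i + 0.5) * src/dst - 0.5`, clamped to the source grid, so constant images
#' stay constant and resizing to the same size is the identity.
#'
#' @param img A [gray_image()].
#' @param target Integer vector `c(height, width)`.
#' @return A [gray_image()] with the target dimensions.
#' @export
resize_image <- function(img, target) {
  assert_gray_image(img)
  target <- as.integer(target)
  if (length(target) != 2L || any(target < 1L)) {
    stop("`target` must be c(height, width) with both >= 1", call. = FALSE)
  }
  if (identical(dim(img$pixels), target)) return(img)
  W_r <- bilinear_weights(nrow(img$pixels), target[1])
  W_c <- bilinear_weights(ncol(img$pixels), target[2])
  out <- W_r %*% img$pixels %*% t(W_c)
  out <- pmin(pmax(out, 0), img$max_value)
  gray_image(out, img$max_value)
}

# Interpolation weight matrix (n_out x n_in) for one axis.
bilinear_weights <- function(n_in, n_out) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  lo <- floor(src)
  hi <- pmin(lo + 1, n_in - 1)
  frac <- src - lo
  W <- matrix(0, n_out, n_in)
  idx <- seq_len(n_out)
  W[cbind(idx, lo + 1)] <- W[cbind(idx, lo + 1)] + (1 - frac)
  W[cbind(idx, hi + 1)] <- W[cbind(idx, hi + 1)] + frac
  W
}

#' Linear contrast stretching
#'
#' Rescales intensities so the observed range maps onto the full
#' `[0, max_value]` dynamic range:
#' `out = round((in - min) * max_value / (max - min))`. A constant image has
#' no range to stretch; it maps to all zeros with a warning.
#'
#' @param img A [gray_image()].
#' @return A [gray_image()] spanning the full range (non-constant input).
#' @export
contrast_stretch <- function(img) {
  assert_gray_image(img)
  rng <- range(img$pixels)
  if (rng[1] == rng[2]) {
    warning("constant image: contrast stretch is degenerate, returning zeros",
            call. = FALSE)
    return(gray_image(matrix(0, nrow(img$pixels), ncol(img$pixels)),
                      img$max_value))
  }
  out <- round((img$pixels - rng[1]) * img$max_value / (rng[2] - rng[1]))
  gray_image(out, img$max_value)
}

#' 3x3 median filtering
#'
#' Each pixel is replaced by the median of its 3x3 neighbourhood; borders are
#' handled by edge replication, which avoids introducing artificial dark
#' frames that would bias a later global threshold.
#'
#' @param img A [gray_image()].
#' @return A [gray_image()].
#' @export
median_filter3 <- function(img) {
  assert_gray_image(img)
  gray_image(cpp_median3(img$pixels), img$max_value)
}

#' Full preprocessing chain
#'
#' Applies, in order: resize to the working resolution, contrast stretching,
#' 3x3 median filtering, and shearlet-domain enhancement. Individual stages
#' can be toggled (the resize always runs), which is what the ablation grid
#' exercises.
#'
#' @param img A [gray_image()].
#' @param target Working resolution, default `c(224, 224)`.
#' @param stages Character subset of `c("contrast", "median", "shearlet")`.
#' @param n_scales,gain,scales_amplified Shearlet enhancement parameters, see
#'   [build_shearlet_system()] and [shearlet_enhance()].
#' @return A [gray_image()] at the target resolution.
#' @export
preprocess_image <- function(img, target = c(224, 224),
                             stages = c("contrast", "median", "shearlet"),
                             n_scales = 3, gain = 1.5,
                             scales_amplified = NULL) {
  out <- resize_image(img, target)
  if ("contrast" %in% stages) {
    const <- length(unique(as.vector(out$pixels))) == 1L
    out <- if (const) out else contrast_stretch(out)
  }
  if ("median" %in% stages) out <- median_filter3(out)
  if ("shearlet" %in% stages) {
    sys <- shearlet_system_cached(dim(out$pixels), n_scales)
    if (is.null(scales_amplified)) {
      scales_amplified <- seq_len(n_scales)[-1][seq_len(min(2, n_scales - 1))]
      if (n_scales == 1) scales_amplified <- 1L
    }
    out <- shearlet_enhance(out, sys,
                            enhance_params(gain = gain,
                                           scales_amplified = scales_amplified))
  }
  out
}
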