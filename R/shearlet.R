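#' Shearlet systems and shearlet-domain enhancement
#'
#' A cone-adapted, band-limited shearlet system built from Meyer-type radial
#' and shear windows on the discrete frequency grid. The squared filter
#' magnitudes form an exact partition of unity (a Parseval frame), so the
#' inverse transform is simply multiplication by the same (real, non-negative)
#' filters followed by summation — reconstruction is exact to floating-point
#' precision, which is what makes the enhancement step testable.
#'
#' Scales are indexed 1 (coarsest) to `n_scales` (finest); at scale `j` the
#' shear parameter spans `-2^j, ..., 2^j` on each of the two frequency cones
#' (column-frequency-dominant and row-frequency-dominant).
#'
#' @name shearlet
NULL

# Meyer auxiliary polynomial: C^3 smoothstep on [0, 1].
meyer_nu <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^4 * (35 - 84 * t + 70 * t^2 - 20 * t^3)
}

# Smooth transition: 0 below a, 1 above b.
meyer_step <- function(x, a, b) meyer_nu((x - a) / (b - a))

# Shear bump g with sum_k g(u - k)^2 = 1 for all u.
shear_bump <- function(u) {
  out <- numeric(length(u))
  inside <- abs(u) < 1
  out[inside] <- cos(pi / 2 * meyer_nu(abs(u[inside])))
  out
}

# FFT frequencies in cycles/sample, Nyquist mapped to +1/2.
fft_freqs <- function(n) {
  f <- (seq_len(n) - 1) / n
  f[f > 0.5] <- f[f > 0.5] - 1
  f[abs(f + 0.5) < 1e-12] <- 0.5
  f
}

#' Build a shearlet system
#'
#' @param size Integer vector `c(height, width)`; both must be at least 16.
#' @param n_scales Number of dyadic scales (>= 1). Default 3.
#' @return An object of class `shearlet_system` with fields `size`,
#'   `n_scales`, `shears_per_scale` (total shear directions per scale, both
#'   cones), `filters` (list of frequency-domain windows, first entry the
#'   lowpass), `band_info` (tibble: band, scale, cone, shear), and
#'   `scale_energy` (per-scale sums of squared filters, used by the fast
#'   enhancement path).
#' @export
build_shearlet_system <- function(size, n_scales = 3) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 16L)) {
    stop("grid must be at least 16 x 16", call. = FALSE)
  }
  n_scales <- as.integer(n_scales)
  if (n_scales < 1L) stop("n_scales must be >= 1", call. = FALSE)
  # top radial boundary 0.8 cycles/sample-pair; each coarser boundary halves.
  top <- 0.8
  bounds <- top * 2^(seq_len(n_scales) - n_scales)
  if (bounds[1] / 2 < 2 / min(size)) {
    stop("grid too small for the requested number of scales", call. = FALSE)
  }

  f1 <- fft_freqs(size[1])  # row frequencies
  f2 <- fft_freqs(size[2])  # column frequencies
  F1 <- matrix(f1, size[1], size[2], byrow = FALSE)
  F2 <- matrix(f2, size[1], size[2], byrow = TRUE)
  rho <- sqrt(F1^2 + F2^2)

  # cumulative radial steps; telescoping makes squared magnitudes sum to 1
  U <- lapply(bounds, function(b) meyer_step(rho, b / 2, b))
  radial_sq <- vector("list", n_scales + 1L)
  radial_sq[[1]] <- 1 - U[[1]]                      # lowpass
  for (j in seq_len(n_scales)) {
    radial_sq[[j + 1]] <- if (j < n_scales) U[[j]] - U[[j + 1]] else U[[j]]
  }

  # cone partition: horizontal cone = column frequency dominant (ties included)
  cone_h <- abs(F2) >= abs(F1)
  slope_h <- ifelse(cone_h & F2 != 0, F1 / F2, 0)
  slope_v <- ifelse(!cone_h & F1 != 0, F2 / F1, 0)

  filters <- list(sqrt(pmax(radial_sq[[1]], 0)))
  info <- list(tibble::tibble(band = 1L, scale = 0L, cone = "low", shear = NA_integer_))
  scale_energy <- vector("list", n_scales + 1L)
  scale_energy[[1]] <- radial_sq[[1]]

  b <- 1L
  for (j in seq_len(n_scales)) {
    s_max <- 2^j
    r <- sqrt(pmax(radial_sq[[j + 1]], 0))
    energy <- matrix(0, size[1], size[2])
    for (cone in c("h", "v")) {
      in_cone <- if (cone == "h") cone_h else !cone_h
      slope <- if (cone == "h") slope_h else slope_v
      for (k in -s_max:s_max) {
        ang <- shear_bump(s_max * slope - k)
        ang[!in_cone] <- 0
        w <- r * ang
        b <- b + 1L
        filters[[b]] <- w
        info[[b]] <- tibble::tibble(band = b, scale = j, cone = cone, shear = k)
        energy <- energy + w^2
      }
    }
    scale_energy[[j + 1]] <- energy
  }

  structure(
    list(
      size = size, n_scales = n_scales,
      shears_per_scale = 2L * (2L * 2^seq_len(n_scales) + 1L),
      filters = filters,
      band_info = dplyr::bind_rows(info),
      scale_energy = scale_energy
    ),
    class = "shearlet_system"
  )
}

#' @export
print.shearlet_system <- function(x, ...) {
  cat(sprintf("<shearlet_system> %d x %d, %d scales, %d bands (+ lowpass)\n",
              x$size[1], x$size[2], x$n_scales, length(x$filters) - 1L))
  invisible(x)
}

# Session cache: systems are deterministic in (size, n_scales).
.shearlet_cache <- new.env(parent = emptyenv())

shearlet_system_cached <- function(size, n_scales) {
  key <- paste(size[1], size[2], n_scales, sep = "x")
  if (is.null(.shearlet_cache[[key]])) {
    .shearlet_cache[[key]] <- build_shearlet_system(size, n_scales)
  }
  .shearlet_cache[[key]]
}

#' Forward shearlet transform
#'
#' Frequency-domain multiplication by each band filter. The lowpass and the
#' unsheared (`k = 0`) bands are real for real input; sheared bands are
#' complex-valued, with the bands at `+k` and `-k` forming conjugate mirrors
#' (their filters are reflections of each other in frequency). Use `Mod()`
#' for magnitude displays.
#'
#' @param x Numeric matrix (or [gray_image()]).
#' @param sys A [build_shearlet_system()] system of matching size.
#' @return List of (complex) coefficient matrices, one per band
#'   (first = lowpass).
#' @export
shearlet_forward <- function(x, sys) {
  if (is_gray_image(x)) x <- x$pixels
  if (!all(dim(x) == sys$size)) stop("image/system size mismatch", call. = FALSE)
  X <- stats::fft(x)
  n <- length(x)
  lapply(sys$filters, function(w) stats::fft(X * w, inverse = TRUE) / n)
}

#' Inverse shearlet transform
#'
#' @param coeffs List of band coefficient matrices from [shearlet_forward()].
#' @param sys The matching system.
#' @return Reconstructed numeric matrix.
#' @export
shearlet_reconstruct <- function(coeffs, sys) {
  stopifnot(length(coeffs) == length(sys$filters))
  n <- prod(sys$size)
  acc <- matrix(0 + 0i, sys$size[1], sys$size[2])
  for (b in seq_along(coeffs)) {
    acc <- acc + stats::fft(coeffs[[b]]) * sys$filters[[b]]
  }
  Re(stats::fft(acc, inverse = TRUE)) / n
}

#' Enhancement parameters
#'
#' @param gain Multiplier (>= 1) applied to band coefficients at the amplified
#'   scales. Default 1.5, which sharpens edges without overflowing 8-bit range
#'   in practice (output is clipped regardless when `clip` is set).
#' @param scales_amplified Integer vector of scale indices to amplify
#'   (1 = coarsest). Default: the finest two scales.
#' @param clip Clip the enhanced image to `[0, max_value]`. Default TRUE.
#' @return An object of class `enhance_params`.
#' @export
enhance_params <- function(gain = 1.5, scales_amplified = NULL, clip = TRUE) {
  if (gain < 1) stop("gain must be >= 1", call. = FALSE)
  structure(list(gain = gain, scales_amplified = scales_amplified, clip = clip),
            class = "enhance_params")
}

#' Shearlet-domain image enhancement
#'
#' Forward transform, multiply the band coefficients of the selected scales by
#' `gain` (the lowpass is never touched), inverse transform. Because forward
#' and inverse are diagonal in frequency, the whole operation collapses to a
#' single frequency-domain multiplier built from the per-scale energies; the
#' result is identical to the explicit band-by-band route.
#'
#' @param img A [gray_image()] whose dimensions match `sys$size`.
#' @param sys A [build_shearlet_system()] system.
#' @param params An [enhance_params()] object.
#' @return With `clip = TRUE` (default), a [gray_image()] rounded and clipped
#'   to `[0, max_value]`; with `clip = FALSE`, the raw (unrounded, unclipped)
#'   numeric matrix, useful for inspecting the enhancement itself.
#' @export
shearlet_enhance <- function(img, sys, params = enhance_params()) {
  assert_gray_image(img)
  if (!all(dim(img$pixels) == sys$size)) {
    stop("image dimensions do not match the shearlet system", call. = FALSE)
  }
  amp <- params$scales_amplified
  if (is.null(amp)) amp <- seq.int(max(1L, sys$n_scales - 1L), sys$n_scales)
  mult <- sys$scale_energy[[1]]
  for (j in seq_len(sys$n_scales)) {
    g <- if (j %in% amp) params$gain else 1
    mult <- mult + g * sys$scale_energy[[j + 1]]
  }
  out <- Re(stats::fft(stats::fft(img$pixels) * mult, inverse = TRUE)) /
    length(img$pixels)
  if (!isTRUE(params$clip)) return(out)
  gray_image(pmin(pmax(round(out), 0), img$max_value), img$max_value)
}
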