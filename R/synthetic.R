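#' Phantom generator parameters
#'
#' Controls the mammogram-like phantom: a half-ellipse breast on a dark
#' background filled with a smooth correlated texture, an optional bright
#' pectoral wedge at the top-left corner, and — for the abnormal class — a
#' radially decaying bright lesion carrying finer internal texture, radial
#' spicules and microcalcification specks.
#'
#' Defaults define the package's reference study conditions: 224 x 224 8-bit
#' frames, lesion radius 15-30 px, intensity contrast 60 (a clearly visible
#' mass), background correlation length 12 px versus 4 px inside the lesion
#' (masses are finer-textured than surrounding parenchyma), additive Gaussian
#' noise of SD 8, no pectoral wedge.
#'
#' @param size `c(height, width)`. Default `c(224, 224)`.
#' @param lesion_radius Range (min, max) of lesion radii in pixels.
#' @param lesion_contrast Peak intensity offset of the lesion above the local
#'   background; 0 makes the two classes identical (null-effect runs).
#' @param spicule_count Number of radial ridges around the lesion.
#' @param calc_count Number of 1-2 px bright microcalcification specks.
#' @param bg_corr_len,lesion_corr_len Gaussian-field correlation lengths (px).
#' @param noise_sd Additive Gaussian pixel noise SD.
#' @param pectoral Add a bright top-corner wedge. Default FALSE.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(size = c(224, 224), lesion_radius = c(22, 40),
                           lesion_contrast = 60, spicule_count = 6,
                           calc_count = 8, bg_corr_len = 12,
                           lesion_corr_len = 3, noise_sd = 8,
                           pectoral = FALSE) {
  p <- list(size = as.integer(size), lesion_radius = as.numeric(lesion_radius),
            lesion_contrast = as.numeric(lesion_contrast),
            spicule_count = as.integer(spicule_count),
            calc_count = as.integer(calc_count),
            bg_corr_len = as.numeric(bg_corr_len),
            lesion_corr_len = as.numeric(lesion_corr_len),
            noise_sd = as.numeric(noise_sd), pectoral = isTRUE(pectoral))
  if (any(p$lesion_radius <= 0) || p$lesion_radius[1] > p$lesion_radius[2]) {
    stop("lesion_radius must be a positive (min, max) range", call. = FALSE)
  }
  if (p$lesion_contrast < 0) stop("lesion_contrast must be >= 0", call. = FALSE)
  structure(p, class = "phantom_params")
}

# Smooth Gaussian random field via FFT filtering of white noise,
# standardised to zero mean / unit SD.
gaussian_field <- function(h, w, corr_len) {
  z <- matrix(stats::rnorm(h * w), h, w)
  f1 <- fft_freqs(h); f2 <- fft_freqs(w)
  K <- exp(-2 * pi^2 * corr_len^2 *
             (matrix(f1^2, h, w) + matrix(f2^2, h, w, byrow = TRUE)))
  g <- Re(stats::fft(stats::fft(z) * K, inverse = TRUE)) / (h * w)
  (g - mean(g)) / stats::sd(g)
}

# Deterministic per-image seed derived from a dataset seed and an index
# (splitmix-style integer mixing, kept below 2^31).
derive_seed <- function(seed, index) {
  x <- (as.numeric(seed) * 2654435761 + as.numeric(index) * 40503 + 97) %%
    2147483629
  as.integer(x)
}

#' Generate one phantom
#'
#' Fully determined by `(params, label, seed)`.
#'
#' @param params A [phantom_params()].
#' @param label `"normal"` or `"abnormal"`.
#' @param seed Integer seed.
#' @return List with `image` (a [gray_image()]) and `truth` (list: `label`,
#'   `lesion_center` (row, col), `lesion_radius`, `lesion_mask`,
#'   `pectoral_mask`; geometry fields are NULL for normal phantoms).
#' @export
generate_phantom <- function(params = phantom_params(), label = "normal",
                             seed = 1) {
  stopifnot(inherits(params, "phantom_params"), label %in% c("normal", "abnormal"))
  h <- params$size[1]; w <- params$size[2]
  withr::with_seed(seed, {
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    # half-ellipse breast anchored on the left edge
    cy <- h / 2
    breast <- ((rows - cy) / (0.46 * h))^2 + (cols / (0.82 * w))^2 <= 1

    img <- matrix(3, h, w)
    bg <- gaussian_field(h, w, params$bg_corr_len)
    # bright glandular patches give normal parenchyma a realistic high-
    # intensity tail, so both classes span a comparable raw dynamic range
    gland <- pmax(gaussian_field(h, w, 1.5 * params$bg_corr_len), 0)
    # skin-line taper: compressed breast tissue thins toward the boundary,
    # so intensity falls off smoothly over ~12% of the ellipse radius
    # rather than stepping to the background
    e <- sqrt(((rows - cy) / (0.46 * h))^2 + (cols / (0.82 * w))^2)
    taper <- pmin(1, pmax(0, (1 - e) / 0.12))
    img[breast] <- 3 + (105 + 22 * bg[breast] + 30 * gland[breast]^2) *
      taper[breast]
    # pixel noise is drawn before any lesion geometry so that, at zero lesion
    # contrast with no spicules/calcs, normal and abnormal phantoms sharing a
    # seed are bitwise identical (exact null)
    noise <- if (params$noise_sd > 0) {
      matrix(stats::rnorm(h * w, sd = params$noise_sd), h, w)
    } else {
      matrix(0, h, w)
    }

    pect <- matrix(0L, h, w)
    if (params$pectoral) {
      # dense pectoral muscle: a bright triangle anchored at the top-left
      # image corner, overlapping the breast so it joins its foreground
      # component (as in medio-lateral views)
      wedge <- rows < 0.30 * h & cols < (0.30 * h - rows) * 1.1
      img[wedge] <- 205 + 6 * bg[wedge]
      pect[wedge] <- 1L
    }

    truth <- list(label = label, lesion_center = NULL, lesion_radius = NULL,
                  lesion_mask = NULL, pectoral_mask = pect)

    if (label == "abnormal" && params$lesion_contrast >= 0) {
      r <- stats::runif(1, params$lesion_radius[1], params$lesion_radius[2])
      # sample a centre whose whole disk (plus spicule reach) fits the breast
      margin <- 2.1 * r + 3
      ok <- breast &
        ((rows - cy) / (0.46 * h - margin))^2 +
        (cols / (0.82 * w - margin))^2 <= 1 &
        rows > margin & rows < h - margin & cols < w - margin &
        cols > r + 2  # fully visible: no clipping at the chest-wall edge
      if (params$pectoral) ok <- ok & rows > 0.35 * h
      # keep masses out of saturated glandular islands, where an additive
      # bump would clip at the detector shoulder and become invisible
      ok <- ok & img <= 175
      if (!any(ok)) stop("lesion cannot fit inside the breast mask", call. = FALSE)
      pick <- which(ok)[sample.int(sum(ok), 1)]
      cr <- rows[pick]; cc <- cols[pick]
      d <- sqrt((rows - cr)^2 + (cols - cc)^2)
      delta <- params$lesion_contrast

      # flat-top radial profile: full contrast to 0.6 r, smooth decay to r
      prof <- ifelse(d <= 0.6 * r, 1,
                     ifelse(d <= r, cos(pi / 2 * (d - 0.6 * r) / (0.4 * r))^2, 0))
      img <- img + delta * prof

      # finer internal texture (amplitude tied to the contrast so it vanishes
      # in null-effect runs) distinguishes the lesion's co-occurrence
      # structure from the smoother background
      lm <- d <= r
      fine <- gaussian_field(h, w, params$lesion_corr_len)
      img[lm] <- img[lm] + 0.5 * delta * fine[lm]

      if (params$spicule_count > 0) {
        theta <- stats::runif(1, 0, 2 * pi) +
          seq(0, 2 * pi, length.out = params$spicule_count + 1)[-1]
        for (t in theta) {
          s <- seq(r * 0.8, r * 1.9, by = 0.5)
          pr <- round(cr + s * sin(t)); pc <- round(cc + s * cos(t))
          keep <- pr >= 1 & pr <= h & pc >= 1 & pc <= w
          idx <- cbind(pr[keep], pc[keep])
          img[idx] <- img[idx] + delta * 0.45 *
            exp(-(s[keep] - r * 0.8) / (0.6 * r))
        }
      }
      if (params$calc_count > 0) {
        ang <- stats::runif(params$calc_count, 0, 2 * pi)
        rad <- stats::runif(params$calc_count, 0, 0.85 * r)
        pr <- pmin(pmax(round(cr + rad * sin(ang)), 2), h - 1)
        pc <- pmin(pmax(round(cc + rad * cos(ang)), 2), w - 1)
        for (k in seq_len(params$calc_count)) {
          # specks are bright relative to their local surround (not an
          # absolute ceiling) so they do not inflate the global range
          img[pr[k] + (-1:0), pc[k] + (-1:0)] <-
            img[pr[k] + (-1:0), pc[k] + (-1:0)] + 0.5 * delta
        }
      }
      truth$lesion_center <- c(row = cr - 1, col = cc - 1)  # 0-based
      truth$lesion_radius <- r
      truth$lesion_mask <- lm * 1L
    }

    # detector-saturation shoulder: structural intensities cap at 235, so
    # every phantom spans the same raw dynamic range (noise tails reach 255)
    # and downstream contrast stretching has a stable gain across the corpus
    img <- pmin(img, 235)
    img <- pmin(pmax(round(img + noise), 0), 255)
    list(image = gray_image(img, 255), truth = truth)
  })
}

#' Generate a balanced labelled phantom dataset
#'
#' `2 * n_per_class` phantoms, alternating normal/abnormal, each drawn with a
#' per-image seed derived deterministically from `seed` and the image index,
#' so any subset is reproducible independently of generation order.
#'
#' @param params A [phantom_params()].
#' @param n_per_class Images per class.
#' @param seed Dataset seed.
#' @return List with `dataset` (a [mammo_dataset()]), `truths` (list of truth
#'   records) and `manifest` (tibble: id, label, seed, lesion geometry).
#' @export
generate_dataset <- function(params = phantom_params(), n_per_class = 50,
                             seed = 1) {
  stopifnot(n_per_class >= 1)
  n <- 2L * as.integer(n_per_class)
  labels <- rep(c("normal", "abnormal"), length.out = n)
  seeds <- vapply(seq_len(n), function(i) derive_seed(seed, i), 1L)
  out <- purrr::map2(labels, seeds, function(lb, sd) {
    generate_phantom(params, lb, sd)
  })
  images <- purrr::map(out, "image")
  truths <- purrr::map(out, "truth")
  ids <- sprintf("phantom%04d", seq_len(n))
  manifest <- tibble::tibble(
    id = ids, label = labels, seed = seeds,
    center_row = purrr::map_dbl(truths, ~ .x$lesion_center["row"] %||% NA_real_),
    center_col = purrr::map_dbl(truths, ~ .x$lesion_center["col"] %||% NA_real_),
    radius = purrr::map_dbl(truths, ~ .x$lesion_radius %||% NA_real_)
  )
  list(dataset = mammo_dataset(images, labels, ids), truths = truths,
       manifest = manifest)
}
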