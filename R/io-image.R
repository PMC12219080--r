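#' Grayscale image container
#'
#' The unit every pipeline stage transforms: a 2D intensity raster stored as a
#' numeric matrix with row 1 at the top of the image, plus the maximum
#' representable intensity (`255` for the 8-bit dynamics the whole pipeline is
#' specified for). Intensities may be non-integral between stages (e.g. after
#' bilinear resizing); they are rounded on write.
#'
#' @param pixels Numeric matrix of intensities, row-major top-down.
#' @param max_value Maximum representable intensity. Default 255.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, max_value = 255) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have height >= 1 and width >= 1", call. = FALSE)
  }
  if (anyNA(pixels)) stop("image intensities must not be NA", call. = FALSE)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > max_value) {
    stop(sprintf("intensities must lie in [0, %s]", max_value), call. = FALSE)
  }
  structure(
    list(pixels = pixels, max_value = as.numeric(max_value)),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d, max_value %g, intensity range [%.6g, %.6g]\n",
    nrow(x$pixels), ncol(x$pixels), x$max_value,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
as.matrix.gray_image <- function(x, ...) x$pixels

is_gray_image <- function(x) inherits(x, "gray_image")

assert_gray_image <- function(img) {
  if (!is_gray_image(img)) stop("expected a `gray_image`", call. = FALSE)
  invisible(img)
}

# --- PGM ---------------------------------------------------------------------

# Pulls whitespace-separated header tokens from a PGM byte stream, skipping
# '#' comment lines, and returns the token values plus the offset of the first
# pixel byte (needed for the binary P5 payload).
pgm_header_tokens <- function(raw, n_tokens) {
  tokens <- character(0)
  i <- 1L
  n <- length(raw)
  while (length(tokens) < n_tokens && i <= n) {
    ch <- rawToChar(raw[i])
    if (ch == "#") {
      while (i <= n && !rawToChar(raw[i]) %in% c("\n", "\r")) i <- i + 1L
    } else if (grepl("[[:space:]]", ch)) {
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !grepl("[[:space:]]", rawToChar(raw[j])) &&
             rawToChar(raw[j]) != "#") {
        j <- j + 1L
      }
      tokens <- c(tokens, rawToChar(raw[i:(j - 1L)]))
      i <- j
    }
  }
  if (length(tokens) < n_tokens) {
    stop("malformed PGM header: ran out of tokens", call. = FALSE)
  }
  # consume exactly one whitespace byte after the last header token (P5 rule)
  list(tokens = tokens, offset = i + 1L)
}

#' Read a PGM image
#'
#' Accepts both the ASCII (`P2`) and binary (`P5`) dialects; `#` comment lines
#' are skipped anywhere in the header. Samples with `maxval > 255` (16-bit
#' PGM) are rescaled to `[0, 255]` on load, since every downstream stage is
#' specified for 8-bit dynamics.
#'
#' @param path Path to a `.pgm` file.
#' @return A [gray_image()].
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P5")) {
    stop(sprintf("malformed PGM header: magic token '%s'", magic), call. = FALSE)
  }
  hdr <- pgm_header_tokens(raw[-(1:2)], 3L)
  dims <- suppressWarnings(as.integer(hdr$tokens))
  if (anyNA(dims)) {
    bad <- hdr$tokens[is.na(dims)][1]
    stop(sprintf("malformed PGM header: token '%s'", bad), call. = FALSE)
  }
  width <- dims[1]; height <- dims[2]; maxval <- dims[3]
  if (width < 1L || height < 1L || maxval < 1L) {
    stop("malformed PGM header: non-positive dimension or maxval", call. = FALSE)
  }
  n_px <- width * height
  if (magic == "P2") {
    rest <- raw[-(1:2)]
    body <- rawToChar(rest[min(hdr$offset, length(rest)):length(rest)])
    body <- gsub("#[^\n]*", "", body)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "[[:space:]]+")[[1]]))
    vals <- vals[!is.na(vals)]
    if (length(vals) < n_px) {
      stop(sprintf("truncated PGM pixel data: expected %d values, found %d",
                   n_px, length(vals)), call. = FALSE)
    }
    vals <- vals[seq_len(n_px)]
  } else {
    start <- 2L + hdr$offset
    bytes_per <- if (maxval > 255L) 2L else 1L
    need <- n_px * bytes_per
    avail <- length(raw) - start + 1L
    if (avail < need) {
      stop(sprintf("truncated PGM pixel data: expected %d bytes, found %d",
                   need, avail), call. = FALSE)
    }
    payload <- raw[start:(start + need - 1L)]
    if (bytes_per == 1L) {
      vals <- as.integer(payload)
    } else {
      # big-endian 16-bit samples, per the PGM standard
      m <- matrix(as.integer(payload), nrow = 2L)
      vals <- m[1, ] * 256L + m[2, ]
    }
  }
  if (maxval > 255L) {
    vals <- round(vals * 255 / maxval)
    maxval <- 255L
  }
  px <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  gray_image(px, max_value = maxval)
}

#' Write a grayscale image to PGM or PNG
#'
#' Intensities are rounded to integers before writing; both formats round-trip
#' losslessly through [read_pgm()] / a PNG reader. PGM output uses the binary
#' `P5` dialect.
#'
#' @param img A [gray_image()].
#' @param path Output path.
#' @param format `"pgm"` or `"png"`. Default guesses from the file extension,
#'   falling back to PGM.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, format = c("auto", "pgm", "png")) {
  assert_gray_image(img)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.png$", path, ignore.case = TRUE)) "png" else "pgm"
  }
  px <- round(img$pixels)
  mx <- round(img$max_value)
  if (format == "pgm") {
    con <- tryCatch(file(path, "wb"), error = function(e) {
      stop("cannot open for writing: ", path, call. = FALSE)
    })
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", ncol(px), nrow(px), mx),
              con, eos = NULL)
    writeBin(as.raw(as.integer(t(px))), con)
  } else {
    png::writePNG(px / mx, target = path)
  }
  invisible(path)
}

#' Read a PNG image as grayscale
#'
#' Multi-channel PNGs are collapsed to luminance by channel averaging.
#'
#' @param path Path to a `.png` file.
#' @param max_value Intensity scale of the returned image. Default 255.
#' @return A [gray_image()].
#' @export
read_png_gray <- function(path, max_value = 255) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:min(3L, dim(arr)[3]), drop = FALSE], c(1, 2), mean)
  gray_image(round(arr * max_value), max_value = max_value)
}
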