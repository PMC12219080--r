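#' Parse MIAS-style annotation text
#'
#' The MIAS info file is plain text with one whitespace-separated record per
#' line: reference id, background-tissue code (`F` fatty, `G` fatty-glandular,
#' `D` dense-glandular), abnormality class (`NORM`, `CALC`, `CIRC`, `SPIC`,
#' `MISC`, `ARCH`, `ASYM`), and — for non-normal records — a severity code
#' (`B` benign, `M` malignant) and lesion centre x, y plus approximate radius
#' in pixels. `NORM` lines carry no severity and no geometry; lines whose
#' geometry field is a `*NOTE*` marker or otherwise non-numeric keep their
#' id/tissue/abnormality with missing geometry.
#'
#' MIAS lesion coordinates use a bottom-left origin; they are converted to
#' this package's (row, col) top-left 0-based convention via
#' [mias_center_to_rowcol()], which needs the image height.
#'
#' @param text A character scalar (file contents) or vector of lines.
#' @return A tibble with one row per non-empty line: `ref_id`, `tissue`,
#'   `abnormality`, `severity` (`NA` for `NORM`), `center_x`, `center_y`,
#'   `radius` (all `NA` when absent).
#' @export
parse_mias_info <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
  keep <- which(nzchar(trimws(lines)))
  tissues <- c("F", "G", "D")
  abns <- c("NORM", "CALC", "CIRC", "SPIC", "MISC", "ARCH", "ASYM")

  recs <- lapply(keep, function(ln) {
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (length(tok) < 3L) {
      stop(sprintf("line %d: expected at least id, tissue, abnormality", ln),
           call. = FALSE)
    }
    if (!tok[2] %in% tissues) {
      stop(sprintf("line %d: unknown tissue code '%s'", ln, tok[2]),
           call. = FALSE)
    }
    if (!tok[3] %in% abns) {
      stop(sprintf("line %d: unknown abnormality code '%s'", ln, tok[3]),
           call. = FALSE)
    }
    severity <- NA_character_
    geom <- rep(NA_real_, 3)
    if (tok[3] != "NORM" && length(tok) >= 4L) {
      if (tok[4] %in% c("B", "M")) severity <- tok[4]
      if (length(tok) >= 7L) {
        g <- suppressWarnings(as.numeric(tok[5:7]))
        if (!anyNA(g)) geom <- g
      }
    }
    tibble::tibble(
      ref_id = tok[1], tissue = tok[2], abnormality = tok[3],
      severity = severity,
      center_x = geom[1], center_y = geom[2], radius = geom[3]
    )
  })
  dplyr::bind_rows(recs)
}

#' Read a MIAS annotation file
#'
#' @param path Path to the info text file.
#' @return See [parse_mias_info()].
#' @export
read_mias_info <- function(path) {
  parse_mias_info(readLines(path, warn = FALSE))
}

#' Convert MIAS lesion coordinates to (row, col)
#'
#' MIAS annotates lesion centres with a bottom-left image origin; this package
#' indexes pixels as (row, col), 0-based, row 0 at the top.
#'
#' @param center_x,center_y MIAS coordinates.
#' @param height Image height in pixels.
#' @return A list with `row` and `col` (0-based).
#' @export
mias_center_to_rowcol <- function(center_x, center_y, height) {
  list(row = height - 1 - center_y, col = center_x)
}

#' Two-class label for a MIAS record
#'
#' `NORM` maps to `"normal"`, every abnormality class to `"abnormal"`,
#' matching the pipeline's two-class framing.
#'
#' @param abnormality Character vector of abnormality codes.
#' @return Character vector of `"normal"` / `"abnormal"`.
#' @export
mias_label <- function(abnormality) {
  ifelse(abnormality == "NORM", "normal", "abnormal")
}

# --- labelled dataset --------------------------------------------------------

#' Labelled image dataset
#'
#' A parallel collection of images, two-class labels and ids.
#'
#' @param images List of [gray_image()] objects.
#' @param labels Character vector in `{"normal", "abnormal"}`.
#' @param ids Character vector of identifiers.
#' @return An object of class `mammo_dataset`.
#' @export
mammo_dataset <- function(images, labels, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("img%04d", seq_along(images))
  stopifnot(length(images) == length(labels), length(labels) == length(ids))
  if (!all(labels %in% c("normal", "abnormal"))) {
    stop("labels must be 'normal' or 'abnormal'", call. = FALSE)
  }
  lapply(images, assert_gray_image)
  structure(list(images = images, labels = labels, ids = ids),
            class = "mammo_dataset")
}

#' @export
length.mammo_dataset <- function(x) length(x$images)

#' @export
print.mammo_dataset <- function(x, ...) {
  cat(sprintf("<mammo_dataset> %d images (%d normal, %d abnormal)\n",
              length(x$images), sum(x$labels == "normal"),
              sum(x$labels == "abnormal")))
  invisible(x)
}

#' Dataset manifest
#'
#' @param data A [mammo_dataset()].
#' @param paths Optional character vector of image paths.
#' @return A tibble with columns `id`, `path`, `label`.
#' @export
dataset_manifest <- function(data, paths = NA_character_) {
  tibble::tibble(id = data$ids, path = paths, label = data$labels)
}

#' Assemble a labelled dataset from a MIAS annotation table
#'
#' @param info Tibble from [read_mias_info()].
#' @param image_dir Directory containing `<ref_id>.pgm` files.
#' @return A [mammo_dataset()].
#' @export
load_mias_dataset <- function(info, image_dir) {
  paths <- file.path(image_dir, paste0(info$ref_id, ".pgm"))
  ok <- file.exists(paths)
  if (!any(ok)) stop("no images found under ", image_dir, call. = FALSE)
  mammo_dataset(
    images = lapply(paths[ok], read_pgm),
    labels = mias_label(info$abnormality[ok]),
    ids = info$ref_id[ok]
  )
}
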