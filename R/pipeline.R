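#' Pipeline configuration
#'
#' One nested configuration drives every stage. Defaults reproduce the
#' package's reference conditions: 224 x 224 working resolution, 3-scale
#' shearlet enhancement with gain 1.5 on the finest two scales,
#' variance-weighted Otsu (`alpha` 1, window 15), Canny at 0.1/0.3 of the
#' peak gradient with `sigma` 1.4, ROI padding 8 px, 32-level quantisation,
#' symmetric GLCM, a channel-scale 0.125 classifier with 49-feature fusion,
#' and Adam training (learning rate 0.001, batch 32, 12 epochs).
#'
#' Unknown keys are rejected by name, so typos fail loudly instead of being
#' silently ignored.
#'
#' @param ... Overrides as nested lists, e.g. `otsu = list(alpha = 0.5)`.
#' @return A validated config object (class `pipeline_config`).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 0L,
    stages = c("contrast", "median", "shearlet", "otsu", "canny"),
    preprocess = list(target = c(224L, 224L), n_scales = 3L, gain = 1.5,
                      scales_amplified = NULL),
    otsu = list(alpha = 1, window = 15L),
    canny = list(low = 0.1, high = 0.3, sigma = 1.4),
    roi = list(pad = 8L),
    pectoral = list(remove = FALSE),
    features = list(ng = 32L, symmetric_glcm = TRUE),
    model = list(channel_scale = 0.125, fusion = TRUE,
                 bilstm_hidden_total = 128L, dense_units = 128L,
                 dropout_conv = 0.25, dropout_lstm = 0.5),
    train = list(learning_rate = 0.001, batch_size = 32L, epochs = 12L),
    simulate = list(n_per_class = 50L, size = c(224L, 224L),
                    lesion_radius = c(22, 40), lesion_contrast = 60,
                    spicule_count = 6L, calc_count = 8L, bg_corr_len = 12,
                    lesion_corr_len = 3, noise_sd = 8, pectoral = FALSE),
    evaluate = list(k = 5L)
  )
  overrides <- list(...)
  merged <- merge_config(defaults, overrides, path = character(0))
  structure(merged, class = "pipeline_config")
}

merge_config <- function(defaults, overrides, path) {
  if (length(overrides) == 0) return(defaults)
  nms <- names(overrides)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("config overrides must be named", call. = FALSE)
  }
  for (nm in nms) {
    full <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(defaults)) {
      stop(sprintf("unknown config key '%s'", full), call. = FALSE)
    }
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(overrides[[nm]])) {
        stop(sprintf("config key '%s' must be a list", full), call. = FALSE)
      }
      defaults[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]],
                                     c(path, nm))
    } else {
      defaults[nm] <- overrides[nm]  # keeps NULL assignments intact
    }
  }
  defaults
}

resolve_config <- function(config) {
  if (is.null(config)) return(pipeline_config())
  if (inherits(config, "pipeline_config")) return(config)
  if (is.list(config)) return(do.call(pipeline_config, config))
  stop("config must be NULL, a pipeline_config, or a named list", call. = FALSE)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  resolve_config(raw %||% list())
}

#' Configuration fingerprint
#'
#' Stable non-cryptographic hash (FNV-1a over the deparsed, name-sorted
#' configuration), logged with every artifact so a run can be matched to the
#' exact configuration that produced it.
#'
#' @param config A [pipeline_config()].
#' @return An 8-hex-digit character scalar.
#' @export
config_hash <- function(config) {
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte touches only the low 8 bits
    h <- (h - h %% 256) + bitwXor(h %% 256, b)
    # exact 32-bit modular multiply by the FNV prime, split to stay
    # within double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- ((lo * 16777619) + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_model_spec <- function(config) {
  m <- config$model
  bilstm_cnn_spec(
    input_size = config$preprocess$target[1],
    channel_scale = m$channel_scale,
    fusion_dim = if (isTRUE(m$fusion)) length(hybrid_feature_names()) else 0L,
    bilstm_hidden_total = m$bilstm_hidden_total,
    dense_units = m$dense_units,
    dropout_conv = m$dropout_conv,
    dropout_lstm = m$dropout_lstm
  )
}

config_train_config <- function(config, seed = NULL) {
  t <- config$train
  train_config(t$learning_rate, t$batch_size, t$epochs,
               seed = seed %||% config$seed)
}

config_phantom_params <- function(config) {
  s <- config$simulate
  phantom_params(size = s$size, lesion_radius = s$lesion_radius,
                 lesion_contrast = s$lesion_contrast,
                 spicule_count = s$spicule_count, calc_count = s$calc_count,
                 bg_corr_len = s$bg_corr_len,
                 lesion_corr_len = s$lesion_corr_len, noise_sd = s$noise_sd,
                 pectoral = s$pectoral)
}

#' Preprocess + segment + describe one image
#'
#' The feature path used everywhere: preprocessing stages from
#' `config$stages`, optional pectoral removal, Otsu/Canny ROI localisation
#' (falling back to the full frame when both are disabled), then the
#' 49-element hybrid descriptor on the ROI crop.
#'
#' @param img A [gray_image()].
#' @param config A [pipeline_config()].
#' @return Named numeric feature vector of length 49.
#' @export
pipeline_features <- function(img, config = NULL) {
  config <- resolve_config(config)
  stages <- config$stages
  pre <- preprocess_image(
    img, target = config$preprocess$target,
    stages = intersect(stages, c("contrast", "median", "shearlet")),
    n_scales = config$preprocess$n_scales, gain = config$preprocess$gain,
    scales_amplified = config$preprocess$scales_amplified
  )
  if (isTRUE(config$pectoral$remove)) {
    cropped <- tryCatch(crop_breast_region(pre, remove_pectoral = TRUE),
                        error = function(e) NULL)
    if (!is.null(cropped)) {
      pre$pixels[cropped$pectoral_mask == 1L] <- 0
    }
  }
  zero <- matrix(0L, nrow(pre$pixels), ncol(pre$pixels))
  mask <- if ("otsu" %in% stages) {
    improved_otsu_threshold(pre, config$otsu$alpha, config$otsu$window)$mask
  } else {
    zero
  }
  edges <- if ("canny" %in% stages) {
    canny_edges(pre, config$canny$low, config$canny$high, config$canny$sigma)
  } else {
    zero
  }
  crop <- if (any(mask != 0) || any(edges != 0)) {
    extract_roi(pre, mask, edges, pad = config$roi$pad)$image
  } else {
    pre
  }
  assemble_hybrid(crop, Ng = config$features$ng,
                  symmetric = config$features$symmetric_glcm)
}

write_config_snapshot <- function(config, out_dir) {
  snap <- file.path(out_dir, "config.yaml")
  cfg <- unclass(config)
  yaml::write_yaml(cfg, snap)
  writeLines(config_hash(config), file.path(out_dir, "config.hash"))
  snap
}

read_manifest_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  images <- lapply(file.path(dir, manifest$path), read_pgm)
  mammo_dataset(images, manifest$label, manifest$id)
}

#' Run a pipeline stage
#'
#' Orchestrates the package's stages as named commands over one configuration
#' and an output directory; every stage writes its artifacts plus the
#' resolved config snapshot and hash.
#'
#' * `simulate` — generate a phantom dataset (PGM images + `manifest.csv`)
#' * `preprocess` — preprocess the input dataset, writing enhanced PGMs
#' * `segment` — write Otsu/Canny masks and ROI boxes (`rois.csv`)
#' * `features` — write the hybrid feature table (`features.csv`)
#' * `train` — fit the classifier on all input images (`model.rds`,
#'   `training_log.csv`)
#' * `evaluate` — stratified cross-validation (`per_fold.csv`, `summary.csv`)
#' * `ablate` — preprocessing ablation grid (`ablation.csv`)
#' * `compare` — per-feature class comparison (`feature_comparison.csv`)
#'
#' @param cmd One of the commands above.
#' @param config A [pipeline_config()], named list, or NULL.
#' @param input Input directory (a previous stage's output) for commands that
#'   consume a dataset; ignored by `simulate`.
#' @param output Output directory; created if missing.
#' @return Invisibly, a character vector of artifact paths.
#' @export
run_pipeline <- function(cmd = c("simulate", "preprocess", "segment",
                                 "features", "train", "evaluate", "ablate",
                                 "compare"),
                         config = NULL, input = NULL, output = "mammotex_out") {
  cmd <- match.arg(cmd)
  config <- resolve_config(config)
  dir.create(output, showWarnings = FALSE, recursive = TRUE)
  artifacts <- write_config_snapshot(config, output)

  need_input <- function() {
    if (is.null(input) || !file.exists(file.path(input, "manifest.csv"))) {
      stop("command '", cmd, "' needs an input directory with manifest.csv",
           call. = FALSE)
    }
    read_manifest_dataset(input)
  }

  if (cmd == "simulate") {
    gen <- generate_dataset(config_phantom_params(config),
                            config$simulate$n_per_class, config$seed)
    paths <- paste0(gen$dataset$ids, ".pgm")
    for (i in seq_along(paths)) {
      write_image(gen$dataset$images[[i]], file.path(output, paths[i]), "pgm")
    }
    manifest <- dplyr::mutate(gen$manifest, path = paths, .after = "id")
    mpath <- file.path(output, "manifest.csv")
    utils::write.csv(manifest, mpath, row.names = FALSE)
    artifacts <- c(artifacts, mpath, file.path(output, paths))
  } else if (cmd == "preprocess") {
    data <- need_input()
    stages <- intersect(config$stages, c("contrast", "median", "shearlet"))
    paths <- paste0(data$ids, "_pre.pgm")
    for (i in seq_along(data$images)) {
      pre <- preprocess_image(data$images[[i]], config$preprocess$target,
                              stages, config$preprocess$n_scales,
                              config$preprocess$gain,
                              config$preprocess$scales_amplified)
      write_image(pre, file.path(output, paths[i]), "pgm")
    }
    manifest <- tibble::tibble(id = data$ids, path = paths,
                               label = data$labels)
    mpath <- file.path(output, "manifest.csv")
    utils::write.csv(manifest, mpath, row.names = FALSE)
    artifacts <- c(artifacts, mpath, file.path(output, paths))
  } else if (cmd == "segment") {
    data <- need_input()
    rois <- list()
    for (i in seq_along(data$images)) {
      pre <- preprocess_image(data$images[[i]], config$preprocess$target,
                              intersect(config$stages,
                                        c("contrast", "median", "shearlet")),
                              config$preprocess$n_scales,
                              config$preprocess$gain,
                              config$preprocess$scales_amplified)
      ot <- improved_otsu_threshold(pre, config$otsu$alpha, config$otsu$window)
      ed <- canny_edges(pre, config$canny$low, config$canny$high,
                        config$canny$sigma)
      roi <- extract_roi(pre, ot$mask, ed, config$roi$pad)
      write_image(gray_image(ot$mask * 255, 255),
                  file.path(output, paste0(data$ids[i], "_mask.png")), "png")
      write_image(gray_image(ed * 255, 255),
                  file.path(output, paste0(data$ids[i], "_edges.png")), "png")
      rois[[i]] <- tibble::tibble(id = data$ids[i], threshold = ot$threshold,
                                  row_min = roi$box$row_min,
                                  row_max = roi$box$row_max,
                                  col_min = roi$box$col_min,
                                  col_max = roi$box$col_max)
    }
    rpath <- file.path(output, "rois.csv")
    utils::write.csv(dplyr::bind_rows(rois), rpath, row.names = FALSE)
    artifacts <- c(artifacts, rpath)
  } else if (cmd == "features") {
    data <- need_input()
    ft <- feature_table(data, config)
    fpath <- file.path(output, "features.csv")
    utils::write.csv(ft, fpath, row.names = FALSE)
    artifacts <- c(artifacts, fpath)
  } else if (cmd == "train") {
    data <- need_input()
    ft <- feature_table(data, config)
    x <- as.matrix(ft[, hybrid_feature_names()])
    scaler <- fit_feature_scaler(x)
    model <- train_model(build_model(config_model_spec(config)), data,
                         apply_feature_scaler(scaler, x),
                         config_train_config(config))
    mpath <- file.path(output, "model.rds")
    saveRDS(list(model = model, scaler = scaler), mpath)
    lpath <- file.path(output, "training_log.csv")
    utils::write.csv(model$history, lpath, row.names = FALSE)
    artifacts <- c(artifacts, mpath, lpath)
  } else if (cmd == "evaluate") {
    data <- need_input()
    cv <- crossvalidate(data, config, k = config$evaluate$k,
                        seed = config$seed)
    p1 <- file.path(output, "per_fold.csv")
    p2 <- file.path(output, "summary.csv")
    utils::write.csv(cv$per_fold, p1, row.names = FALSE)
    utils::write.csv(cv$summary, p2, row.names = FALSE)
    artifacts <- c(artifacts, p1, p2)
  } else if (cmd == "ablate") {
    data <- need_input()
    grid <- list(none = character(0), full = config$stages)
    ab <- run_ablation(grid, data, config, k = config$evaluate$k,
                       seed = config$seed)
    apath <- file.path(output, "ablation.csv")
    utils::write.csv(ab$table, apath, row.names = FALSE)
    artifacts <- c(artifacts, apath)
  } else if (cmd == "compare") {
    data <- need_input()
    ft <- feature_table(data, config)
    cmp <- compare_feature_groups(ft, data$labels, method = "welch",
                                  seed = config$seed)
    cpath <- file.path(output, "feature_comparison.csv")
    utils::write.csv(cmp, cpath, row.names = FALSE)
    artifacts <- c(artifacts, cpath)
  }
  invisible(artifacts)
}
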