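#' Confusion matrix with "abnormal" as the positive class
#'
#' @param truth,pred Character vectors in `{"normal", "abnormal"}`.
#' @param positive The positive class. Default `"abnormal"`.
#' @return An object of class `confusion_matrix` (fields `tp`, `tn`, `fp`,
#'   `fn`).
#' @export
confusion <- function(truth, pred, positive = "abnormal") {
  if (length(truth) != length(pred) || length(truth) < 1L) {
    stop("truth and pred must be equal-length, non-empty", call. = FALSE)
  }
  valid <- c("normal", "abnormal")
  if (!all(truth %in% valid) || !all(pred %in% valid)) {
    stop("labels must be 'normal' or 'abnormal'", call. = FALSE)
  }
  structure(list(
    tp = sum(truth == positive & pred == positive),
    tn = sum(truth != positive & pred != positive),
    fp = sum(truth != positive & pred == positive),
    fn = sum(truth == positive & pred != positive)
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp %d  fn %d  fp %d  tn %d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn)
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator), reporting 0", what),
            call. = FALSE)
    return(0)
  }
  num / den
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and their F1 harmonic mean. Ratios
#' with a zero denominator are reported as 0 with a warning so degenerate
#' folds do not abort a cross-validation run.
#'
#' @param cm A [confusion()] result.
#' @return One-row tibble with the five metrics (values in `[0, 1]`).
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  sens <- safe_ratio(cm$tp, cm$tp + cm$fn, "sensitivity")
  spec <- safe_ratio(cm$tn, cm$tn + cm$fp, "specificity")
  prec <- safe_ratio(cm$tp, cm$tp + cm$fp, "precision")
  f1 <- if (prec + sens == 0) {
    warning("F1 undefined (zero precision and sensitivity), reporting 0",
            call. = FALSE)
    0
  } else {
    2 * prec * sens / (prec + sens)
  }
  tibble::tibble(accuracy = (cm$tp + cm$tn) / total, sensitivity = sens,
                 specificity = spec, precision = prec, f1 = f1)
}

#' Stratified k-fold assignment
#'
#' Shuffles each class separately (seeded) and deals indices round-robin, so
#' per-fold class counts deviate from perfect proportionality by at most one
#' sample.
#'
#' @param labels Character label vector.
#' @param k Number of folds. Default 5.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, parallel to `labels`.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 0) {
  tab <- table(labels)
  if (any(tab < k)) {
    stop(sprintf("class '%s' has fewer than k = %d members",
                 names(tab)[which.min(tab)], k), call. = FALSE)
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Feature scaling fitted on training data only
#'
#' Per-column z-normalisation; zero-SD columns are passed through centred.
#'
#' @param x Numeric matrix (training rows).
#' @return A scaler object for [apply_feature_scaler()].
#' @export
fit_feature_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  structure(list(mean = mu, sd = sd), class = "feature_scaler")
}

#' @rdname fit_feature_scaler
#' @param scaler A fitted scaler.
#' @export
apply_feature_scaler <- function(scaler, x) {
  sweep(sweep(x, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' Stratified cross-validation of the full pipeline
#'
#' For each fold: features are z-normalised with statistics fitted on the
#' training rows only, the classifier is trained on the training rows, and
#' the held-out fold is scored. Per-fold metrics are aggregated as
#' mean and standard deviation.
#'
#' @param data A [mammo_dataset()].
#' @param config A [pipeline_config()] or NULL for defaults.
#' @param k Number of folds. Default 5.
#' @param seed Seed for fold assignment and training.
#' @param features Optional precomputed feature tibble from [feature_table()]
#'   (must be row-aligned with `data`); computed when NULL.
#' @return An object of class `cv_result`: `per_fold` tibble, `summary`
#'   tibble (metric, mean, sd), `predictions` tibble, `k`, `seed`.
#' @export
crossvalidate <- function(data, config = NULL, k = 5, seed = 0,
                          features = NULL) {
  config <- resolve_config(config)
  if (is.null(features)) features <- feature_table(data, config)
  fmat_all <- as.matrix(features[, hybrid_feature_names()])
  folds <- stratified_kfold(data$labels, k, seed)
  spec <- config_model_spec(config)
  cfg <- config_train_config(config, seed)

  per_fold <- list()
  preds_all <- list()
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    scaler <- fit_feature_scaler(fmat_all[tr, , drop = FALSE])
    ftr <- apply_feature_scaler(scaler, fmat_all[tr, , drop = FALSE])
    fte <- apply_feature_scaler(scaler, fmat_all[te, , drop = FALSE])
    train_set <- mammo_dataset(data$images[tr], data$labels[tr], data$ids[tr])
    model <- build_model(spec)
    model <- train_model(model, train_set, ftr,
                         train_config(cfg$learning_rate, cfg$batch_size,
                                      cfg$epochs, seed = cfg$seed + f))
    pred <- predict(model, data$images[te], fte)
    cm <- confusion(data$labels[te], pred$label)
    per_fold[[f]] <- dplyr::mutate(compute_metrics(cm), fold = f,
                                   .before = 1)
    preds_all[[f]] <- dplyr::mutate(pred, id = data$ids[te],
                                    truth = data$labels[te], fold = f)
  }
  per_fold <- dplyr::bind_rows(per_fold)
  summary <- tidyr::pivot_longer(per_fold, -"fold", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  structure(list(per_fold = per_fold, summary = summary,
                 predictions = dplyr::bind_rows(preds_all), k = k,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold stratified CV (seed %d)\n", x$k, x$seed))
  acc <- x$summary[x$summary$metric == "accuracy", ]
  cat(sprintf("  mean accuracy %.3f +- %.3f\n", acc$mean, acc$sd))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$per_fold

#' @export
glance.cv_result <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean", "sd"))
}

#' Per-feature class comparison
#'
#' For every feature column, reports the class means and a two-sided p-value
#' from either a Welch t-test or a seeded label-permutation test of the mean
#' difference. Zero-variance features fall back from Welch to permutation
#' with a warning.
#'
#' @param features Feature tibble (or matrix) with one row per image.
#' @param labels Character labels parallel to rows.
#' @param method `"welch"` (default) or `"permutation"`.
#' @param n_perm Permutation resamples. Default 1000.
#' @param seed Seed for the permutation draw.
#' @return Tibble: `feature`, `mean_normal`, `mean_abnormal`, `p_value`.
#' @export
compare_feature_groups <- function(features, labels, method = c("welch", "permutation"),
                                   n_perm = 1000, seed = 0) {
  method <- match.arg(method)
  x <- as.matrix(if (is.data.frame(features)) {
    features[, !(names(features) %in% c("id", "label")), drop = FALSE]
  } else {
    features
  })
  g1 <- labels == "normal"
  g2 <- labels == "abnormal"
  if (!any(g1) || !any(g2)) stop("both classes must be non-empty", call. = FALSE)

  perm_p <- function(v) {
    obs <- abs(mean(v[g2]) - mean(v[g1]))
    n2 <- sum(g2)
    stats_ <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample(length(v), n2)
        sel <- logical(length(v)); sel[idx] <- TRUE
        abs(mean(v[sel]) - mean(v[!sel]))
      }, numeric(1))
    })
    (1 + sum(stats_ >= obs - 1e-15)) / (n_perm + 1)
  }

  rows <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    p <- if (method == "welch") {
      if (stats::sd(v[g1]) == 0 && stats::sd(v[g2]) == 0) {
        if (mean(v[g1]) == mean(v[g2])) {
          1
        } else {
          warning("zero-variance feature under Welch: using permutation",
                  call. = FALSE)
          perm_p(v)
        }
      } else if (stats::sd(v[g1]) == 0 || stats::sd(v[g2]) == 0) {
        warning("zero-variance feature under Welch: using permutation",
                call. = FALSE)
        perm_p(v)
      } else {
        stats::t.test(v[g2], v[g1])$p.value
      }
    } else {
      perm_p(v)
    }
    tibble::tibble(feature = colnames(x)[j] %||% paste0("V", j),
                   mean_normal = mean(v[g1]), mean_abnormal = mean(v[g2]),
                   p_value = p)
  })
  dplyr::bind_rows(rows)
}

#' Preprocessing/segmentation ablation grid
#'
#' Runs one cross-validation per configuration, toggling the named stages
#' (`contrast`, `median`, `shearlet`, `otsu`, `canny`), on the same dataset
#' and fold seed, and returns one summary row per configuration.
#'
#' @param grid Named list: configuration name -> character vector of enabled
#'   stages (may be `character(0)` for the raw-resize baseline).
#' @param data A [mammo_dataset()].
#' @param config Base [pipeline_config()] (stages are overridden per run).
#' @param k,seed Cross-validation parameters.
#' @return List with `table` (tibble: config, accuracy, sensitivity,
#'   specificity, f1, plus SDs) and `runs` (named list of `cv_result`).
#' @export
run_ablation <- function(grid, data, config = NULL, k = 5, seed = 0) {
  stopifnot(length(grid) >= 1)
  config <- resolve_config(config)
  runs <- list()
  rows <- list()
  for (nm in names(grid)) {
    cfg_i <- config
    cfg_i$stages <- as.character(grid[[nm]])
    cv <- crossvalidate(data, cfg_i, k = k, seed = seed)
    runs[[nm]] <- cv
    w <- glance(cv)
    rows[[nm]] <- dplyr::mutate(w, config = nm, .before = 1)
  }
  list(table = dplyr::bind_rows(rows), runs = runs)
}
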