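# End-to-end orchestration: preprocess -> AR features -> (KDA) -> ANN,
# window-level evaluation with confusion matrices, and bundle persistence.

#' Pipeline configuration
#'
#' Collects every tunable of the train/classify flows in one list. Defaults
#' follow the pipeline's base case: gravity filter weight 0.8, order-3
#' moving average, 3-s non-overlapping windows, AR order 10 (30 features),
#' KDA with the median-heuristic bandwidth and `C - 1` components, and a
#' 3-hidden-neuron network.
#'
#' @param alpha gravity low-pass weight in `[0, 1)`.
#' @param ma_order moving-average filter order (samples).
#' @param window_seconds analysis window length (s).
#' @param overlap_fraction window overlap in `[0, 1)`.
#' @param ar_order AR feature order per axis.
#' @param use_kda apply kernel discriminant analysis before the classifier?
#' @param gamma,n_components,eps forwarded to [fit_kda()].
#' @param hidden_size,learning_rate,epochs,batch_size forwarded to
#'   [train_ann()].
#' @param seed master seed for the training randomness.
#' @return A `har_config` list.
#' @export
har_config <- function(alpha = 0.8, ma_order = 3L, window_seconds = 3,
                       overlap_fraction = 0, ar_order = 10L, use_kda = TRUE,
                       gamma = "auto", n_components = NULL, eps = NULL,
                       hidden_size = 3L, learning_rate = 0.1, epochs = 500L,
                       batch_size = 32L, seed = 1L) {
  structure(list(alpha = alpha, ma_order = as.integer(ma_order),
                 window_seconds = window_seconds,
                 overlap_fraction = overlap_fraction,
                 ar_order = as.integer(ar_order), use_kda = use_kda,
                 gamma = gamma, n_components = n_components, eps = eps,
                 hidden_size = as.integer(hidden_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "har_config")
}

# Preprocess one recording and return its windows.
preprocess_recording <- function(rec, config) {
  rec <- remove_gravity(rec, config$alpha)
  rec <- smooth_recording(rec, config$ma_order)
  segment_recording(rec, config$window_seconds, config$overlap_fraction)
}

# Preprocess a corpus into a feature matrix + window metadata.
corpus_features <- function(corpus, config) {
  feats <- list(); meta <- list()
  for (rec in corpus) {
    for (w in preprocess_recording(rec, config)) {
      f <- extract_features(w, config$ar_order)
      feats[[length(feats) + 1L]] <- f$values
      meta[[length(meta) + 1L]] <- data.frame(
        activity = if (is.null(w$activity)) NA_character_ else w$activity,
        position = if (is.null(w$position)) NA_character_ else w$position,
        subject = if (is.null(w$subject)) NA_character_ else w$subject,
        stringsAsFactors = FALSE)
    }
  }
  list(X = do.call(rbind, feats), meta = do.call(rbind, meta))
}

#' Train the full activity-recognition pipeline
#'
#' Runs gravity removal, smoothing and segmentation on every recording,
#' extracts AR-coefficient features per window, optionally projects them
#' through kernel discriminant analysis, and trains the feed-forward
#' classifier. All randomness is controlled by `config$seed`.
#'
#' @param corpus list of labeled [accel_recording()]s; at least one window
#'   per activity class.
#' @param config a [har_config()].
#' @return An object of class `har_bundle` holding the preprocessing
#'   parameters, feature standardization statistics, KDA model (when
#'   enabled), ANN model, class names and training-subject set.
#' @export
train_pipeline <- function(corpus, config = har_config()) {
  cf <- corpus_features(corpus, config)
  if (is.null(cf$X) || !nrow(cf$X)) stop_data("corpus yields no windows")
  if (anyNA(cf$meta$activity)) stop_data("corpus contains unlabeled recordings")
  labels <- cf$meta$activity
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop_data("need at least 2 activity classes")

  # The classifier inputs (KDA projections or raw AR features) are z-scored
  # with training statistics: unit-scale inputs keep the small network's
  # gradient steps effective regardless of corpus size or projection scale.
  if (isTRUE(config$use_kda)) {
    kda <- fit_kda(cf$X, labels, gamma = config$gamma,
                   n_components = config$n_components, eps = config$eps)
    Z <- project_kda(kda, cf$X)
  } else {
    kda <- NULL
    Z <- cf$X
  }
  center <- colMeans(Z)
  scale_ <- apply(Z, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  std <- list(center = center, scale = scale_)
  Z <- sweep(sweep(Z, 2, center, "-"), 2, scale_, "/")

  ann <- train_ann(Z, labels, hidden_size = config$hidden_size,
                   learning_rate = config$learning_rate,
                   epochs = config$epochs, batch_size = config$batch_size,
                   seed = config$seed)

  structure(list(version = 1L, config = config, standardization = std,
                 kda = kda, ann = ann, classes = classes,
                 train_subjects = sort(unique(stats::na.omit(cf$meta$subject)))),
            class = "har_bundle")
}

#' @export
print.har_bundle <- function(x, ...) {
  cat(sprintf("<har_bundle> %d classes, AR order %d, %s, ANN [%s]\n",
              length(x$classes), x$config$ar_order,
              if (is.null(x$kda)) "no KDA" else
                sprintf("KDA d = %d", x$kda$n_components),
              paste(x$ann$layer_sizes, collapse = "-")))
  invisible(x)
}

# Map raw window features through the bundle's projection (KDA if enabled)
# and input standardization into classifier inputs.
bundle_inputs <- function(bundle, X) {
  Z <- if (!is.null(bundle$kda)) project_kda(bundle$kda, X) else X
  sweep(sweep(Z, 2, bundle$standardization$center, "-"), 2,
        bundle$standardization$scale, "/")
}

#' Classify a recording window by window
#'
#' Runs the online path: preprocess, segment, extract AR features, project,
#' classify — each window independently and in order. Identical to the
#' per-window path used by [evaluate_pipeline()].
#'
#' @param bundle a trained [train_pipeline()] bundle.
#' @param rec an [accel_recording()].
#' @return A data frame with `window` index, `label`, and one score column
#'   per class (softmax scores summing to 1); zero rows if the recording is
#'   shorter than one window.
#' @export
classify_stream <- function(bundle, rec) {
  windows <- preprocess_recording(rec, bundle$config)
  if (!length(windows)) {
    out <- data.frame(window = integer(0), label = character(0))
    for (cl in bundle$classes) out[[cl]] <- numeric(0)
    return(out)
  }
  X <- do.call(rbind, lapply(windows, function(w)
    extract_features(w, bundle$config$ar_order)$values))
  Z <- bundle_inputs(bundle, X)
  pred <- predict(bundle$ann, Z, type = "both")
  out <- data.frame(window = seq_along(windows), label = pred$labels,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(pred$scores))
}

#' Build a confusion matrix
#'
#' @param true,predicted label vectors of equal length.
#' @param classes class name ordering (default: sorted union).
#' @return An object of class `har_confusion` with integer `counts` (rows =
#'   true class), `row_percent` (rows sum to 100 for non-empty rows),
#'   `per_class_accuracy` (diagonal of `row_percent`) and `mean_accuracy`
#'   (unweighted mean of the diagonal over non-empty rows).
#' @export
confusion_matrix <- function(true, predicted,
                             classes = sort(unique(c(true, predicted)))) {
  if (length(true) != length(predicted)) stop_param("length mismatch")
  counts <- table(factor(true, levels = classes),
                  factor(predicted, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(true = classes, predicted = classes))
  rs <- rowSums(counts)
  row_percent <- counts * 0
  nonempty <- rs > 0
  row_percent[nonempty, ] <- 100 * counts[nonempty, , drop = FALSE] / rs[nonempty]
  diag_acc <- diag(row_percent)
  structure(list(classes = classes, counts = counts,
                 row_percent = row_percent,
                 per_class_accuracy = diag_acc,
                 mean_accuracy = mean(diag_acc[nonempty]),
                 n_windows = sum(counts)),
            class = "har_confusion")
}

#' @export
print.har_confusion <- function(x, digits = 1, ...) {
  cat(sprintf("<har_confusion> %d windows (row-normalized %%)\n", x$n_windows))
  print(round(x$row_percent, digits))
  cat(sprintf("Mean %.*f\n", digits, x$mean_accuracy))
  invisible(x)
}

#' Write a confusion matrix as CSV
#'
#' Layout: one row per true class with row-normalized percentages, followed
#' by a `Mean` row carrying the unweighted diagonal mean.
#'
#' @param cm a [confusion_matrix()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  df <- data.frame(Activity = cm$classes, round(cm$row_percent, 1),
                   check.names = FALSE)
  mean_row <- c("Mean", round(cm$mean_accuracy, 1),
                rep("", length(cm$classes) - 1L))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("Activity", cm$classes), collapse = ","), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(paste(mean_row, collapse = ","), con)
  invisible(path)
}

#' Evaluate a trained pipeline on a labeled corpus
#'
#' Classifies every window of every recording and aggregates a window-level
#' confusion matrix (no majority voting across windows). With
#' `subject_independent = TRUE`, the evaluation subjects must be disjoint
#' from the bundle's recorded training subjects — the protocol for honest
#' generalization claims.
#'
#' @param bundle a trained [train_pipeline()] bundle.
#' @param corpus list of labeled [accel_recording()]s.
#' @param subject_independent enforce disjoint train/eval subject sets?
#' @return A [confusion_matrix()] result over the bundle's classes.
#' @export
evaluate_pipeline <- function(bundle, corpus, subject_independent = FALSE) {
  if (subject_independent) {
    eval_subjects <- unique(unlist(lapply(corpus, `[[`, "subject")))
    overlap <- intersect(eval_subjects, bundle$train_subjects)
    if (length(overlap)) {
      stop_data("subject-independent protocol violated; overlapping subjects: ",
                paste(overlap, collapse = ", "))
    }
  }
  truth <- character(0); pred <- character(0)
  for (rec in corpus) {
    res <- classify_stream(bundle, rec)
    if (!nrow(res)) next
    truth <- c(truth, rep(rec$activity, nrow(res)))
    pred <- c(pred, res$label)
  }
  if (!length(truth)) stop_data("corpus yields no windows to evaluate")
  confusion_matrix(truth, pred, classes = bundle$classes)
}

#' Quantify the benefit of the KDA step
#'
#' Trains two pipelines under identical seeds — one with kernel discriminant
#' analysis, one feeding standardized AR features straight to the classifier
#' — and evaluates both on the same corpus.
#'
#' @param config a [har_config()] (its `use_kda` field is overridden for
#'   each variant).
#' @param corpus_train,corpus_eval labeled corpora.
#' @param subject_independent forwarded to [evaluate_pipeline()].
#' @return A list with `with_kda` and `without_kda` confusion matrices and
#'   `accuracy_delta` (mean accuracy with minus without).
#' @export
ablate_kda <- function(config, corpus_train, corpus_eval,
                       subject_independent = FALSE) {
  cfg_on <- config; cfg_on$use_kda <- TRUE
  cfg_off <- config; cfg_off$use_kda <- FALSE
  cm_on <- evaluate_pipeline(train_pipeline(corpus_train, cfg_on),
                             corpus_eval, subject_independent)
  cm_off <- evaluate_pipeline(train_pipeline(corpus_train, cfg_off),
                              corpus_eval, subject_independent)
  list(with_kda = cm_on, without_kda = cm_off,
       accuracy_delta = cm_on$mean_accuracy - cm_off$mean_accuracy)
}

#' Save / load a pipeline bundle
#'
#' Bundles persist as self-describing JSON containing the configuration,
#' standardization statistics, the KDA model (training vectors, alpha,
#' eigenvalues) and the ANN weights at full precision, so a reloaded bundle
#' reproduces [evaluate_pipeline()] output bit-exactly.
#'
#' @param bundle a `har_bundle`.
#' @param path file path for the JSON document.
#' @return `save_bundle` returns `path` invisibly; `load_bundle` the
#'   restored bundle.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "har_bundle"))
  cfg <- unclass(bundle$config)
  kda <- bundle$kda
  doc <- list(
    format = "arhar-bundle", version = bundle$version,
    config = cfg,
    standardization = list(center = num_to_chr(bundle$standardization$center),
                           scale = num_to_chr(bundle$standardization$scale)),
    classes = bundle$classes,
    train_subjects = bundle$train_subjects,
    kda = if (is.null(kda)) NULL else list(
      X = num_to_chr(kda$X), m = nrow(kda$X), D = ncol(kda$X),
      labels = kda$labels, classes = kda$classes,
      gamma = num_to_chr(kda$gamma),
      alpha = num_to_chr(kda$alpha), n_components = kda$n_components,
      eigenvalues = num_to_chr(kda$eigenvalues), eps = num_to_chr(kda$eps),
      center = num_to_chr(kda$center), scale = num_to_chr(kda$scale),
      standardize = kda$standardize),
    ann = list(layer_sizes = bundle$ann$layer_sizes,
               W1 = num_to_chr(bundle$ann$W1), b1 = num_to_chr(bundle$ann$b1),
               W2 = num_to_chr(bundle$ann$W2), b2 = num_to_chr(bundle$ann$b2),
               classes = bundle$ann$classes,
               loss_history = num_to_chr(bundle$ann$loss_history),
               config = bundle$ann$config))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop_format("unreadable bundle file: ",
                                                  conditionMessage(e)))
  if (!is.list(doc) || !identical(doc$format, "arhar-bundle")) {
    stop_format("not a valid pipeline bundle file")
  }
  cfg <- doc$config
  config <- do.call(har_config, cfg[!vapply(cfg, is.null, logical(1))])
  kda <- NULL
  if (!is.null(doc$kda) && length(doc$kda)) {
    k <- doc$kda
    kda <- structure(list(
      X = matrix(chr_to_num(k$X), k$m, k$D), labels = as.character(k$labels),
      classes = as.character(k$classes), gamma = chr_to_num(k$gamma),
      alpha = matrix(chr_to_num(k$alpha), k$m, k$n_components),
      eigenvalues = chr_to_num(k$eigenvalues),
      n_components = as.integer(k$n_components), eps = chr_to_num(k$eps),
      center = chr_to_num(k$center), scale = chr_to_num(k$scale),
      standardize = isTRUE(k$standardize)), class = "kda_model")
  }
  a <- doc$ann
  ls <- as.integer(a$layer_sizes)
  ann <- structure(list(layer_sizes = ls,
                        W1 = matrix(chr_to_num(a$W1), ls[1], ls[2]),
                        b1 = chr_to_num(a$b1),
                        W2 = matrix(chr_to_num(a$W2), ls[2], ls[3]),
                        b2 = chr_to_num(a$b2),
                        classes = as.character(a$classes),
                        loss_history = chr_to_num(a$loss_history),
                        config = a$config), class = "ann_model")
  structure(list(version = doc$version, config = config,
                 standardization = list(
                   center = chr_to_num(doc$standardization$center),
                   scale = chr_to_num(doc$standardization$scale)),
                 kda = kda, ann = ann,
                 classes = as.character(doc$classes),
                 train_subjects = as.character(doc$train_subjects)),
            class = "har_bundle")
}
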