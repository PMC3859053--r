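#' Train a small feed-forward neural network classifier
#'
#' A `[d, hidden, C]` feed-forward network — logistic sigmoid hidden layer,
#' softmax output — trained by seeded mini-batch gradient descent on the
#' cross-entropy loss. The default hidden layer has 3 neurons, the
#' architecture used for the activity classifier downstream of the kernel
#' discriminant projection. Weights and biases are initialized from
#' uniform(-0.5, 0.5) under `seed`, and the per-epoch shuffle also draws from
#' the seeded stream, so training is bit-reproducible.
#'
#' @param features numeric matrix (m x d) of input vectors.
#' @param labels class label per row; at least 2 distinct classes.
#' @param hidden_size neurons in the hidden layer (default 3).
#' @param learning_rate gradient-descent step size (default 0.1).
#' @param epochs full passes over the data (default 500).
#' @param batch_size mini-batch size (default 32; capped at m).
#' @param seed RNG seed controlling initialization and shuffling.
#' @return An object of class `ann_model` with the layer weights, class
#'   names, per-epoch mean cross-entropy `loss_history`, and the training
#'   configuration echo.
#' @export
train_ann <- function(features, labels, hidden_size = 3L,
                      learning_rate = 0.1, epochs = 500L, batch_size = 32L,
                      seed = 1L) {
  X <- features_as_matrix(features)
  m <- nrow(X)
  labels <- as.character(labels)
  if (length(labels) != m) stop_param("labels must match the number of rows")
  classes <- sort(unique(labels))
  C <- length(classes)
  if (C < 2L) stop_param("need at least 2 classes")
  d <- ncol(X)
  h <- as.integer(hidden_size)
  Y <- diag(C)[match(labels, classes), , drop = FALSE]
  batch_size <- min(as.integer(batch_size), m)

  with_seed(seed, {
    W1 <- matrix(stats::runif(d * h, -0.5, 0.5), d, h)
    b1 <- stats::runif(h, -0.5, 0.5)
    W2 <- matrix(stats::runif(h * C, -0.5, 0.5), h, C)
    b2 <- stats::runif(C, -0.5, 0.5)
    loss_history <- numeric(epochs)

    for (ep in seq_len(epochs)) {
      ord <- sample.int(m)
      total_loss <- 0
      for (start in seq.int(1L, m, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, m)]
        Xb <- X[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        nb <- length(idx)

        H <- stats::plogis(sweep(Xb %*% W1, 2, b1, "+"))
        Z <- sweep(H %*% W2, 2, b2, "+")
        Z <- Z - apply(Z, 1, max)
        P <- exp(Z)
        P <- P / rowSums(P)

        total_loss <- total_loss - sum(Yb * log(pmax(P, 1e-300)))

        dZ <- (P - Yb) / nb
        dW2 <- crossprod(H, dZ)
        db2 <- colSums(dZ)
        dH <- dZ %*% t(W2) * H * (1 - H)
        dW1 <- crossprod(Xb, dH)
        db1 <- colSums(dH)

        W2 <- W2 - learning_rate * dW2
        b2 <- b2 - learning_rate * db2
        W1 <- W1 - learning_rate * dW1
        b1 <- b1 - learning_rate * db1
      }
      loss_history[ep] <- total_loss / m
    }

    structure(list(layer_sizes = c(d, h, C), W1 = W1, b1 = b1, W2 = W2,
                   b2 = b2, classes = classes, loss_history = loss_history,
                   config = list(learning_rate = learning_rate,
                                 epochs = as.integer(epochs),
                                 batch_size = batch_size,
                                 hidden_size = h, seed = seed)),
              class = "ann_model")
  })
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("<ann_model> [%s] network, classes: %s\n",
              paste(x$layer_sizes, collapse = "-"),
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  final training cross-entropy: %.4f\n",
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

ann_forward <- function(model, X) {
  H <- stats::plogis(sweep(X %*% model$W1, 2, model$b1, "+"))
  Z <- sweep(H %*% model$W2, 2, model$b2, "+")
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z)
  P / rowSums(P)
}

#' Predict activity classes with a trained network
#'
#' @param object an `ann_model`.
#' @param newdata a single input vector or a matrix of rows, dimension
#'   matching the model input.
#' @param type `"class"` for labels, `"prob"` for the softmax score matrix,
#'   `"both"` for a list with `labels` and `scores`.
#' @param ... unused.
#' @return Labels, scores (rows sum to 1), or both. Ties break toward the
#'   lower class index.
#' @export
predict.ann_model <- function(object, newdata, type = c("class", "prob", "both"),
                              ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(as.numeric(newdata), nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$layer_sizes[1L]) stop_param("dimension mismatch")
  P <- ann_forward(object, newdata)
  colnames(P) <- object$classes
  labels <- object$classes[apply(P, 1, which.max)]
  switch(type, class = labels, prob = P, both = list(labels = labels, scores = P))
}

#' Save / load a trained network
#'
#' Models persist as self-describing JSON (format version, layer sizes,
#' weights at full precision, class names, training config), so a network
#' trained offline round-trips bit-exactly into the classification path.
#'
#' @param model an `ann_model`.
#' @param path file path for the JSON document.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `ann_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ann_model"))
  doc <- list(format = "arhar-ann", version = 1L,
              layer_sizes = model$layer_sizes,
              W1 = num_to_chr(model$W1), b1 = num_to_chr(model$b1),
              W2 = num_to_chr(model$W2), b2 = num_to_chr(model$b2),
              classes = model$classes,
              loss_history = num_to_chr(model$loss_history),
              config = model$config)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop_format("unreadable model file: ",
                                                  conditionMessage(e)))
  need <- c("format", "layer_sizes", "W1", "b1", "W2", "b2", "classes")
  if (!is.list(doc) || !all(need %in% names(doc)) ||
      !identical(doc$format, "arhar-ann")) {
    stop_format("not a valid ann model file")
  }
  ls <- as.integer(doc$layer_sizes)
  if (length(doc$W1) != ls[1] * ls[2] || length(doc$W2) != ls[2] * ls[3]) {
    stop_format("corrupted model file: weight shapes inconsistent")
  }
  structure(list(layer_sizes = ls,
                 W1 = matrix(chr_to_num(doc$W1), ls[1], ls[2]),
                 b1 = chr_to_num(doc$b1),
                 W2 = matrix(chr_to_num(doc$W2), ls[2], ls[3]),
                 b2 = chr_to_num(doc$b2),
                 classes = as.character(doc$classes),
                 loss_history = chr_to_num(doc$loss_history),
                 config = doc$config),
            class = "ann_model")
}
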