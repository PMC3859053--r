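#' Radial basis function kernel
#'
#' `K(xi, xj) = exp(-gamma * ||xi - xj||^2)`.
#'
#' @param xi,xj numeric vectors of equal dimension.
#' @param gamma positive bandwidth parameter.
#' @return The kernel value in (0, 1].
#' @export
rbf_kernel <- function(xi, xj, gamma) {
  if (length(xi) != length(xj)) stop_param("dimension mismatch")
  if (!is.numeric(gamma) || gamma <= 0) stop_param("gamma must be positive")
  exp(-gamma * sum((xi - xj)^2))
}

# Full RBF kernel matrix between the rows of A (m x D) and B (q x D).
rbf_kernel_matrix <- function(A, B, gamma) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0  # numerical guard
  exp(-gamma * d2)
}

#' Class indicator matrix of the KDA eigenproblem
#'
#' `W[i, j] = 1/m_k` when samples i and j belong to the same class k (with
#' `m_k` members), else 0; block-diagonal under class-sorted ordering.
#'
#' @param labels vector of class assignments, at least one sample per class.
#' @return The m x m matrix `W`.
#' @export
class_indicator_matrix <- function(labels) {
  if (!length(labels)) stop_param("empty label list")
  labels <- as.character(labels)
  m <- length(labels)
  counts <- table(labels)
  W <- matrix(0, m, m)
  for (k in names(counts)) {
    idx <- which(labels == k)
    W[idx, idx] <- 1 / counts[[k]]
  }
  W
}

# Median-heuristic RBF bandwidth: gamma = 1 / (2 * median(pairwise dist)^2).
median_heuristic_gamma <- function(X) {
  d <- stats::dist(X)
  med <- stats::median(d[d > 0])
  if (!is.finite(med) || med == 0) return(1)
  1 / (2 * med^2)
}

#' Fit a kernel discriminant analysis model
#'
#' Seeks the nonlinear discriminating directions that maximize the Rayleigh
#' quotient `J(alpha) = (alpha' K W K alpha) / (alpha' K K alpha)` in the
#' RBF-induced feature space, i.e. the leading eigenvectors of the
#' generalized eigenproblem `K W K alpha = lambda K K alpha`, where `K` is the
#' kernel matrix and `W` the globally centered class indicator matrix
#' (`class_indicator_matrix(labels) - 1/m`, matching a between-class scatter
#' defined around the global mean). The right-hand matrix is
#' ridge-regularized to `K K + eps I` (it is rank-deficient in practice), and
#' the problem is solved by Cholesky whitening followed by a symmetric
#' eigendecomposition. At most `C - 1` directions carry between-class
#' discrimination, so `n_components <= C - 1`.
#'
#' Features are z-score standardized (per dimension, training statistics)
#' before kernel evaluation by default, since AR coefficients at different
#' lags live on different scales; the statistics are stored and re-applied by
#' [project_kda()].
#'
#' @param features numeric matrix (m samples x D dims), a list of
#'   [extract_features()] vectors, or anything coercible by `rbind`.
#' @param labels class label per sample; every class non-empty, `m >= C >= 2`.
#' @param gamma RBF bandwidth, or `"auto"` for the median heuristic.
#' @param n_components number of retained directions `d` (default `C - 1`).
#' @param eps ridge regularization; default `1e-8 * trace(KK)`, which keeps
#'   projections invariant under duplication of the training set.
#' @param standardize z-score the feature columns first?
#' @return An object of class `kda_model` holding the (standardized) training
#'   matrix, labels, `gamma`, `alpha` (m x d eigen-coefficients ordered by
#'   descending eigenvalue, each column scaled so its basis vector has unit
#'   norm in feature space, first non-negligible entry positive),
#'   `eigenvalues`, and the standardization statistics.
#' @export
fit_kda <- function(features, labels, gamma = "auto", n_components = NULL,
                    eps = NULL, standardize = TRUE) {
  X <- features_as_matrix(features)
  labels <- as.character(labels)
  m <- nrow(X)
  if (length(labels) != m) stop_param("labels must match the number of rows")
  classes <- sort(unique(labels))
  C <- length(classes)
  if (C < 2L) stop_param("need at least 2 classes")
  if (any(table(labels) < 1L)) stop_param("every class needs >= 1 sample")

  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, stats::sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
    X <- sweep(sweep(X, 2, center, "-"), 2, scale_, "/")
  } else {
    center <- rep(0, ncol(X))
    scale_ <- rep(1, ncol(X))
  }

  if (identical(gamma, "auto")) gamma <- median_heuristic_gamma(X)
  if (!is.numeric(gamma) || gamma <= 0) stop_param("gamma must be positive")

  K <- rbf_kernel_matrix(X, X, gamma)
  # Between-class operator: the class-indicator projector minus the global
  # mean term, so that alpha' K Wc K alpha = sum_k m_k (mean_k - mean)^2 of
  # the projected values — the kernelized between-class scatter. Without the
  # global-mean subtraction the constant direction is a spurious unit
  # eigenvalue carrying no discrimination.
  W <- class_indicator_matrix(labels) - 1 / m
  KWK <- K %*% W %*% K
  KWK <- (KWK + t(KWK)) / 2
  KK <- K %*% K
  # Auto ridge scales with trace(KK) alone (not trace(KK)/m): duplicating the
  # training set maps the eigenproblem onto itself with ridge eps/4 while
  # trace(KK) grows 4-fold, so this rule keeps projections exactly invariant
  # under sample duplication.
  if (is.null(eps)) eps <- 1e-8 * sum(diag(KK))
  M2 <- KK + diag(eps, m)

  # Whitening route: with M2 = R'R, solve the symmetric problem
  # R^-T KWK R^-1 u = lambda u, then map back alpha = R^-1 u.
  R <- tryCatch(chol((M2 + t(M2)) / 2), error = function(e)
    stop_data("eigensolver failure: regularized KK not positive definite"))
  Ci <- backsolve(R, t(backsolve(R, KWK, transpose = TRUE)), transpose = TRUE)
  es <- eigen((Ci + t(Ci)) / 2, symmetric = TRUE)

  d <- if (is.null(n_components)) C - 1L else as.integer(n_components)
  d <- min(d, C - 1L, m)
  lambda <- es$values[seq_len(d)]
  A <- backsolve(R, es$vectors[, seq_len(d), drop = FALSE])
  # Scale each alpha so the basis vector omega = sum_i alpha_i phi(x_i) has
  # unit norm in feature space (alpha' K alpha = 1): this makes projections
  # invariant to duplicating the training set. Sign fixed by the first
  # non-negligible entry.
  for (j in seq_len(ncol(A))) {
    nrm <- sqrt(max(0, sum(A[, j] * (K %*% A[, j]))))
    if (nrm > 0) A[, j] <- A[, j] / nrm
    lead <- which(abs(A[, j]) > 1e-10)
    if (length(lead) && A[lead[1L], j] < 0) A[, j] <- -A[, j]
  }

  structure(list(X = X, labels = labels, classes = classes, gamma = gamma,
                 alpha = A, eigenvalues = lambda, n_components = d,
                 eps = eps, center = center, scale = scale_,
                 standardize = standardize),
            class = "kda_model")
}

#' @export
print.kda_model <- function(x, ...) {
  cat(sprintf(
    "<kda_model> m = %d training vectors, %d classes, d = %d, gamma = %.4g\n",
    nrow(x$X), length(x$classes), x$n_components, x$gamma))
  cat("  eigenvalues:", paste(sprintf("%.4g", x$eigenvalues), collapse = " "), "\n")
  invisible(x)
}

# Coerce features to a plain numeric matrix (rows = samples).
features_as_matrix <- function(features) {
  if (is.list(features) && !is.data.frame(features)) {
    features <- do.call(rbind, lapply(features, function(f) {
      if (inherits(f, "feature_vector")) f$values else as.numeric(f)
    }))
  }
  X <- as.matrix(features)
  if (anyNA(X) || any(!is.finite(X))) stop_data("non-finite feature values")
  storage.mode(X) <- "double"
  X
}

#' Project feature vectors onto the KDA basis
#'
#' Component j of the projection of a query x is
#' `alpha_j' [K(x_1, x), ..., K(x_m, x)]'` over the m training vectors.
#' Queries are standardized with the training statistics first.
#'
#' @param model a [fit_kda()] model.
#' @param x a single feature vector or a matrix of rows to project (training
#'   dimension D).
#' @return A q x d matrix of projections (a 1-row matrix for a single
#'   vector).
#' @export
project_kda <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  x <- features_as_matrix(x)
  if (ncol(x) != length(model$center)) stop_param("dimension mismatch")
  xs <- sweep(sweep(x, 2, model$center, "-"), 2, model$scale, "/")
  Kx <- rbf_kernel_matrix(model$X, xs, model$gamma)  # m x q
  t(Kx) %*% model$alpha
}
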