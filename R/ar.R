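#' Fit an autoregressive model by Burg's maximum-entropy method
#'
#' Estimates the AR(M) model `x[n] = sum_i a_i x[n-i] + e[n]` with the Burg
#' lattice recursion, which minimizes the combined forward and backward
#' prediction-error power at each stage. Every reflection coefficient lies in
#' (-1, 1), so the fitted model is always stable — a property that matters
#' here because fitted models are simulated from.
#'
#' @param x numeric series, non-constant, with `length(x) > 2 * order`.
#' @param order model order M (number of past samples used).
#' @param axis optional channel tag ("x", "y" or "z") carried in the result.
#' @return An object of class `ar_model` with fields `order`, `coefficients`
#'   (predictor weights `a_1..a_M`), `innovation_variance` (final
#'   prediction-error power), `reflection` (lattice reflection coefficients)
#'   and `axis`.
#' @export
fit_ar_burg <- function(x, order, axis = NULL) {
  n <- length(x)
  if (order < 1) stop_param("order must be >= 1")
  order <- as.integer(order)
  if (n <= 2L * order) stop_param("series too short: need length > 2 * order")
  if (stats::sd(x) == 0) stop_data("degenerate (constant) series")

  # Lattice recursion on the prediction polynomial A(z) = 1 + c_1 z^-1 + ...
  a_poly <- 1
  ef <- x            # forward prediction errors
  eb <- x            # backward prediction errors
  e_pow <- mean(x^2) # stage-0 error power
  refl <- numeric(order)
  for (m in seq_len(order)) {
    f <- ef[-1L]
    b <- eb[-length(eb)]
    denom <- sum(f^2) + sum(b^2)
    k <- if (denom > 0) -2 * sum(f * b) / denom else 0
    refl[m] <- k
    a_poly <- c(a_poly, 0) + k * rev(c(a_poly, 0))
    ef <- f + k * b
    eb <- b + k * f
    e_pow <- e_pow * (1 - k^2)
  }
  structure(list(order = order,
                 coefficients = -a_poly[-1L],
                 innovation_variance = e_pow,
                 reflection = refl,
                 axis = axis),
            class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> order %d%s, innovation variance %.4g\n", x$order,
              if (is.null(x$axis)) "" else paste0(" (axis ", x$axis, ")"),
              x$innovation_variance))
  cat("  a:", paste(sprintf("%.4f", x$coefficients), collapse = " "), "\n")
  invisible(x)
}

ar_is_stable <- function(coefficients) {
  if (!length(coefficients)) return(TRUE)
  all(Mod(polyroot(c(1, -coefficients))) > 1)
}

#' One-step predictions and residuals of an AR model
#'
#' For `n > M` computes `xhat[n] = sum_i a_i x[n-i]` and the one-step
#' prediction error `e[n] = x[n] - xhat[n]`.
#'
#' @param model an [fit_ar_burg()] model (or any `ar_model`).
#' @param x numeric series with `length(x) > model$order`.
#' @return A list with `predictions` and `residuals`, both of length
#'   `length(x) - model$order`.
#' @export
predict_one_step <- function(model, x) {
  p <- model$order
  if (length(x) <= p) stop_param("series must be longer than the model order")
  lagged <- stats::embed(x, p + 1L)          # col 1 = x[n], cols 2.. = x[n-1]..
  preds <- as.numeric(lagged[, -1L, drop = FALSE] %*% model$coefficients)
  list(predictions = preds, residuals = lagged[, 1L] - preds)
}

#' Simulate a realization of an AR model
#'
#' Generates `x[t] = sum_i a_i x[t-i] + e[t]` with i.i.d. Gaussian
#' innovations of variance `model$innovation_variance`, discarding a burn-in
#' of `10 * order` samples so the returned stretch is (approximately)
#' stationary.
#'
#' @param model a stable `ar_model`.
#' @param n number of samples returned.
#' @param seed integer seed for reproducibility, or `NULL` to draw from the
#'   current RNG stream.
#' @return Numeric vector of length `n`.
#' @export
simulate_ar <- function(model, n, seed = NULL) {
  if (n < 1) stop_param("n must be positive")
  if (!ar_is_stable(model$coefficients)) {
    stop_data("unstable AR coefficients: simulation would diverge")
  }
  sigma <- sqrt(model$innovation_variance)
  burn <- 10L * model$order
  with_seed(seed, {
    e <- stats::rnorm(n + burn, 0, sigma)
    x <- as.numeric(stats::filter(e, model$coefficients, method = "recursive"))
    x[(burn + 1L):(burn + n)]
  })
}

#' Akaike information criterion for a Gaussian AR fit
#'
#' `AIC = -2 L_m + 2 m` where the maximized Gaussian log-likelihood is
#' `L_m = -(n/2) (log(2 pi sigma2) + 1)` from the residual variance. Lower is
#' better; the `+2m` term penalizes model complexity so the criterion trades
#' goodness of fit against parameter count.
#'
#' @param residual_variance estimated innovation variance, > 0.
#' @param n_effective number of observations entering the likelihood.
#' @param m number of estimated parameters (AR coefficients + innovation
#'   variance).
#' @return The AIC value.
#' @export
aic_score <- function(residual_variance, n_effective, m) {
  if (residual_variance <= 0) stop_param("residual_variance must be positive")
  if (n_effective <= 0) stop_param("n_effective must be positive")
  n_effective * (log(2 * pi * residual_variance) + 1) + 2 * m
}

#' Select the AR model order by axis-averaged AIC
#'
#' For every window and axis, fits each candidate order by Burg's method and
#' scores it with [aic_score()] (parameter count `order + 1`); scores are
#' averaged over the three axes and over windows. `rule = "min"` selects the
#' argmin; `rule = "elbow"` selects the smallest order whose relative AIC
#' improvement over the previous candidate falls below
#' `improvement_threshold`, codifying the point where the AIC curve "evens
#' out". Ties break toward the smaller order.
#'
#' @param windows list of [signal_window()] objects.
#' @param candidate_orders integer vector of candidate orders (sorted
#'   internally).
#' @param rule `"min"` or `"elbow"`.
#' @param improvement_threshold relative-improvement cutoff for the elbow
#'   rule.
#' @return An object of class `aic_curve` with `orders`, `scores` and
#'   `selected_order`.
#' @export
select_order <- function(windows, candidate_orders, rule = c("min", "elbow"),
                         improvement_threshold = 0.01) {
  rule <- match.arg(rule)
  if (!length(windows)) stop_param("empty window list")
  candidate_orders <- sort(unique(as.integer(candidate_orders)))
  scores <- vapply(candidate_orders, function(ord) {
    per_window <- vapply(windows, function(w) {
      nw <- nrow(w$samples)
      ax <- vapply(1:3, function(j) {
        fit <- fit_ar_burg(w$samples[, j], ord)
        aic_score(fit$innovation_variance, nw, ord + 1L)
      }, numeric(1))
      mean(ax)
    }, numeric(1))
    mean(per_window)
  }, numeric(1))

  selected <- if (rule == "min" || length(candidate_orders) == 1L) {
    candidate_orders[which.min(scores)]
  } else {
    rel_gain <- (scores[-length(scores)] - scores[-1L]) /
      abs(scores[-length(scores)])
    hit <- which(rel_gain < improvement_threshold)
    if (length(hit)) candidate_orders[hit[1L] + 1L] else
      candidate_orders[length(candidate_orders)]
  }
  structure(list(orders = candidate_orders, scores = scores,
                 selected_order = selected, rule = rule),
            class = "aic_curve")
}

#' @export
print.aic_curve <- function(x, ...) {
  cat(sprintf("<aic_curve> rule = %s, selected order %d\n", x$rule,
              x$selected_order))
  print(data.frame(order = x$orders, aic = round(x$scores, 2)))
  invisible(x)
}

#' Signal-to-noise ratio of a model reproduction, in dB
#'
#' `SNR = 10 log10( sum(v^2) / sum((v - vbar)^2) )` between the original
#' series `v` and its model-based reproduction `vbar`. Returns `Inf` when the
#' reproduction is exact.
#'
#' @param original numeric series `v`.
#' @param fitted model reproduction `vbar`, same length.
#' @return SNR in decibels.
#' @export
snr_db <- function(original, fitted) {
  if (length(original) != length(fitted)) stop_param("length mismatch")
  if (!length(original)) stop_param("empty series")
  denom <- sum((original - fitted)^2)
  if (denom == 0) return(Inf)
  10 * log10(sum(original^2) / denom)
}

# Plateau rule for a curve of quality values over increasing candidates:
# select the last candidate *before* the first relative gain below the
# threshold — the smallest setting already offering essentially the full
# quality. A curve improving everywhere selects the largest candidate.
plateau_select <- function(candidates, values, threshold) {
  if (length(candidates) == 1L) return(candidates)
  rel_gain <- (values[-1L] - values[-length(values)]) /
    abs(values[-length(values)])
  hit <- which(rel_gain < threshold)
  if (length(hit)) candidates[hit[1L]] else candidates[length(candidates)]
}

#' Select the analysis window length from the SNR plateau
#'
#' For each candidate window length, segments the recording, fits an order-`M`
#' Burg model per axis and window, and measures the SNR between the window
#' tail and its one-step predictions; SNR values are averaged across axes and
#' windows. The curve typically rises steeply and then evens out; the
#' selected length is the last candidate *before* the first relative gain
#' below `improvement_threshold` — the shortest window offering essentially
#' the same goodness of fit as longer ones, which is what a responsive
#' real-time classifier wants. If the curve keeps improving everywhere, the
#' largest candidate is selected.
#'
#' The reproduction compared against the original is the deterministic
#' one-step prediction sequence of the fitted model (sample-aligned with the
#' data); an independently simulated realization would not be comparable
#' sample-by-sample.
#'
#' @param rec an [accel_recording()] at least as long as the largest
#'   candidate.
#' @param candidates candidate window lengths in seconds (default 1..10 s).
#' @param order AR order fitted per axis (default 10).
#' @param improvement_threshold relative SNR-gain cutoff defining the
#'   plateau.
#' @return An object of class `snr_curve` with `window_lengths`,
#'   `snr_values`, `selected_window`.
#' @export
select_window_length <- function(rec, candidates = 1:10, order = 10L,
                                 improvement_threshold = 0.01) {
  stopifnot(inherits(rec, "accel_recording"))
  candidates <- sort(unique(as.numeric(candidates)))
  max_n <- round(max(candidates) * rec$sampling_rate)
  if (length(rec$time) < max_n) {
    stop_param("recording shorter than the largest candidate window")
  }
  min_n <- round(min(candidates) * rec$sampling_rate)
  if (min_n <= 2L * order) {
    stop_param("smallest candidate window (", min_n, " samples) cannot ",
               "support an order-", order, " fit; need > 2 * order samples")
  }
  snr_vals <- vapply(candidates, function(w) {
    wins <- segment_recording(rec, window_seconds = w)
    per_window <- vapply(wins, function(win) {
      ax <- vapply(1:3, function(j) {
        v <- win$samples[, j]
        fit <- fit_ar_burg(v, order)
        pred <- predict_one_step(fit, v)
        snr_db(v[(order + 1L):length(v)], pred$predictions)
      }, numeric(1))
      mean(ax)
    }, numeric(1))
    mean(per_window)
  }, numeric(1))

  selected <- plateau_select(candidates, snr_vals, improvement_threshold)
  structure(list(window_lengths = candidates, snr_values = snr_vals,
                 selected_window = selected),
            class = "snr_curve")
}

#' @export
print.snr_curve <- function(x, ...) {
  cat(sprintf("<snr_curve> selected window %.3g s\n", x$selected_window))
  print(data.frame(seconds = x$window_lengths, snr_db = round(x$snr_values, 3)))
  invisible(x)
}

#' Validate an AR model on held-out data via residual whiteness
#'
#' Computes one-step residuals of `model` on a held-out series (from a
#' different sample than the one the model was fitted on) and applies
#' [whiteness_test()]. A well-specified model leaves white residuals; an
#' under-specified one leaves structure behind.
#'
#' @param model an `ar_model`.
#' @param heldout numeric series (one axis of a held-out window).
#' @param lags_tested,threshold forwarded to [whiteness_test()].
#' @return A `whiteness_report`.
#' @export
validate_model <- function(model, heldout, lags_tested = 20L,
                           threshold = 0.10) {
  res <- predict_one_step(model, heldout)$residuals
  whiteness_test(res, lags_tested = lags_tested, threshold = threshold)
}

#' Extract the AR-coefficient feature vector of a window
#'
#' Fits an order-`p` Burg model to each axis and concatenates the predictor
#' coefficients in x-then-y-then-z order:
#' `[a_x1..a_xp, a_y1..a_yp, a_z1..a_zp]`, a `3p`-dimensional feature vector
#' (30 values for the default order 10).
#'
#' @param window a [signal_window()] with more than `2p` samples per axis.
#' @param order AR order `p` per axis (default 10).
#' @return An object of class `feature_vector` with `values` (length `3p`),
#'   `order` and the window's labels.
#' @export
extract_features <- function(window, order = 10L) {
  stopifnot(inherits(window, "signal_window"))
  vals <- unlist(lapply(1:3, function(j) {
    fit_ar_burg(window$samples[, j], order,
                axis = c("x", "y", "z")[j])$coefficients
  }), use.names = FALSE)
  structure(list(values = vals, order = as.integer(order),
                 activity = window$activity, position = window$position,
                 subject = window$subject),
            class = "feature_vector")
}
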