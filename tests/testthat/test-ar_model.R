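test_that("Burg fits recover generating coefficients and agree with the
           closed-form Yule-Walker oracle", {
  set.seed(10)
  x1 <- as.numeric(arima.sim(list(ar = 0.8), 1e4))
  f1 <- fit_ar_burg(x1, 1)
  expect_true(f1$coefficients > 0.77 && f1$coefficients < 0.83)
  # Yule-Walker closed form r1/r0 as independent oracle for AR(1)
  r <- autocorrelation(x1 - mean(x1), 1)$values
  expect_equal(f1$coefficients, r[2] / r[1], tolerance = 0.01)

  set.seed(11)
  x2 <- as.numeric(arima.sim(list(ar = c(1.2, -0.5)), 1e4))
  f2 <- fit_ar_burg(x2, 2)
  expect_lt(max(abs(f2$coefficients - c(1.2, -0.5))), 0.05)

  # white noise: true coefficient 0
  set.seed(12)
  fw <- fit_ar_burg(rnorm(1e4), 1)
  expect_lt(abs(fw$coefficients), 0.05)
})

test_that("Burg models are stable with reflection coefficients in (-1, 1)", {
  set.seed(13)
  for (i in 1:10) {
    x <- as.numeric(arima.sim(list(ar = c(1.2, -0.5)), 500))
    f <- fit_ar_burg(x, sample(1:12, 1))
    expect_true(all(abs(f$reflection) < 1))
    expect_true(all(Mod(polyroot(c(1, -f$coefficients))) > 1))
    expect_gte(f$innovation_variance, 0)
  }
  expect_error(fit_ar_burg(rep(1, 100), 2), "degenerate")
  expect_error(fit_ar_burg(rnorm(10), 5), "too short")
})

test_that("one-step predictions follow the AR recursion", {
  p <- predict_one_step(mk_ar(1), c(2, 2, 2))
  expect_equal(p$predictions, c(2, 2))
  expect_equal(p$residuals, c(0, 0))
  p0 <- predict_one_step(mk_ar(c(0, 0)), c(1, 2, 3, 4))
  expect_equal(p0$predictions, c(0, 0))
  expect_equal(p0$residuals, c(3, 4))
  ph <- predict_one_step(mk_ar(c(0.5, 0.25)), c(4, 2, 1))
  expect_equal(ph$predictions, 2)   # 0.5*2 + 0.25*4
  expect_equal(ph$residuals, -1)
  expect_error(predict_one_step(mk_ar(c(0.5, 0.25)), c(1, 2)), "longer")
})

test_that("simulation is seeded, respects sigma^2 = 0, and is stationary", {
  expect_equal(simulate_ar(mk_ar(0.5, 0), 10, seed = 1), rep(0, 10))
  expect_identical(simulate_ar(mk_ar(0.8), 100, seed = 7),
                   simulate_ar(mk_ar(0.8), 100, seed = 7))
  x <- simulate_ar(mk_ar(0.8, 1), 1e5, seed = 8)
  expect_equal(var(x), 1 / (1 - 0.64), tolerance = 0.05)
  expect_error(simulate_ar(mk_ar(1.1), 10, seed = 1), "unstable")
})

test_that("AIC combines the Gaussian likelihood with the parameter penalty", {
  expect_equal(aic_score(1, 100, 2), 100 * (log(2 * pi) + 1) + 4)
  # equal likelihood, one more parameter -> exactly +2
  expect_equal(aic_score(2.5, 64, 4) - aic_score(2.5, 64, 3), 2)
  # halving the residual variance lowers AIC by n log 2
  expect_equal(aic_score(1, 200, 3) - aic_score(0.5, 200, 3), 200 * log(2))
  expect_error(aic_score(0, 10, 1), "positive")
})

test_that("AIC order selection recovers the generating order", {
  sel <- vapply(1:20, function(s) {
    w <- with_seed_test(s, {
      m <- vapply(1:3, function(j) {
        as.numeric(arima.sim(list(ar = c(1.2, -0.5)), 2000))
      }, numeric(2000))
      signal_window(m, 20, 100)
    })
    select_order(list(w), 1:8, rule = "min")$selected_order
  }, 0L)
  expect_gte(mean(sel == 2L), 0.8)
  # single candidate is returned as-is
  w1 <- profile_window(make_default_profiles(10, 1)$walking, 400, 21)
  expect_identical(select_order(list(w1), 5)$selected_order, 5L)
  expect_error(select_order(list(), 1:5), "empty")
})

test_that("SNR follows its closed form and the plateau rule matches the
           hand-worked curve", {
  expect_identical(snr_db(c(1, 2), c(1, 2)), Inf)
  expect_equal(snr_db(c(1, 1), c(0, 0)), 0)
  expect_equal(snr_db(2, 1), 10 * log10(4))
  expect_error(snr_db(1:3, 1:2), "mismatch")
  # curve [5, 8, 8.05, 8.06] dB over 1..4 s at 1% threshold -> 2 s
  expect_equal(arhar:::plateau_select(1:4, c(5, 8, 8.05, 8.06), 0.01), 2)
  # strictly improving everywhere -> largest candidate
  expect_equal(arhar:::plateau_select(1:4, c(1, 2, 4, 8), 0.01), 4)
})

test_that("window-length selection runs on a recording and returns an
           aligned curve", {
  rec <- generate_recording(make_default_profiles(10, 1)$walking,
                            position_transform("identity"),
                            subject_seed = 30, duration = 40, jitter = 0)
  rec <- remove_gravity(rec)
  curve <- select_window_length(rec, candidates = 2:5, order = 10)
  expect_length(curve$snr_values, 4L)
  expect_true(curve$selected_window %in% curve$window_lengths)
  expect_true(all(is.finite(curve$snr_values)))
  expect_error(select_window_length(rec, candidates = c(2, 100)), "shorter")
  # a 1 s window at 20 Hz cannot carry an order-10 fit
  expect_error(select_window_length(rec, candidates = 1:3, order = 10),
               "support")
})

test_that("held-out whiteness validation separates matched from mismatched
           models", {
  prof <- make_default_profiles(10, 1)$walking
  gen <- mk_ar(prof$ar[[1]], prof$sigma2[1])
  fit <- fit_ar_burg(simulate_ar(gen, 4000, seed = 31), 10)
  expect_true(validate_model(fit, simulate_ar(gen, 500, seed = 32))$white)
  # order-1 misfit leaves structure in the residuals
  fit1 <- fit_ar_burg(simulate_ar(gen, 4000, seed = 31), 1)
  expect_false(validate_model(fit1, simulate_ar(gen, 500, seed = 32))$white)
  # constant residuals are degenerate, never white
  expect_false(validate_model(mk_ar(1), rep(3, 200))$white)
})

test_that("feature extraction concatenates per-axis coefficients
           deterministically", {
  w <- profile_window(make_default_profiles(10, 1)$running, 200, 33)
  f <- extract_features(w, order = 10)
  expect_length(f$values, 30L)
  expect_length(extract_features(w, order = 1)$values, 3L)
  expect_identical(f$values, extract_features(w, order = 10)$values)
  # axis blocks equal the per-axis Burg fits, x then y then z
  expect_equal(f$values[1:10], fit_ar_burg(w$samples[, 1], 10)$coefficients)
  expect_equal(f$values[21:30], fit_ar_burg(w$samples[, 3], 10)$coefficients)
  # windows generated by a known AR(2) recover the generating coefficients
  w2 <- with_seed_test(34, {
    m <- vapply(1:3, function(j) as.numeric(arima.sim(list(ar = c(1.2, -0.5)),
                                                      2000)), numeric(2000))
    signal_window(m, 20, 100)
  })
  f2 <- extract_features(w2, order = 2)
  expect_lt(max(abs(f2$values - rep(c(1.2, -0.5), 3))), 0.05)
})
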