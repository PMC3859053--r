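test_that("recordings round-trip through CSV bit-identically", {
  rec <- accel_recording(time = (0:59) / 20, x = rnorm(60), y = rnorm(60),
                         z = rnorm(60), activity = "walking",
                         position = "front-pocket-left", subject = "S1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  expect_identical(length(readLines(path)), 61L)  # header + 60 samples
  back <- read_recording(path)
  expect_identical(back$x, rec$x)
  expect_identical(back$y, rec$y)
  expect_identical(back$z, rec$z)
  expect_identical(back$time, rec$time)
  expect_equal(back$sampling_rate, 20)
  expect_identical(back$activity, "walking")
  expect_identical(back$subject, "S1")
})

test_that("sampling rate is inferred and label columns are optional", {
  rec <- accel_recording(time = c(0, 0.05, 0.10, 0.15), x = 1:4, y = 1:4,
                         z = 1:4)
  expect_equal(rec$sampling_rate, 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  header <- strsplit(readLines(path, 1L), ",")[[1]]
  expect_setequal(header, c("t", "x", "y", "z"))
  expect_null(read_recording(path)$activity)
})

test_that("invalid recordings are rejected", {
  t_ok <- (0:9) / 20
  expect_error(accel_recording(sample(t_ok), 1:10, 1:10, 1:10),
               "strictly increasing")
  expect_error(accel_recording(t_ok, 1:9, 1:10, 1:10), "match")
  # spacing inconsistent with declared rate
  expect_error(accel_recording(t_ok, 1:10, 1:10, 1:10, sampling_rate = 50),
               "spacing")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), path)
  expect_error(read_recording(path), "missing required columns")
})

test_that("gravity removal matches the filter recursion and kills constants", {
  rec <- accel_recording(time = (0:2) / 20, x = c(0, 1, 1), y = c(5, 5, 5),
                         z = c(-2, -2, -2))
  out <- remove_gravity(rec, alpha = 0.5)
  expect_equal(out$x, c(0, 0.5, 0.25))  # hand recursion: g = 0, 0.5, 0.75
  expect_equal(out$y, c(0, 0, 0))       # constant channel -> identically zero
  expect_equal(out$z, c(0, 0, 0))
  # alpha = 0 tracks instantly
  expect_equal(remove_gravity(rec, alpha = 0)$x, c(0, 0, 0))
  expect_error(remove_gravity(rec, alpha = 1), "alpha")
  expect_error(remove_gravity(rec, alpha = -0.1), "alpha")
  expect_identical(out$activity, rec$activity)
})

test_that("moving-average smoothing is causal with a prefix ramp", {
  rec <- accel_recording(time = (0:3) / 20, x = c(3, 6, 9, 12),
                         y = c(1, 1, 1, 1), z = c(0, 0, 0, 0))
  sm <- smooth_recording(rec, 3)
  expect_equal(sm$x, c(3, 4.5, 6, 9))
  expect_equal(sm$y, rec$y)  # constants unchanged
  expect_equal(smooth_recording(rec, 1)$x, rec$x)  # order 1 is the identity
  expect_error(smooth_recording(rec, 0), "order")
  # length preserved, output within the input range
  set.seed(1)
  r2 <- accel_recording(time = (0:99) / 20, x = rnorm(100), y = rnorm(100),
                        z = rnorm(100))
  s2 <- smooth_recording(r2, 3)
  expect_length(s2$x, 100L)
  expect_true(all(s2$x >= min(r2$x) & s2$x <= max(r2$x)))
})

test_that("segmentation yields 60-sample windows at 3 s / 20 Hz", {
  set.seed(2)
  rec <- accel_recording(time = (0:199) / 20, x = rnorm(200), y = rnorm(200),
                         z = rnorm(200), activity = "running")
  wins <- segment_recording(rec, window_seconds = 3)
  expect_length(wins, 3L)  # floor((200 - 60)/60) + 1
  expect_true(all(vapply(wins, function(w) nrow(w$samples), 0L) == 60L))
  expect_identical(wins[[1]]$activity, "running")
  # disjoint windows jointly covering a prefix
  expect_equal(do.call(rbind, lapply(wins, `[[`, "samples")),
               cbind(x = rec$x[1:180], y = rec$y[1:180], z = rec$z[1:180]))
  # shorter than one window -> empty list, not an error
  short <- accel_recording(time = (0:49) / 20, x = rnorm(50), y = rnorm(50),
                           z = rnorm(50))
  expect_identical(segment_recording(short, 3), list())
  # overlap halves the step
  expect_length(segment_recording(rec, 3, overlap_fraction = 0.5), 5L)
})
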