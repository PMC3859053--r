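test_that("default profiles are stable, seeded, and strongly autocorrelated", {
  p <- make_default_profiles(order = 10, seed = 1)
  expect_named(p, c("standing", "walking", "walking-upstairs",
                    "walking-downstairs", "running", "hopping"))
  for (prof in p) {
    for (a in prof$ar) {
      expect_length(a, 10L)
      expect_true(all(Mod(polyroot(c(1, -a))) > 1))
    }
    expect_true(all(prof$sigma2 > 0))
    expect_equal(sum(prof$gravity^2), 1)
  }
  expect_identical(make_default_profiles(10, 1), p)  # seeded determinism
  expect_false(identical(make_default_profiles(10, 2)$walking$ar, p$walking$ar))
  # movement signals carry the strong positive lag-1 signature
  s <- simulate_ar(mk_ar(p$walking$ar[[1]], p$walking$sigma2[1]), 2000,
                   seed = 60)
  expect_gt(autocorrelation(s, 1, normalized = TRUE, demean = TRUE)$values[2],
            0.5)
})

test_that("position transforms are validated and alter the signal but not
           the label", {
  expect_error(position_transform("bad", matrix(1, 3, 3)), "orthonormal")
  expect_error(position_transform("bad", diag(3), gain = c(1, -1, 1)), "gain")
  pos <- default_positions()
  expect_length(pos, 5L)
  for (p in pos) {
    expect_lt(max(abs(crossprod(p$rotation) - diag(3))), 1e-8)
  }
  prof <- make_default_profiles(10, 1)$walking
  r1 <- generate_recording(prof, pos[[1]], subject_seed = 61, duration = 10)
  r2 <- generate_recording(prof, pos[[5]], subject_seed = 61, duration = 10)
  expect_gt(max(abs(r1$x - r2$x)), 0)
  expect_identical(r1$activity, r2$activity)
  expect_false(identical(r1$position, r2$position))
})

test_that("generated recordings carry gravity plus an autocorrelated
           motion component", {
  prof <- make_default_profiles(10, 1)$walking
  rec <- generate_recording(prof, position_transform("identity"),
                            subject_seed = 62, duration = 30, jitter = 0)
  expect_identical(generate_recording(prof, position_transform("identity"),
                                      subject_seed = 62, duration = 30,
                                      jitter = 0)$x, rec$x)
  # channel means sit near the 9.81-scaled gravity orientation
  expect_equal(c(mean(rec$x), mean(rec$y), mean(rec$z)),
               9.81 * prof$gravity, tolerance = 0.5)
  lin <- remove_gravity(rec)
  expect_gt(autocorrelation(lin$x, 1, normalized = TRUE,
                            demean = TRUE)$values[2], 0.5)
  expect_error(generate_recording(prof, position_transform("identity"),
                                  1, duration = 0.5), "too short")
})

test_that("dataset generation is a seeded subject x activity x position
           product", {
  cfg <- small_config()
  corpus <- generate_dataset(cfg)
  expect_length(corpus, 2L * 3L * 2L)
  expect_identical(vapply(generate_dataset(cfg), `[[`, "", "subject"),
                   vapply(corpus, `[[`, "", "subject"))
  expect_identical(generate_dataset(cfg)[[5]]$x, corpus[[5]]$x)
  labs <- table(vapply(corpus, `[[`, "", "activity"))
  expect_true(all(labs == 4L))
  # disjoint subject ids under an offset
  off <- generate_dataset(small_config(subject_offset = 2))
  expect_length(intersect(unique(vapply(off, `[[`, "", "subject")),
                          unique(vapply(corpus, `[[`, "", "subject"))), 0L)
})

test_that("activities separate in feature space and positions inflate
           within-class scatter", {
  cfg0 <- generator_config(n_subjects = 1,
                           activities = c("standing", "walking", "running"),
                           positions = default_positions()[1], jitter = 0,
                           session_seconds = 30, seed = 3)
  feats <- function(corpus) {
    do.call(rbind, lapply(corpus, function(r) {
      do.call(rbind, lapply(segment_recording(smooth_recording(
        remove_gravity(r), 3), 3), function(w) extract_features(w, 10)$values))
    }))
  }
  labs <- function(corpus) {
    unlist(lapply(corpus, function(r)
      rep(r$activity, length(segment_recording(r, 3)))))
  }
  c0 <- generate_dataset(cfg0)
  X0 <- feats(c0); y0 <- labs(c0)
  D <- as.matrix(dist(X0))
  same <- outer(y0, y0, "==") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[(!outer(y0, y0, "==")) & upper.tri(D)]))

  # adding positions strictly inflates the within-class scatter trace
  cfg5 <- cfg0; cfg5$positions <- default_positions()
  X5 <- feats(generate_dataset(cfg5)); y5 <- labs(generate_dataset(cfg5))
  wtrace <- function(X, y) {
    sum(unlist(lapply(unique(y), function(k) {
      Xi <- X[y == k, , drop = FALSE]
      sum(scale(Xi, scale = FALSE)^2)
    }))) / nrow(X)
  }
  expect_gt(wtrace(X5, y5), wtrace(X0, y0))
})
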