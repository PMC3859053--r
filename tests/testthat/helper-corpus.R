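# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Plain AR model object for simulation in tests.
mk_ar <- function(coefficients, sigma2 = 1) {
  structure(list(order = length(coefficients),
                 coefficients = coefficients,
                 innovation_variance = sigma2),
            class = "ar_model")
}

# A triaxial window simulated from an activity profile.
profile_window <- function(profile, n, seed, sampling_rate = 20) {
  with_seed_test(seed, {
    m <- vapply(1:3, function(j) {
      simulate_ar(mk_ar(profile$ar[[j]], profile$sigma2[j]), n)
    }, numeric(n))
    signal_window(m, sampling_rate, n / sampling_rate)
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Small labeled corpus for fast pipeline tests: 2 subjects x 3 activities x
# 2 positions, 12 s sessions (4 windows each).
small_config <- function(seed = 5, subject_offset = 0) {
  generator_config(
    n_subjects = 2, activities = c("standing", "walking", "running"),
    positions = default_positions()[c(1, 5)], session_seconds = 12,
    seed = seed, subject_offset = subject_offset)
}

small_train_corpus <- function() memo("small_train", generate_dataset(small_config()))
small_eval_corpus <- function() {
  memo("small_eval", generate_dataset(small_config(subject_offset = 2)))
}
small_bundle <- function() {
  memo("small_bundle",
       train_pipeline(small_train_corpus(), har_config(seed = 5, epochs = 300)))
}

# Full-protocol corpora for the end-to-end checks: 5 training and 3 held-out
# subjects, 6 activities, 5 positions, 30 s sessions.
full_train_corpus <- function() {
  memo("full_train", generate_dataset(generator_config(n_subjects = 5, seed = 11)))
}
full_eval_corpus <- function() {
  memo("full_eval",
       generate_dataset(generator_config(n_subjects = 3, seed = 11,
                                         subject_offset = 5)))
}

# KDA ablation on the full corpora, computed once and shared by the
# position-variance and end-to-end checks.
full_ablation <- function() {
  memo("full_ablation",
       ablate_kda(har_config(seed = 11), full_train_corpus(),
                  full_eval_corpus(), subject_independent = TRUE))
}
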