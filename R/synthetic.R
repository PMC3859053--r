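# Synthetic corpus generator: labeled multi-subject, multi-position triaxial
# recordings with the statistical structure the analysis pipeline assumes —
# strongly positively autocorrelated per-activity AR processes plus a gravity
# offset, with phone-position effects that inflate within-class variance.

har_activities <- function() {
  c("standing", "walking", "walking-upstairs", "walking-downstairs",
    "running", "hopping")
}

#' Construct an activity profile
#'
#' An activity profile is the generative description of one activity: a
#' stable AR process per axis (coefficients + innovation variance) and the
#' gravity orientation of the phone during that activity.
#'
#' @param name activity name.
#' @param ar list of 3 coefficient vectors (axes x, y, z), each a stable AR
#'   process.
#' @param sigma2 numeric length-3 innovation variances, all > 0.
#' @param gravity unit 3-vector; the gravity component is
#'   `9.81 * gravity` in device coordinates.
#' @return An object of class `activity_profile`.
#' @export
activity_profile <- function(name, ar, sigma2, gravity) {
  stopifnot(length(ar) == 3L, length(sigma2) == 3L, length(gravity) == 3L)
  if (any(sigma2 <= 0)) stop_param("innovation variances must be positive")
  for (a in ar) {
    if (!ar_is_stable(a)) stop_data("unstable AR process in profile '", name, "'")
  }
  gravity <- gravity / sqrt(sum(gravity^2))
  structure(list(name = name, ar = ar, sigma2 = as.numeric(sigma2),
                 gravity = as.numeric(gravity), order = length(ar[[1L]])),
            class = "activity_profile")
}

# AR coefficients from pole pairs: A(z) = prod (1 - 2 rho cos(theta) z + rho^2 z^2)
# (optionally times a real pole), returned in predictor convention.
ar_from_poles <- function(moduli, angles, real_pole = NULL) {
  poly <- 1
  for (i in seq_along(moduli)) {
    quad <- c(1, -2 * moduli[i] * cos(angles[i]), moduli[i]^2)
    poly <- convolve_poly(poly, quad)
  }
  if (!is.null(real_pole)) poly <- convolve_poly(poly, c(1, -real_pole))
  -poly[-1L]
}

convolve_poly <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) out[i:(i + length(q) - 1L)] <-
      out[i:(i + length(q) - 1L)] + p[i] * q
  out
}

#' Build the default activity profiles
#'
#' One profile per activity (standing, walking, walking-upstairs,
#' walking-downstairs, running, hopping), each an order-`order` AR process
#' per axis built by pole placement: a dominant, lightly damped conjugate
#' pole pair at an activity-specific cadence frequency (slightly offset per
#' axis) plus weaker background pairs. Standing is modeled as low-power,
#' near-white postural sway; the locomotion activities have strong
#' periodicity and higher power, running/hopping the most. All processes are
#' stable by construction, and their realizations show the strong positive
#' lag-1 autocorrelation that motivates AR-coefficient features.
#'
#' @param order AR order per axis (default 10; must be >= 2).
#' @param seed integer seed; profiles are deterministic given it.
#' @param sampling_rate Hz used to convert cadence frequencies to pole
#'   angles (default 20).
#' @return Named list of [activity_profile()] objects.
#' @export
make_default_profiles <- function(order = 10L, seed = 1L, sampling_rate = 20) {
  if (order < 2L) stop_param("order must be >= 2")
  order <- as.integer(order)
  defs <- list(
    standing             = list(f = 0.4, rho = 0.55, s2 = 0.004,
                                g = c(0.05, 0.02, 1)),
    walking              = list(f = 1.0, rho = 0.97, s2 = 0.25,
                                g = c(0.15, 0.05, 0.99)),
    `walking-upstairs`   = list(f = 0.7, rho = 0.96, s2 = 0.25,
                                g = c(0.25, 0.05, 0.95)),
    `walking-downstairs` = list(f = 1.4, rho = 0.96, s2 = 0.30,
                                g = c(-0.20, 0.10, 0.95)),
    running              = list(f = 2.3, rho = 0.97, s2 = 0.70,
                                g = c(0.30, -0.05, 0.95)),
    hopping              = list(f = 3.1, rho = 0.975, s2 = 0.90,
                                g = c(0.05, 0.25, 0.95))
  )
  npairs <- order %/% 2L
  odd <- order %% 2L == 1L
  with_seed(seed, {
    profiles <- lapply(names(defs), function(nm) {
      p <- defs[[nm]]
      ar <- lapply(1:3, function(axis) {
        # dominant cadence pair, slightly detuned per axis
        theta_dom <- 2 * pi * (p$f * stats::runif(1, 0.92, 1.08)) / sampling_rate
        moduli <- c(p$rho, stats::runif(npairs - 1L, 0.55, 0.80))
        angles <- c(theta_dom, stats::runif(npairs - 1L, 0.2, pi - 0.2))
        real_pole <- if (odd) stats::runif(1, -0.4, 0.4) else NULL
        ar_from_poles(moduli, angles, real_pole)
      })
      s2 <- p$s2 * stats::runif(3, 0.8, 1.2)
      activity_profile(nm, ar, s2, p$g)
    })
    names(profiles) <- names(defs)
    profiles
  })
}

rot_about <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, byrow = TRUE),
         y = matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, byrow = TRUE),
         z = matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, byrow = TRUE))
}

#' Construct a phone-position transform
#'
#' A position transform models how carrying the phone in a different pocket
#' changes the recorded signal for the same activity: a rotation of the
#' device axes, a per-axis gain, and a per-axis constant offset. These
#' transforms create the position-induced within-class variance that the
#' kernel discriminant step is designed to suppress.
#'
#' @param name position name.
#' @param rotation 3 x 3 orthonormal matrix (checked to 1e-8).
#' @param gain per-axis positive scale factors.
#' @param offset per-axis constant offsets.
#' @return An object of class `position_transform`.
#' @export
position_transform <- function(name, rotation = diag(3), gain = c(1, 1, 1),
                               offset = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop_param("rotation must be orthonormal (within 1e-8)")
  }
  if (any(gain <= 0)) stop_param("gains must be positive")
  structure(list(name = name, rotation = rotation, gain = as.numeric(gain),
                 offset = as.numeric(offset)),
            class = "position_transform")
}

#' Default phone placements
#'
#' Five pocket placements (both front trouser pockets, both back trouser
#' pockets, jacket inner pocket) with fixed, increasingly different
#' rotations, gains and offsets.
#'
#' @return Named list of [position_transform()] objects.
#' @export
default_positions <- function() {
  ps <- list(
    position_transform("front-pocket-left",
                       rot_about("z", 8) %*% rot_about("x", 5),
                       c(1.00, 1.00, 1.00), c(0.15, 0.00, 0.10)),
    position_transform("front-pocket-right",
                       rot_about("z", -12) %*% rot_about("y", 9),
                       c(1.05, 0.95, 1.00), c(-0.20, 0.10, 0.00)),
    position_transform("back-pocket-left",
                       rot_about("x", 35) %*% rot_about("z", 18),
                       c(0.95, 1.05, 1.00), c(0.10, -0.25, 0.20)),
    position_transform("back-pocket-right",
                       rot_about("x", -32) %*% rot_about("z", -24),
                       c(1.10, 0.90, 1.05), c(0.00, 0.30, -0.20)),
    position_transform("jacket-inner-pocket",
                       rot_about("y", 55) %*% rot_about("z", 40),
                       c(0.90, 1.00, 1.10), c(0.40, 0.20, -0.30))
  )
  names(ps) <- vapply(ps, `[[`, "", "name")
  ps
}

# Reflect any pole of A(z) = 1 - sum a_i z^i that falls on or inside the unit
# circle back outside it, keeping conjugate symmetry, and rebuild the
# coefficients. min_mod keeps a stability margin.
re_stabilize <- function(a, min_mod = 1.02) {
  roots <- polyroot(c(1, -a))
  mods <- Mod(roots)
  bad <- mods < min_mod
  if (!any(bad)) return(a)
  roots[bad] <- roots[bad] / mods[bad]^2              # reflect inside -> outside
  mods <- Mod(roots)
  push <- mods < min_mod
  roots[push] <- roots[push] * (min_mod / mods[push]) # enforce margin
  poly <- 1
  for (r in roots) poly <- convolve_poly(poly, c(1, -1 / r))
  a_new <- -Re(poly[-1L])
  if (!ar_is_stable(a_new)) stop_data("re-stabilization failed")
  a_new
}

#' Generate one synthetic recording
#'
#' Simulates the profile's per-axis AR process (with the subject's
#' multiplicative coefficient jitter, re-stabilized if the perturbation
#' pushes a pole toward the unit circle), applies the position transform
#' (rotation, gain, offset), and adds the gravity component
#' `9.81 * profile$gravity`. Labels (activity, position, subject) are
#' attached.
#'
#' @param profile an [activity_profile()].
#' @param position a [position_transform()].
#' @param subject_seed integer seed; the recording is deterministic given
#'   it.
#' @param duration session length in seconds.
#' @param sampling_rate Hz (default 20).
#' @param jitter relative coefficient perturbation s.d. modeling
#'   between-subject variation (default 0.05).
#' @param subject subject identifier label.
#' @return An [accel_recording()].
#' @export
generate_recording <- function(profile, position, subject_seed,
                               duration = 30, sampling_rate = 20,
                               jitter = 0.05, subject = NULL) {
  stopifnot(inherits(profile, "activity_profile"),
            inherits(position, "position_transform"))
  if (jitter < 0) stop_param("jitter must be >= 0")
  n <- round(duration * sampling_rate)
  if (n < 2L * profile$order) stop_param("duration too short for the AR order")
  with_seed(subject_seed, {
    motion <- vapply(1:3, function(axis) {
      a <- profile$ar[[axis]]
      if (jitter > 0) {
        a <- re_stabilize(a * (1 + jitter * stats::rnorm(length(a))))
      }
      model <- structure(list(order = length(a), coefficients = a,
                              innovation_variance = profile$sigma2[axis]),
                         class = "ar_model")
      simulate_ar(model, n)
    }, numeric(n))
    out <- sweep(motion %*% t(position$rotation), 2, position$gain, "*")
    out <- sweep(out, 2, position$offset + 9.81 * profile$gravity, "+")
    accel_recording(time = (seq_len(n) - 1L) / sampling_rate,
                    x = out[, 1L], y = out[, 2L], z = out[, 3L],
                    sampling_rate = sampling_rate,
                    activity = profile$name, position = position$name,
                    subject = subject)
  })
}

#' Generator configuration
#'
#' @param n_subjects number of subjects.
#' @param activities activity names (subset of the 6 defaults).
#' @param positions list of [position_transform()]s (default the 5 pocket
#'   placements).
#' @param sampling_rate Hz (default 20).
#' @param session_seconds length of each recording session (default 30 s,
#'   i.e. ten 3-s windows).
#' @param order AR order of the generating processes (default 10).
#' @param jitter between-subject coefficient jitter (default 5%).
#' @param seed master seed; all per-recording seeds derive from it.
#' @param subject_offset starting index for subject ids (use a nonzero
#'   offset to generate evaluation subjects disjoint from training ones).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects = 5L, activities = har_activities(),
                             positions = default_positions(),
                             sampling_rate = 20, session_seconds = 30,
                             order = 10L, jitter = 0.05, seed = 1L,
                             subject_offset = 0L) {
  if (n_subjects < 1L || !length(activities) || !length(positions)) {
    stop_param("counts must be >= 1")
  }
  structure(list(n_subjects = as.integer(n_subjects), activities = activities,
                 positions = positions, sampling_rate = sampling_rate,
                 session_seconds = session_seconds, order = as.integer(order),
                 jitter = jitter, seed = as.integer(seed),
                 subject_offset = as.integer(subject_offset)),
            class = "generator_config")
}

#' Generate a labeled synthetic corpus
#'
#' Produces one recording per subject x activity x position combination.
#' Per-recording seeds are derived deterministically from the master seed,
#' so the whole corpus is reproducible.
#'
#' @param config a [generator_config()].
#' @return List of [accel_recording()]s of length
#'   `n_subjects * length(activities) * length(positions)`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  profiles <- make_default_profiles(order = config$order, seed = config$seed,
                                    sampling_rate = config$sampling_rate)
  missing_acts <- setdiff(config$activities, names(profiles))
  if (length(missing_acts)) {
    stop_param("unknown activities: ", paste(missing_acts, collapse = ", "))
  }
  grid <- expand.grid(subject = seq_len(config$n_subjects),
                      activity = config$activities,
                      position = seq_along(config$positions),
                      stringsAsFactors = FALSE)
  seeds <- derive_seeds(config$seed + 7L * config$subject_offset, nrow(grid))
  lapply(seq_len(nrow(grid)), function(i) {
    generate_recording(
      profiles[[grid$activity[i]]],
      config$positions[[grid$position[i]]],
      subject_seed = seeds[i],
      duration = config$session_seconds,
      sampling_rate = config$sampling_rate,
      jitter = config$jitter,
      subject = paste0("S", config$subject_offset + grid$subject[i])
    )
  })
}
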