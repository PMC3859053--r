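#' Construct a triaxial accelerometer recording
#'
#' An `accel_recording` holds a timestamped triaxial acceleration signal plus
#' optional activity/position/subject annotations. It is the unit that the
#' preprocessing, segmentation and synthetic-generation functions operate on.
#'
#' @param time numeric vector of timestamps in seconds, strictly increasing,
#'   with inter-sample spacing within 10% of `1/sampling_rate`.
#' @param x,y,z numeric channels (device acceleration units, e.g. m/s^2), all
#'   the same length as `time`.
#' @param sampling_rate sampling frequency in Hz. If `NULL`, inferred as the
#'   reciprocal of the median timestamp spacing.
#' @param activity,position,subject optional scalar labels carried through the
#'   pipeline (activity class, phone placement, subject identifier).
#' @return An object of class `accel_recording`.
#' @export
accel_recording <- function(time, x, y, z, sampling_rate = NULL,
                            activity = NULL, position = NULL, subject = NULL) {
  n <- length(time)
  if (n < 2L) stop_data("a recording needs at least 2 samples")
  if (length(x) != n || length(y) != n || length(z) != n) {
    stop_data("channels x, y, z must match the timestamp length")
  }
  if (anyNA(time) || anyNA(x) || anyNA(y) || anyNA(z)) {
    stop_data("recording contains missing values")
  }
  dt <- diff(time)
  if (any(dt <= 0)) stop_data("timestamps must be strictly increasing")
  if (is.null(sampling_rate)) sampling_rate <- 1 / stats::median(dt)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop_param("sampling_rate must be positive")
  }
  nominal <- 1 / sampling_rate
  if (any(abs(dt - nominal) > 0.1 * nominal)) {
    stop_data("inter-sample spacing deviates more than 10% from 1/sampling_rate")
  }
  structure(
    list(time = as.numeric(time), x = as.numeric(x), y = as.numeric(y),
         z = as.numeric(z), sampling_rate = as.numeric(sampling_rate),
         activity = activity, position = position, subject = subject),
    class = "accel_recording"
  )
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> %d samples @ %.4g Hz (%.3g s)\n",
              length(x$time), x$sampling_rate,
              length(x$time) / x$sampling_rate))
  lab <- c(activity = x$activity, position = x$position, subject = x$subject)
  if (length(lab)) {
    cat("  labels:", paste(names(lab), unlist(lab), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.accel_recording <- function(x) length(x$time)

# Replace the three channels of a recording, keeping time/rate/labels.
replace_channels <- function(rec, x, y, z) {
  rec$x <- as.numeric(x); rec$y <- as.numeric(y); rec$z <- as.numeric(z)
  rec
}

default_dialect <- function() {
  list(time = "t", x = "x", y = "y", z = "z",
       activity = "activity", position = "position", subject = "subject")
}

#' Read an accelerometer recording from delimited text
#'
#' Reads a CSV file whose columns are mapped through `dialect` (default names
#' `t,x,y,z` plus optional `activity,position,subject`). The sampling rate is
#' inferred from the median timestamp spacing unless given.
#'
#' @param path file path to a CSV with a header row.
#' @param dialect named list mapping the roles `time,x,y,z` (required) and
#'   `activity,position,subject` (optional) to column names.
#' @param sampling_rate optional declared sampling rate in Hz.
#' @return An [accel_recording()].
#' @export
read_recording <- function(path, dialect = default_dialect(),
                           sampling_rate = NULL) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  d <- utils::modifyList(default_dialect(), dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- unlist(d[c("time", "x", "y", "z")])
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_format("missing required columns: ",
                                paste(miss, collapse = ", "))
  if (nrow(df) < 2L) stop_format("recording file needs at least 2 data rows")
  grab <- function(role) {
    col <- d[[role]]
    if (!is.null(col) && col %in% names(df)) df[[col]][1L] else NULL
  }
  accel_recording(
    time = df[[d$time]], x = df[[d$x]], y = df[[d$y]], z = df[[d$z]],
    sampling_rate = sampling_rate,
    activity = grab("activity"), position = grab("position"),
    subject = grab("subject")
  )
}

#' Write an accelerometer recording to delimited text
#'
#' Writes a header + one row per sample; numeric values use 17 significant
#' digits so that `read_recording(write_recording(rec))` reproduces the
#' recording bit-identically. Label columns are emitted only when present.
#'
#' @param rec an [accel_recording()].
#' @param path output file path.
#' @param dialect column-name mapping, as in [read_recording()].
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = default_dialect()) {
  stopifnot(inherits(rec, "accel_recording"))
  d <- utils::modifyList(default_dialect(), dialect)
  fmt <- function(v) sprintf("%.17g", v)
  cols <- list(fmt(rec$time), fmt(rec$x), fmt(rec$y), fmt(rec$z))
  names(cols) <- c(d$time, d$x, d$y, d$z)
  for (role in c("activity", "position", "subject")) {
    if (!is.null(rec[[role]])) {
      cols[[d[[role]]]] <- rep(as.character(rec[[role]]), length(rec$time))
    }
  }
  out <- tryCatch(file(path, "w"), error = function(e)
    stop_format("cannot open for writing: ", path))
  on.exit(close(out))
  writeLines(paste(names(cols), collapse = ","), out)
  writeLines(do.call(paste, c(cols, sep = ",")), out)
  invisible(path)
}
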