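# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_param <- function(...) {
  stop(structure(class = c("arhar_parameter_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stop_data <- function(...) {
  stop(structure(class = c("arhar_data_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stop_format <- function(...) {
  stop(structure(class = c("arhar_format_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

# Lossless double <-> string conversion for JSON persistence: 17 significant
# digits round-trip IEEE doubles exactly, which jsonlite's numeric output
# does not guarantee.
num_to_chr <- function(x) sprintf("%.17g", as.numeric(x))
chr_to_num <- function(x) as.numeric(x)

# Derive a stream of valid 32-bit seeds from a master seed, deterministically.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}
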