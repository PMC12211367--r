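# Internal helpers shared across modules.

abort_eq <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "exoquality_error"), ...)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so no hidden global state leaks out of seeded operations.
with_seed_local <- function(seed, code) {
  if (!is.null(seed)) {
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
    set.seed(seed)
  }
  force(code)
}

# Counter-based child seeds derived from a master seed; reproducible
# independent streams for repeated simulation runs.
spawn_seeds <- function(seed, n) {
  with_seed_local(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    abort_eq(
      sprintf("`%s` must be a single integer >= %d.", name, min),
      "exoquality_config_error"
    )
  }
  invisible(as.integer(x))
}

# Write a file atomically: the writer callback receives a temporary path in
# the same directory, which is renamed into place only on success.
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    abort_eq(sprintf("Could not write '%s'.", path), "exoquality_io_error")
  }
  invisible(path)
}
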