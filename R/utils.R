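#' @keywords internal
"_PACKAGE"

# Derive a reproducible sub-seed from a master seed and a stage label, so the
# draws of one stage do not perturb another's when stages are added or
# reordered. Plain 32-bit arithmetic; stays below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

# Run an expression with a locally-set RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
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
  expr
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_probability <- function(x, field, n = NULL) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_field(field, "must be probabilities in [0, 1]")
  }
  if (!is.null(n) && length(x) != n) {
    stop_field(field, sprintf("must have length %d", n))
  }
  invisible(x)
}

check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || anyNA(x) || any(x != floor(x)) || any(x < min)) {
    stop_field(field, sprintf("must be integer(s) >= %d", min))
  }
  invisible(x)
}
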