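# internal validation helpers

stop_if_not_scalar_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single finite %s number, got %s.",
      name, if (strict) "positive" else "non-negative",
      paste(utils::capture.output(str(x)), collapse = " ")
    ))
  }
  invisible(x)
}

# seconds of the sample clock for a recording tibble
recording_rate <- function(recording) {
  r <- attr(recording, "sampling_rate_hz")
  if (is.null(r)) {
    dt <- diff(recording$time_s)
    r <- 1 / stats::median(dt)
  }
  r
}

recording_span <- function(recording) {
  range(recording$time_s)
}

# local RNG scope: restores .Random.seed on exit
with_seed <- function(seed, code) {
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
  force(code)
}
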