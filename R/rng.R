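#' Derive a reproducible child seed from a master seed and a label
#'
#' All randomness in the simulator flows from a single master seed; every
#' component (waveform pool, client training streams, probe subsampling,
#' k-means restarts, ...) draws from its own child seed derived here, so that
#' any output is a pure function of `(config, seed)` and independent of the
#' order in which components run.
#'
#' @param seed master integer seed
#' @param ... labels (strings or integers) identifying the consumer stream
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()]
#' @export
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(parts)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
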