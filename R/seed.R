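#' Derive a reproducible child seed for a named stream
#'
#' All stochastic stages of the pipeline draw from named child streams of a
#' single master seed, so that any one stage can be re-run in isolation and
#' reproduce its draws exactly. The child seed is a small deterministic hash
#' of the master seed and the stream name.
#'
#' @param seed Integer master seed.
#' @param stream Character stream name (e.g. `"meiosis"`, `"poolseq:S"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1L, "meiosis")
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1, keeps arithmetic exact in doubles
  h <- as.double(abs(seed)) %% m
  for (b in utf8ToInt(stream)) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h)
}

# Evaluate expr with the RNG seeded from a named child stream, restoring the
# caller's RNG state afterwards.
with_stream <- function(seed, stream, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(child_seed(seed, stream))
  expr
}
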